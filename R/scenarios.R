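#' Count and percentage of values strictly below a threshold
#'
#' @param values Non-empty numeric vector.
#' @param threshold Numeric cut-off; strictly-below counts (a value equal to
#'   the threshold does not).
#' @return A list with `count` and `percent` (100 * count / n, rounded
#'   half-up to one decimal).
#' @examples
#' proportion_below(c(12.99, 13.00), 13) # 1 of 2, 50.0%
#' @export
proportion_below <- function(values, threshold) {
  stopifnot(length(values) >= 1)
  count <- sum(values < threshold, na.rm = TRUE)
  list(count = count, percent = round_half_up(100 * count / length(values), 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over the hypergeometric
#' distribution with the table's margins fixed, the probabilities of all
#' tables no more probable than the observed one. Probabilities are computed
#' in log space via `lgamma`, so counts in the hundreds of thousands are
#' handled without overflow.
#'
#' @param a,b,c,d Cell counts, rows = group and columns = outcome
#'   (`a`,`b` = row 1; `c`,`d` = row 2). Alternatively pass a 2x2 matrix
#'   as `a`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(5, 5, 5, 5) # 1
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == floor(cells)))
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  col2 <- b + d
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    stop_fhirprep("Fisher exact test undefined: zero margin",
      class = "fhirprep_degenerate_table"
    )
  }
  n <- row1 + row2
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  k <- max(0, col1 - row2):min(row1, col1)
  logp <- lchoose2(row1, k) + lchoose2(row2, col1 - k) - lchoose2(n, col1)
  logp_obs <- lchoose2(row1, a) + lchoose2(row2, col1 - a) - lchoose2(n, col1)
  # relative tolerance guards against ties lost to floating point
  p <- sum(exp(logp[logp <= logp_obs + log1p(1e-7)]))
  min(p, 1)
}

store_hash <- function(store) {
  tmp <- tempfile(fileext = ".ndjson")
  on.exit(unlink(tmp))
  writeLines(store$resources$json, tmp, useBytes = TRUE)
  unname(tools::md5sum(tmp))
}

spec_hash <- function(spec) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(spec_to_json(spec), tmp)
  unname(tools::md5sum(tmp))
}

new_scenario_report <- function(scenario, groups, tests, provenance) {
  structure(
    list(
      scenario = scenario, groups = groups, tests = tests,
      provenance = provenance
    ),
    class = "fhir_scenario_report"
  )
}

#' @export
print.fhir_scenario_report <- function(x, ...) {
  cat("<fhir_scenario_report> ", x$scenario, "\n", sep = "")
  print(x$groups)
  if (!is.null(x$tests) && nrow(x$tests)) print(x$tests)
  invisible(x)
}

#' Anemia prevalence in patients with and without malignancy
#'
#' For each gender, takes every patient's minimum hemoglobin (LOINC 718-7),
#' splits patients by whether an ICD-10 `C*` condition was ever recorded
#' (include-ever vs exclude-ever criterion), restricts to adults (completed
#' age >= 18 at the time of the minimum), and counts patients below the WHO
#' anemia thresholds: 13 g/dL for men, 12 g/dL for women. Group differences
#' are tested per gender with the Fisher exact test; when a group is empty
#' (e.g. a store without Condition resources) the test is skipped.
#'
#' @param store A [fhir_store()].
#' @return A `fhir_scenario_report` with one group row per
#'   gender x malignancy status (`n_patients`, `n_anemic`, `pct_anemic`
#'   rounded half-up to one decimal) and one Fisher test row per gender.
#' @export
run_anemia_scenario <- function(store) {
  thresholds <- c(male = 13, female = 12)
  hgb <- code_selector("718-7", system = "http://loinc.org")
  groups <- list()
  for (g in c("male", "female")) {
    for (cancer in c(TRUE, FALSE)) {
      spec <- filter_spec(
        base = base_selector("Observation", hgb, genders = g),
        criteria = list(criterion(
          if (cancer) "include" else "exclude",
          "Condition", code_selector("C", match = "prefix")
        )),
        feature_set = feature_spec("min_per_patient")
      )
      ft <- extract_features(store, spec)
      ft <- ft[!is.na(ft$age) & ft$age >= 18 & !is.na(ft$value), , drop = FALSE]
      pb <- if (nrow(ft)) {
        proportion_below(ft$value, thresholds[[g]])
      } else {
        list(count = 0L, percent = NA_real_)
      }
      groups[[length(groups) + 1L]] <- tibble::tibble(
        gender = g, cancer = cancer,
        n_patients = nrow(ft), n_anemic = pb$count,
        pct_anemic = pb$percent
      )
    }
  }
  groups <- dplyr::bind_rows(groups)
  tests <- list()
  for (g in c("male", "female")) {
    gc <- groups[groups$gender == g & groups$cancer, ]
    gn <- groups[groups$gender == g & !groups$cancer, ]
    p <- if (gc$n_patients > 0 && gn$n_patients > 0) {
      tryCatch(
        fisher_exact(
          gc$n_anemic, gc$n_patients - gc$n_anemic,
          gn$n_anemic, gn$n_patients - gn$n_anemic
        ),
        fhirprep_degenerate_table = function(e) NA_real_
      )
    } else {
      NA_real_
    }
    tests[[g]] <- tibble::tibble(
      gender = g, test = "fisher_exact", p_value = p,
      skipped = is.na(p)
    )
  }
  new_scenario_report(
    "anemia_cancer", groups, dplyr::bind_rows(tests),
    list(store_hash = store_hash(store))
  )
}

#' Compute the anemia report directly from published group counts
#'
#' The same proportion arithmetic and Fisher tests as
#' [run_anemia_scenario()], but fed with pre-tabulated per-group counts
#' rather than a resource store — useful to reanalyse published contingency
#' data.
#'
#' @param counts A tibble like [example_anemia_counts()]: columns `gender`,
#'   `cancer`, `n_patients`, `n_anemic`.
#' @return A `fhir_scenario_report`.
#' @export
anemia_report_from_counts <- function(counts) {
  groups <- dplyr::mutate(
    counts,
    pct_anemic = round_half_up(100 * .data$n_anemic / .data$n_patients, 1)
  )
  tests <- lapply(unique(groups$gender), function(g) {
    gc <- groups[groups$gender == g & groups$cancer, ]
    gn <- groups[groups$gender == g & !groups$cancer, ]
    tibble::tibble(
      gender = g, test = "fisher_exact",
      p_value = fisher_exact(
        gc$n_anemic, gc$n_patients - gc$n_anemic,
        gn$n_anemic, gn$n_patients - gn$n_anemic
      ),
      skipped = FALSE
    )
  })
  new_scenario_report(
    "anemia_cancer_counts", groups, dplyr::bind_rows(tests),
    list(source = "tabulated counts")
  )
}

#' Published group counts for the anemia example
#'
#' Adult patients with a hemoglobin minimum on record in a three-year
#' tertiary-care dataset, split by gender and malignancy status, with the
#' number anemic by WHO thresholds (13 g/dL men, 12 g/dL women):
#' 9,075 men and 9,035 women with cancer (6,316 and 5,674 anemic) versus
#' 45,766 men and 53,777 women without (16,247 and 22,586 anemic).
#'
#' @return A tibble with columns `gender`, `cancer`, `n_patients`,
#'   `n_anemic`.
#' @export
example_anemia_counts <- function() {
  tibble::tibble(
    gender = c("male", "female", "male", "female"),
    cancer = c(TRUE, TRUE, FALSE, FALSE),
    n_patients = c(9075L, 9035L, 45766L, 53777L),
    n_anemic = c(6316L, 5674L, 16247L, 22586L)
  )
}

#' Prepare a hemoglobin dataset for indirect reference-interval estimation
#'
#' Runs the built-in `reference_interval_prep` specification: hemoglobin in
#' men aged 18-65, excluding patients ever diagnosed with a malignancy
#' (ICD-10 `C*`), ever transfused (OPS `8-80*`), ever showing hemoglobin
#' below 8.0 g/dL, or operated on (OPS `5-*`) within 90 days of the
#' measurement, then one random finding per patient. The returned interval
#' is a naive percentile band — the 2.5th and 97.5th percentiles of the
#' surviving values — intended as a demonstration stand-in, not an indirect
#' mixture-deconvolution estimate; the feature table is the dataset such an
#' algorithm would consume.
#'
#' @param store A [fhir_store()].
#' @param seed Integer seed for the per-patient random draw.
#' @return A `fhir_ri_prep`: list with `features` (the feature table),
#'   `ri` (named lower/upper naive percentile bounds), `n`, `method`, and
#'   `provenance`.
#' @export
run_reference_interval_prep <- function(store, seed = 1L) {
  spec <- builtin_specs()$reference_interval_prep
  spec$feature_set <- feature_spec("random_one_per_patient",
    random_seed = seed
  )
  ft <- extract_features(store, spec)
  vals <- ft$value[!is.na(ft$value)]
  ri <- if (length(vals) >= 2) {
    stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      features = ft,
      ri = c(lower = ri[1], upper = ri[2]),
      n = nrow(ft),
      method = "naive 2.5/97.5 percentile band (demonstration stand-in)",
      provenance = list(
        spec_hash = spec_hash(spec), store_hash = store_hash(store),
        seed = as.integer(seed)
      )
    ),
    class = "fhir_ri_prep"
  )
}

#' @export
print.fhir_ri_prep <- function(x, ...) {
  cat("<fhir_ri_prep> n = ", x$n, " patients\n", sep = "")
  cat(sprintf("  naive interval: %.1f - %.1f\n", x$ri["lower"], x$ri["upper"]))
  cat("  method:", x$method, "\n")
  invisible(x)
}

#' Potassium under liposomal amphotericin B
#'
#' Study group: potassium observations (LOINC 2823-3) lying within 7 days
#' (either side, closed) of an amphotericin B administration (OPS
#' `6-002.q*`), via a window-mode inclusion criterion. Control group:
#' potassium observations of patients who received the drug at some time
#' but contribute no observation to the study group — the patient-level set
#' difference is applied first, then those patients' observations are
#' collected, so the two groups share no patient. Group means are compared
#' with Welch's two-sided two-sample t-test.
#'
#' @param store A [fhir_store()].
#' @return A `fhir_scenario_report` with per-group `n_patients`,
#'   `n_results`, `mean_value` (rounded half-up to one decimal) and
#'   `mean_raw`, plus the t-test row.
#' @export
run_drug_scenario <- function(store) {
  specs <- builtin_specs()
  study_spec <- specs$amphotericin_potassium
  ever_spec <- study_spec
  ever_spec$criteria <- list(criterion(
    "include", "Procedure", code_selector("6-002.q", match = "prefix")
  ))
  study_ft <- extract_features(store, study_spec)
  ever_ft <- extract_features(store, ever_spec)
  study_patients <- unique(study_ft$patient_id)
  control_patients <- setdiff(unique(ever_ft$patient_id), study_patients)
  control_ft <- ever_ft[ever_ft$patient_id %in% control_patients, , drop = FALSE]

  mk <- function(name, ft) {
    tibble::tibble(
      group = name,
      n_patients = length(unique(ft$patient_id)),
      n_results = nrow(ft),
      mean_value = round_half_up(mean(ft$value, na.rm = TRUE), 1),
      mean_raw = mean(ft$value, na.rm = TRUE)
    )
  }
  groups <- dplyr::bind_rows(mk("study", study_ft), mk("control", control_ft))
  p <- if (nrow(study_ft) >= 2 && nrow(control_ft) >= 2) {
    stats::t.test(study_ft$value, control_ft$value)$p.value
  } else {
    NA_real_
  }
  tests <- tibble::tibble(
    test = "welch_t_two_sided", p_value = p, skipped = is.na(p)
  )
  new_scenario_report(
    "amphotericin_potassium", groups, tests,
    list(
      spec_hash = spec_hash(study_spec),
      store_hash = store_hash(store)
    )
  )
}
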