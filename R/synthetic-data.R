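ICD_SYSTEM <- "http://fhir.de/CodeSystem/dimdi/icd-10-gm"
OPS_SYSTEM <- "http://fhir.de/CodeSystem/dimdi/ops"
LOINC_SYSTEM <- "http://loinc.org"

#' Define a synthetic laboratory panel
#'
#' @param loinc LOINC code of the analyte.
#' @param unit Unit string attached to every value.
#' @param male_mean,male_sd,female_mean,female_sd Per-gender Normal baseline
#'   (sd must be positive). Patients of other/unknown gender draw from the
#'   pooled mean.
#' @param tests_per_encounter Poisson mean of the number of results emitted
#'   per encounter.
#' @return A `synth_lab_panel`.
#' @export
lab_panel <- function(loinc, unit, male_mean, male_sd, female_mean, female_sd,
                      tests_per_encounter = 2) {
  stopifnot(male_sd > 0, female_sd > 0, tests_per_encounter >= 0)
  structure(
    list(
      loinc = loinc, unit = unit,
      male_mean = male_mean, male_sd = male_sd,
      female_mean = female_mean, female_sd = female_sd,
      tests_per_encounter = tests_per_encounter
    ),
    class = "synth_lab_panel"
  )
}

#' Define an injected effect
#'
#' An effect shifts the Normal mean of one analyte for observations exposed
#' to a trigger: either every observation of patients carrying a condition
#' with the given ICD prefix (`window_days = "always"`), or observations
#' lying within `window_days` days (closed, either side) of a procedure with
#' the given OPS prefix.
#'
#' @param target_loinc Analyte whose values are shifted.
#' @param shift Additive mean shift in panel units (finite).
#' @param condition_prefix,procedure_prefix Exactly one must be given.
#' @param window_days `"always"` (condition triggers) or a non-negative day
#'   count (procedure triggers).
#' @return A `synth_effect`.
#' @export
synth_effect <- function(target_loinc, shift, condition_prefix = NULL,
                         procedure_prefix = NULL, window_days = "always") {
  stopifnot(is.finite(shift))
  if (is.null(condition_prefix) == is.null(procedure_prefix)) {
    stop_fhirprep("exactly one of condition_prefix / procedure_prefix required",
      class = "fhirprep_validation_error"
    )
  }
  if (!identical(window_days, "always")) {
    stopifnot(is.numeric(window_days), window_days >= 0)
  }
  structure(
    list(
      target_loinc = target_loinc, shift = shift,
      condition_prefix = condition_prefix,
      procedure_prefix = procedure_prefix,
      window_days = window_days
    ),
    class = "synth_effect"
  )
}

#' Synthetic hospital dataset configuration
#'
#' Parameters of the generator: cohort size and demographics, encounter
#' process, diagnosis prevalences by ICD-10 prefix, procedure rates by OPS
#' prefix, laboratory panels, and injected effects. All randomness derives
#' from `seed`; the same configuration always yields byte-identical output.
#'
#' @param seed Integer seed (mandatory).
#' @param n_patients Number of patients.
#' @param female_fraction Probability a patient is female.
#' @param birth_year_range Length-2 integer vector of birth years (uniform).
#' @param encounters_per_patient Poisson mean of encounters per patient.
#' @param date_range Length-2 character vector of ISO dates bounding
#'   encounter periods.
#' @param encounter_duration_days Length-2 numeric vector; durations drawn
#'   uniformly between the two.
#' @param condition_prevalence Named numeric vector, ICD-10 prefix ->
#'   per-patient probability.
#' @param procedure_rates Named numeric vector, OPS prefix -> per-encounter
#'   probability.
#' @param lab_panels List of [lab_panel()] objects.
#' @param effects List of [synth_effect()] objects.
#' @return A `synth_config`.
#' @export
synth_config <- function(seed,
                         n_patients = 2000,
                         female_fraction = 0.52,
                         birth_year_range = c(1930L, 2005L),
                         encounters_per_patient = 3,
                         date_range = c("2016-01-01", "2018-12-31"),
                         encounter_duration_days = c(1, 14),
                         condition_prevalence = c(C = 0.15),
                         procedure_rates = c("8-80" = 0.05, "5-" = 0.08),
                         lab_panels = list(),
                         effects = list()) {
  errs <- character()
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    errs <- c(errs, "seed: mandatory")
  }
  if (n_patients < 0) errs <- c(errs, "n_patients: must be >= 0")
  if (female_fraction < 0 || female_fraction > 1) {
    errs <- c(errs, "female_fraction: must lie in [0,1]")
  }
  if (length(condition_prevalence) &&
    (any(condition_prevalence < 0) || any(condition_prevalence > 1))) {
    errs <- c(errs, "condition_prevalence: probabilities must lie in [0,1]")
  }
  if (length(procedure_rates) &&
    (any(procedure_rates < 0) || any(procedure_rates > 1))) {
    errs <- c(errs, "procedure_rates: probabilities must lie in [0,1]")
  }
  if (encounters_per_patient < 0) {
    errs <- c(errs, "encounters_per_patient: must be >= 0")
  }
  if (!all(vapply(lab_panels, inherits, logical(1), "synth_lab_panel"))) {
    errs <- c(errs, "lab_panels: must be lab_panel() objects")
  }
  if (!all(vapply(effects, inherits, logical(1), "synth_effect"))) {
    errs <- c(errs, "effects: must be synth_effect() objects")
  }
  if (length(errs)) {
    stop_fhirprep(
      paste0(
        "invalid synthetic configuration:\n",
        paste0("  - ", errs, collapse = "\n")
      ),
      class = "fhirprep_validation_error", errors = errs
    )
  }
  structure(
    list(
      seed = as.integer(seed), n_patients = as.integer(n_patients),
      female_fraction = female_fraction,
      birth_year_range = as.integer(birth_year_range),
      encounters_per_patient = encounters_per_patient,
      date_range = date_range,
      encounter_duration_days = encounter_duration_days,
      condition_prevalence = condition_prevalence,
      procedure_rates = procedure_rates,
      lab_panels = lab_panels, effects = effects
    ),
    class = "synth_config"
  )
}

#' Default synthetic hospital configuration
#'
#' A desk-scale stand-in for a tertiary-care laboratory dataset: 2,000
#' patients over 2016-2018 with hemoglobin (LOINC 718-7, g/dL; male
#' baseline 15.0 +/- 1.1, female 13.4 +/- 1.0) and potassium (LOINC 2823-3,
#' mM; 4.0 +/- 0.4) panels, a 15% malignancy prevalence (ICD-10 `C*`),
#' transfusion (OPS `8-80*`), surgery (OPS `5-*`) and liposomal
#' amphotericin B (OPS `6-002.q*`) procedures, a -2.5 g/dL hemoglobin shift
#' in patients with malignancy, and a -0.4 mM potassium shift within 7 days
#' of an amphotericin administration. The numeric baselines are invented but
#' physiologically plausible; analyses on this data should only ever assert
#' recovery of the configured effects, not the absolute levels.
#'
#' @param seed Integer seed.
#' @return A `synth_config`.
#' @export
default_synth_config <- function(seed = 1L) {
  synth_config(
    seed = seed,
    n_patients = 2000,
    female_fraction = 0.52,
    birth_year_range = c(1930L, 2005L),
    encounters_per_patient = 3,
    date_range = c("2016-01-01", "2018-12-31"),
    encounter_duration_days = c(1, 14),
    condition_prevalence = c(C = 0.15),
    procedure_rates = c("8-80" = 0.05, "5-" = 0.08, "6-002.q" = 0.02),
    lab_panels = list(
      lab_panel("718-7", "g/dL", 15.0, 1.1, 13.4, 1.0, tests_per_encounter = 2),
      lab_panel("2823-3", "mM", 4.0, 0.4, 4.0, 0.4, tests_per_encounter = 2)
    ),
    effects = list(
      synth_effect("718-7", -2.5, condition_prefix = "C", window_days = "always"),
      synth_effect("2823-3", -0.4, procedure_prefix = "6-002.q", window_days = 7)
    )
  )
}

# a code with a short random suffix so prefix matching is nontrivial
make_code <- function(prefix, n) {
  if (grepl("^[A-Z]$", prefix)) {
    sprintf(
      "%s%02d.%d", prefix, sample.int(100, n, replace = TRUE) - 1L,
      sample.int(10, n, replace = TRUE) - 1L
    )
  } else if (endsWith(prefix, "-")) {
    sprintf(
      "%s%03d.%d", prefix, sample.int(1000, n, replace = TRUE) - 1L,
      sample.int(10, n, replace = TRUE) - 1L
    )
  } else {
    sprintf("%s%d", prefix, sample.int(10, n, replace = TRUE) - 1L)
  }
}

#' Generate a synthetic FHIR dataset with ground-truth labels
#'
#' Emits Patients, Encounters, Conditions, Procedures and Observations as
#' NDJSON lines. Every Condition, Procedure and Observation timestamp lies
#' inside one of its patient's encounter periods and carries the encounter
#' reference, so encounter-period matching is exercised by construction.
#' Output is fully reproducible from the configuration seed, byte for byte.
#'
#' @param cfg A [synth_config()].
#' @return A `synth_dataset`: list with `lines` (NDJSON character vector),
#'   `labels` (ground truth: `$observations` with per-observation
#'   `is_shifted`/`active_effects`/`shift_total`, `$patients` with
#'   per-prefix condition flags), and `counts` (emitted resources per type).
#' @seealso [synth_write()], [default_synth_config()]
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(cfg$seed)

  n <- cfg$n_patients
  empty <- function() {
    structure(
      list(
        lines = character(),
        labels = list(
          observations = tibble::tibble(
            fhir_id = character(), patient_id = character(),
            loinc = character(), time = double(), value = double(),
            is_shifted = logical(), shift_total = double(),
            active_effects = list()
          ),
          patients = tibble::tibble(fhir_id = character())
        ),
        counts = stats::setNames(
          integer(length(SUPPORTED_TYPES)), SUPPORTED_TYPES
        )
      ),
      class = "synth_dataset"
    )
  }
  if (n == 0) return(empty())

  # ---- patients -----------------------------------------------------------
  pid <- sprintf("p%05d", seq_len(n))
  gender <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
  y0 <- cfg$birth_year_range[1]
  y1 <- cfg$birth_year_range[2]
  birth <- as.Date(sprintf("%d-01-01", y0)) +
    floor(stats::runif(n) * (as.numeric(as.Date(sprintf("%d-12-31", y1)) -
      as.Date(sprintf("%d-01-01", y0))) + 1))
  pat_lines <- sprintf(
    '{"resourceType":"Patient","id":"%s","gender":"%s","birthDate":"%s"}',
    pid, gender, format(birth, "%Y-%m-%d")
  )

  # ---- encounters ---------------------------------------------------------
  n_enc <- stats::rpois(n, cfg$encounters_per_patient)
  E <- sum(n_enc)
  enc_pat_idx <- rep(seq_len(n), n_enc)
  range_start <- parse_instant(cfg$date_range[1])
  range_end <- parse_instant(cfg$date_range[2]) + SECONDS_PER_DAY - 1
  dur <- stats::runif(
    E, cfg$encounter_duration_days[1],
    cfg$encounter_duration_days[2]
  ) * SECONDS_PER_DAY
  start <- range_start + stats::runif(E) * pmax(range_end - range_start - dur, 0)
  start <- floor(start)
  end <- floor(start + dur)
  eid <- sprintf("e%06d", seq_len(E))
  enc_lines <- sprintf(
    paste0(
      '{"resourceType":"Encounter","id":"%s",',
      '"subject":{"reference":"Patient/%s"},',
      '"period":{"start":"%s","end":"%s"}}'
    ),
    eid, pid[enc_pat_idx], format_instant(start), format_instant(end)
  )
  enc <- tibble::tibble(
    eid = eid, pat = enc_pat_idx,
    start = start, end = end
  )

  # ---- conditions ---------------------------------------------------------
  cond_rows <- list()
  pat_flags <- tibble::tibble(fhir_id = pid)
  enc_by_pat <- split(seq_len(E), enc_pat_idx)
  for (prefix in names(cfg$condition_prevalence)) {
    has <- stats::runif(n) < cfg$condition_prevalence[[prefix]]
    # patients without encounters cannot carry a dated condition
    has <- has & pid %in% pid[enc_pat_idx]
    pat_flags[[paste0("has_", prefix)]] <- has
    idx <- which(has)
    if (length(idx)) {
      chosen_enc <- vapply(idx, function(i) {
        rows <- enc_by_pat[[as.character(i)]]
        rows[sample.int(length(rows), 1)]
      }, integer(1))
      t_rec <- floor(enc$start[chosen_enc] +
        stats::runif(length(idx)) * (enc$end[chosen_enc] - enc$start[chosen_enc]))
      cond_rows[[prefix]] <- tibble::tibble(
        pat = idx, enc_row = chosen_enc, time = t_rec,
        code = make_code(prefix, length(idx)), prefix = prefix
      )
    }
  }
  cond <- dplyr::bind_rows(cond_rows)
  if (nrow(cond)) {
    cond$cid <- sprintf("c%06d", seq_len(nrow(cond)))
    cond_lines <- sprintf(
      paste0(
        '{"resourceType":"Condition","id":"%s",',
        '"subject":{"reference":"Patient/%s"},',
        '"encounter":{"reference":"Encounter/%s"},',
        '"code":{"coding":[{"system":"%s","code":"%s"}]},',
        '"recordedDate":"%s"}'
      ),
      cond$cid, pid[cond$pat], enc$eid[cond$enc_row],
      ICD_SYSTEM, cond$code, format_instant(cond$time)
    )
  } else {
    cond_lines <- character()
  }

  # ---- procedures ---------------------------------------------------------
  proc_rows <- list()
  for (prefix in names(cfg$procedure_rates)) {
    sel <- which(stats::runif(E) < cfg$procedure_rates[[prefix]])
    if (length(sel)) {
      t_perf <- floor(enc$start[sel] +
        stats::runif(length(sel)) * (enc$end[sel] - enc$start[sel]))
      proc_rows[[prefix]] <- tibble::tibble(
        enc_row = sel, pat = enc$pat[sel], time = t_perf,
        code = make_code(prefix, length(sel)), prefix = prefix
      )
    }
  }
  proc <- dplyr::bind_rows(proc_rows)
  if (nrow(proc)) {
    proc$prid <- sprintf("pr%06d", seq_len(nrow(proc)))
    proc_lines <- sprintf(
      paste0(
        '{"resourceType":"Procedure","id":"%s",',
        '"subject":{"reference":"Patient/%s"},',
        '"encounter":{"reference":"Encounter/%s"},',
        '"code":{"coding":[{"system":"%s","code":"%s"}]},',
        '"performedDateTime":"%s"}'
      ),
      proc$prid, pid[proc$pat], enc$eid[proc$enc_row],
      OPS_SYSTEM, proc$code, format_instant(proc$time)
    )
  } else {
    proc_lines <- character()
  }

  # ---- observations -------------------------------------------------------
  obs_rows <- list()
  for (p in cfg$lab_panels) {
    k <- stats::rpois(E, p$tests_per_encounter)
    rows <- rep(seq_len(E), k)
    if (!length(rows)) next
    t_obs <- floor(enc$start[rows] +
      stats::runif(length(rows)) * (enc$end[rows] - enc$start[rows]))
    g <- gender[enc$pat[rows]]
    mu <- ifelse(g == "male", p$male_mean,
      ifelse(g == "female", p$female_mean, (p$male_mean + p$female_mean) / 2)
    )
    sdv <- ifelse(g == "male", p$male_sd,
      ifelse(g == "female", p$female_sd, (p$male_sd + p$female_sd) / 2)
    )
    base_val <- stats::rnorm(length(rows), mu, sdv)
    obs_rows[[p$loinc]] <- tibble::tibble(
      enc_row = rows, pat = enc$pat[rows], time = t_obs,
      loinc = p$loinc, unit = p$unit, base_val = base_val
    )
  }
  obs <- dplyr::bind_rows(obs_rows)

  # ---- effects ------------------------------------------------------------
  if (nrow(obs)) {
    obs$shift_total <- 0
    obs$active_effects <- vector("list", nrow(obs))
    for (k in seq_along(cfg$effects)) {
      ef <- cfg$effects[[k]]
      active <- rep(FALSE, nrow(obs))
      target <- obs$loinc == ef$target_loinc
      if (!is.null(ef$condition_prefix)) {
        flag <- pat_flags[[paste0("has_", ef$condition_prefix)]]
        if (is.null(flag) && nrow(cond)) {
          flag <- pid %in% pid[cond$pat[cond$prefix == ef$condition_prefix]]
        }
        if (!is.null(flag)) active <- target & flag[obs$pat]
        if (!identical(ef$window_days, "always")) {
          # condition triggers with a finite window: measure from recordedDate
          w <- ef$window_days * SECONDS_PER_DAY
          trig <- cond[cond$prefix == ef$condition_prefix, , drop = FALSE]
          active <- target & obs_in_window(obs, trig, w)
        }
      } else {
        trig <- proc[proc$prefix == ef$procedure_prefix, , drop = FALSE]
        if (identical(ef$window_days, "always")) {
          active <- target & obs$pat %in% trig$pat
        } else {
          w <- ef$window_days * SECONDS_PER_DAY
          active <- target & obs_in_window(obs, trig, w)
        }
      }
      obs$shift_total <- obs$shift_total + ifelse(active, ef$shift, 0)
      obs$active_effects[active] <- lapply(
        obs$active_effects[active],
        function(x) c(x, k)
      )
    }
    obs$value <- round(obs$base_val + obs$shift_total, 1)
    obs <- dplyr::arrange(obs, .data$enc_row, .data$time, .data$loinc)
    obs$oid <- sprintf("o%07d", seq_len(nrow(obs)))
    obs_lines <- sprintf(
      paste0(
        '{"resourceType":"Observation","id":"%s",',
        '"subject":{"reference":"Patient/%s"},',
        '"encounter":{"reference":"Encounter/%s"},',
        '"code":{"coding":[{"system":"%s","code":"%s"}]},',
        '"valueQuantity":{"value":%.1f,"unit":"%s"},',
        '"effectiveDateTime":"%s"}'
      ),
      obs$oid, pid[obs$pat], enc$eid[obs$enc_row],
      LOINC_SYSTEM, obs$loinc, obs$value, obs$unit, format_instant(obs$time)
    )
  } else {
    obs_lines <- character()
    obs$shift_total <- numeric(0)
    obs$active_effects <- list()
    obs$value <- numeric(0)
    obs$oid <- character(0)
  }

  lines <- c(pat_lines, enc_lines, cond_lines, proc_lines, obs_lines)
  counts <- stats::setNames(integer(length(SUPPORTED_TYPES)), SUPPORTED_TYPES)
  counts["Patient"] <- n
  counts["Encounter"] <- E
  counts["Condition"] <- nrow(cond)
  counts["Procedure"] <- nrow(proc)
  counts["Observation"] <- nrow(obs)

  labels <- list(
    observations = tibble::tibble(
      fhir_id = obs$oid,
      patient_id = pid[obs$pat],
      loinc = obs$loinc,
      time = obs$time,
      value = obs$value,
      is_shifted = obs$shift_total != 0,
      shift_total = obs$shift_total,
      active_effects = obs$active_effects
    ),
    patients = pat_flags
  )
  structure(
    list(lines = lines, labels = labels, counts = counts),
    class = "synth_dataset"
  )
}

# observations within w seconds (closed) of any trigger row of same patient
obs_in_window <- function(obs, trig, w) {
  if (!nrow(trig) || !nrow(obs)) return(rep(FALSE, nrow(obs)))
  o <- tibble::tibble(.row = seq_len(nrow(obs)), pat = obs$pat, t = obs$time)
  tr <- tibble::tibble(pat = trig$pat, tt = trig$time)
  j <- dplyr::inner_join(o, tr, by = "pat", relationship = "many-to-many")
  hit <- unique(j$.row[abs(j$t - j$tt) <= w])
  seq_len(nrow(obs)) %in% hit
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset> ", length(x$lines), " resources\n", sep = "")
  nz <- x$counts[x$counts > 0]
  if (length(nz)) cat(" ", paste(names(nz), nz, collapse = ", "), "\n")
  invisible(x)
}

#' Load a synthetic dataset straight into a document store
#'
#' Equivalent to [synth_write()] followed by [store_open()], without
#' touching disk.
#'
#' @param gen A `synth_dataset` from [synth_generate()].
#' @return A `fhir_store`.
#' @export
as_fhir_store <- function(gen) {
  stopifnot(inherits(gen, "synth_dataset"))
  load_docs(fhir_store(), gen$lines)
}

#' Write a synthetic dataset to disk
#'
#' @param gen A `synth_dataset` from [synth_generate()].
#' @param out NDJSON output path.
#' @param labels_path Optional path for the ground-truth labels (JSON).
#' @return `out`, invisibly.
#' @export
synth_write <- function(gen, out, labels_path = NULL) {
  stopifnot(inherits(gen, "synth_dataset"))
  writeLines(gen$lines, out, useBytes = TRUE)
  if (!is.null(labels_path)) {
    lab <- gen$labels
    obs <- lab$observations
    obs$time <- format_instant(obs$time)
    jsonlite::write_json(
      list(observations = obs, patients = lab$patients),
      labels_path,
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(out)
}
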