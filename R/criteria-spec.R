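COMPARATORS <- c("lt", "le", "gt", "ge", "eq", "ne")
MATCH_MODES <- c("exact", "prefix")
CRIT_MODES <- c("ever", "window")
AGGREGATIONS <- c(
  "none", "min_per_patient", "max_per_patient",
  "first_per_patient", "random_one_per_patient"
)
FEATURE_COLUMNS <- c("patient_id", "gender", "age", "value", "unit", "code", "time")
GENDERS <- c("male", "female", "other", "unknown")

#' Code selector
#'
#' Selects coded resources by code list, either exactly or by raw string
#' prefix (so `"C"` with `match = "prefix"` selects every ICD-10 C code, and
#' `"8-80"` every OPS transfusion code). When `system` is `NULL` matching is
#' code-only; otherwise the stored coding system must equal the selector
#' system, or one must contain the other case-insensitively (so the short
#' name `"LOINC"` matches the canonical URI `http://loinc.org`).
#'
#' @param codes Non-empty character vector of codes (or prefixes).
#' @param system Coding system URI or short name, or `NULL`.
#' @param match `"exact"` or `"prefix"`.
#' @return A `fhir_code_selector`.
#' @export
code_selector <- function(codes, system = NULL, match = "exact") {
  stopifnot(is.character(codes), length(codes) >= 1, all(nzchar(codes)))
  match <- rlang::arg_match(match, MATCH_MODES)
  structure(list(system = system, codes = codes, match = match),
    class = "fhir_code_selector"
  )
}

#' Value restriction on a numeric resource value
#'
#' @param comparator One of `lt, le, gt, ge, eq, ne`.
#' @param threshold Finite numeric threshold.
#' @param unit Expected unit string, or `NULL` (units then unchecked).
#' @return A `fhir_value_filter`.
#' @export
value_filter <- function(comparator, threshold, unit = NULL) {
  comparator <- rlang::arg_match(comparator, COMPARATORS)
  stopifnot(is.numeric(threshold), is.finite(threshold))
  structure(list(comparator = comparator, threshold = as.numeric(threshold), unit = unit),
    class = "fhir_value_filter"
  )
}

#' Base resource selection
#'
#' Defines the initial result set ("base resources") that inclusion and
#' exclusion criteria are then tested against: a resource type, a code
#' selector, and optional value, demographic and calendar-time restrictions.
#' Ages are in completed years at the resource's own time, bounds inclusive.
#'
#' @param resource_type Supported FHIR type (typically `"Observation"`).
#' @param code_selector A [code_selector()].
#' @param value_filter Optional [value_filter()].
#' @param genders Optional character subset of
#'   `c("male","female","other","unknown")`.
#' @param age_min,age_max Optional inclusive age bounds in years.
#' @param time_range Optional `list(start =, end =)` of ISO 8601 strings or
#'   epoch instants; closed interval.
#' @return A `fhir_base_selector`.
#' @export
base_selector <- function(resource_type, code_selector, value_filter = NULL,
                          genders = NULL, age_min = NULL, age_max = NULL,
                          time_range = NULL) {
  stopifnot(resource_type %in% SUPPORTED_TYPES)
  stopifnot(inherits(code_selector, "fhir_code_selector"))
  if (!is.null(value_filter)) stopifnot(inherits(value_filter, "fhir_value_filter"))
  if (!is.null(genders)) stopifnot(all(genders %in% GENDERS))
  if (!is.null(age_min) && !is.null(age_max)) stopifnot(age_min <= age_max)
  if (!is.null(time_range)) {
    time_range <- normalize_period(time_range)
  }
  structure(
    list(
      resource_type = resource_type, code_selector = code_selector,
      value_filter = value_filter,
      patient_filter = list(
        genders = genders,
        age_min = age_min, age_max = age_max
      ),
      time_range = time_range
    ),
    class = "fhir_base_selector"
  )
}

normalize_period <- function(p) {
  start <- p$start
  end <- p$end
  if (is.character(start)) start <- parse_instant(start)
  if (is.character(end)) end <- parse_instant(end)
  if (!is.null(start) && !is.null(end) && !is.na(start) && !is.na(end)) {
    stopifnot(start <= end)
  }
  list(start = start %||% NA_real_, end = end %||% NA_real_)
}

#' Inclusion or exclusion criterion
#'
#' A criterion is grounded in resources of another type that match a code
#' selector (and optionally a value filter). In `"ever"` mode it acts at
#' patient level: the criterion holds for every base resource of a patient
#' who has at least one matching resource at any time. In `"window"` mode it
#' acts per base resource: the criterion holds when the base resource's time
#' falls within the closed day-window
#' `[t - window_before_days, t + window_after_days]` around a matching
#' resource's time, or — when `use_encounter_period` and the matching
#' resource's encounter resolves to a period — within that encounter period.
#' Day windows may be `Inf` (unbounded).
#'
#' @param polarity `"include"` (base resources must satisfy it) or
#'   `"exclude"` (base resources satisfying it are removed).
#' @param resource_type Supported FHIR type the criterion is grounded in.
#' @param code_selector A [code_selector()].
#' @param value_filter Optional [value_filter()].
#' @param mode `"ever"` or `"window"`.
#' @param window_before_days,window_after_days Non-negative day counts;
#'   required in window mode, must be absent in ever mode.
#' @param use_encounter_period Whether window mode may also match through the
#'   criterion resource's encounter period (default `TRUE`).
#' @return A `fhir_criterion`.
#' @export
criterion <- function(polarity, resource_type, code_selector,
                      value_filter = NULL, mode = "ever",
                      window_before_days = NULL, window_after_days = NULL,
                      use_encounter_period = TRUE) {
  polarity <- rlang::arg_match(polarity, c("include", "exclude"))
  mode <- rlang::arg_match(mode, CRIT_MODES)
  stopifnot(resource_type %in% SUPPORTED_TYPES)
  stopifnot(inherits(code_selector, "fhir_code_selector"))
  if (!is.null(value_filter)) stopifnot(inherits(value_filter, "fhir_value_filter"))
  if (mode == "window") {
    if (is.null(window_before_days) || is.null(window_after_days)) {
      stop_fhirprep("window mode requires window_before_days and window_after_days",
        class = "fhirprep_validation_error"
      )
    }
    stopifnot(window_before_days >= 0, window_after_days >= 0)
  } else if (!is.null(window_before_days) || !is.null(window_after_days)) {
    stop_fhirprep("window_*_days only allowed in window mode",
      class = "fhirprep_validation_error"
    )
  }
  structure(
    list(
      polarity = polarity, resource_type = resource_type,
      code_selector = code_selector, value_filter = value_filter,
      mode = mode,
      window_before_days = window_before_days,
      window_after_days = window_after_days,
      use_encounter_period = isTRUE(use_encounter_period)
    ),
    class = "fhir_criterion"
  )
}

#' Feature-set directives
#'
#' @param aggregation One of `none`, `min_per_patient`, `max_per_patient`,
#'   `first_per_patient`, `random_one_per_patient` (the last requires
#'   `random_seed`).
#' @param random_seed Integer seed for `random_one_per_patient`.
#' @param columns Ordered subset of
#'   `c("patient_id","gender","age","value","unit","code","time")`.
#' @return A `fhir_feature_spec`.
#' @export
feature_spec <- function(aggregation = "none", random_seed = NULL,
                         columns = FEATURE_COLUMNS) {
  aggregation <- rlang::arg_match(aggregation, AGGREGATIONS)
  if (aggregation == "random_one_per_patient" && is.null(random_seed)) {
    stop_fhirprep("random_one_per_patient requires random_seed",
      class = "fhirprep_validation_error"
    )
  }
  stopifnot(all(columns %in% FEATURE_COLUMNS), length(columns) >= 1)
  structure(
    list(
      aggregation = aggregation,
      random_seed = if (!is.null(random_seed)) as.integer(random_seed),
      columns = columns
    ),
    class = "fhir_feature_spec"
  )
}

#' Full filter specification
#'
#' @param base A [base_selector()].
#' @param criteria List of [criterion()] objects (may be empty). Criteria
#'   combine as a conjunction: a base resource is kept when every inclusion
#'   criterion matches it and no exclusion criterion does.
#' @param feature_set A [feature_spec()].
#' @return A `fhir_filter_spec`.
#' @export
filter_spec <- function(base, criteria = list(), feature_set = feature_spec()) {
  stopifnot(inherits(base, "fhir_base_selector"))
  stopifnot(all(vapply(criteria, inherits, logical(1), "fhir_criterion")))
  stopifnot(inherits(feature_set, "fhir_feature_spec"))
  structure(list(base = base, criteria = criteria, feature_set = feature_set),
    class = "fhir_filter_spec"
  )
}

#' @export
print.fhir_filter_spec <- function(x, ...) {
  cat("<fhir_filter_spec>\n")
  cat(
    "  base:", x$base$resource_type,
    paste(x$base$code_selector$codes, collapse = ","),
    sprintf("(%s)", x$base$code_selector$match), "\n"
  )
  for (i in seq_along(x$criteria)) {
    c <- x$criteria[[i]]
    w <- if (c$mode == "window") {
      sprintf(" window %s/%s d", c$window_before_days, c$window_after_days)
    } else {
      ""
    }
    cat(sprintf(
      "  [%d] %s %s %s %s (%s)%s\n", i, c$polarity, c$resource_type,
      paste(c$code_selector$codes, collapse = ","), c$code_selector$match,
      c$mode, w
    ))
  }
  cat("  feature_set:", x$feature_set$aggregation, "\n")
  invisible(x)
}

# ---- JSON parsing with exhaustive error collection ------------------------

collect_err <- function(errs, path, msg) {
  c(errs, sprintf("%s: %s", path, msg))
}

parse_code_selector <- function(d, path, errs) {
  if (is.null(d)) {
    return(list(val = NULL, errs = collect_err(errs, path, "code_selector required")))
  }
  codes <- unlist(d$codes)
  if (is.null(codes) || length(codes) == 0 || any(!nzchar(codes))) {
    errs <- collect_err(errs, paste0(path, ".codes"), "non-empty code list required")
    return(list(val = NULL, errs = errs))
  }
  match <- d$match %||% "exact"
  if (!match %in% MATCH_MODES) {
    errs <- collect_err(errs, paste0(path, ".match"), "must be exact or prefix")
    return(list(val = NULL, errs = errs))
  }
  list(val = code_selector(as.character(codes), d$system, match), errs = errs)
}

parse_value_filter <- function(d, path, errs) {
  if (is.null(d)) return(list(val = NULL, errs = errs))
  cmp <- d$comparator
  if (is.null(cmp) || !cmp %in% COMPARATORS) {
    return(list(val = NULL, errs = collect_err(
      errs, paste0(path, ".comparator"),
      sprintf("must be one of %s", paste(COMPARATORS, collapse = ", "))
    )))
  }
  if (is.null(d$threshold) || !is.numeric(d$threshold) || !is.finite(d$threshold)) {
    return(list(val = NULL, errs = collect_err(
      errs, paste0(path, ".threshold"), "finite number required"
    )))
  }
  list(val = value_filter(cmp, d$threshold, d$unit), errs = errs)
}

parse_criterion <- function(d, path, errs) {
  ok <- TRUE
  pol <- d$polarity
  if (is.null(pol) || !pol %in% c("include", "exclude")) {
    errs <- collect_err(errs, paste0(path, ".polarity"), "must be include or exclude")
    ok <- FALSE
  }
  rt <- d$resource_type
  if (is.null(rt) || !rt %in% SUPPORTED_TYPES) {
    errs <- collect_err(
      errs, paste0(path, ".resource_type"),
      sprintf("must be one of %s", paste(SUPPORTED_TYPES, collapse = ", "))
    )
    ok <- FALSE
  }
  cs <- parse_code_selector(d$code_selector, paste0(path, ".code_selector"), errs)
  errs <- cs$errs
  if (is.null(cs$val)) ok <- FALSE
  vf <- parse_value_filter(d$value_filter, paste0(path, ".value_filter"), errs)
  errs <- vf$errs
  mode <- d$mode %||% "ever"
  if (!mode %in% CRIT_MODES) {
    errs <- collect_err(errs, paste0(path, ".mode"), "must be ever or window")
    ok <- FALSE
  }
  wb <- d$window_before_days
  wa <- d$window_after_days
  if (identical(mode, "window")) {
    if (is.null(wb)) {
      errs <- collect_err(
        errs, paste0(path, ".window_before_days"),
        "required in window mode"
      )
      ok <- FALSE
    } else if (!is.numeric(wb) || (is.finite(wb) && wb < 0)) {
      errs <- collect_err(
        errs, paste0(path, ".window_before_days"),
        "non-negative number required"
      )
      ok <- FALSE
    }
    if (is.null(wa)) {
      errs <- collect_err(
        errs, paste0(path, ".window_after_days"),
        "required in window mode"
      )
      ok <- FALSE
    } else if (!is.numeric(wa) || (is.finite(wa) && wa < 0)) {
      errs <- collect_err(
        errs, paste0(path, ".window_after_days"),
        "non-negative number required"
      )
      ok <- FALSE
    }
  } else if (!is.null(wb) || !is.null(wa)) {
    errs <- collect_err(errs, paste0(path), "window_*_days only allowed in window mode")
    ok <- FALSE
  }
  if (!ok) return(list(val = NULL, errs = errs))
  list(
    val = criterion(pol, rt, cs$val, vf$val, mode,
      window_before_days = if (mode == "window") wb,
      window_after_days = if (mode == "window") wa,
      use_encounter_period = d$use_encounter_period %||% TRUE
    ),
    errs = errs
  )
}

#' Parse a JSON filter specification
#'
#' Parses and fully validates the JSON dialect (see the package vignette for
#' the schema; the three built-in scenario specs in [builtin_specs()] are
#' worked examples). Defaults are materialised: `match = "exact"`,
#' `use_encounter_period = true`, `aggregation = "none"`, all seven feature
#' columns. Validation is exhaustive, not fail-fast: every violation is
#' reported with its JSON path.
#'
#' @param doc A JSON string, a path to a JSON file, or a parsed list.
#' @return A `fhir_filter_spec`.
#' @seealso [spec_to_json()], [validate_spec()]
#' @export
parse_spec <- function(doc) {
  if (is.character(doc) && length(doc) == 1 && file.exists(doc) &&
    !grepl("^\\s*\\{", doc)) {
    doc <- readChar(doc, file.info(doc)$size)
  }
  if (is.character(doc)) {
    doc <- jsonlite::fromJSON(paste(doc, collapse = "\n"), simplifyVector = FALSE)
  }
  errs <- character()

  b <- doc$base
  base <- NULL
  if (is.null(b)) {
    errs <- collect_err(errs, "base", "required")
  } else {
    rt <- b$resource_type
    if (is.null(rt) || !rt %in% SUPPORTED_TYPES) {
      errs <- collect_err(
        errs, "base.resource_type",
        sprintf("must be one of %s", paste(SUPPORTED_TYPES, collapse = ", "))
      )
    }
    cs <- parse_code_selector(b$code_selector, "base.code_selector", errs)
    errs <- cs$errs
    vf <- parse_value_filter(b$value_filter, "base.value_filter", errs)
    errs <- vf$errs
    pf <- b$patient_filter %||% list()
    genders <- unlist(pf$genders)
    if (!is.null(genders) && !all(genders %in% GENDERS)) {
      errs <- collect_err(
        errs, "base.patient_filter.genders",
        sprintf("must be among %s", paste(GENDERS, collapse = ", "))
      )
      genders <- NULL
    }
    if (!is.null(pf$age_min) && !is.null(pf$age_max) && pf$age_min > pf$age_max) {
      errs <- collect_err(errs, "base.patient_filter", "age_min must be <= age_max")
    }
    tr <- NULL
    if (!is.null(b$time_range)) {
      tr <- tryCatch(normalize_period(b$time_range), error = function(e) {
        errs <<- collect_err(errs, "base.time_range", "start must be <= end")
        NULL
      })
    }
    if (!is.null(cs$val) && !is.null(rt) && rt %in% SUPPORTED_TYPES &&
      !(!is.null(pf$age_min) && !is.null(pf$age_max) && pf$age_min > pf$age_max)) {
      base <- base_selector(rt, cs$val, vf$val,
        genders = genders,
        age_min = pf$age_min, age_max = pf$age_max, time_range = tr
      )
    }
  }

  crits <- list()
  for (i in seq_along(doc$criteria)) {
    pc <- parse_criterion(doc$criteria[[i]], sprintf("criteria[%d]", i - 1L), errs)
    errs <- pc$errs
    if (!is.null(pc$val)) crits[[length(crits) + 1L]] <- pc$val
  }

  fsd <- doc$feature_set %||% list()
  agg <- fsd$aggregation %||% "none"
  fs <- NULL
  if (!agg %in% AGGREGATIONS) {
    errs <- collect_err(
      errs, "feature_set.aggregation",
      sprintf("must be one of %s", paste(AGGREGATIONS, collapse = ", "))
    )
  } else if (agg == "random_one_per_patient" && is.null(fsd$random_seed)) {
    errs <- collect_err(errs, "feature_set.random_seed", "required for random_one_per_patient")
  } else {
    cols <- unlist(fsd$columns) %||% FEATURE_COLUMNS
    if (!all(cols %in% FEATURE_COLUMNS)) {
      errs <- collect_err(
        errs, "feature_set.columns",
        sprintf("must be among %s", paste(FEATURE_COLUMNS, collapse = ", "))
      )
    } else {
      fs <- feature_spec(agg, fsd$random_seed, cols)
    }
  }

  if (length(errs)) {
    stop_fhirprep(
      paste0(
        "invalid filter specification:\n",
        paste0("  - ", errs, collapse = "\n")
      ),
      class = "fhirprep_validation_error",
      errors = errs
    )
  }
  filter_spec(base, crits, fs)
}

#' Serialise a filter specification to canonical JSON
#'
#' Inverse of [parse_spec()]: `parse_spec(spec_to_json(x))` reproduces `x`.
#'
#' @param spec A `fhir_filter_spec`.
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
spec_to_json <- function(spec, pretty = FALSE) {
  stopifnot(inherits(spec, "fhir_filter_spec"))
  cs_out <- function(cs) {
    out <- list(codes = as.list(cs$codes), match = cs$match)
    if (!is.null(cs$system)) out$system <- cs$system
    out
  }
  vf_out <- function(vf) {
    if (is.null(vf)) return(NULL)
    out <- list(comparator = vf$comparator, threshold = vf$threshold)
    if (!is.null(vf$unit)) out$unit <- vf$unit
    out
  }
  b <- spec$base
  base <- list(
    resource_type = b$resource_type,
    code_selector = cs_out(b$code_selector)
  )
  if (!is.null(vf_out(b$value_filter))) base$value_filter <- vf_out(b$value_filter)
  pf <- b$patient_filter
  if (!is.null(pf$genders) || !is.null(pf$age_min) || !is.null(pf$age_max)) {
    base$patient_filter <- Filter(Negate(is.null), list(
      genders = if (!is.null(pf$genders)) as.list(pf$genders),
      age_min = pf$age_min, age_max = pf$age_max
    ))
  }
  if (!is.null(b$time_range)) {
    base$time_range <- list(
      start = if (!is.na(b$time_range$start)) format_instant(b$time_range$start),
      end = if (!is.na(b$time_range$end)) format_instant(b$time_range$end)
    )
    base$time_range <- Filter(Negate(is.null), base$time_range)
  }
  crits <- lapply(spec$criteria, function(c) {
    out <- list(
      polarity = c$polarity, resource_type = c$resource_type,
      code_selector = cs_out(c$code_selector)
    )
    if (!is.null(vf_out(c$value_filter))) out$value_filter <- vf_out(c$value_filter)
    out$mode <- c$mode
    if (c$mode == "window") {
      out$window_before_days <- c$window_before_days
      out$window_after_days <- c$window_after_days
    }
    out$use_encounter_period <- c$use_encounter_period
    out
  })
  fs <- list(
    aggregation = spec$feature_set$aggregation,
    columns = as.list(spec$feature_set$columns)
  )
  if (!is.null(spec$feature_set$random_seed)) fs$random_seed <- spec$feature_set$random_seed
  as.character(jsonlite::toJSON(
    list(base = base, criteria = crits, feature_set = fs),
    auto_unbox = TRUE, digits = NA, pretty = pretty, null = "null"
  ))
}

#' Sanity-check a specification against a loaded store
#'
#' Never errors; returns warnings for conditions that usually indicate a
#' misspecified query: code selectors matching nothing in the store, day
#' windows wider than the store's whole time span, and value-filter units
#' that disagree with the units observed on matching resources.
#'
#' @param spec A `fhir_filter_spec`.
#' @param store A [fhir_store()].
#' @return Character vector of warnings (empty when all checks pass).
#' @export
validate_spec <- function(spec, store) {
  warnings <- character()
  check_sel <- function(rt, cs, vf, what) {
    rows <- dplyr::filter(store$resources, .data$type == rt)
    m <- code_match_rows(rows, cs)
    if (!any(m)) {
      warnings <<- c(warnings, sprintf(
        "%s: code selector {%s} matches no %s resource in store",
        what, paste(cs$codes, collapse = ","), rt
      ))
      return(invisible())
    }
    if (!is.null(vf) && !is.null(vf$unit)) {
      units <- unique(stats::na.omit(rows$unit[m]))
      if (length(units) && !vf$unit %in% units) {
        warnings <<- c(warnings, sprintf(
          "%s: value_filter unit '%s' never observed (store has: %s)",
          what, vf$unit, paste(units, collapse = ", ")
        ))
      }
    }
  }
  check_sel(
    spec$base$resource_type, spec$base$code_selector,
    spec$base$value_filter, "base"
  )
  span <- NULL
  times <- store$resources$time
  if (any(!is.na(times))) {
    span <- (max(times, na.rm = TRUE) - min(times, na.rm = TRUE)) / SECONDS_PER_DAY
  }
  for (i in seq_along(spec$criteria)) {
    c <- spec$criteria[[i]]
    check_sel(
      c$resource_type, c$code_selector, c$value_filter,
      sprintf("criteria[%d]", i - 1L)
    )
    if (c$mode == "window" && !is.null(span)) {
      w <- c$window_before_days + c$window_after_days
      if (is.finite(w) && w > span) {
        warnings <- c(warnings, sprintf(
          "criteria[%d]: window of %s days exceeds the store's %0.0f-day span",
          i - 1L, format(w), span
        ))
      }
    }
  }
  warnings
}

#' Built-in scenario specifications
#'
#' The three worked clinical scenarios shipped with the package, as parsed
#' specification objects:
#' \describe{
#'   \item{reference_interval_prep}{Hemoglobin (LOINC 718-7) in men aged
#'     18-65, excluding patients ever carrying a malignancy diagnosis
#'     (ICD-10 `C*`), ever transfused (OPS `8-80*`), ever showing hemoglobin
#'     below 8.0 g/dL, or operated on (OPS `5-*`) within 90 days of the
#'     measurement; one random finding per patient. This is the input a
#'     downstream indirect reference-interval algorithm would receive.}
#'   \item{anemia_cancer}{Hemoglobin observations with the minimum per
#'     patient, excluding patients ever carrying an ICD-10 `C*` diagnosis
#'     (the without-cancer arm; the scenario runner flips the polarity for
#'     the with-cancer arm).}
#'   \item{amphotericin_potassium}{Potassium (LOINC 2823-3) observations
#'     within 7 days either side of a liposomal amphotericin B
#'     administration (OPS `6-002.q*`).}
#' }
#'
#' @return Named list of `fhir_filter_spec` objects.
#' @export
builtin_specs <- function() {
  hgb <- code_selector("718-7", system = "http://loinc.org")
  list(
    reference_interval_prep = filter_spec(
      base = base_selector("Observation", hgb,
        genders = "male", age_min = 18, age_max = 65
      ),
      criteria = list(
        criterion("exclude", "Condition", code_selector("C", match = "prefix")),
        criterion("exclude", "Procedure", code_selector("8-80", match = "prefix")),
        criterion("exclude", "Observation", hgb, value_filter("lt", 8.0, "g/dL")),
        criterion("exclude", "Procedure", code_selector("5-", match = "prefix"),
          mode = "window", window_before_days = 90, window_after_days = 90
        )
      ),
      feature_set = feature_spec("random_one_per_patient", random_seed = 1L)
    ),
    anemia_cancer = filter_spec(
      base = base_selector("Observation", hgb),
      criteria = list(
        criterion("exclude", "Condition", code_selector("C", match = "prefix"))
      ),
      feature_set = feature_spec("min_per_patient")
    ),
    amphotericin_potassium = filter_spec(
      base = base_selector(
        "Observation",
        code_selector("2823-3", system = "http://loinc.org")
      ),
      criteria = list(
        criterion("include", "Procedure", code_selector("6-002.q", match = "prefix"),
          mode = "window", window_before_days = 7, window_after_days = 7
        )
      ),
      feature_set = feature_spec("none")
    )
  )
}
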