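# Matching semantics. A criterion matches a base resource either because a
# matching criterion resource exists for the patient at any time (ever mode)
# or because the base resource's time t_B satisfies, for SOME matching
# criterion resource with time t_C,
#   (a) t_B in [t_C - before*86400, t_C + after*86400]   (closed), or
#   (b) t_B in [period.start, period.end] of the criterion resource's
#       encounter (closed; only when use_encounter_period and the encounter
#       resolves to a period).
# (a) and (b) combine as a union. Base resources without a time are dropped
# from evaluation (with a warning) whenever time is needed.

# vectorised code-selector match over resource rows
code_match_rows <- function(rows, cs) {
  if (!nrow(rows)) return(logical(0))
  sys_sel <- cs$system
  sys_ok <- function(systems) {
    if (is.null(sys_sel) || !nzchar(sys_sel)) return(rep(TRUE, length(systems)))
    a <- tolower(systems)
    b <- tolower(sys_sel)
    a == b | vapply(a, function(s) {
      nzchar(s) && (grepl(b, s, fixed = TRUE) || grepl(s, b, fixed = TRUE))
    }, logical(1), USE.NAMES = FALSE)
  }
  if (cs$match == "exact") {
    purrr::map2_lgl(rows$codes, rows$systems, function(co, sy) {
      any(co %in% cs$codes & sys_ok(sy))
    })
  } else {
    purrr::map2_lgl(rows$codes, rows$systems, function(co, sy) {
      if (!length(co)) return(FALSE)
      pref <- vapply(co, function(x) any(startsWith(x, cs$codes)), logical(1))
      any(pref & sys_ok(sy))
    })
  }
}

value_match_rows <- function(rows, vf) {
  if (is.null(vf)) return(rep(TRUE, nrow(rows)))
  v <- rows$value
  out <- switch(vf$comparator,
    lt = v < vf$threshold,
    le = v <= vf$threshold,
    gt = v > vf$threshold,
    ge = v >= vf$threshold,
    eq = v == vf$threshold,
    ne = v != vf$threshold
  )
  out & !is.na(v)
}

#' Select the base resource set
#'
#' Applies the base selector: resource type, code selector, optional value
#' filter, calendar time range (closed), and patient filter (gender; age in
#' completed years at the resource's own time, bounds inclusive). Result
#' order is deterministic: `(patient, time, fhir_id)`.
#'
#' Base resources without an anchor time are dropped, with a warning, when
#' time is needed — i.e. when a time range or age bound is set, or when
#' `window_needed` says a window criterion will be evaluated downstream.
#'
#' @param store A [fhir_store()].
#' @param base A [base_selector()].
#' @param window_needed Set `TRUE` when the caller will evaluate window-mode
#'   criteria against the selection.
#' @return Tibble of base resource rows.
#' @export
select_base <- function(store, base, window_needed = FALSE) {
  rows <- dplyr::filter(store$resources, .data$type == base$resource_type)
  rows <- rows[code_match_rows(rows, base$code_selector), , drop = FALSE]
  rows <- rows[value_match_rows(rows, base$value_filter), , drop = FALSE]

  pf <- base$patient_filter
  need_time <- window_needed ||
    !is.null(base$time_range) ||
    !is.null(pf$age_min) || !is.null(pf$age_max)
  if (need_time) {
    n_untimed <- sum(is.na(rows$time))
    if (n_untimed > 0) {
      warning(sprintf(
        "%d base resource(s) without a time dropped (time required)", n_untimed
      ), call. = FALSE)
      rows <- rows[!is.na(rows$time), , drop = FALSE]
    }
  }
  if (!is.null(base$time_range)) {
    tr <- base$time_range
    keep <- rep(TRUE, nrow(rows))
    if (!is.na(tr$start)) keep <- keep & rows$time >= tr$start
    if (!is.na(tr$end)) keep <- keep & rows$time <= tr$end
    rows <- rows[keep, , drop = FALSE]
  }
  if (!is.null(pf$genders) || !is.null(pf$age_min) || !is.null(pf$age_max)) {
    rows <- dplyr::left_join(
      rows,
      dplyr::rename(store$patients,
        p_gender = "gender", p_birth = "birth_date"
      ),
      by = c(subject_ref = "fhir_id")
    )
    keep <- rep(TRUE, nrow(rows))
    if (!is.null(pf$genders)) {
      keep <- keep & !is.na(rows$p_gender) & rows$p_gender %in% pf$genders
    }
    if (!is.null(pf$age_min) || !is.null(pf$age_max)) {
      age <- patient_age_at(rows$p_birth, rows$time)
      keep <- keep & !is.na(age)
      if (!is.null(pf$age_min)) keep <- keep & age >= pf$age_min
      if (!is.null(pf$age_max)) keep <- keep & age <= pf$age_max
    }
    rows <- rows[keep, , drop = FALSE]
    rows$p_gender <- NULL
    rows$p_birth <- NULL
  }
  dplyr::arrange(rows, .data$subject_ref, .data$time, .data$fhir_id)
}

# all (patient, time, encounter period) instances grounding a criterion,
# for every patient at once
criterion_instances_all <- function(store, c) {
  rows <- dplyr::filter(store$resources, .data$type == c$resource_type)
  rows <- rows[code_match_rows(rows, c$code_selector), , drop = FALSE]
  rows <- rows[value_match_rows(rows, c$value_filter), , drop = FALSE]
  inst <- dplyr::select(rows, "subject_ref", inst_time = "time", "encounter_ref")
  if (isTRUE(c$use_encounter_period)) {
    enc <- store$resources %>%
      dplyr::filter(.data$type == "Encounter") %>%
      dplyr::select("fhir_id", per_start = "enc_start", per_end = "enc_end")
    inst <- dplyr::left_join(inst, enc, by = c(encounter_ref = "fhir_id"))
  } else {
    inst$per_start <- NA_real_
    inst$per_end <- NA_real_
  }
  inst[!is.na(inst$subject_ref), , drop = FALSE]
}

#' Instances grounding a criterion for one patient
#'
#' @param store A [fhir_store()].
#' @param patient_id Patient `fhir_id`.
#' @param c A [criterion()].
#' @return Tibble with one row per matching resource of the patient:
#'   `time` (epoch instant or `NA`) and the resolved encounter period
#'   (`period_start`, `period_end`; `NA` when the encounter is absent,
#'   dangling, or `use_encounter_period` is off).
#' @export
criterion_instances <- function(store, patient_id, c) {
  inst <- criterion_instances_all(store, c)
  inst <- inst[inst$subject_ref == patient_id, , drop = FALSE]
  tibble::tibble(
    time = inst$inst_time,
    period_start = inst$per_start,
    period_end = inst$per_end
  )
}

# vectorised: does the criterion match each base row?
matches_rows <- function(base_rows, c, store) {
  if (!nrow(base_rows)) return(logical(0))
  inst <- criterion_instances_all(store, c)
  if (c$mode == "ever") {
    return(base_rows$subject_ref %in% unique(inst$subject_ref))
  }
  # window mode
  before_s <- c$window_before_days * SECONDS_PER_DAY
  after_s <- c$window_after_days * SECONDS_PER_DAY
  b <- tibble::tibble(
    .row = seq_len(nrow(base_rows)),
    subject_ref = base_rows$subject_ref,
    b_time = base_rows$time
  )
  j <- dplyr::inner_join(b, inst, by = "subject_ref", relationship = "many-to-many")
  if (!nrow(j)) return(rep(FALSE, nrow(base_rows)))
  in_window <- !is.na(j$inst_time) & !is.na(j$b_time) &
    j$b_time >= j$inst_time - before_s & j$b_time <= j$inst_time + after_s
  in_period <- !is.na(j$per_start) & !is.na(j$b_time) &
    j$b_time >= j$per_start &
    (is.na(j$per_end) | j$b_time <= j$per_end)
  hit_rows <- unique(j$.row[in_window | in_period])
  seq_len(nrow(base_rows)) %in% hit_rows
}

#' Does a criterion match one base resource?
#'
#' @param base A one-row base resource tibble (e.g. a row of
#'   [select_base()]'s result).
#' @param c A [criterion()].
#' @param store A [fhir_store()].
#' @return `TRUE`/`FALSE`.
#' @export
matches <- function(base, c, store) {
  stopifnot(nrow(base) == 1)
  if (c$mode == "window" && is.na(base$time)) {
    stop_fhirprep("window-mode matching requires a base resource time",
      class = "fhirprep_validation_error"
    )
  }
  matches_rows(base, c, store)
}

#' Evaluate a filter specification against a store
#'
#' Selects the base resource set, then applies the criteria conjunctively:
#' a base resource is kept when every inclusion criterion matches it and no
#' exclusion criterion does. Ever-mode criteria are evaluated once per
#' patient. The audit records, per criterion in listed order, how many of
#' the then-surviving base resources it removed, so the removals sum to
#' `n_base - n_kept`.
#'
#' @param store A [fhir_store()].
#' @param spec A `fhir_filter_spec` (see [parse_spec()], [filter_spec()]).
#' @return A `fhir_filter_result`: list with `kept` (tibble of surviving
#'   base rows), `n_base`, and `audit` (tibble of per-criterion removals).
#' @export
apply_spec <- function(store, spec) {
  stopifnot(inherits(spec, "fhir_filter_spec"))
  any_window <- any(vapply(spec$criteria, function(c) c$mode == "window", logical(1)))
  base <- select_base(store, spec$base, window_needed = any_window)
  n_base <- nrow(base)
  kept <- base
  audit <- tibble::tibble(
    index = integer(), polarity = character(),
    resource_type = character(), mode = character(), removed = integer()
  )
  for (i in seq_along(spec$criteria)) {
    c <- spec$criteria[[i]]
    m <- matches_rows(kept, c, store)
    drop <- if (c$polarity == "exclude") m else !m
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      index = i, polarity = c$polarity, resource_type = c$resource_type,
      mode = c$mode, removed = sum(drop)
    ))
    kept <- kept[!drop, , drop = FALSE]
  }
  structure(
    list(kept = kept, n_base = n_base, audit = audit, spec = spec),
    class = "fhir_filter_result"
  )
}

#' @export
print.fhir_filter_result <- function(x, ...) {
  cat(
    "<fhir_filter_result> ", nrow(x$kept), " of ", x$n_base,
    " base resources kept\n",
    sep = ""
  )
  if (nrow(x$audit)) print(x$audit)
  invisible(x)
}
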