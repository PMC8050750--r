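#' Build the flat feature table from a filter result
#'
#' One row per kept base resource, joined with basic patient data. `age` is
#' the patient's completed age at the row's own time (not at extraction
#' time); `code` is the resource's first coding. Rows whose patient cannot
#' be resolved in the store are dropped with a warning. Order is
#' deterministic: `(patient_id, time, fhir_id)`.
#'
#' @param result A `fhir_filter_result` from [apply_spec()].
#' @param store The same [fhir_store()] the result came from.
#' @param fs A [feature_spec()]; its `columns` fix the column order of the
#'   final table (an internal `fhir_id` is retained for deterministic
#'   tie-breaking until [write_features_csv()]).
#' @return A `fhir_feature_table` (tibble subclass), not yet aggregated.
#' @seealso [aggregate_features()], [extract_features()]
#' @export
build_features <- function(result, store, fs = feature_spec()) {
  stopifnot(inherits(result, "fhir_filter_result"))
  rows <- result$kept
  tbl <- tibble::tibble(
    patient_id = rows$subject_ref,
    value = rows$value,
    unit = rows$unit,
    code = purrr::map_chr(rows$codes, function(co) {
      if (length(co)) co[[1]] else NA_character_
    }),
    time = rows$time,
    fhir_id = rows$fhir_id
  )
  tbl <- dplyr::left_join(tbl, store$patients, by = c(patient_id = "fhir_id"))
  unresolved <- is.na(tbl$patient_id) | !tbl$patient_id %in% store$patients$fhir_id
  if (any(unresolved)) {
    warning(sprintf(
      "%d row(s) dropped: patient not resolvable in store", sum(unresolved)
    ), call. = FALSE)
    tbl <- tbl[!unresolved, , drop = FALSE]
  }
  tbl$age <- patient_age_at(tbl$birth_date, tbl$time)
  tbl <- dplyr::arrange(tbl, .data$patient_id, .data$time, .data$fhir_id)
  tbl <- tbl[, c(
    intersect(FEATURE_COLUMNS, c(fs$columns, FEATURE_COLUMNS)),
    "fhir_id"
  )]
  new_feature_table(tbl, fs)
}

new_feature_table <- function(tbl, fs) {
  structure(tbl,
    class = c("fhir_feature_table", class(tibble::as_tibble(tbl))),
    feature_spec = fs
  )
}

#' Per-patient aggregation of a feature table
#'
#' Reduces the table to exactly one row per patient:
#' `min_per_patient`/`max_per_patient` pick the row with the extreme value
#' (ties broken by earliest time, then smallest `fhir_id`; patients with no
#' non-missing value are dropped with a warning), `first_per_patient` the
#' earliest row, and `random_one_per_patient` a uniform choice driven by a
#' per-patient random stream derived from `(random_seed, patient_id)` — so
#' the draw for one patient does not change when other patients are added
#' or removed.
#'
#' @param t A `fhir_feature_table`.
#' @param fs A [feature_spec()]; defaults to the one the table was built
#'   with.
#' @return The aggregated `fhir_feature_table`.
#' @export
aggregate_features <- function(t, fs = attr(t, "feature_spec")) {
  stopifnot(inherits(t, "fhir_feature_table"))
  agg <- fs$aggregation
  if (agg == "none" || !nrow(t)) return(new_feature_table(t, fs))
  tbl <- tibble::as_tibble(t)

  if (agg %in% c("min_per_patient", "max_per_patient")) {
    has_val <- !is.na(tbl$value)
    dropped <- setdiff(unique(tbl$patient_id), unique(tbl$patient_id[has_val]))
    if (length(dropped)) {
      warning(sprintf(
        "%d patient(s) dropped: no non-missing value to aggregate",
        length(dropped)
      ), call. = FALSE)
    }
    tbl <- tbl[has_val, , drop = FALSE]
    tbl <- if (agg == "min_per_patient") {
      dplyr::arrange(tbl, .data$patient_id, .data$value, .data$time, .data$fhir_id)
    } else {
      dplyr::arrange(tbl, .data$patient_id, dplyr::desc(.data$value), .data$time, .data$fhir_id)
    }
    out <- dplyr::slice_head(dplyr::group_by(tbl, .data$patient_id), n = 1)
    out <- dplyr::ungroup(out)
  } else if (agg == "first_per_patient") {
    tbl <- dplyr::arrange(tbl, .data$patient_id, .data$time, .data$fhir_id)
    out <- dplyr::ungroup(dplyr::slice_head(dplyr::group_by(tbl, .data$patient_id), n = 1))
  } else { # random_one_per_patient
    seed <- fs$random_seed
    pids <- sort(unique(tbl$patient_id))
    picks <- lapply(pids, function(pid) {
      sub <- tbl[tbl$patient_id == pid, , drop = FALSE]
      sub <- dplyr::arrange(sub, .data$time, .data$fhir_id)
      local_seed <- (as.numeric(seed) + as.numeric(str_hash32(pid))) %% 2147483647
      idx <- withr_seed_sample(as.integer(local_seed), nrow(sub))
      sub[idx, , drop = FALSE]
    })
    out <- dplyr::bind_rows(picks)
  }
  out <- dplyr::arrange(out, .data$patient_id)
  new_feature_table(out, fs)
}

# one uniform draw from 1..n under a local seed, leaving the global RNG alone
withr_seed_sample <- function(seed, n) {
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
  set.seed(seed)
  sample.int(n, 1)
}

#' Run the whole extraction pipeline
#'
#' [apply_spec()], [build_features()], [aggregate_features()] and column
#' selection in one call: store and spec in, analysis-ready tibble out.
#'
#' @param store A [fhir_store()].
#' @param spec A `fhir_filter_spec`.
#' @return A `fhir_feature_table` with the spec's feature columns.
#' @export
extract_features <- function(store, spec) {
  result <- apply_spec(store, spec)
  t <- build_features(result, store, spec$feature_set)
  aggregate_features(t, spec$feature_set)
}

#' Write a feature table as CSV
#'
#' RFC 4180 CSV with a header row, UTF-8, ISO 8601 times and `.` decimal
#' separator; only the feature-spec columns are written (the internal
#' `fhir_id` tie-break column is dropped).
#'
#' @param t A `fhir_feature_table`.
#' @param path Output path.
#' @return The number of data rows written.
#' @export
write_features_csv <- function(t, path) {
  fs <- attr(t, "feature_spec") %||% feature_spec()
  cols <- intersect(fs$columns, names(t))
  out <- tibble::as_tibble(t)[, cols, drop = FALSE]
  if ("time" %in% names(out)) out$time <- format_instant(out$time)
  readr::write_csv(out, path, na = "")
  nrow(out)
}

#' Read back a feature-table CSV
#'
#' @param path CSV written by [write_features_csv()].
#' @return A tibble; `time` parsed back to epoch instants.
#' @export
read_features_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("time" %in% names(out)) {
    out$time <- if (inherits(out$time, "POSIXt")) {
      as.numeric(out$time)
    } else {
      parse_instant(as.character(out$time))
    }
  }
  if ("patient_id" %in% names(out)) out$patient_id <- as.character(out$patient_id)
  out
}
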