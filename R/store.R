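#' Create an empty FHIR document store
#'
#' The store mirrors the one-table layout used by FHIR-on-relational
#' deployments — a surrogate `id`, the resource's `fhir_id`, its `type` and
#' the raw JSON document — extended with the extracted index columns the
#' filter engine queries (patient/encounter linkage, anchor time, codings,
#' value, demographics, encounter period). `(type, fhir_id)` is unique;
#' reloading an existing resource replaces the prior row (last-write-wins)
#' with a warning in the load report.
#'
#' @return A `fhir_store` object.
#' @seealso [store_load_ndjson()], [store_load_bundle()], [store_stats()]
#' @export
fhir_store <- function() {
  structure(
    list(
      resources = empty_resources(),
      patients = tibble::tibble(
        fhir_id = character(), gender = character(),
        birth_date = as.Date(character())
      ),
      last_report = NULL
    ),
    class = "fhir_store"
  )
}

empty_resources <- function() {
  tibble::tibble(
    id = integer(),
    fhir_id = character(),
    type = character(),
    subject_ref = character(),
    encounter_ref = character(),
    time = double(),
    value = double(),
    unit = character(),
    gender = character(),
    birth_date = as.Date(character()),
    enc_start = double(),
    enc_end = double(),
    systems = list(),
    codes = list(),
    json = character()
  )
}

#' @export
print.fhir_store <- function(x, ...) {
  cat("<fhir_store> ", nrow(x$resources), " resources\n", sep = "")
  s <- store_stats(x)
  if (nrow(s)) print(s)
  invisible(x)
}

# insert parsed rows with last-write-wins duplicate handling
store_insert <- function(store, rows, warnings = character()) {
  if (nrow(rows)) {
    dup_keys <- paste(rows$type, rows$fhir_id)
    prior_keys <- paste(store$resources$type, store$resources$fhir_id)
    # duplicates within the batch: keep the last occurrence
    batch_dup <- duplicated(dup_keys, fromLast = TRUE)
    n_batch_dup <- sum(batch_dup)
    rows_keep <- rows[!batch_dup, , drop = FALSE]
    keys_keep <- dup_keys[!batch_dup]
    replaced <- prior_keys %in% keys_keep
    n_dup <- sum(replaced) + n_batch_dup
    if (n_dup > 0) {
      warnings <- c(warnings, sprintf(
        "%d duplicate resource(s) replaced (last write wins)", n_dup
      ))
    }
    kept_prior <- store$resources[!replaced, , drop = FALSE]
    rows_keep$id <- seq.int(
      from = if (nrow(kept_prior)) max(kept_prior$id) + 1L else 1L,
      length.out = nrow(rows_keep)
    )
    store$resources <- dplyr::bind_rows(kept_prior, rows_keep)
  }
  pats <- store$resources %>%
    dplyr::filter(.data$type == "Patient") %>%
    dplyr::select("fhir_id", "gender", "birth_date")
  store$patients <- pats

  non_patient <- store$resources$type != "Patient"
  n_orphan <- sum(non_patient & is.na(store$resources$subject_ref))
  if (n_orphan > 0) {
    warnings <- c(warnings, sprintf(
      "%d non-Patient resource(s) without subject reference", n_orphan
    ))
  }
  list(store = store, warnings = warnings)
}

# vectorised field extraction over a batch of parsed documents; returns the
# resource rows plus skip/warning bookkeeping. Semantically identical to
# parse_resource() row by row, but without per-row tibble construction.
extract_columns <- function(docs, body, body_idx) {
  n <- length(docs)
  fhir_id <- character(n)
  type <- character(n)
  subj <- rep(NA_character_, n)
  encr <- rep(NA_character_, n)
  time_s <- rep(NA_character_, n)
  value <- rep(NA_real_, n)
  unit <- rep(NA_character_, n)
  gender <- rep(NA_character_, n)
  birth_s <- rep(NA_character_, n)
  es_s <- rep(NA_character_, n)
  ee_s <- rep(NA_character_, n)
  systems <- vector("list", n)
  codes <- vector("list", n)
  ok <- logical(n)
  skipped <- 0L
  warnings <- character()
  skip <- function(i, msg) {
    skipped <<- skipped + 1L
    if (length(warnings) < 50) {
      warnings <<- c(warnings, sprintf("line %d skipped: %s", body_idx[i], msg))
    }
  }

  for (i in seq_len(n)) {
    d <- docs[[i]]
    rt <- d$resourceType
    if (is.null(rt) || !rt %in% SUPPORTED_TYPES) {
      skip(i, sprintf("unsupported resourceType: %s", rt %||% "<missing>"))
      next
    }
    if (is.null(d$id) || !nzchar(d$id)) {
      skip(i, sprintf("%s resource without id", rt))
      next
    }
    ok[i] <- TRUE
    fhir_id[i] <- as.character(d$id)
    type[i] <- rt
    sr <- normalize_ref(d$subject$reference %||% d$subject$id %||% NULL)
    if (!is.null(sr)) subj[i] <- sr
    er <- normalize_ref(d$encounter$reference %||% d$context$reference %||% NULL)
    if (!is.null(er)) encr[i] <- er

    cc <- switch(rt,
      Condition = ,
      Procedure = ,
      Observation = d$code,
      MedicationStatement = d$medicationCodeableConcept,
      NULL
    )
    codings <- extract_codings(cc)
    systems[[i]] <- vapply(codings, function(x) x$system, character(1))
    codes[[i]] <- vapply(codings, function(x) x$code, character(1))

    tc <- switch(rt,
      Observation = d$effectiveDateTime %||% d$issued,
      Condition = d$recordedDate %||% d$onsetDateTime,
      Procedure = d$performedDateTime %||% d$performedPeriod$start,
      MedicationStatement = d$effectiveDateTime %||% d$effectivePeriod$start,
      Encounter = d$period$start,
      Patient = NULL
    )
    if (!is.null(tc)) time_s[i] <- tc

    if (rt == "Observation" && !is.null(d$valueQuantity)) {
      v <- d$valueQuantity$value
      if (!is.null(v) && is.numeric(v) && is.finite(v)) value[i] <- as.numeric(v)
      u <- d$valueQuantity$unit
      if (!is.null(u)) unit[i] <- u
    }
    if (rt == "Patient") {
      gender[i] <- d$gender %||% "unknown"
      if (!is.null(d$birthDate)) birth_s[i] <- d$birthDate
    }
    if (rt == "Encounter" && !is.null(d$period)) {
      if (!is.null(d$period$start)) es_s[i] <- d$period$start
      if (!is.null(d$period$end)) ee_s[i] <- d$period$end
    }
  }

  tp <- try_parse_instant(time_s)
  ts <- try_parse_instant(es_s)
  te <- try_parse_instant(ee_s)
  bad_time <- (tp$bad | ts$bad | te$bad) & ok
  bad_period <- ok & !is.na(ts$values) & !is.na(te$values) &
    te$values < ts$values
  for (i in which(bad_time)) skip(i, "malformed timestamp")
  for (i in which(bad_period & !bad_time)) skip(i, "encounter period end precedes start")
  ok <- ok & !bad_time & !bad_period

  birth <- as.Date(rep(NA_character_, n))
  has_birth <- ok & !is.na(birth_s)
  if (any(has_birth)) {
    suppressWarnings(bd <- as.Date(birth_s[has_birth], format = "%Y-%m-%d"))
    birth[has_birth] <- bd
  }

  rows <- tibble::tibble(
    fhir_id = fhir_id[ok],
    type = type[ok],
    subject_ref = subj[ok],
    encounter_ref = encr[ok],
    time = tp$values[ok],
    value = value[ok],
    unit = unit[ok],
    gender = gender[ok],
    birth_date = birth[ok],
    enc_start = ts$values[ok],
    enc_end = te$values[ok],
    systems = systems[ok],
    codes = codes[ok],
    json = body[ok]
  )
  list(rows = rows, skipped = skipped, warnings = warnings)
}

load_docs <- function(store, texts) {
  blank <- !nzchar(trimws(texts))
  skipped <- sum(blank)
  warnings <- character()
  if (skipped > 0) {
    warnings <- c(warnings, sprintf("%d blank line(s) skipped", skipped))
  }
  body <- texts[!blank]
  body_idx <- which(!blank)

  # fast path: one array parse for the whole batch; per-line fallback when
  # any line is malformed JSON
  docs <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(body, collapse = ","), "]"),
      simplifyVector = FALSE
    ),
    error = function(e) NULL
  )
  if (is.null(docs)) {
    docs <- vector("list", length(body))
    for (i in seq_along(body)) {
      docs[[i]] <- tryCatch(
        jsonlite::fromJSON(body[[i]], simplifyVector = FALSE),
        error = function(e) NULL
      )
      if (is.null(docs[[i]])) {
        skipped <- skipped + 1L
        if (length(warnings) < 50) {
          warnings <- c(warnings, sprintf(
            "line %d skipped: malformed JSON", body_idx[i]
          ))
        }
      }
    }
    keep <- !vapply(docs, is.null, logical(1))
    docs <- docs[keep]
    body <- body[keep]
    body_idx <- body_idx[keep]
  }

  parsed <- extract_columns(docs, body, body_idx)
  skipped <- skipped + parsed$skipped
  warnings <- c(warnings, parsed$warnings)
  ins <- store_insert(store, parsed$rows, warnings)
  store <- ins$store
  loaded <- table(factor(parsed$rows$type, levels = SUPPORTED_TYPES))
  report <- structure(
    list(
      loaded = stats::setNames(as.integer(loaded), names(loaded)),
      skipped = skipped,
      warnings = ins$warnings
    ),
    class = "fhir_load_report"
  )
  store$last_report <- report
  store
}

#' @export
print.fhir_load_report <- function(x, ...) {
  cat("<fhir_load_report>\n")
  nz <- x$loaded[x$loaded > 0]
  cat("  loaded:", if (length(nz)) paste(names(nz), nz, collapse = ", ") else "0", "\n")
  cat("  skipped:", x$skipped, "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Load newline-delimited JSON resources into a store
#'
#' One JSON resource per line; blank or malformed lines are counted as
#' skipped, never fatal. Resources already present (same type and `fhir_id`)
#' are replaced, with a duplicate warning in the report.
#'
#' @param store A [fhir_store()].
#' @param path Path to an NDJSON file.
#' @return The updated store; retrieve the load report with [load_report()].
#' @export
store_load_ndjson <- function(store, path) {
  if (!file.exists(path)) {
    stop_fhirprep(sprintf("cannot read file: %s", path),
      class = "fhirprep_io_error"
    )
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  load_docs(store, lines)
}

#' Load a FHIR Bundle into a store
#'
#' @param store A [fhir_store()].
#' @param path Path to a Bundle JSON file with an `entry` array
#'   (searchset, collection or transaction bundles).
#' @return The updated store; retrieve the load report with [load_report()].
#' @export
store_load_bundle <- function(store, path) {
  if (!file.exists(path)) {
    stop_fhirprep(sprintf("cannot read file: %s", path),
      class = "fhirprep_io_error"
    )
  }
  d <- jsonlite::fromJSON(readChar(path, file.info(path)$size),
    simplifyVector = FALSE
  )
  if (is.null(d$entry)) {
    stop_fhirprep("Bundle has no entry array", class = "fhirprep_io_error")
  }
  texts <- vapply(d$entry, function(e) {
    if (is.null(e$resource)) return("")
    as.character(jsonlite::toJSON(e$resource, auto_unbox = TRUE, digits = NA))
  }, character(1))
  load_docs(store, texts)
}

#' Report of the most recent load into a store
#'
#' @param store A [fhir_store()].
#' @return A `fhir_load_report` (counts loaded per type, skipped count,
#'   warnings), or `NULL` if nothing has been loaded.
#' @export
load_report <- function(store) store$last_report

#' Resources of one type
#'
#' @param store A [fhir_store()].
#' @param type One of Patient, Encounter, Condition, Procedure, Observation,
#'   MedicationStatement.
#' @return A tibble of resource rows (see [parse_resource()] for columns).
#' @export
get_by_type <- function(store, type) {
  stopifnot(type %in% SUPPORTED_TYPES)
  dplyr::filter(store$resources, .data$type == !!type)
}

#' Demographics of one patient
#'
#' @param store A [fhir_store()].
#' @param pid Patient `fhir_id`.
#' @return A one-row tibble (`fhir_id`, `gender`, `birth_date`) or `NULL`.
#' @export
get_patient <- function(store, pid) {
  hit <- dplyr::filter(store$patients, .data$fhir_id == pid)
  if (!nrow(hit)) return(NULL)
  hit[1, ]
}

#' Resolve an encounter reference to its period
#'
#' @param store A [fhir_store()].
#' @param eid Encounter `fhir_id`.
#' @return A list `list(start =, end =)` of epoch instants, or `NULL` when
#'   the encounter is absent or has no period (the latter with a warning).
#' @export
resolve_encounter <- function(store, eid) {
  hit <- store$resources[store$resources$type == "Encounter" &
    store$resources$fhir_id == eid, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  if (is.na(hit$enc_start[1])) {
    warning(sprintf("Encounter/%s has no period", eid), call. = FALSE)
    return(NULL)
  }
  list(start = hit$enc_start[1], end = hit$enc_end[1])
}

#' Resource counts per type
#'
#' @param store A [fhir_store()].
#' @return A tibble with columns `type` and `n` covering all six supported
#'   types (zero rows included).
#' @export
store_stats <- function(store) {
  tibble::tibble(
    type = SUPPORTED_TYPES,
    n = vapply(
      SUPPORTED_TYPES,
      function(t) sum(store$resources$type == t), integer(1),
      USE.NAMES = FALSE
    )
  )
}

#' Export a store to NDJSON
#'
#' Writes the raw `data` documents one per line, in surrogate-id order, so
#' that reloading reproduces the store byte-for-byte.
#'
#' @param store A [fhir_store()].
#' @param path Output file path.
#' @return The number of lines written, invisibly.
#' @export
store_save <- function(store, path) {
  writeLines(store$resources$json, path, useBytes = TRUE)
  invisible(nrow(store$resources))
}

#' Open a store previously saved with [store_save()]
#'
#' @param path NDJSON file path.
#' @return A `fhir_store`.
#' @export
store_open <- function(path) {
  store_load_ndjson(fhir_store(), path)
}
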