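#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

SUPPORTED_TYPES <- c(
  "Patient", "Encounter", "Condition", "Procedure",
  "Observation", "MedicationStatement"
)

#' Parse one FHIR R4 resource
#'
#' Minimal, index-oriented parsing: the raw document is retained verbatim and
#' only the fields the filter engine needs are lifted into columns — patient
#' and encounter linkage, the resource's anchor time, codings, numeric value
#' and unit, demographics, encounter period. Reference strings may be relative
#' (`"Patient/p1"`) or bare ids; both are normalised to the bare id.
#'
#' @param doc A JSON string, or an already-parsed list with a `resourceType`
#'   field among Patient, Encounter, Condition, Procedure, Observation,
#'   MedicationStatement.
#' @return A one-row tibble with columns `fhir_id`, `type`, `subject_ref`,
#'   `encounter_ref`, `time` (epoch seconds, UTC), `value`, `unit`, `gender`,
#'   `birth_date`, `enc_start`, `enc_end`, list-columns `systems`/`codes`,
#'   and `json` (the raw document).
#' @seealso [resource_time()], [resource_codes()]
#' @examples
#' parse_resource('{"resourceType":"Patient","id":"p1","gender":"male",
#'                  "birthDate":"1980-01-15"}')
#' @export
parse_resource <- function(doc) {
  if (is.character(doc)) {
    txt <- doc
    d <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  } else {
    d <- doc
    txt <- as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA))
  }
  parse_resource_doc(d, txt)
}

# internal: parsed list + original text -> one-row tibble
parse_resource_doc <- function(d, txt) {
  rt <- d$resourceType
  if (is.null(rt) || !rt %in% SUPPORTED_TYPES) {
    stop_fhirprep(
      sprintf("unsupported resourceType: %s", rt %||% "<missing>"),
      class = "fhirprep_unsupported_type"
    )
  }
  if (is.null(d$id) || !nzchar(d$id)) {
    stop_fhirprep(sprintf("%s resource without id", rt),
      class = "fhirprep_missing_id"
    )
  }

  subject_ref <- normalize_ref(d$subject$reference %||% d$subject$id %||% NULL)
  encounter_ref <- normalize_ref(
    d$encounter$reference %||% d$context$reference %||% NULL
  )

  cc <- switch(rt,
    Condition = ,
    Procedure = ,
    Observation = d$code,
    MedicationStatement = d$medicationCodeableConcept,
    NULL
  )
  codings <- extract_codings(cc)

  tm <- tryCatch(
    anchor_time(d, rt),
    fhirprep_time_error = function(e) {
      stop_fhirprep(
        sprintf("resource %s/%s: %s", rt, d$id, conditionMessage(e)),
        class = "fhirprep_time_error"
      )
    }
  )

  value <- NA_real_
  unit <- NA_character_
  if (rt == "Observation" && !is.null(d$valueQuantity)) {
    v <- d$valueQuantity$value
    if (!is.null(v) && is.numeric(v) && is.finite(v)) value <- as.numeric(v)
    unit <- d$valueQuantity$unit %||% NA_character_
  }

  gender <- NA_character_
  birth_date <- as.Date(NA)
  if (rt == "Patient") {
    gender <- d$gender %||% "unknown"
    if (!is.null(d$birthDate)) {
      birth_date <- tryCatch(as.Date(d$birthDate), error = function(e) as.Date(NA))
    }
  }

  enc_start <- NA_real_
  enc_end <- NA_real_
  if (rt == "Encounter" && !is.null(d$period)) {
    enc_start <- parse_instant(d$period$start %||% NA_character_)
    enc_end <- parse_instant(d$period$end %||% NA_character_)
    if (!is.na(enc_start) && !is.na(enc_end) && enc_end < enc_start) {
      stop_fhirprep(
        sprintf("Encounter/%s period end precedes start", d$id),
        class = "fhirprep_time_error"
      )
    }
  }

  tibble::tibble(
    fhir_id = as.character(d$id),
    type = rt,
    subject_ref = subject_ref %||% NA_character_,
    encounter_ref = encounter_ref %||% NA_character_,
    time = tm,
    value = value,
    unit = unit,
    gender = gender,
    birth_date = birth_date,
    enc_start = enc_start,
    enc_end = enc_end,
    systems = list(vapply(codings, function(x) x$system, character(1))),
    codes = list(vapply(codings, function(x) x$code, character(1))),
    json = txt
  )
}

normalize_ref <- function(ref) {
  if (is.null(ref) || !nzchar(ref)) return(NULL)
  parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
  parts[length(parts)]
}

extract_codings <- function(cc) {
  if (is.null(cc) || is.null(cc$coding)) return(list())
  out <- lapply(cc$coding, function(co) {
    code <- co$code %||% NULL
    if (is.null(code) || !nzchar(code)) return(NULL)
    list(system = co$system %||% "", code = as.character(code))
  })
  out[!vapply(out, is.null, logical(1))]
}

# one anchor time per resource, with the documented fallbacks
anchor_time <- function(d, rt) {
  cand <- switch(rt,
    Observation = d$effectiveDateTime %||% d$issued,
    Condition = d$recordedDate %||% d$onsetDateTime,
    Procedure = d$performedDateTime %||% d$performedPeriod$start,
    MedicationStatement = d$effectiveDateTime %||% d$effectivePeriod$start,
    Encounter = d$period$start,
    Patient = NULL
  )
  if (is.null(cand)) return(NA_real_)
  parse_instant(cand)
}

#' Anchor time of a parsed resource
#'
#' Each resource contributes a single point in time to the matching logic:
#' Observations use `effectiveDateTime` (falling back to `issued`), Conditions
#' `recordedDate` (falling back to `onsetDateTime`), Procedures
#' `performedDateTime` (falling back to `performedPeriod.start`),
#' MedicationStatements `effectiveDateTime` (falling back to
#' `effectivePeriod.start`) and Encounters `period.start`. Patients are
#' timeless.
#'
#' @param r A resource row from [parse_resource()] (or several rows).
#' @return Numeric epoch seconds, `NA` when no candidate element is present.
#' @export
resource_time <- function(r) {
  r$time
}

#' Codings of a resource's primary code element
#'
#' @param r A one-row resource tibble from [parse_resource()].
#' @return A tibble with columns `system` and `code`, one row per coding
#'   entry, in document order; zero rows when the resource is uncoded.
#' @export
resource_codes <- function(r) {
  tibble::tibble(
    system = r$systems[[1]],
    code = r$codes[[1]]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
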