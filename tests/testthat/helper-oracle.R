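# Independent brute-force evaluator used as the oracle for the filter
# engine: plain nested loops over materialized (base, instance) pairs, no
# vectorization, no caching, no joins. Returns the kept fhir_ids, sorted.

DAY <- 86400

oracle_code_match <- function(systems, codes, cs) {
  if (length(codes) == 0) return(FALSE)
  for (i in seq_along(codes)) {
    code_ok <- if (cs$match == "exact") {
      codes[i] %in% cs$codes
    } else {
      any(vapply(cs$codes, function(p) startsWith(codes[i], p), logical(1)))
    }
    sys_ok <- TRUE
    if (!is.null(cs$system) && nzchar(cs$system)) {
      a <- tolower(systems[i])
      b <- tolower(cs$system)
      sys_ok <- (a == b) ||
        (nzchar(a) && (grepl(b, a, fixed = TRUE) || grepl(a, b, fixed = TRUE)))
    }
    if (code_ok && sys_ok) return(TRUE)
  }
  FALSE
}

oracle_value_match <- function(value, vf) {
  if (is.null(vf)) return(TRUE)
  if (is.na(value)) return(FALSE)
  switch(vf$comparator,
    lt = value < vf$threshold, le = value <= vf$threshold,
    gt = value > vf$threshold, ge = value >= vf$threshold,
    eq = value == vf$threshold, ne = value != vf$threshold
  )
}

oracle_apply_spec <- function(store, spec) {
  rows <- store$resources
  b <- spec$base
  any_window <- any(vapply(spec$criteria, function(c) c$mode == "window", logical(1)))
  pf <- b$patient_filter
  need_time <- any_window || !is.null(b$time_range) ||
    !is.null(pf$age_min) || !is.null(pf$age_max)

  base_idx <- integer()
  for (i in seq_len(nrow(rows))) {
    if (rows$type[i] != b$resource_type) next
    if (!oracle_code_match(rows$systems[[i]], rows$codes[[i]], b$code_selector)) next
    if (!oracle_value_match(rows$value[i], b$value_filter)) next
    if (need_time && is.na(rows$time[i])) next
    if (!is.null(b$time_range)) {
      tr <- b$time_range
      if (!is.na(tr$start) && rows$time[i] < tr$start) next
      if (!is.na(tr$end) && rows$time[i] > tr$end) next
    }
    if (!is.null(pf$genders) || !is.null(pf$age_min) || !is.null(pf$age_max)) {
      pat <- NULL
      for (j in seq_len(nrow(rows))) {
        if (rows$type[j] == "Patient" &&
          identical(rows$fhir_id[j], rows$subject_ref[i])) {
          pat <- j
          break
        }
      }
      if (is.null(pat)) next
      if (!is.null(pf$genders) && !(rows$gender[pat] %in% pf$genders)) next
      if (!is.null(pf$age_min) || !is.null(pf$age_max)) {
        if (is.na(rows$birth_date[pat])) next
        age <- oracle_age(rows$birth_date[pat], rows$time[i])
        if (!is.null(pf$age_min) && age < pf$age_min) next
        if (!is.null(pf$age_max) && age > pf$age_max) next
      }
    }
    base_idx <- c(base_idx, i)
  }

  kept <- character()
  for (i in base_idx) {
    keep <- TRUE
    for (c in spec$criteria) {
      m <- oracle_criterion_matches(rows, i, c)
      if (c$polarity == "include" && !m) keep <- FALSE
      if (c$polarity == "exclude" && m) keep <- FALSE
    }
    if (keep) kept <- c(kept, rows$fhir_id[i])
  }
  sort(kept)
}

oracle_criterion_matches <- function(rows, base_i, c) {
  pid <- rows$subject_ref[base_i]
  if (is.na(pid)) return(FALSE)
  bt <- rows$time[base_i]
  for (j in seq_len(nrow(rows))) {
    if (rows$type[j] != c$resource_type) next
    if (!identical(rows$subject_ref[j], pid)) next
    if (!oracle_code_match(rows$systems[[j]], rows$codes[[j]], c$code_selector)) next
    if (!oracle_value_match(rows$value[j], c$value_filter)) next
    if (c$mode == "ever") return(TRUE)
    # window mode, clause (a): day window around the instance time
    tc <- rows$time[j]
    if (!is.na(tc) && !is.na(bt) &&
      bt >= tc - c$window_before_days * DAY &&
      bt <= tc + c$window_after_days * DAY) {
      return(TRUE)
    }
    # clause (b): the instance's encounter period
    if (isTRUE(c$use_encounter_period) && !is.na(rows$encounter_ref[j])) {
      for (k in seq_len(nrow(rows))) {
        if (rows$type[k] == "Encounter" &&
          identical(rows$fhir_id[k], rows$encounter_ref[j]) &&
          !is.na(rows$enc_start[k])) {
          inside <- !is.na(bt) && bt >= rows$enc_start[k] &&
            (is.na(rows$enc_end[k]) || bt <= rows$enc_end[k])
          if (inside) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# independent completed-years computation: count passed anniversaries,
# where an invalid Feb-29 anniversary falls on Mar 1
oracle_age <- function(birth, t_epoch) {
  d <- as.Date(as.POSIXct(t_epoch, origin = "1970-01-01", tz = "UTC"), tz = "UTC")
  bl <- as.POSIXlt(birth)
  age <- 0
  repeat {
    y <- bl$year + 1900 + age + 1
    ann <- as.Date(sprintf("%04d-%02d-%02d", y, bl$mon + 1, bl$mday))
    if (is.na(ann)) ann <- as.Date(sprintf("%04d-03-01", y))
    if (ann > d) break
    age <- age + 1
  }
  age
}
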