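# In-code fixtures: tiny handcrafted stores plus a randomized store/spec
# factory for property tests. Nothing is read from disk.

json_patient <- function(id, gender = "male", birth = "1980-01-15") {
  sprintf(
    '{"resourceType":"Patient","id":"%s","gender":"%s","birthDate":"%s"}',
    id, gender, birth
  )
}

json_encounter <- function(id, pid, start, end) {
  sprintf(
    paste0(
      '{"resourceType":"Encounter","id":"%s",',
      '"subject":{"reference":"Patient/%s"},',
      '"period":{"start":"%s","end":"%s"}}'
    ),
    id, pid, start, end
  )
}

json_observation <- function(id, pid, code = "718-7", value = 13.5,
                             unit = "g/dL", time = "2017-03-02T08:00:00Z",
                             eid = NULL, system = "http://loinc.org") {
  enc <- if (!is.null(eid)) {
    sprintf(',"encounter":{"reference":"Encounter/%s"}', eid)
  } else {
    ""
  }
  sprintf(
    paste0(
      '{"resourceType":"Observation","id":"%s",',
      '"subject":{"reference":"Patient/%s"}%s,',
      '"code":{"coding":[{"system":"%s","code":"%s"}]},',
      '"valueQuantity":{"value":%s,"unit":"%s"},',
      '"effectiveDateTime":"%s"}'
    ),
    id, pid, enc, system, code, format(value), unit, time
  )
}

json_condition <- function(id, pid, code = "C50.1", time = "2017-01-05",
                           eid = NULL,
                           system = "http://fhir.de/CodeSystem/dimdi/icd-10-gm") {
  enc <- if (!is.null(eid)) {
    sprintf(',"encounter":{"reference":"Encounter/%s"}', eid)
  } else {
    ""
  }
  sprintf(
    paste0(
      '{"resourceType":"Condition","id":"%s",',
      '"subject":{"reference":"Patient/%s"}%s,',
      '"code":{"coding":[{"system":"%s","code":"%s"}]},',
      '"recordedDate":"%s"}'
    ),
    id, pid, enc, system, code, time
  )
}

json_procedure <- function(id, pid, code = "5-123.4", time = "2017-01-05",
                           eid = NULL,
                           system = "http://fhir.de/CodeSystem/dimdi/ops") {
  enc <- if (!is.null(eid)) {
    sprintf(',"encounter":{"reference":"Encounter/%s"}', eid)
  } else {
    ""
  }
  sprintf(
    paste0(
      '{"resourceType":"Procedure","id":"%s",',
      '"subject":{"reference":"Patient/%s"}%s,',
      '"code":{"coding":[{"system":"%s","code":"%s"}]},',
      '"performedDateTime":"%s"}'
    ),
    id, pid, enc, system, code, time
  )
}

store_from_lines <- function(lines) {
  tmp <- tempfile(fileext = ".ndjson")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  suppressWarnings(store_load_ndjson(fhir_store(), tmp))
}

# day offsets from a fixed origin keep handcrafted timelines readable
day_iso <- function(day, hour = 12) {
  format_instant(parse_instant("2017-01-01") + day * 86400 + hour * 3600)
}

# ---- randomized store + spec factory for oracle/property tests ------------

CODE_POOL <- c("C12.3", "C50.1", "E11.9", "5-123.4", "5-987.0", "8-801.2",
               "6-002.q0", "718-7", "2823-3")

random_store <- function(seed, n_patients = 20) {
  set.seed(seed)
  lines <- character()
  pids <- sprintf("p%02d", seq_len(n_patients))
  genders <- sample(c("male", "female"), n_patients, replace = TRUE)
  births <- sprintf("19%02d-0%d-1%d", sample(30:99, n_patients, replace = TRUE),
    sample(1:9, n_patients, replace = TRUE), sample(0:9, n_patients, replace = TRUE))
  lines <- c(lines, json_patient(pids, genders, births))
  eids <- character(0)
  enc_owner <- character(0)
  k <- 0
  for (i in seq_len(n_patients)) {
    for (j in seq_len(sample(0:3, 1))) {
      k <- k + 1
      id <- sprintf("e%03d", k)
      d0 <- sample(0:600, 1)
      len <- sample(1:20, 1)
      lines <- c(lines, json_encounter(id, pids[i], day_iso(d0), day_iso(d0 + len)))
      eids <- c(eids, id)
      enc_owner <- c(enc_owner, pids[i])
    }
  }
  n_res <- sample(20:60, 1)
  for (r in seq_len(n_res)) {
    pid <- sample(pids, 1)
    own <- eids[enc_owner == pid]
    eid <- if (length(own) && stats::runif(1) < 0.6) sample(own, 1) else NULL
    if (!is.null(eid) && stats::runif(1) < 0.1) eid <- "e999" # dangling
    code <- sample(CODE_POOL, 1)
    t <- day_iso(sample(0:700, 1), sample(0:23, 1))
    kind <- sample(c("obs", "cond", "proc"), 1)
    lines <- c(lines, switch(kind,
      obs = json_observation(sprintf("o%03d", r), pid,
        code = code,
        value = round(stats::runif(1, 2, 20), 1), time = t, eid = eid
      ),
      cond = json_condition(sprintf("c%03d", r), pid, code = code, time = t, eid = eid),
      proc = json_procedure(sprintf("q%03d", r), pid, code = code, time = t, eid = eid)
    ))
  }
  store_from_lines(lines)
}

random_spec <- function(seed) {
  set.seed(seed + 10000)
  base_code <- sample(c("718-7", "2823-3", "C", "5-"), 1)
  base_match <- if (base_code %in% c("C", "5-")) "prefix" else "exact"
  base_type <- if (base_code %in% c("718-7", "2823-3")) "Observation" else {
    sample(c("Observation", "Condition", "Procedure"), 1)
  }
  vf <- if (base_type == "Observation" && stats::runif(1) < 0.3) {
    value_filter(sample(c("lt", "ge"), 1), round(stats::runif(1, 5, 15), 1))
  }
  genders <- if (stats::runif(1) < 0.3) sample(c("male", "female"), 1)
  age_min <- if (stats::runif(1) < 0.3) sample(0:40, 1)
  n_crit <- sample(0:3, 1)
  crits <- lapply(seq_len(n_crit), function(i) {
    mode <- sample(c("ever", "window"), 1)
    code <- sample(CODE_POOL, 1)
    use_prefix <- stats::runif(1) < 0.5
    cs <- if (use_prefix) {
      code_selector(substr(code, 1, sample(1:3, 1)), match = "prefix")
    } else {
      code_selector(code)
    }
    criterion(
      sample(c("include", "exclude"), 1),
      sample(c("Condition", "Procedure", "Observation"), 1),
      cs,
      mode = mode,
      window_before_days = if (mode == "window") sample(0:30, 1),
      window_after_days = if (mode == "window") sample(0:30, 1),
      use_encounter_period = stats::runif(1) < 0.7
    )
  })
  filter_spec(
    base_selector(base_type, code_selector(base_code, match = base_match),
      value_filter = vf, genders = genders, age_min = age_min
    ),
    criteria = crits
  )
}

# ---- shared synthetic stores (memoized; default configuration) ------------

.synth_cache <- new.env(parent = emptyenv())

synth_store_cached <- function(seed) {
  key <- as.character(seed)
  if (is.null(.synth_cache[[key]])) {
    gen <- synth_generate(default_synth_config(seed))
    .synth_cache[[key]] <- list(gen = gen, store = as_fhir_store(gen))
  }
  .synth_cache[[key]]
}
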