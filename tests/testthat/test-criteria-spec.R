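test_that("minimal JSON spec parses with all defaults materialized", {
  spec <- parse_spec(
    '{"base":{"resource_type":"Observation","code_selector":{"codes":["718-7"]}}}'
  )
  expect_s3_class(spec, "fhir_filter_spec")
  expect_equal(spec$base$code_selector$match, "exact")
  expect_length(spec$criteria, 0)
  expect_equal(spec$feature_set$aggregation, "none")
  expect_equal(spec$feature_set$columns, c(
    "patient_id", "gender", "age", "value", "unit", "code", "time"
  ))
})

test_that("a full spec with exclusion and aggregation parses as stated", {
  spec <- parse_spec('{
    "base": {"resource_type": "Observation",
             "code_selector": {"codes": ["718-7"], "system": "http://loinc.org"}},
    "criteria": [{"polarity": "exclude", "resource_type": "Condition",
                  "code_selector": {"codes": ["C"], "match": "prefix"},
                  "mode": "ever"}],
    "feature_set": {"aggregation": "min_per_patient"}
  }')
  expect_equal(spec$criteria[[1]]$polarity, "exclude")
  expect_equal(spec$criteria[[1]]$mode, "ever")
  expect_equal(spec$criteria[[1]]$code_selector$match, "prefix")
  expect_true(spec$criteria[[1]]$use_encounter_period)
  expect_equal(spec$feature_set$aggregation, "min_per_patient")
})

test_that("validation is exhaustive and reports JSON paths", {
  bad <- '{
    "base": {"resource_type": "Banana",
             "code_selector": {"codes": []}},
    "criteria": [{"polarity": "exclude", "resource_type": "Condition",
                  "code_selector": {"codes": ["C"]},
                  "mode": "window"}],
    "feature_set": {"aggregation": "random_one_per_patient"}
  }'
  err <- tryCatch(parse_spec(bad), error = function(e) e)
  expect_s3_class(err, "fhirprep_validation_error")
  errors <- err$errors
  expect_true(any(grepl("base.resource_type", errors)))
  expect_true(any(grepl("base.code_selector.codes", errors)))
  expect_true(any(grepl("criteria\\[0\\].window_before_days", errors)))
  expect_true(any(grepl("criteria\\[0\\].window_after_days", errors)))
  expect_true(any(grepl("feature_set.random_seed", errors)))
  expect_gte(length(errors), 5)
})

test_that("constructors enforce the window-mode invariant", {
  cs <- code_selector("C", match = "prefix")
  expect_error(
    criterion("exclude", "Condition", cs, mode = "window"),
    class = "fhirprep_validation_error"
  )
  expect_error(
    criterion("exclude", "Condition", cs, window_before_days = 7),
    class = "fhirprep_validation_error"
  )
})

test_that("serialize/parse round-trip is the identity on specs", {
  specs <- c(builtin_specs(), list(custom = filter_spec(
    base_selector("Observation", code_selector("2823-3", system = "LOINC"),
      value_filter = value_filter("ge", 3.0, "mM"),
      genders = c("male", "female"), age_min = 18, age_max = 90,
      time_range = list(start = "2016-01-01", end = "2018-12-31")
    ),
    criteria = list(
      criterion("include", "Procedure", code_selector("6-002.q", match = "prefix"),
        mode = "window", window_before_days = 7, window_after_days = 7,
        use_encounter_period = FALSE
      )
    ),
    feature_set = feature_spec("random_one_per_patient",
      random_seed = 99,
      columns = c("patient_id", "value")
    )
  )))
  for (nm in names(specs)) {
    rt <- parse_spec(spec_to_json(specs[[nm]]))
    expect_equal(rt, specs[[nm]], info = nm)
  }
})

test_that("built-in scenario specs encode the documented criteria", {
  b <- builtin_specs()
  ri <- b$reference_interval_prep
  expect_length(ri$criteria, 4)
  expect_true(all(vapply(ri$criteria, function(c) c$polarity, "") == "exclude"))
  expect_equal(ri$base$patient_filter$genders, "male")
  expect_equal(ri$base$patient_filter$age_min, 18)
  expect_equal(ri$base$patient_filter$age_max, 65)
  modes <- vapply(ri$criteria, function(c) c$mode, "")
  expect_equal(sum(modes == "window"), 1)
  win <- ri$criteria[[which(modes == "window")]]
  expect_equal(win$window_before_days, 90)
  expect_equal(win$window_after_days, 90)
  expect_equal(win$code_selector$codes, "5-")
  vals <- vapply(ri$criteria, function(c) !is.null(c$value_filter), logical(1))
  expect_equal(ri$criteria[[which(vals)]]$value_filter$comparator, "lt")
  expect_equal(ri$criteria[[which(vals)]]$value_filter$threshold, 8.0)

  an <- b$anemia_cancer
  expect_true(all(vapply(an$criteria, function(c) c$mode, "") == "ever"))
  expect_equal(an$feature_set$aggregation, "min_per_patient")

  dr <- b$amphotericin_potassium
  expect_equal(dr$criteria[[1]]$window_before_days, 7)
  expect_equal(dr$criteria[[1]]$window_after_days, 7)
  expect_equal(dr$criteria[[1]]$code_selector$codes, "6-002.q")
})

test_that("the shipped example spec files stay in sync with the built-ins", {
  b <- builtin_specs()
  for (nm in names(b)) {
    path <- system.file("extdata", paste0(nm, ".json"), package = "fhirprep")
    expect_true(nzchar(path), info = nm)
    expect_equal(parse_spec(path), b[[nm]], info = nm)
  }
})

test_that("validate_spec warns on absent codes and unit mismatches only", {
  s <- store_from_lines(c(
    json_patient("p1"),
    json_observation("o1", "p1", code = "2823-3", value = 4.1, unit = "mM")
  ))
  spec <- filter_spec(base_selector(
    "Observation", code_selector("9999-9")
  ))
  w <- validate_spec(spec, s)
  expect_length(w, 1)
  expect_match(w, "matches no")

  spec2 <- filter_spec(base_selector(
    "Observation", code_selector("2823-3"),
    value_filter = value_filter("lt", 3.0, unit = "mmol/L")
  ))
  w2 <- validate_spec(spec2, s)
  expect_true(any(grepl("unit", w2)))

  # a matching synthetic store raises no warnings for the built-in specs
  fix <- synth_store_cached(42)
  expect_length(validate_spec(builtin_specs()$anemia_cancer, fix$store), 0)
  expect_length(validate_spec(builtin_specs()$amphotericin_potassium, fix$store), 0)
})
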