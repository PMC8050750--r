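# Shared timeline fixture: a criterion procedure at day 30 whose encounter
# spans days 10-50 (window 7/7 days around day 30), and three candidate
# base observations: day 90 (outside everything), day 33 (inside the day
# window), day 45 (outside the window but inside the encounter period).
timeline_store <- function(with_encounter = TRUE) {
  store_from_lines(c(
    json_patient("p1", "male", "1970-01-01"),
    json_encounter("ec", "p1", day_iso(10, 0), day_iso(50, 0)),
    json_procedure("pr1", "p1",
      code = "6-002.q0", time = day_iso(30),
      eid = if (with_encounter) "ec"
    ),
    json_observation("r1", "p1", code = "2823-3", value = 4.0, time = day_iso(90)),
    json_observation("r2", "p1", code = "2823-3", value = 4.0, time = day_iso(33)),
    json_observation("r3", "p1", code = "2823-3", value = 4.0, time = day_iso(45))
  ))
}

drug_window_criterion <- function(use_encounter_period = TRUE) {
  criterion("exclude", "Procedure", code_selector("6-002.q", match = "prefix"),
    mode = "window", window_before_days = 7, window_after_days = 7,
    use_encounter_period = use_encounter_period
  )
}

test_that("select_base filters by code, value, demographics and sorts", {
  s <- store_from_lines(c(
    json_patient("p1", "male", "1980-01-01"),
    json_patient("p2", "female", "2001-06-01"),
    json_observation("o3", "p1", value = 7.9, time = day_iso(3)),
    json_observation("o1", "p1", value = 13.0, time = day_iso(1)),
    json_observation("o2", "p2", value = 8.0, time = day_iso(2)),
    json_observation("ox", "p1", code = "2823-3", value = 4.0, time = day_iso(1))
  ))
  base <- select_base(s, base_selector("Observation", code_selector("718-7")))
  expect_equal(base$fhir_id, c("o1", "o3", "o2"))

  # strict comparator: of {7.9, 8.0} only 7.9 survives lt 8.0
  blt <- select_base(s, base_selector("Observation", code_selector("718-7"),
    value_filter = value_filter("lt", 8.0)
  ))
  expect_equal(blt$fhir_id, "o3")

  # age bounds inclusive at the resource's own time: p2 is 17 in mid-2018
  bage <- select_base(s, base_selector("Observation", code_selector("718-7"),
    age_min = 18, age_max = 65
  ))
  expect_false("o2" %in% bage$fhir_id)
  expect_true(all(c("o1", "o3") %in% bage$fhir_id))

  bg <- select_base(s, base_selector("Observation", code_selector("718-7"),
    genders = "female"
  ))
  expect_equal(bg$fhir_id, "o2")
})

test_that("untimed base resources are dropped with a warning when time matters", {
  s <- store_from_lines(c(
    json_patient("p1", "male", "1980-01-01"),
    json_observation("o1", "p1", time = day_iso(1)),
    paste0(
      '{"resourceType":"Observation","id":"o2",',
      '"subject":{"reference":"Patient/p1"},',
      '"code":{"coding":[{"code":"718-7"}]},',
      '"valueQuantity":{"value":12,"unit":"g/dL"}}'
    )
  ))
  sel <- base_selector("Observation", code_selector("718-7"))
  expect_equal(nrow(select_base(s, sel)), 2)
  expect_warning(
    b <- select_base(s, sel, window_needed = TRUE),
    "without a time"
  )
  expect_equal(b$fhir_id, "o1")
})

test_that("criterion_instances finds matching resources and their periods", {
  s <- store_from_lines(c(
    json_patient("p1"),
    json_encounter("e1", "p1", day_iso(0, 0), day_iso(5, 0)),
    json_procedure("q1", "p1", code = "5-123.4", time = day_iso(2), eid = "e1"),
    json_procedure("q2", "p1", code = "8-800.1", time = day_iso(3)),
    json_procedure("q3", "p1", code = "5-987.0", time = day_iso(4), eid = "e404")
  ))
  c5 <- criterion("exclude", "Procedure", code_selector("5-", match = "prefix"))
  inst <- criterion_instances(s, "p1", c5)
  expect_equal(nrow(inst), 2)
  expect_equal(sum(!is.na(inst$period_start)), 1) # q3's encounter dangles
  expect_equal(nrow(criterion_instances(s, "p1",
    criterion("exclude", "Procedure", code_selector("9-", match = "prefix"))
  )), 0)
})

test_that("window matching reproduces the three-resource timeline", {
  s <- timeline_store(with_encounter = TRUE)
  base <- select_base(s, base_selector("Observation", code_selector("2823-3")),
    window_needed = TRUE
  )
  crit <- drug_window_criterion()
  m <- vapply(
    base$fhir_id,
    function(id) matches(base[base$fhir_id == id, ], crit, s), logical(1)
  )
  expect_false(m[["r1"]]) # outside window, outside encounter period
  expect_true(m[["r2"]]) # inside the 7-day window
  expect_true(m[["r3"]]) # outside window, inside encounter period

  # without the encounter-period clause, r3 flips to unmatched
  crit_np <- drug_window_criterion(use_encounter_period = FALSE)
  expect_false(matches(base[base$fhir_id == "r3", ], crit_np, s))

  # when the criterion resource has no encounter, r3 is unmatched too
  s2 <- timeline_store(with_encounter = FALSE)
  base2 <- select_base(s2, base_selector("Observation", code_selector("2823-3")),
    window_needed = TRUE
  )
  expect_false(matches(base2[base2$fhir_id == "r3", ], drug_window_criterion(), s2))
  expect_true(matches(base2[base2$fhir_id == "r2", ], drug_window_criterion(), s2))
})

test_that("a zero-width window matches a base resource at the criterion time", {
  s <- store_from_lines(c(
    json_patient("p1"),
    json_procedure("q1", "p1", code = "6-002.q0", time = day_iso(10)),
    json_observation("o1", "p1", code = "2823-3", time = day_iso(10))
  ))
  base <- select_base(s, base_selector("Observation", code_selector("2823-3")),
    window_needed = TRUE
  )
  c0 <- criterion("include", "Procedure", code_selector("6-002.q", match = "prefix"),
    mode = "window", window_before_days = 0, window_after_days = 0
  )
  expect_true(matches(base, c0, s))
})

test_that("apply_spec combines criteria conjunctively with a consistent audit", {
  s <- timeline_store()
  spec0 <- filter_spec(base_selector("Observation", code_selector("2823-3")))
  r0 <- apply_spec(s, spec0)
  expect_equal(nrow(r0$kept), r0$n_base) # empty criteria list = identity

  spec1 <- filter_spec(
    base_selector("Observation", code_selector("2823-3")),
    criteria = list(drug_window_criterion())
  )
  r1 <- apply_spec(s, spec1)
  expect_equal(r1$kept$fhir_id, "r1")
  expect_equal(sum(r1$audit$removed), r1$n_base - nrow(r1$kept))

  # an exclude-ever criterion matching every patient empties the result
  spec2 <- filter_spec(
    base_selector("Observation", code_selector("2823-3")),
    criteria = list(criterion("exclude", "Procedure",
      code_selector("6-", match = "prefix")
    ))
  )
  expect_equal(nrow(apply_spec(s, spec2)$kept), 0)
})

test_that("generator ground-truth labels predict the engine's kept set", {
  fix <- synth_store_cached(42)
  spec <- filter_spec(
    base_selector("Observation", code_selector("718-7")),
    criteria = list(criterion("exclude", "Condition",
      code_selector("C", match = "prefix")
    ))
  )
  kept <- apply_spec(fix$store, spec)$kept
  labels <- fix$gen$labels
  cancer_patients <- labels$patients$fhir_id[labels$patients$has_C]
  expected <- labels$observations$fhir_id[
    labels$observations$loinc == "718-7" &
      !labels$observations$patient_id %in% cancer_patients
  ]
  expect_setequal(kept$fhir_id, expected)
})

test_that("unbounded windows equal ever-mode on timed instances", {
  s <- store_from_lines(c(
    json_patient("p1"), json_patient("p2"),
    json_condition("c1", "p1", code = "C50.1", time = day_iso(300)),
    # p2's condition carries no date at all
    paste0(
      '{"resourceType":"Condition","id":"c2",',
      '"subject":{"reference":"Patient/p2"},',
      '"code":{"coding":[{"code":"C61.0"}]}}'
    ),
    json_observation("o1", "p1", time = day_iso(1)),
    json_observation("o2", "p2", time = day_iso(1))
  ))
  base <- select_base(s, base_selector("Observation", code_selector("718-7")),
    window_needed = TRUE
  )
  ever <- criterion("exclude", "Condition", code_selector("C", match = "prefix"))
  inf_win <- criterion("exclude", "Condition", code_selector("C", match = "prefix"),
    mode = "window", window_before_days = Inf, window_after_days = Inf
  )
  for (id in base$fhir_id) {
    row <- base[base$fhir_id == id, ]
    if (id == "o1") {
      expect_equal(matches(row, inf_win, s), matches(row, ever, s))
    } else {
      # the untimed instance supports ever-mode but not window-mode
      expect_true(matches(row, ever, s))
      expect_false(matches(row, inf_win, s))
    }
  }
})

test_that("criteria application is monotone and order-independent", {
  for (seed in 1:6) {
    store <- random_store(seed)
    spec <- random_spec(seed)
    if (!length(spec$criteria)) next
    kept_full <- suppressWarnings(apply_spec(store, spec)$kept$fhir_id)

    # dropping any one criterion never shrinks the kept set
    for (i in seq_along(spec$criteria)) {
      sub <- spec
      sub$criteria <- spec$criteria[-i]
      kept_sub <- suppressWarnings(apply_spec(store, sub)$kept$fhir_id)
      expect_true(all(kept_full %in% kept_sub))
    }

    # permuting criteria leaves the kept set unchanged
    perm <- spec
    perm$criteria <- rev(spec$criteria)
    expect_setequal(
      suppressWarnings(apply_spec(store, perm)$kept$fhir_id),
      kept_full
    )
  }
})

test_that("the engine agrees with the brute-force oracle on random cases", {
  for (seed in 101:110) {
    store <- random_store(seed)
    spec <- random_spec(seed)
    engine <- sort(suppressWarnings(apply_spec(store, spec)$kept$fhir_id))
    oracle <- suppressWarnings(oracle_apply_spec(store, spec))
    expect_identical(engine, oracle, info = sprintf("seed %d", seed))
  }
})
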