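test_that("proportion_below uses strict inequality and half-up rounding", {
  r <- proportion_below(c(12.99, 13.00), 13)
  expect_equal(r$count, 1)
  expect_equal(r$percent, 50.0)
  expect_equal(proportion_below(c(14, 15), 13)$percent, 0.0)
  # exact tie 1/16 = 6.25% rounds half-up to 6.3 (half-even would give 6.2)
  expect_equal(proportion_below(c(0, rep(1, 15)), 0.5)$percent, 6.3)
})

test_that("fisher_exact matches exhaustive enumeration on small tables", {
  # independent oracle: enumerate all tables with the observed margins
  brute_fisher <- function(a, b, c, d) {
    r1 <- a + b
    r2 <- c + d
    c1 <- a + c
    n <- r1 + r2
    ks <- max(0, c1 - r2):min(r1, c1)
    probs <- vapply(ks, function(k) {
      choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
    }, numeric(1))
    p_obs <- probs[ks == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(
    c(3, 7, 8, 2), c(5, 5, 5, 5), c(1, 9, 9, 1), c(10, 0, 0, 10),
    c(2, 3, 4, 5), c(0, 5, 5, 0), c(7, 1, 2, 8), c(12, 4, 3, 11)
  )
  for (t in cases) {
    expect_equal(
      fisher_exact(t[1], t[2], t[3], t[4]),
      brute_fisher(t[1], t[2], t[3], t[4]),
      tolerance = 1e-12,
      info = paste(t, collapse = ",")
    )
  }
  expect_equal(fisher_exact(5, 5, 5, 5), 1.0)
})

test_that("fisher_exact agrees with the reference implementation", {
  set.seed(4)
  for (i in 1:20) {
    t <- matrix(rpois(4, 8), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(
      fisher_exact(t),
      stats::fisher.test(t)$p.value,
      tolerance = 1e-9
    )
  }
  # large counts stay finite and tiny
  p <- fisher_exact(6316, 2759, 16247, 29519)
  expect_true(is.finite(p))
  expect_lt(p, 0.001)
})

test_that("fisher_exact rejects degenerate tables", {
  expect_error(fisher_exact(0, 0, 3, 4), class = "fhirprep_degenerate_table")
  expect_error(fisher_exact(3, 0, 4, 0), class = "fhirprep_degenerate_table")
})

test_that("anemia groups partition the eligible patients", {
  fix <- synth_store_cached(42)
  rep <- run_anemia_scenario(fix$store)
  g <- rep$groups
  expect_equal(nrow(g), 4)

  # group sizes per gender sum to the adult patients of that gender with a
  # hemoglobin minimum on record
  for (gender in c("male", "female")) {
    spec <- filter_spec(
      base_selector("Observation", code_selector("718-7"), genders = gender),
      feature_set = feature_spec("min_per_patient")
    )
    ft <- extract_features(fix$store, spec)
    eligible <- sum(!is.na(ft$age) & ft$age >= 18 & !is.na(ft$value))
    expect_equal(sum(g$n_patients[g$gender == gender]), eligible)
  }
  # and the with/without cancer patient sets are disjoint by construction
  labels <- fix$gen$labels$patients
  expect_equal(sum(labels$has_C & !labels$has_C), 0)
})

test_that("anemia scenario reports Fisher tests and skips degenerate groups", {
  fix <- synth_store_cached(42)
  rep <- run_anemia_scenario(fix$store)
  expect_true(all(!rep$tests$skipped))
  expect_true(all(rep$tests$p_value >= 0 & rep$tests$p_value <= 1))

  # a store without Condition resources: cancer groups empty, test skipped
  s <- store_from_lines(c(
    json_patient("p1", "male", "1960-01-01"),
    json_observation("o1", "p1", value = 11.0, time = day_iso(10))
  ))
  rep0 <- run_anemia_scenario(s)
  g0 <- rep0$groups
  expect_equal(sum(g0$n_patients[g0$cancer]), 0)
  expect_true(all(rep0$tests$skipped))
  expect_equal(g0$n_patients[!g0$cancer & g0$gender == "male"], 1)
})

test_that("published counts reproduce the printed percentages and bounds", {
  rep <- anemia_report_from_counts(example_anemia_counts())
  g <- rep$groups
  expect_equal(g$pct_anemic[g$gender == "male" & g$cancer], 69.6)
  expect_equal(g$pct_anemic[g$gender == "female" & g$cancer], 62.8)
  expect_equal(g$pct_anemic[g$gender == "male" & !g$cancer], 35.5)
  expect_equal(g$pct_anemic[g$gender == "female" & !g$cancer], 42.0)
  expect_true(all(rep$tests$p_value < 0.001))
})

test_that("drug scenario groups are patient-disjoint with the injected sign", {
  fix <- synth_store_cached(42)
  rep <- run_drug_scenario(fix$store)
  g <- rep$groups

  study_ft <- extract_features(fix$store, builtin_specs()$amphotericin_potassium)
  ever_spec <- builtin_specs()$amphotericin_potassium
  ever_spec$criteria <- list(criterion("include", "Procedure",
    code_selector("6-002.q", match = "prefix")
  ))
  ever_ft <- extract_features(fix$store, ever_spec)
  study_p <- unique(study_ft$patient_id)
  control_p <- setdiff(unique(ever_ft$patient_id), study_p)
  expect_length(intersect(study_p, control_p), 0)
  expect_equal(g$n_patients[g$group == "study"], length(study_p))
  expect_equal(g$n_patients[g$group == "control"], length(control_p))

  # the injected -0.4 mM shift lowers the study mean
  expect_lt(g$mean_raw[g$group == "study"], g$mean_raw[g$group == "control"])

  # a patient with the drug but no potassium contributes to neither group
  all_p <- unique(c(study_p, control_p))
  pot <- fix$gen$labels$observations
  pot_p <- unique(pot$patient_id[pot$loinc == "2823-3"])
  expect_true(all(all_p %in% pot_p))
})

test_that("reference-interval prep excludes every flagged patient", {
  fix <- synth_store_cached(42)
  prep <- run_reference_interval_prep(fix$store, seed = 7)
  expect_equal(prep$n, nrow(prep$features))
  expect_equal(anyDuplicated(prep$features$patient_id), 0)
  expect_match(prep$method, "percentile")
  labels <- fix$gen$labels
  cancer <- labels$patients$fhir_id[labels$patients$has_C]
  expect_length(intersect(prep$features$patient_id, cancer), 0)
  expect_true(prep$ri["lower"] < prep$ri["upper"])
})

test_that("scenario reports are bit-reproducible for a fixed store and seed", {
  fix <- synth_store_cached(42)
  expect_identical(
    run_drug_scenario(fix$store),
    run_drug_scenario(fix$store)
  )
  expect_identical(
    run_reference_interval_prep(fix$store, seed = 3)$features,
    run_reference_interval_prep(fix$store, seed = 3)$features
  )
})

test_that("tidy, glance and autoplot methods work on the result types", {
  fix <- synth_store_cached(42)
  rep <- run_anemia_scenario(fix$store)
  expect_s3_class(tidy(rep), "tbl_df")
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_groups, 4)

  res <- apply_spec(fix$store, builtin_specs()$anemia_cancer)
  expect_equal(glance(res)$n_base, res$n_base)
  expect_equal(nrow(tidy(res)), 1)

  ft <- extract_features(fix$store, builtin_specs()$anemia_cancer)
  expect_s3_class(autoplot(ft), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(run_drug_scenario(fix$store)), "ggplot")
})
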