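test_that("build_reference needs two controls and covers all domains", {
  set.seed(21)
  expect_error(build_reference(list(random_session("solo"))), "at least 2")
  two <- list(make_session("a"), make_session("a2"))
  # two identical controls: cut lines equal their common scores
  ref <- build_reference(two)
  expect_equal(ref$mean_rate_pct, 100)
  expect_equal(ref$mean_rt_s, 2)
  expect_setequal(names(ref$domains), default_battery()$domains$domain)
})

test_that("synthetic control cohort yields a power-law prosody reference", {
  coh <- simulate_cohort(control_cohort_spec(n = 101, seed = 31))
  ref <- build_reference(coh)
  e <- ref$domains$emotional_prosody
  expect_equal(e$selection$best_model, "power_law")
  # oracle: rerunning the selection on the same binned data agrees
  sel2 <- select_model(e$binned, c(e$rate_mean, e$rate_sd))
  expect_equal(e$selection$best_model, sel2$best_model)
  expect_equal(e$selection$ssr, sel2$ssr)
})

test_that("quadrant map partitions the plane with A-ward boundaries", {
  ref <- list(mean_rate_pct = 93.20, mean_rt_s = 5.87)
  expect_equal(classify_quadrant(95, 4.0, ref), "A")
  expect_equal(classify_quadrant(95, 8.0, ref), "B")
  expect_equal(classify_quadrant(72.83, 4.0, ref), "C")
  expect_equal(classify_quadrant(72.83, 8.18, ref), "D")
  # exact boundary goes to the better side
  expect_equal(classify_quadrant(93.20, 5.87, ref), "A")
  expect_equal(classify_quadrant(93.20, 6.0, ref), "B")
  expect_equal(classify_quadrant(93.0, 5.87, ref), "C")
  # every random point lands in exactly one field
  set.seed(22)
  for (i in 1:50) {
    f <- classify_quadrant(runif(1, 0, 100), runif(1, 0.2, 20), ref)
    expect_true(f %in% c("A", "B", "C", "D"))
  }
})

test_that("quadrants move monotonically with rate and time", {
  ref <- list(mean_rate_pct = 80, mean_rt_s = 6)
  rank_rate <- c(A = 2, B = 2, C = 1, D = 1)  # high-rate fields
  rank_time <- c(A = 1, B = 2, C = 1, D = 2)  # slow fields
  set.seed(23)
  for (i in 1:40) {
    r <- runif(1, 0, 100); t <- runif(1, 1, 12)
    f0 <- classify_quadrant(r, t, ref)
    f_up <- classify_quadrant(min(r + runif(1, 0, 30), 100), t, ref)
    expect_gte(rank_rate[[f_up]], rank_rate[[f0]])  # more correct never demotes
    f_slow <- classify_quadrant(r, t + runif(1, 0, 8), ref)
    expect_gte(rank_time[[f_slow]], rank_time[[f0]])  # slower never promotes
  }
})

test_that("profiling the control mean profile lands on the A boundary with zero z", {
  coh <- simulate_cohort(control_cohort_spec(n = 60, seed = 33))
  ref <- build_reference(coh)
  # construct a respondent whose domain times equal the control means and
  # whose rates/summary sit exactly on the reference means
  rt <- vapply(ref$domains, function(e) e$rt_mean, numeric(1))
  nc <- c(ToM = 26, emotional_prosody = 24, social_perception = 9,
          irony = 5, metaphor = 5)
  s <- make_session("meanlike", rt = rt, n_correct = nc)
  p <- profile_respondent(s, ref)
  expect_equal(p$summary_rt_s, ref$mean_rt_s)
  expect_equal(p$field, "A")  # boundary in time, above mean in rate
  expect_equal(p$placements$rt_zscore, rep(0, 5), tolerance = 1e-12)
})

test_that("a 43% rate sits far below the control norm on every domain model", {
  coh <- simulate_cohort(control_cohort_spec(n = 101, seed = 34))
  ref <- build_reference(coh)
  rates <- c(ToM = round(26 * .43), emotional_prosody = round(24 * .43),
             social_perception = round(9 * .43), irony = round(5 * .43),
             metaphor = round(5 * .43))
  s <- make_session("low", n_correct = rates)
  p <- profile_respondent(s, ref)
  expect_true(all(p$placements$rate_percentile < 10))
  # empirical-CDF placement agrees on the direction
  pe <- profile_respondent(s, ref, rate_percentile_from = "empirical")
  expect_true(all(pe$placements$rate_percentile < 10))
})

test_that("reports are deterministic and name the field and domains", {
  coh <- simulate_cohort(control_cohort_spec(n = 30, seed = 35))
  ref <- build_reference(coh)
  s <- simulate_cohort(patient_cohort_spec(n = 1, seed = 36))[[1]]
  p1 <- profile_respondent(s, ref)
  p2 <- profile_respondent(s, ref)
  expect_identical(p1$report, p2$report)
  expect_true(any(grepl("Field: [A-D]", p1$report)))
  expect_true(any(grepl("emotional_prosody", p1$report)))
  expect_equal(sum(p1$scatter$role == "control"), 30)
  expect_equal(sum(p1$scatter$role == "respondent"), 1)
  expect_error(profile_respondent(s, structure(list(domains = list(),
                                                    mean_rate_pct = 90, mean_rt_s = 6,
                                                    scores = ref$scores),
                                               class = "normative_reference")),
               "absent from reference")
})

test_that("cumulative performance curve matches the counting oracle", {
  all100 <- list(make_session("h1"), make_session("h2"))
  curve <- cumulative_performance_curve(all100)
  expect_equal(curve$fraction_at_or_above, rep(1, 101))
  # cohort at summary rates (0, 100): the curve at threshold 75 is 0.5
  zero <- make_session("z0", n_correct = c(ToM = 0, emotional_prosody = 0,
                                           social_perception = 0, irony = 0,
                                           metaphor = 0))
  duo <- cumulative_performance_curve(list(zero, make_session("z1")))
  expect_equal(duo$fraction_at_or_above[duo$rate_threshold == 75], 0.5)
  # random cohort vs brute force
  set.seed(24)
  coh <- lapply(1:12, function(i) random_session(sprintf("r%d", i)))
  rates <- score_cohort(coh)$summary_rate_pct
  curve <- cumulative_performance_curve(coh)
  for (t in c(0, 13, 50, 77.5 %/% 1, 100)) {
    expect_equal(curve$fraction_at_or_above[curve$rate_threshold == t],
                 sum(rates >= t) / length(rates))
  }
  expect_true(all(diff(curve$fraction_at_or_above) <= 0))
})
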