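# Aggregation, Student's t contrasts, length scans, window detection,
# bound/released pairing, thermal and difference curves.

test_that("profile statistics match hand arithmetic", {
  p <- profile_of(c(10, 12, 14))  # percent-scale values work the same
  expect_equal(p$mean, 12)
  expect_equal(p$sem, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(p$n, 3L)
  single <- profile_of(0.3)
  expect_equal(single$sem, 0)
  expect_true(single$low_n)
  expect_error(aggregate_profile(fake_results(0.3, qc_pass = FALSE)),
               class = "nascentfret_unusable_experiment")
})

test_that("QC-failed replicates are excluded and counted", {
  res <- fake_results(c(0.3, 0.4, 0.9), qc_pass = c(TRUE, TRUE, FALSE))
  p <- aggregate_profile(res)
  expect_equal(p$n, 2L)
  expect_equal(p$n_excluded, 1L)
  expect_equal(p$mean, 0.35)
  p_all <- aggregate_profile(res, include_qc_failed = TRUE)
  expect_equal(p_all$n, 3L)
})

test_that("pooled t test matches the reference implementation to 1e-10", {
  cases <- list(
    list(a = c(4.1, 4.2, 4.0), b = c(6.0, 6.1, 6.2)),
    list(a = c(0.32, 0.35, 0.40, 0.38), b = c(0.30, 0.31, 0.36)),
    list(a = rnorm(6, 0.4, 0.02), b = rnorm(5, 0.35, 0.03))
  )
  set.seed(1)
  for (cs in cases) {
    pa <- profile_of(cs$a); pb <- profile_of(cs$b)
    ours <- compare_conditions(pa, pb)
    ref <- t.test(cs$a, cs$b, var.equal = TRUE)
    expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$degrees_of_freedom, unname(ref$parameter))
    # Welch variant against its reference too
    ours_w <- compare_conditions(pa, pb, var_equal = FALSE)
    ref_w <- t.test(cs$a, cs$b)
    expect_equal(ours_w$t_statistic, unname(ref_w$statistic),
                 tolerance = 1e-10)
    expect_equal(ours_w$p_value, ref_w$p.value, tolerance = 1e-10)
    # one-tailed p is half the two-tailed p for the same |t| direction
    one <- compare_conditions(pa, pb, tail = "one")
    ref_one <- t.test(cs$a, cs$b, var.equal = TRUE,
                      alternative = "greater")
    expect_equal(one$p_value, ref_one$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate comparisons behave: identical groups, low n", {
  p <- profile_of(c(0.4, 0.4, 0.4))
  cmp <- compare_conditions(p, p)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_conditions(profile_of(0.4), p),
               class = "nascentfret_insufficient_replicates")
})

test_that("paired comparison uses per-replicate differences", {
  a <- c(0.40, 0.42, 0.44, 0.41); b <- c(0.36, 0.39, 0.40, 0.37)
  cmp <- compare_conditions(profile_of(a), profile_of(b), paired = TRUE)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(cmp$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
})

scan_profiles <- function(construct, truncs, n = 4, seed = 1) {
  lapply(truncs, function(tr) {
    key <- condition_key(construct, 487, tr)
    sets <- simulate_experiment_series(key, n = n, seed = seed)
    aggregate_profile(dplyr::bind_rows(lapply(sets,
                                              compute_experiment_fret)))
  })
}

test_that("length scan: identical series give zero differences", {
  wt <- scan_profiles("WT", c(604, 654))
  scan <- length_scan(wt, wt)
  expect_equal(scan$difference, c(0, 0))
  expect_equal(scan$p_value, c(1, 1))
  expect_error(length_scan(wt, scan_profiles("WT", c(604, 664))),
               class = "nascentfret_grid_mismatch")
})

test_that("negative-control variants show no significant truncation", {
  truncs <- c(604, 614, 654)
  wt <- scan_profiles("WT", truncs, seed = 3)
  g551d <- scan_profiles("G551D", truncs, seed = 3)
  scan <- length_scan(wt, g551d)
  win <- detect_folding_window(scan)
  expect_equal(win$n_truncations, 0L)
  expect_true(is.na(win$start_truncation))
})

test_that("A455E window starts at 584 with the deepest loss at 654", {
  truncs <- c(500, 550, 568, 584, 604, 614, 624, 654)
  wt <- scan_profiles("WT", truncs, seed = 2)
  mut <- scan_profiles("A455E", truncs, seed = 2)
  scan <- length_scan(wt, mut)
  expect_equal(scan$truncation[which.max(scan$difference)], 654)
  win <- detect_folding_window(scan)
  expect_equal(win$start_truncation, 584)
  expect_equal(win$end_truncation, 654)
})

test_that("window detection is idempotent and flank-invariant", {
  scan <- tibble::tibble(
    truncation = c(550, 568, 604, 614, 654, 704),
    mean_ref = 0.4, sem_ref = 0.01, n_ref = 4,
    mean_mut = 0.35, sem_mut = 0.01, n_mut = 4,
    difference = c(0.0, 0.01, 0.05, 0.05, 0.05, 0.0),
    t_statistic = 1, degrees_of_freedom = 6,
    p_value = c(0.9, 0.4, 0.01, 0.002, 0.03, 0.7)
  )
  win <- detect_folding_window(scan)
  expect_equal(c(win$start_truncation, win$end_truncation), c(604, 654))
  expect_identical(detect_folding_window(win$scan)$scan, win$scan)
  # adding a non-significant flank changes nothing
  flank <- scan[1, ]; flank$truncation <- 500
  win2 <- detect_folding_window(dplyr::bind_rows(flank, scan))
  expect_equal(c(win2$start_truncation, win2$end_truncation), c(604, 654))
  # a significant increase (mutant above reference) does not count
  inc <- scan; inc$difference[6] <- -0.05; inc$p_value[6] <- 0.01
  expect_equal(detect_folding_window(inc)$end_truncation, 654)
})

test_that("release pairing enforces exposure equivalence", {
  b604 <- scan_profiles("WT", 604)[[1]]
  r568 <- local({
    key <- condition_key("WT", 487, 568, ribosome_state = "released")
    sets <- simulate_experiment_series(key, n = 4, seed = 1)
    aggregate_profile(dplyr::bind_rows(lapply(sets,
                                              compute_experiment_fret)))
  })
  cmp <- release_comparison(b604, r568)  # 604 - 568 = 36, inside 30-40
  expect_true(cmp$equivalence$exposure_equivalent)
  expect_equal(cmp$equivalence$tunnel_offset, 36)
  b704 <- scan_profiles("A455E", 704)[[1]]
  r664 <- local({
    key <- condition_key("A455E", 487, 664, ribosome_state = "released")
    sets <- simulate_experiment_series(key, n = 4, seed = 1)
    aggregate_profile(dplyr::bind_rows(lapply(sets,
                                              compute_experiment_fret)))
  })
  expect_equal(release_comparison(b704, r664)$equivalence$tunnel_offset, 40)
  err <- expect_error(release_comparison(b604, b704),
                      class = "nascentfret_bad_condition")
  # non-equivalent truncations are refused naming both exposed ranges
  r500 <- r568; r500$condition$truncation <- 500L
  err2 <- expect_error(release_comparison(b604, r500),
                       class = "nascentfret_pairing_error")
  expect_match(conditionMessage(err2), "604")
  expect_match(conditionMessage(err2), "500")
  expect_equal(exposed_length(604, "bound", 36), 568)
  expect_equal(exposed_length(568, "released"), 568)
})

test_that("thermal curves profile per temperature with unequal n", {
  key <- condition_key("WT", 487, 654)
  sets <- c(
    simulate_thermal_series(key, temperatures = c(25, 40), n = 3, seed = 1),
    simulate_thermal_series(key, temperatures = 50, n = 7, seed = 2)
  )
  res <- dplyr::bind_rows(lapply(sets, compute_experiment_fret))
  tc <- thermal_curve(res)
  expect_equal(tc$temperature, c(25, 40, 50))
  expect_equal(tc$n, c(3L, 3L, 7L))
  expect_true(all(diff(tc$mean) < 0))
  # noise-free fixture curve is exactly monotone
  quiet <- simulate_thermal_series(key, temperatures = c(4, 25, 35, 45),
                                   n = 2, params = quiet_params())
  tq <- thermal_curve(dplyr::bind_rows(lapply(quiet,
                                              compute_experiment_fret)))
  expect_true(attr(tq, "monotone_nonincreasing"))
})

test_that("difference curves: propagated SEM, zero for identical input", {
  expect_equal(sqrt(0.8^2 + 0.9^2), 1.2041595, tolerance = 1e-6)
  key_wt <- condition_key("WT", 487, 654)
  key_mut <- condition_key("A455E", 487, 654)
  temps <- c(4, 25, 40, 50)
  wt <- thermal_curve(dplyr::bind_rows(lapply(
    simulate_thermal_series(key_wt, temperatures = temps, n = 3, seed = 1),
    compute_experiment_fret)))
  mut <- thermal_curve(dplyr::bind_rows(lapply(
    simulate_thermal_series(key_mut, temperatures = temps, n = 3, seed = 1),
    compute_experiment_fret)))
  dc <- delta_fret(wt, mut)
  expect_equal(dc$delta_sem, sqrt(wt$sem^2 + mut$sem^2), tolerance = 1e-12)
  # wild-type sits above the mutant through the transition, converging at
  # the top of the range
  expect_true(all(dc$delta_mean[dc$temperature <= 40] > 0.02))
  expect_lt(dc$delta_mean[dc$temperature == 50],
            max(dc$delta_mean))
  self <- delta_fret(wt, wt)
  expect_true(all(self$delta_mean == 0))
  mut_grid <- mut[mut$temperature != 40, ]
  expect_error(delta_fret(wt, mut_grid),
               class = "nascentfret_grid_mismatch")
})
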