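# Generator properties: spectra, counts, determinism, replicate series,
# thermal behaviour, blot tables.

test_that("blank spectra are flat at the background level", {
  p <- quiet_params()
  for (role in c("BD", "BDA")) {
    sp <- simulate_spectrum(p, role)
    expect_equal(sp$intensity, rep(p$bg_level, 151))
  }
})

test_that("donor spectrum peaks near 475 nm and quenching lowers it", {
  p <- quiet_params()
  d <- simulate_spectrum(p, "D")
  expect_true(d$wavelength[which.max(d$intensity)] %in% 470:480)
  pk <- extract_peak_intensity(d)
  expect_true(all(pk$wavelengths_used >= 470 & pk$wavelengths_used <= 482))
  for (e in c(0.1, 0.4, 0.9)) {
    da <- simulate_spectrum(p, "DA", e_chain = e)
    expect_gt(max(d$intensity), max(da$intensity))
  }
})

test_that("expected counts follow the concentration equation", {
  p <- quiet_params(ce = 0.95, sa = 10, vol = 0.5, rnc_conc = 400,
                    cpm_background = 100)
  expect_equal(simulate_counts(p, "D"), 2000)
  expect_equal(simulate_counts(p, "BD"), 100)
  # and Eq. 1 round-trips the concentration
  conc <- rnc_concentration(simulate_counts(p, "D"),
                            simulate_counts(p, "BD"),
                            p$ce, p$sa, p$vol)
  expect_equal(conc$value, 400)
})

test_that("Poisson counting is unbiased (law of large numbers)", {
  p <- generative_params(count_minutes = 1)  # one draw per cpm
  set.seed(42)
  draws <- replicate(1e4, simulate_counts(p, "D"))
  expect_equal(mean(draws), 2000, tolerance = 0.01)
})

test_that("same (condition, seed, replicate) gives a bit-identical set", {
  key <- condition_key("WT", 487, 654)
  a <- simulate_reaction_set(key, seed = 7, replicate = 2)
  b <- simulate_reaction_set(key, seed = 7, replicate = 2)
  expect_identical(a, b)
  c_ <- simulate_reaction_set(key, seed = 8, replicate = 2)
  expect_false(identical(a$samples$D$spectrum$intensity,
                         c_$samples$D$spectrum$intensity))
})

test_that("replicates are independent across substreams", {
  key <- condition_key("WT", 487, 624)
  e1 <- numeric(200); e2 <- numeric(200)
  for (r in 1:200) {
    s1 <- simulate_reaction_set(key, seed = r, replicate = 1)
    s2 <- simulate_reaction_set(key, seed = r, replicate = 2)
    e1[r] <- compute_experiment_fret(s1)$e_fret
    e2[r] <- compute_experiment_fret(s2)$e_fret
  }
  expect_lt(abs(cor(e1, e2)), 0.2)
})

test_that("noise controls replicate scatter of a series", {
  key <- condition_key("WT", 487, 624)
  noisy <- simulate_experiment_series(key, n = 4, seed = 1)
  e_noisy <- vapply(noisy, function(s) compute_experiment_fret(s)$e_fret,
                    numeric(1))
  expect_length(unique(e_noisy), 4L)
  expect_gt(sd(e_noisy), 0)
  quiet <- simulate_experiment_series(key, n = 4, params = quiet_params(),
                                      seed = 1)
  e_quiet <- vapply(quiet, function(s) compute_experiment_fret(s)$e_fret,
                    numeric(1))
  expect_equal(max(e_quiet) - min(e_quiet), 0)
})

test_that("brightness rescaling leaves pipeline FRET unchanged", {
  key <- condition_key("A455E", 487, 654)
  base <- compute_experiment_fret(
    simulate_reaction_set(key, params = quiet_params()))$e_fret
  for (c_ in c(0.1, 3, 40)) {
    scaled <- compute_experiment_fret(simulate_reaction_set(
      key, params = quiet_params(donor_brightness = 100 * c_)))$e_fret
    expect_equal(scaled, base, tolerance = 1e-10)
  }
})

test_that("thermal series: denaturation is monotone, control is flat", {
  temps <- c(4, 15, 25, 35, 40, 45, 50)
  key <- condition_key("WT", 487, 654)
  sets <- simulate_thermal_series(key, temperatures = temps, n = 1,
                                  params = quiet_params())
  e <- vapply(sets, function(s) compute_experiment_fret(s)$e_fret,
              numeric(1))
  expect_true(all(diff(e) <= 1e-12))
  # donor brightness itself falls with temperature...
  peaks <- vapply(sets, function(s)
    extract_peak_intensity(s$samples$D$spectrum)$value, numeric(1))
  expect_true(all(diff(peaks) < 0))
  # ...but for the CFP-tether control the FRET ratio is untouched
  ctrl <- condition_key("WT", 389, 744)
  sets_c <- simulate_thermal_series(ctrl, temperatures = temps, n = 1,
                                    params = quiet_params())
  e_c <- vapply(sets_c, function(s) compute_experiment_fret(s)$e_fret,
                numeric(1))
  expect_equal(e_c, rep(0.30, length(temps)), tolerance = 1e-10)
  expect_error(simulate_thermal_series(key, temperatures = c(25, 60)),
               class = "nascentfret_bad_param")
})

test_that("blot tables round-trip the configured band-C fraction", {
  lanes0 <- simulate_blot_table(c(WT = 1, A455E = 0), n = 3, noise_cv = 0)
  expect_true(all(lanes0$band_c[lanes0$construct == "A455E"] == 0))
  lanes <- simulate_blot_table(c(WT = 1, "A455E+PT" = 0.2), n = 4,
                               noise_cv = 0)
  m <- relative_trafficking(lanes, "A455E+PT")
  expect_equal(m$relative_to_reference, 20)
  # noisy recovery is unbiased over many seeds
  rel <- vapply(1:100, function(s) {
    l <- simulate_blot_table(c(WT = 1, "A455E+PT" = 0.2), n = 4,
                             noise_cv = 0.05, seed = s)
    relative_trafficking(l, "A455E+PT")$relative_to_reference
  }, numeric(1))
  expect_equal(mean(rel), 20, tolerance = 0.02)
})

test_that("missing conditions are reported, known ones resolved", {
  truth <- ground_truth_table()
  expect_error(gt_lookup(truth, condition_key("WT", 487, 999)),
               class = "nascentfret_missing_condition")
  expect_equal(gt_lookup(truth, condition_key("WT", 487, 624)), 0.396)
  expect_equal(gt_lookup(truth, condition_key("WT", 487, 500)), 0.041)
  # thermal interpolation between anchors
  e30 <- gt_lookup(truth, condition_key("WT", 487, 654, temperature = 30))
  e25 <- gt_lookup(truth, condition_key("WT", 487, 654, temperature = 25))
  e35 <- gt_lookup(truth, condition_key("WT", 487, 654, temperature = 35))
  expect_true(e35 < e30 && e30 < e25)
})
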