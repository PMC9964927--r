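test_that("a one-hour series at 62.5 Hz has exactly 225,000 samples", {
  p <- electrome_gen_params(seed = 5)
  s <- generate_electrome(p, stimulus_scenario("CONTROL"), "BEFORE")
  expect_length(s$samples, 225000L)
})

test_that("the generator is deterministic in its seed", {
  p <- electrome_gen_params(duration_s = 120, seed = 99)
  sc <- stimulus_scenario("W_HS", "SYSTEMIC")
  a <- generate_electrome(p, sc, "AFTER")
  b <- generate_electrome(p, sc, "AFTER")
  expect_identical(a$samples, b$samples)
  p2 <- electrome_gen_params(duration_s = 120, seed = 100)
  expect_false(identical(generate_electrome(p2, sc, "AFTER")$samples,
                         a$samples))
})

test_that("spikeless white configuration has unit variance", {
  p <- electrome_gen_params(duration_s = 160, baseline_sigma = 1,
                            spectral_exponent = 0, spike_rate = 0,
                            seed = 3)
  s <- generate_electrome(p, stimulus_scenario("CONTROL"), "BEFORE")
  expect_equal(var(s$samples), 1, tolerance = 0.05)
})

test_that("spike peaks reach at least 50 uV locally and are scaled systemically", {
  p <- electrome_gen_params(duration_s = 600, baseline_sigma = 0.001,
                            spike_rate = 3, seed = 17)
  loc <- generate_electrome(p, stimulus_scenario("W", "LOCAL"), "BEFORE")
  sys <- generate_electrome(p, stimulus_scenario("W", "SYSTEMIC"), "BEFORE")
  expect_gte(max(abs(loc$samples)), 50 * 0.999)
  expect_equal(max(abs(sys$samples)) / max(abs(loc$samples)), 0.5,
               tolerance = 1e-4)
  expect_error(electrome_gen_params(spike_amp_range = c(10, 100)), "50")
})

test_that("stimulated series lose entropy and gain slow-band power early on", {
  cfg <- tdaf_config(features = c("apen", "dfa", "abp"),
                     bands = rbind(default_bands(),
                                   data.frame(name = "slow", f_lo = 0,
                                              f_hi = 4)))
  nrep <- 3
  before <- make_series_group("HS", "LOCAL", "BEFORE", nrep, 50)
  after <- make_series_group("HS", "LOCAL", "AFTER", nrep, 6050)
  reps <- run_tdaf(c(before, after), cfg)
  cp_apen <- compare_phases(reps[["tlb.apen"]], reps[["tla.apen"]])
  cp_dfa <- compare_phases(reps[["tlb.dfa_alpha"]], reps[["tla.dfa_alpha"]])
  cp_slow <- compare_phases(reps[["tlb.abp_slow"]], reps[["tla.abp_slow"]])
  cp_delta <- compare_phases(reps[["tlb.abp_delta"]], reps[["tla.abp_delta"]])
  expect_lt(cp_apen$effect_mean_diff, -0.1)   # entropy drops
  expect_gt(cp_dfa$effect_mean_diff, 0)       # correlation rises
  expect_gt(cp_slow$effect_mean_diff, 0)      # 0-4 Hz energy rises
  expect_gt(cp_delta$effect_mean_diff, 0)     # local delta band rises too
})

test_that("control series show no before/after entropy shift", {
  cfg <- tdaf_config(features = "apen")
  nrep <- 4
  before <- make_series_group("CONTROL", "LOCAL", "BEFORE", nrep, 70)
  after <- make_series_group("CONTROL", "LOCAL", "AFTER", nrep, 6070)
  reps <- run_tdaf(c(before, after), cfg)
  cp <- compare_phases(reps[["clb.apen"]], reps[["cla.apen"]])
  expect_lt(abs(cp$effect_mean_diff), 0.15)
})

test_that("turgor series have the right grid and calibrated CVs", {
  ts <- generate_turgor(turgor_gen_params(seed = 2),
                        stimulus_scenario("HS", "SYSTEMIC"))
  expect_length(ts$samples, 720L)  # 7200 s at one sample per 10 s
  cv <- before_after_cv(ts)
  expect_equal(unname(cv[1]), 18.84, tolerance = 2 / 18.84)
  expect_equal(unname(cv[2]), 27.06, tolerance = 2 / 27.06)

  whs <- generate_turgor(turgor_gen_params(seed = 8),
                         stimulus_scenario("W_HS", "SYSTEMIC"))
  cv2 <- before_after_cv(whs)
  expect_gt(cv2[2] / cv2[1], 2)

  expect_error(turgor_gen_params(cv_before_pct = -1), "positive")
})

test_that("noise-free turgor reduces to a sampled sinusoid with closed-form CV", {
  p <- turgor_gen_params(noise_fraction = 0, seed = 1)
  ts <- generate_turgor(p, stimulus_scenario("CONTROL", "SYSTEMIC"))
  norm <- normalize_percent(ts)
  t <- (seq_along(norm$samples) - 1) * 10
  before <- norm$samples[t < 3600]
  # closed form: CV of mu + A sin(wt) sampled over whole periods is
  # 100 * (A / sqrt(2)) / mu (up to the sample sd correction)
  A <- (max(before) - min(before)) / 2
  mu <- mean(before)
  expect_equal(coefficient_of_variation(before), 100 * A / sqrt(2) / mu,
               tolerance = 0.01)
})

test_that("generate_experiment writes a loadable, reproducible manifest", {
  out <- withr::local_tempdir()
  p <- electrome_gen_params(duration_s = 16, seed = 31)
  man <- generate_experiment(2, out, params = p,
                             turgor_params = turgor_gen_params(seed = 31))
  volt <- man[man$kind == "voltage", ]
  expect_equal(nrow(volt), 32L)  # 2 replicates x 4 treatments x 2 tissues x 2 phases
  expect_true(all(file.exists(file.path(out, man$file))))
  expect_false(any(duplicated(man$seed)))

  # every listed file loads with the listed class
  for (i in sample(nrow(volt), 6)) {
    s <- read_series(file.path(out, volt$file[i]),
                     treatment = volt$treatment[i],
                     tissue = volt$tissue[i], phase = volt$phase[i])
    expect_equal(s$label, volt$class[i])
  }

  # distinct replicates get distinct seeds hence distinct samples
  s1 <- read_series(file.path(out, volt$file[1]))
  pair <- volt[volt$treatment == volt$treatment[1] &
                 volt$tissue == volt$tissue[1] &
                 volt$phase == volt$phase[1], ]
  s2 <- read_series(file.path(out, pair$file[2]))
  expect_false(identical(s1$samples, s2$samples))
})
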