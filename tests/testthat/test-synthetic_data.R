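test_that("the tear-sampling schedule is 15 s then 30 s spaced", {
  s600 <- default_schedule(600)
  expect_length(s600, 25)                 # 9 early + 16 late samples
  expect_equal(s600[1], 0)
  expect_equal(s600[1:9], seq(0, 120, 15))
  expect_equal(diff(s600[9:25]), rep(30, 16))
  expect_length(default_schedule(120), 9)
  expect_error(default_schedule(60), "duration_s")
})

test_that("trace generation is exact without noise and reproducible with it", {
  sched <- default_schedule(600)
  clean <- generate_trace(206.51, 0.0142, sched, noise_cv = 0)
  expect_equal(clean$values_mV, 206.51 * exp(-0.0142 * sched),
               tolerance = 1e-14)
  a <- generate_trace(200, 0.01, sched, noise_cv = 0.023, seed = 12)
  b <- generate_trace(200, 0.01, sched, noise_cv = 0.023, seed = 12)
  expect_identical(a$values_mV, b$values_mV)
  expect_true(all(a$values_mV >= 0))
})

test_that("fitted rates from noisy traces at instrument SNR stay within 5% (median)", {
  set.seed(20)
  errs <- vapply(1:100, function(i) {
    kd <- runif(1, 0.005, 0.03)
    tr <- generate_trace(200, kd, noise_cv = 1 / 44)
    abs(fit_decay(tr)$kd_per_s - kd) / kd
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("forward stromal fluorescence is the exact algebraic inverse", {
  pro <- study_protocol()
  icf <- pro$instrument$icf
  expect_equal(forward_stromal_fluorescence(0, 0.01, 200, 500, icf, pro), 0)
  fs1 <- forward_stromal_fluorescence(0.5, 0.01, 200, 500, icf, pro)
  fs2 <- forward_stromal_fluorescence(1.0, 0.01, 200, 500, icf, pro)
  expect_equal(fs2, 2 * fs1, tolerance = 1e-13)
  set.seed(31)
  for (i in 1:100) {
    kd <- runif(1, 0.0015, 0.044); f0 <- runif(1, 40, 500)
    q <- runif(1, 420, 600); p <- runif(1, 0.05, 3)
    fs <- forward_stromal_fluorescence(p, kd, f0, q, icf, pro)
    expect_lt(abs(pdc_multi_drop(kd, q, icf, fs, f0, pro$probe, pro$loading,
                                 pro$tear_volume_uL, pro$n_loading) - p) / p,
              1e-10)
  }
})

test_that("simulated cohorts have the study shape and honest bookkeeping", {
  sim <- generate_cohort(truth_config(seed = 42))
  expect_equal(nrow(sim$records), 49)
  expect_equal(length(unique(sim$records$subject_id)), 29)
  expect_equal(length(sim$traces), 49)
  expect_equal(nrow(sim$truth), 49)
  expect_equal(sim$records$q_um, stromal_thickness(sim$records$cct_um))
  # reproducibility: identical seed, identical cohort
  sim2 <- generate_cohort(truth_config(seed = 42))
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$traces[[7]]$values_mV, sim2$traces[[7]]$values_mV)
  # raw stromal readings embed the channel gain and autofluorescence
  tc <- truth_config(seed = 42)
  expect_equal(
    correct_stromal_fluorescence(sim$records$fds_raw_mV,
                                 tc$autofluorescence_mV, tc$channel_gain),
    sim$records$fds_corrected_mV, tolerance = 1e-10)
})

test_that("the full pipeline recovers truth on noiseless simulated raw data", {
  pro <- study_protocol()
  sim <- generate_cohort(truth_config(noise_cv = 0, seed = 7), pro)
  rec <- recover_cohort(sim, pro)
  expect_lt(max(abs(rec$kd_per_s - sim$truth$kd_per_s) / sim$truth$kd_per_s),
            1e-6)
  expect_lt(max(abs(rec$pdc_nm_s - rec$true_pdc_nm_s) / rec$true_pdc_nm_s),
            1e-5)
})

test_that("the deterministic stand-in cohort reproduces its calibration targets", {
  coh <- synthetic_s1_cohort()
  expect_equal(nrow(coh), 49)
  expect_equal(length(unique(coh$subject_id)), 29)
  expect_identical(coh, synthetic_s1_cohort())   # deterministic
  expect_equal(mean(coh$kd_per_s), 0.0142, tolerance = 1e-10)
  expect_equal(mean(coh$f0dp_mV), 206.51, tolerance = 1e-10)
  expect_true(all(diff(sort(coh$pdc_nm_s)) >= 0))
  expect_true(all(coh$kd_per_s > 0 & coh$f0dp_mV > 0 & coh$q_um > 0))
})

test_that("depth scans show box-kernel resolution and concentration quenching", {
  # no absorption: flat plateau past the interface
  flat <- simulate_depth_scan(scan_config(concentration_uM = 1,
                                          molar_absorptivity_ex = 0,
                                          molar_absorptivity_em = 0))
  plateau <- flat$apparent[flat$depth_um >= 500 + 140]
  expect_equal(max(plateau) - min(plateau), 0, tolerance = 1e-14)

  # quenching steepens with concentration: 50 uM > 10 uM > 1 uM
  slope_of <- function(conc) {
    s <- simulate_depth_scan(scan_config(concentration_uM = conc))
    p <- s[s$depth_um >= 700 & s$depth_um <= 1900, ]
    -coef(lm(log(p$normalized) ~ p$depth_um))[[2]]
  }
  s1 <- slope_of(1); s10 <- slope_of(10); s50 <- slope_of(50)
  expect_gt(s50, s10)
  expect_gt(s10, s1)
  expect_lt(s1, 1e-4)   # dilute solution is essentially flat

  # unconvolved profile equals the closed-form exponential
  sc <- scan_config(concentration_uM = 50)
  s <- simulate_depth_scan(sc)
  k <- (sc$molar_absorptivity_ex + sc$molar_absorptivity_em) * 50 * 1e-10
  z <- s$depth_um
  expected <- ifelse(z < 500, 0, 50 * exp(-k * (z - 500)))
  expect_equal(s$unconvolved, expected, tolerance = 1e-12)
})

test_that("the step-edge transition width equals the focal-diamond depth", {
  for (cfg in list(scan_config(focal_diamond_depth_um = 280, step_um = 1),
                   scan_config(focal_diamond_depth_um = 500, step_um = 5),
                   scan_config(focal_diamond_depth_um = 120, step_um = 2))) {
    width <- scan_transition_width(simulate_depth_scan(cfg))
    expect_equal(width, cfg$focal_diamond_depth_um,
                 tolerance = cfg$step_um / cfg$focal_diamond_depth_um)
  }
})
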