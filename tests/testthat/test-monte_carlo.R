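test_that("Weibull moment matching solves the gamma-moment equations", {
  # CV = 1 is the exponential special case
  w <- weibull_from_moments(0.54, 0.54)
  expect_equal(w[["shape"]], 1, tolerance = 1e-9)
  expect_equal(w[["scale"]], 0.54, tolerance = 1e-9)

  # forward-moment oracle across the cohort-scale parameter sets
  for (ms in list(c(0.0142, 0.0107), c(206.51, 113.89), c(10.19, 8.22))) {
    w <- weibull_from_moments(ms[1], ms[2])
    mom <- distribution_moments(
      param_distribution("x", "weibull", shape = w[["shape"]],
                         scale = w[["scale"]]))
    expect_equal(mom[["mean"]], ms[1], tolerance = 1e-10)
    expect_equal(mom[["sd"]], ms[2], tolerance = 1e-10)
  }
  expect_error(weibull_from_moments(1, 0), "sd")
})

test_that("degenerate point-mass configs collapse to the deterministic equation", {
  pro <- study_protocol()
  cfg <- mcs_config(
    distributions = list(
      param_distribution("kd", "point", value = 0.0142),
      param_distribution("f0dp", "point", value = 206.51),
      param_distribution("fs", "point", value = 0.0076),
      param_distribution("q", "point", value = 522)
    ),
    iterations = 50, seed = 4, protocol = pro
  )
  ens <- run_mcs(cfg)
  direct <- pdc_multi_drop(0.0142, 522, pro$instrument$icf, 0.0076, 206.51,
                           pro$probe, pro$loading, pro$tear_volume_uL,
                           pro$n_loading)
  expect_equal(ens$samples, rep(direct, 50), tolerance = 1e-13)
  expect_equal(length(ens$samples), 50)
})

test_that("the ensemble is reproducible per seed and covered configs are enforced", {
  cfg <- default_mcs_config(iterations = 2000, seed = 77)
  expect_identical(run_mcs(cfg)$samples, run_mcs(cfg)$samples)
  expect_error(
    mcs_config(distributions = list(
      param_distribution("kd", "point", value = 0.01))),
    "coverage gap")
  expect_error(
    mcs_config(distributions = list(
      param_distribution("kd", "point", value = 0.01),
      param_distribution("kd", "point", value = 0.02),
      param_distribution("f0dp", "point", value = 200),
      param_distribution("fs", "point", value = 1),
      param_distribution("q", "point", value = 500))),
    "duplicate")
})

test_that("raising the stromal-fluorescence location stochastically raises permeability", {
  cfg_lo <- default_mcs_config(iterations = 4000, seed = 21)
  cfg_hi <- cfg_lo
  fs <- cfg_lo$distributions$fs$params
  cfg_hi$distributions$fs <- param_distribution("fs", "weibull",
                                                shape = fs$shape,
                                                scale = fs$scale * 2)
  lo <- run_mcs(cfg_lo)$samples
  hi <- run_mcs(cfg_hi)$samples
  expect_gt(mean(hi), mean(lo))
  expect_gt(median(hi), median(lo))
  # first-order stochastic dominance on a quantile grid
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(quantile(hi, qs) >= quantile(lo, qs)))
})

test_that("shrinking every spread collapses the ensemble onto the deterministic value", {
  pro <- study_protocol()
  centers <- list(kd = 0.0142, f0dp = 206.51, fs = 0.0076, q = 522)
  deterministic <- pdc_multi_drop(centers$kd, centers$q, pro$instrument$icf,
                                  centers$fs, centers$f0dp, pro$probe,
                                  pro$loading, pro$tear_volume_uL,
                                  pro$n_loading)
  spread_cfg <- function(rel) {
    dists <- lapply(names(centers), function(nm) {
      m <- centers[[nm]]
      if (rel == 0) return(param_distribution(nm, "point", value = m))
      w <- weibull_from_moments(m, m * rel)
      param_distribution(nm, "weibull", shape = w[["shape"]],
                         scale = w[["scale"]])
    })
    mcs_config(dists, iterations = 4000, seed = 5, protocol = pro)
  }
  sds <- sapply(c(0.3, 0.1, 0.02), function(rel) {
    s <- run_mcs(spread_cfg(rel))$samples
    c(sd = sd(s), bias = abs(mean(s) - deterministic) / deterministic)
  })
  expect_true(all(diff(sds["sd", ]) < 0))      # ensemble spread shrinks
  expect_lt(sds["bias", 3], 0.01)              # and the mean homes in
  expect_equal(run_mcs(spread_cfg(0))$samples[1], deterministic,
               tolerance = 1e-13)
})

test_that("ensemble means are stable across seeds within Monte Carlo error", {
  a <- run_mcs(default_mcs_config(iterations = 10000, seed = 31))
  b <- run_mcs(default_mcs_config(iterations = 10000, seed = 32))
  mc_se <- sqrt(sd(a$samples)^2 / 10000 + sd(b$samples)^2 / 10000)
  expect_lt(abs(mean(a$samples) - mean(b$samples)), 3 * mc_se)
})

test_that("distribution comparison returns KS distance with its critical value", {
  set.seed(6)
  x <- rexp(500)
  expect_equal(compare_distributions(x, x)$ks_distance, 0)
  expect_equal(compare_distributions(x, x + 100)$ks_distance, 1)
  cmpd <- compare_distributions(x, rexp(800))
  expect_lt(cmpd$ks_distance, cmpd$ks_critical_5pct)
  expect_equal(cmpd$ks_critical_5pct,
               sqrt(-log(0.025) / 2) * sqrt((500 + 800) / (500 * 800)),
               tolerance = 1e-12)
  expect_equal(sum(cmpd$histogram$simulated_counts), 500)
  expect_equal(sum(cmpd$histogram$empirical_counts), 800)
  expect_error(compare_distributions(numeric(0), x), "non-empty")
})

test_that("one-at-a-time sensitivity ranks the linear drivers about equally", {
  cfg <- default_mcs_config(iterations = 2000, seed = 9)
  sens <- mcs_sensitivity(cfg, rel = 0.2)
  expect_setequal(sens$parameter, c("kd", "f0dp", "fs", "q", "gain"))
  # Pdc is linear in kd, fs, q and gain: unit relative sensitivity
  lin <- sens$rel_sensitivity[sens$parameter %in% c("kd", "fs", "q", "gain")]
  expect_true(all(abs(lin - 1) < 0.15))
  # and inversely proportional to f0dp: negative sensitivity
  expect_lt(sens$rel_sensitivity[sens$parameter == "f0dp"], 0)
})
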