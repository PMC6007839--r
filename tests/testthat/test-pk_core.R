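test_that("drop mass and initial tear concentration follow %w/v dilution arithmetic", {
  expect_equal(drop_mass(2, 0.35), 7)        # 0.35 g/100 mL = 3.5 ug/uL
  expect_equal(drop_mass(6, 2), 120)
  expect_equal(drop_mass(0, 5), 0)
  expect_error(drop_mass(-1, 0.35), "volume_uL")

  expect_equal(initial_tear_concentration(7, 2, 7), 7 / 9, tolerance = 1e-12)
  expect_equal(initial_tear_concentration(120, 6, 7), 9.2308, tolerance = 1e-4)
  expect_equal(initial_tear_concentration(0, 2, 7), 0)
  expect_error(initial_tear_concentration(7, 0, 0), "must be > 0")
})

test_that("probe-drop AUC matches the closed form, quadrature, and half-life intuition", {
  expect_equal(auc_probe(100, 0.01), 10000)
  # at one half-life the finite AUC is half the total
  expect_equal(auc_probe(100, 0.01, log(2) / 0.01), 5000, tolerance = 1e-12)
  expect_equal(auc_probe(206.51, 0.0142), 14543.0, tolerance = 1e-4)

  # numerical quadrature as independent oracle across a parameter sweep
  for (kd in c(0.0015, 0.0142, 0.044)) {
    for (horizon in c(60, 300, Inf)) {
      quad <- stats::integrate(function(t) 206.51 * exp(-kd * t), 0,
                               if (is.finite(horizon)) horizon else Inf,
                               rel.tol = 1e-12)$value
      expect_equal(auc_probe(206.51, kd, horizon), quad, tolerance = 1e-9)
    }
  }

  # finite-horizon AUC grows monotonically to the unbounded value
  horizons <- c(10, 50, 100, 300, 600)
  aucs <- auc_probe(150, 0.01, horizons)
  expect_true(all(diff(aucs) > 0))
  expect_lt(max(aucs), auc_probe(150, 0.01))
  expect_error(auc_probe(100, 0), "kd_per_s")
})

test_that("AUC(T)/AUC(Inf) equals 1 - exp(-kd*T) exactly", {
  set.seed(42)
  for (i in 1:50) {
    f0 <- runif(1, 10, 500)
    kd <- runif(1, 0.0015, 0.044)
    T <- runif(1, 5, 1200)
    expect_equal(auc_probe(f0, kd, T) / auc_probe(f0, kd),
                 1 - exp(-kd * T), tolerance = 1e-13)
  }
})

test_that("loading-drop fluorescence scales from the probe drop by mass and dilution", {
  probe <- drop_spec(2, 0.35)
  loading <- drop_spec(6, 2)

  expect_equal(loading_f0_from_probe(123.4, probe, probe, 7), 123.4)
  expect_equal(loading_f0_from_probe(200, probe, loading, 7),
               200 * (120 / 7) * (9 / 13), tolerance = 1e-12)
  expect_equal(loading_f0_from_probe(200, probe, loading, 7), 2373.6,
               tolerance = 1e-4)
  # doubling the loading mass doubles the prediction
  double <- drop_spec(6, 4)
  expect_equal(loading_f0_from_probe(200, probe, double, 7),
               2 * loading_f0_from_probe(200, probe, loading, 7))
  expect_error(loading_f0_from_probe(200, drop_spec(2, 0), loading, 7),
               "positive dye mass")
})

test_that("loading AUC is the probe AUC of the scaled intercept", {
  probe <- drop_spec(2, 0.35)
  loading <- drop_spec(6, 2)
  expect_equal(auc_loading(200, 0.01, probe, loading, 7), 237362.6,
               tolerance = 1e-4)
  expect_equal(auc_loading(321, 0.02, probe, probe, 7), 321 / 0.02)
  # composition identity across a sweep
  set.seed(7)
  for (i in 1:20) {
    f0 <- runif(1, 50, 400); kd <- runif(1, 0.002, 0.04)
    vd <- runif(1, 4, 10)
    expect_equal(
      auc_loading(f0, kd, probe, loading, vd),
      auc_probe(loading_f0_from_probe(f0, probe, loading, vd), kd),
      tolerance = 1e-13
    )
  }
  # inverse proportionality in kd
  expect_equal(auc_loading(200, 0.02, probe, loading, 7),
               auc_loading(200, 0.01, probe, loading, 7) / 2)
})

test_that("stromal thickness derives from CCT with the OCT regression", {
  expect_equal(stromal_thickness(500), 480)
  expect_equal(stromal_thickness(600), 586)
  # 50/1.06 ~ 47.1698 um is the boundary below which Q is non-physical
  expect_error(stromal_thickness(47.16), "non-positive")
})

test_that("instrument correction factor is delta over tear-film thickness", {
  icf <- instrument_correction_factor(instrument_config(280, 3))
  expect_equal(icf, 140 / 3, tolerance = 1e-12)
  expect_equal(round(icf), 47)
  expect_equal(instrument_correction_factor(instrument_config(6, 3)), 1)
  expect_equal(instrument_correction_factor(instrument_config(500, 5)), 50)
  # ICF >= 1 whenever delta >= t_d
  for (d2 in c(10, 100, 280)) {
    expect_gte(instrument_correction_factor(instrument_config(d2, d2 / 2)), 1)
  }
  expect_error(instrument_config(0, 3), "focal_diamond_depth_um")
})

test_that("stromal fluorescence correction subtracts background, applies gain, clamps at 0", {
  expect_equal(correct_stromal_fluorescence(12, 2, 1), 10)
  expect_equal(correct_stromal_fluorescence(5, 5, 1), 0)
  expect_equal(correct_stromal_fluorescence(12, 2, 0.5), 5)
  expect_warning(out <- correct_stromal_fluorescence(1, 2, 1), "clamped")
  expect_equal(out, 0)
})

test_that("multi-drop permeability equation has the expected structure", {
  probe <- drop_spec(2, 0.35); loading <- drop_spec(6, 2)
  args <- list(kd_per_s = 0.0142, q_um = 522, icf = 140 / 3, fs_mV = 0.008,
               F0dP_mV = 206.51, probe = probe, loading = loading,
               tear_volume_uL = 7, n_loading = 2)

  expect_equal(do.call(pdc_multi_drop, modifyList(args, list(fs_mV = 0))), 0)

  # n = 2 reproduces the hand-written two-drop formula symbol for symbol
  by_hand <- 0.0142 * (522 * 1000) * (140 / 3) * 0.008 / (2 * 206.51) *
    (7 / 120) * (6 + 7) / (2 + 7)
  expect_equal(do.call(pdc_multi_drop, args), by_hand, tolerance = 1e-13)

  # linear in fs, inverse in F0dP and n_loading
  base <- do.call(pdc_multi_drop, args)
  expect_equal(do.call(pdc_multi_drop, modifyList(args, list(fs_mV = 0.016))),
               2 * base)
  expect_equal(do.call(pdc_multi_drop, modifyList(args, list(F0dP_mV = 413.02))),
               base / 2)
  expect_equal(do.call(pdc_multi_drop, modifyList(args, list(n_loading = 4))),
               base / 2)
  # detector-gain gauge invariance: scaling fs and F0dP together is neutral
  expect_equal(do.call(pdc_multi_drop,
                       modifyList(args, list(fs_mV = 0.008 * 3.7,
                                             F0dP_mV = 206.51 * 3.7))),
               base, tolerance = 1e-13)
  expect_error(do.call(pdc_multi_drop, modifyList(args, list(n_loading = 0))),
               "n_loading")
  expect_error(do.call(pdc_multi_drop, modifyList(args, list(F0dP_mV = 0))),
               "F0dP_mV")
})

test_that("permeability inverts the synthetic forward model to machine precision", {
  pro <- study_protocol()
  icf <- pro$instrument$icf
  set.seed(11)
  for (i in 1:100) {
    kd <- runif(1, 0.0015, 0.044)
    f0 <- runif(1, 50, 500)
    q <- runif(1, 400, 600)
    pdc <- runif(1, 0.05, 3)
    fs <- forward_stromal_fluorescence(pdc, kd, f0, q, icf, pro)
    back <- pdc_multi_drop(kd, q, icf, fs, f0, pro$probe, pro$loading,
                           pro$tear_volume_uL, pro$n_loading)
    expect_lt(abs(back - pdc) / pdc, 1e-12)
  }
})

test_that("protocol configurations round-trip through YAML and JSON", {
  pro <- protocol_config(tear_volume_uL = 8.5, n_loading = 3)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_protocol(pro, path)
    back <- read_protocol(path)
    expect_equal(back$tear_volume_uL, 8.5)
    expect_equal(back$n_loading, 3L)
    expect_equal(back$probe$mass_ug, 7)
    expect_equal(back$instrument$icf, pro$instrument$icf)
  }
  expect_error(protocol_config(t1_s = 500, t2_s = 400), "timeline")
})
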