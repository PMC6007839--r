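# shared fixtures: the two-drop study protocol and small generators

study_protocol <- function() {
  protocol_config(
    probe = drop_spec(2, 0.35),
    loading = drop_spec(6, 2),
    n_loading = 2,
    tear_volume_uL = 7,
    instrument = instrument_config(280, 3)
  )
}

# brute-force SSE grid search over (f0, kd) — independent oracle for fit_decay
grid_fit <- function(times, values, f0_range, kd_range, n_grid = 201) {
  f0s <- seq(f0_range[1], f0_range[2], length.out = n_grid)
  kds <- seq(kd_range[1], kd_range[2], length.out = n_grid)
  best <- c(f0 = NA_real_, kd = NA_real_, sse = Inf)
  for (f0 in f0s) {
    pred <- outer(kds, times, function(k, t) f0 * exp(-k * t))
    sse <- rowSums((sweep(pred, 2, values))^2)
    i <- which.min(sse)
    if (sse[i] < best[["sse"]]) best <- c(f0 = f0, kd = kds[i], sse = sse[i])
  }
  best
}
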