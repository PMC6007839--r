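#' Timed fluorescence trace from one site of one eye
#'
#' @param times_s Strictly increasing sample times, seconds.
#' @param values_mV Fluorescence readings, millivolts.
#' @param eye_id Identifier of the eye.
#' @param site `"tear"` or `"stroma"`.
#' @param background_mV Pre-dye fluorescence at this site (subtracted before
#'   fitting); tears default to 0, their autofluorescence being negligible.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times_s, values_mV, eye_id = "eye",
                               site = c("tear", "stroma"),
                               background_mV = 0) {
  site <- match.arg(site)
  check_number(times_s, "times_s", allow_vector = TRUE)
  check_number(values_mV, "values_mV", allow_vector = TRUE)
  check_number(background_mV, "background_mV", 0)
  if (length(times_s) != length(values_mV)) {
    stop_domain("times_s and values_mV must have the same length")
  }
  if (length(times_s) >= 2 && any(diff(times_s) <= 0)) {
    stop_domain("times_s must be strictly increasing")
  }
  structure(
    list(eye_id = as.character(eye_id), site = site,
         times_s = as.numeric(times_s), values_mV = as.numeric(values_mV),
         background_mV = background_mV),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("<fluorescence_trace> %s (%s), %d points over %g s\n",
              x$eye_id, x$site, length(x$times_s), diff(range(x$times_s))))
  invisible(x)
}

#' Read and write fluorescence trace files
#'
#' Traces are stored as delimited text with a header. The single-trace
#' format has columns `time_s, fluorescence_mV`; the long multi-eye format
#' adds `eye_id` and `site` columns, in which case a named list of traces is
#' returned.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param background_mV Background passed to each [fluorescence_trace()].
#' @return One `fluorescence_trace`, or a named list of them for the long
#'   format.
#' @export
read_trace <- function(path, sep = ",", background_mV = 0) {
  if (!file.exists(path)) stop_domain("trace file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("time_s", "fluorescence_mv")
  if (!all(need %in% names(df))) {
    stop_domain("trace file must have columns time_s and fluorescence_mV")
  }
  if (all(c("eye_id", "site") %in% names(df))) {
    parts <- split(df, list(df$eye_id, df$site), drop = TRUE)
    out <- lapply(parts, function(p) {
      p <- p[order(p$time_s), ]
      fluorescence_trace(p$time_s, p$fluorescence_mv, eye_id = p$eye_id[1],
                         site = p$site[1], background_mV = background_mV)
    })
    return(out)
  }
  df <- df[order(df$time_s), ]
  fluorescence_trace(df$time_s, df$fluorescence_mv,
                     background_mV = background_mV)
}

#' @rdname read_trace
#' @param trace A `fluorescence_trace`.
#' @export
write_trace <- function(trace, path, sep = ",") {
  stopifnot(inherits(trace, "fluorescence_trace"))
  utils::write.table(
    data.frame(time_s = trace$times_s, fluorescence_mV = trace$values_mV),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit single-exponential tear clearance
#'
#' Fits F(t) = F0 * exp(-kd * t) to a tear trace by unweighted nonlinear
#' least squares with the plateau constrained to zero (tear autofluorescence
#' being negligible). Start values come from the first reading (F0) and a
#' log-linear regression on the strictly positive readings (kd), after which
#' Levenberg-Marquardt refinement is run. A free-plateau variant is
#' available behind `free_plateau = TRUE` for sensitivity analysis only.
#'
#' @param trace A [fluorescence_trace()] with `site = "tear"` and at least
#'   3 points.
#' @param free_plateau Fit an additional additive plateau term (default
#'   `FALSE`, the model of record).
#' @return An object of class `decay_fit` with fields `f0_mV`, `kd_per_s`,
#'   `half_life_s`, `r_squared`, `residual_sd_mV`, `converged`, `n_points`,
#'   and `plateau_mV` when `free_plateau = TRUE`.
#' @export
fit_decay <- function(trace, free_plateau = FALSE) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  if (trace$site != "tear") {
    stop_domain("fit_decay() expects a tear trace (clearance kinetics)")
  }
  t <- trace$times_s
  y <- trace$values_mV - trace$background_mV
  if (length(t) < 3) stop_domain("need at least 3 points to fit a decay")
  if (any(y < 0)) {
    warning("negative background-subtracted readings; clamped to 0 for fitting",
            call. = FALSE)
    y <- pmax(y, 0)
  }

  # derivative-free start: intercept from the first reading, rate from a
  # log-linear regression over the strictly positive readings
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ t[pos])
    kd0 <- max(-stats::coef(lf)[[2]], 1e-6)
    f00 <- max(exp(stats::coef(lf)[[1]]), max(y), 1e-6)
  } else {
    kd0 <- 0.01
    f00 <- max(y, 1e-6)
  }

  df <- data.frame(t = t, y = y)
  fit <- tryCatch({
    if (free_plateau) {
      minpack.lm::nlsLM(y ~ f0 * exp(-kd * t) + c0, data = df,
                        start = list(f0 = f00, kd = kd0, c0 = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ f0 * exp(-kd * t), data = df,
                        start = list(f0 = f00, kd = kd0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(
      list(f0_mV = NA_real_, kd_per_s = NA_real_, half_life_s = NA_real_,
           r_squared = NA_real_, residual_sd_mV = NA_real_,
           converged = FALSE, n_points = length(t),
           plateau_mV = if (free_plateau) NA_real_ else NULL),
      class = "decay_fit"))
  }

  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  kd <- unname(cf[["kd"]])
  structure(
    list(
      f0_mV = unname(cf[["f0"]]),
      kd_per_s = kd,
      half_life_s = if (kd > 0) log(2) / kd else NA_real_,
      r_squared = r2,
      residual_sd_mV = sqrt(ss_res / max(length(t) - length(cf), 1)),
      converged = TRUE,
      n_points = length(t),
      plateau_mV = if (free_plateau) unname(cf[["c0"]]) else NULL
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<decay_fit> NOT CONVERGED (", x$n_points, " points)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<decay_fit> F0 = %.2f mV, kd = %.5f /s (t1/2 = %.1f s), R2 = %.4f, n = %d\n",
    x$f0_mV, x$kd_per_s, x$half_life_s, x$r_squared, x$n_points))
  invisible(x)
}

#' Tear-film half-life of fluorescein
#'
#' @param kd_per_s Elimination rate constant, per second (> 0).
#' @return Half-life ln(2)/kd in seconds.
#' @export
half_life <- function(kd_per_s) {
  check_number(kd_per_s, "kd_per_s", 0, strict = TRUE, allow_vector = TRUE)
  log(2) / kd_per_s
}

#' Quality control of a clearance fit
#'
#' A fit passes when it converged, the rate constant is positive, and the
#' coefficient of determination clears the threshold (decay fits of clean
#' traces typically exceed 0.9).
#'
#' @param fit A [fit_decay()] result.
#' @param min_r_squared Minimum acceptable R-squared (default 0.9).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   machine-readable codes among `"not_converged"`, `"nonpositive_rate"`,
#'   `"low_r_squared"`).
#' @export
qc_fit <- function(fit, min_r_squared = 0.9) {
  stopifnot(inherits(fit, "decay_fit"))
  reasons <- character()
  if (!isTRUE(fit$converged)) reasons <- c(reasons, "not_converged")
  if (isTRUE(fit$converged) && (!is.finite(fit$kd_per_s) || fit$kd_per_s <= 0)) {
    reasons <- c(reasons, "nonpositive_rate")
  }
  if (isTRUE(fit$converged) && is.finite(fit$r_squared) &&
      fit$r_squared < min_r_squared) {
    reasons <- c(reasons, "low_r_squared")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
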