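# internal argument checks shared across modules

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, strict = FALSE,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || (!allow_vector && length(x) != 1L)) {
    stop_domain("`", name, "` must be a ",
                if (allow_vector) "numeric vector" else "single number")
  }
  if (any(!is.finite(x))) {
    stop_domain("`", name, "` must be finite")
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    stop_domain("`", name, "` must be ", if (strict) "> " else ">= ",
                lower, " (got ", paste(signif(x[if (strict) x <= lower else x < lower], 6), collapse = ", "), ")")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
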