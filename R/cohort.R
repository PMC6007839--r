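#' Canonical per-eye record columns
#'
#' The canonical cohort table has one row per eye with unit-suffixed
#' columns: `subject_id`, `sex`, `age_years`, `eye` ("right"/"left"),
#' `cct_um`, `q_um`, `kd_per_s`, `f0dp_mV`, `fds_raw_mV`,
#' `fds_corrected_mV`, `drop_ratio`, `pdc_no_icf_nm_s`, `pdc_nm_s`.
#' @keywords internal
#' @name cohort-columns
NULL

canonical_columns <- c(
  "subject_id", "sex", "age_years", "eye", "cct_um", "q_um", "kd_per_s",
  "f0dp_mV", "fds_raw_mV", "fds_corrected_mV", "drop_ratio",
  "pdc_no_icf_nm_s", "pdc_nm_s"
)

# S1-style spreadsheet layout: header-recognition patterns applied to
# normalized (lowercase, alphanumeric-only) headers, in canonical order.
s1_patterns <- list(
  subject_id = "^subject", sex = "^sex$", age_years = "^age",
  eye = "^eye", cct_um = "^cct", q_um = "^q", kd_per_s = "^kd",
  f0dp_mV = "^fdp0$|^f0dp", fds_raw_mV = "^fds$",
  fds_corrected_mV = "correct.*fds|^fds.*correct|^correctedfds$",
  drop_ratio = "^ratio", pdc_no_icf_nm_s = "pdc.*without.*icf|pdcnoicf",
  pdc_nm_s = "^pdc$|^pdcnms$"
)

s1_headers <- c(
  subject_id = "Subject ID", sex = "Sex", age_years = "Age (years)",
  eye = "Eye", cct_um = "CCT (um)", q_um = "Q nm", kd_per_s = "kd (per sec)",
  f0dp_mV = "fdp0", fds_raw_mV = "Fds", fds_corrected_mV = "corrected Fds",
  drop_ratio = "ratio", pdc_no_icf_nm_s = "Pdc without ICF", pdc_nm_s = "Pdc"
)

normalize_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

numeric_cols <- setdiff(canonical_columns, c("subject_id", "sex", "eye"))

#' Read a per-eye cohort table
#'
#' Two dialects are supported. `"canonical"` expects the package's
#' unit-suffixed headers. `"s1_file"` reads the deposited-raw-data
#' spreadsheet layout (exported as CSV): case-insensitive header matching,
#' eye coded 1 = right / 2 = left, and a stromal-thickness column whose
#' legend says nanometres — its magnitude is auto-detected (values > 1e4
#' are treated as nm and converted to um, with a message).
#'
#' @param path CSV file path.
#' @param dialect `"canonical"` or `"s1_file"`.
#' @return A data.frame of eye records in canonical columns.
#' @export
read_cohort_table <- function(path, dialect = c("canonical", "s1_file")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_domain("cohort table not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  if (dialect == "canonical") {
    missing <- setdiff(canonical_columns, names(raw))
    if (length(missing)) {
      stop_domain("cohort table missing required column(s): ",
                  paste(missing, collapse = ", "))
    }
    df <- raw[canonical_columns]
  } else {
    norm <- normalize_header(names(raw))
    idx <- vapply(names(s1_patterns), function(col) {
      hit <- grep(s1_patterns[[col]], norm)
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
    if (anyNA(idx)) {
      stop_domain("cohort table missing required column(s): ",
                  paste(names(idx)[is.na(idx)], collapse = ", "))
    }
    df <- raw[idx]
    names(df) <- names(s1_patterns)
    df$eye <- ifelse(df$eye %in% c(1, "1"), "right",
                     ifelse(df$eye %in% c(2, "2"), "left",
                            tolower(as.character(df$eye))))
  }

  for (col in numeric_cols) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad)) {
      stop_domain("non-numeric value in column `", col, "` at row ",
                  bad[1], ": \"", v[bad[1]], "\"")
    }
    df[[col]] <- num
  }
  df$subject_id <- as.character(df$subject_id)

  # S1 legend stores Q in nm; detect magnitude and normalize to um
  if (any(df$q_um > 1e4, na.rm = TRUE)) {
    message("q column magnitude suggests nanometres; converting to um")
    df$q_um <- df$q_um / 1000
  }
  rownames(df) <- NULL
  df
}

#' Write a per-eye cohort table
#'
#' @param records Canonical eye-record data.frame.
#' @param path Output CSV path.
#' @param dialect `"canonical"` (unit-suffixed headers) or `"s1_file"`
#'   (the deposited-raw-data layout: eye coded 1/2, stromal thickness in nm).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path,
                               dialect = c("canonical", "s1_file")) {
  dialect <- match.arg(dialect)
  missing <- setdiff(canonical_columns, names(records))
  if (length(missing)) {
    stop_domain("records missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- records[canonical_columns]
  if (dialect == "s1_file") {
    df$eye <- ifelse(df$eye == "right", 1L, 2L)
    df$q_um <- df$q_um * 1000
    names(df) <- unname(s1_headers[canonical_columns])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recompute per-eye permeability for a cohort
#'
#' Applies the multi-drop permeability equation to every eye: the record's
#' `kd_per_s`, `f0dp_mV` and corrected stromal fluorescence, the protocol's
#' instrument correction factor, and the drop-scaling ratio. A stored
#' per-eye `drop_ratio` takes precedence over the protocol-derived one
#' (it may embed per-session adjustments); with `strict = TRUE` the
#' protocol ratio is recomputed and a warning is issued when the two
#' disagree by more than 1%. Stromal thickness uses the stored `q_um` when
#' present, else is derived from `cct_um`.
#'
#' Per-record failures are collected rather than fatal: failed rows get
#' `NA` permeability and `pdc_ok = FALSE`, and the number of failures is
#' reported in a message.
#'
#' @param records Canonical eye-record data.frame.
#' @param protocol A [protocol_config()].
#' @param strict Recompute the drop ratio and warn on > 1% disagreement.
#' @return The records with `pdc_nm_s`, `pdc_no_icf_nm_s` and `pdc_ok`
#'   populated.
#' @export
compute_pdc_records <- function(records, protocol = protocol_config(),
                                strict = FALSE) {
  stopifnot(is.data.frame(records), inherits(protocol, "protocol_config"))
  icf <- protocol$instrument$icf
  ratio_protocol <- protocol_drop_ratio(protocol)
  n <- nrow(records)
  pdc <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      q <- records$q_um[i]
      if (is.na(q) || q <= 0) q <- stromal_thickness(records$cct_um[i])
      ratio <- records$drop_ratio[i]
      if (is.null(ratio) || is.na(ratio) || ratio <= 0) ratio <- ratio_protocol
      if (strict && abs(ratio - ratio_protocol) / ratio_protocol > 0.01) {
        warning(sprintf(
          "row %d: stored drop_ratio %.5g disagrees with protocol %.5g by > 1%%",
          i, ratio, ratio_protocol), call. = FALSE)
      }
      pdc_multi_drop(
        kd_per_s = records$kd_per_s[i], q_um = q, icf = icf,
        fs_mV = records$fds_corrected_mV[i], F0dP_mV = records$f0dp_mV[i],
        probe = protocol$probe, loading = protocol$loading,
        tear_volume_uL = protocol$tear_volume_uL,
        n_loading = protocol$n_loading
      ) * ratio / ratio_protocol
    }, error = function(e) NA_real_)
    pdc[i] <- res
    ok[i] <- is.finite(res)
  }
  if (any(!ok)) {
    message(sum(!ok), " of ", n,
            " record(s) failed permeability computation; excluded from summaries")
  }
  records$pdc_nm_s <- pdc
  records$pdc_no_icf_nm_s <- pdc / icf
  records$pdc_ok <- ok
  records
}

#' Descriptive summary of a cohort quantity
#'
#' @param values Numeric vector (non-finite values dropped); at least one
#'   finite value required.
#' @param bin_width Histogram bin width; `NULL` picks Sturges breaks.
#' @param n_subjects Optional distinct-subject count to carry in the
#'   summary.
#' @return An object of class `cohort_summary`: `n_eyes`, `n_subjects`,
#'   `mean`, `sd` (n - 1 denominator; 0 with `sd_undefined = TRUE` for a
#'   single value), `se` (over eyes), `median`, `min`, `max`, and a
#'   `histogram` (breaks + counts).
#' @export
summarize_cohort <- function(values, bin_width = NULL, n_subjects = NA) {
  if (!is.numeric(values)) stop_domain("`values` must be numeric")
  values <- values[is.finite(values)]
  if (!length(values)) stop_domain("no finite values to summarize")
  n <- length(values)
  sd_undef <- n < 2
  s <- if (sd_undef) 0 else stats::sd(values)
  breaks <- if (is.null(bin_width)) {
    "Sturges"
  } else {
    lo <- floor(min(values) / bin_width) * bin_width
    seq(lo, max(values) + bin_width, by = bin_width)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(
    list(n_eyes = n, n_subjects = n_subjects,
         mean = mean(values), sd = s, se = s / sqrt(n),
         median = stats::median(values),
         min = min(values), max = max(values),
         sd_undefined = sd_undef,
         histogram = list(breaks = h$breaks, counts = h$counts)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<cohort_summary> n = %d eyes%s: mean %.3g +/- %.3g (SE %.3g), ",
           "median %.3g, range %.3g-%.3g\n"),
    x$n_eyes,
    if (is.na(x$n_subjects)) "" else sprintf(" (%d subjects)", x$n_subjects),
    x$mean, x$sd, x$se, x$median, x$min, x$max))
  invisible(x)
}

#' @export
as.list.cohort_summary <- function(x, ...) {
  list(n_eyes = x$n_eyes, n_subjects = x$n_subjects, mean = x$mean,
       sd = x$sd, se = x$se, median = x$median, min = x$min, max = x$max,
       sd_undefined = x$sd_undefined, histogram = x$histogram)
}
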