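#' Fluorescein drop specification
#'
#' A drop is described by its instilled volume and fluorescein concentration
#' in % weight/volume (grams per 100 mL); the dye mass follows directly since
#' 1% w/v corresponds to 10 ug/uL.
#'
#' @param volume_uL Instilled volume in microlitres (>= 0).
#' @param concentration_pct_wv Fluorescein concentration in % w/v (>= 0).
#' @return An object of class `drop_spec` with fields `volume_uL`,
#'   `concentration_pct_wv` and the derived `mass_ug`.
#' @examples
#' drop_spec(2, 0.35)   # the dilute probe drop, 7 ug of dye
#' drop_spec(6, 2)      # a loading drop, 120 ug
#' @export
drop_spec <- function(volume_uL, concentration_pct_wv) {
  check_number(volume_uL, "volume_uL", lower = 0)
  check_number(concentration_pct_wv, "concentration_pct_wv", lower = 0)
  structure(
    list(
      volume_uL = volume_uL,
      concentration_pct_wv = concentration_pct_wv,
      mass_ug = drop_mass(volume_uL, concentration_pct_wv)
    ),
    class = "drop_spec"
  )
}

#' @export
print.drop_spec <- function(x, ...) {
  cat(sprintf("<drop_spec> %g uL of %g%% w/v fluorescein (%g ug)\n",
              x$volume_uL, x$concentration_pct_wv, x$mass_ug))
  invisible(x)
}

#' Fluorescein mass in an instilled drop
#'
#' @param volume_uL Drop volume in microlitres.
#' @param concentration_pct_wv Concentration in % w/v; 1% w/v = 10 ug/uL.
#' @return Dye mass in micrograms.
#' @export
drop_mass <- function(volume_uL, concentration_pct_wv) {
  check_number(volume_uL, "volume_uL", lower = 0, allow_vector = TRUE)
  check_number(concentration_pct_wv, "concentration_pct_wv", lower = 0,
               allow_vector = TRUE)
  concentration_pct_wv * 10 * volume_uL
}

#' Instrument geometry of the confocal spot fluorometer
#'
#' The focal diamond is the intersection volume of the excitation and
#' emission beams; its full axial extent (2 delta) sets the depth resolution.
#' Because the tear film is far thinner than the focal diamond while the
#' stroma is thicker, fluorescence per unit dye concentration differs
#' between the two sites by the instrument correction factor
#' ICF = delta / tear-film thickness.
#'
#' @param focal_diamond_depth_um Full axial extent 2*delta in micrometres.
#' @param tear_film_thickness_um Tear-film thickness t_d in micrometres.
#' @param quench_threshold_pct Concentration (% w/v) above which inner-filter
#'   quenching is assumed to distort readings; default 0.38.
#' @param snr Nominal signal-to-noise ratio of a fluorescence reading.
#' @return An object of class `instrument_config` with the inputs and the
#'   derived `icf`.
#' @export
instrument_config <- function(focal_diamond_depth_um = 280,
                              tear_film_thickness_um = 3,
                              quench_threshold_pct = 0.38,
                              snr = 44) {
  check_number(focal_diamond_depth_um, "focal_diamond_depth_um", 0, strict = TRUE)
  check_number(tear_film_thickness_um, "tear_film_thickness_um", 0, strict = TRUE)
  check_number(quench_threshold_pct, "quench_threshold_pct", 0)
  check_number(snr, "snr", 0, strict = TRUE)
  cfg <- structure(
    list(
      focal_diamond_depth_um = focal_diamond_depth_um,
      tear_film_thickness_um = tear_film_thickness_um,
      quench_threshold_pct = quench_threshold_pct,
      snr = snr
    ),
    class = "instrument_config"
  )
  cfg$icf <- instrument_correction_factor(cfg)
  cfg
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf(
    "<instrument_config> 2d = %g um, t_d = %g um, ICF = %.2f (~%d)\n",
    x$focal_diamond_depth_um, x$tear_film_thickness_um, x$icf, round(x$icf)))
  invisible(x)
}

#' Instrument correction factor (ICF)
#'
#' Ratio of the focal-diamond volume to its intersection with the tear film,
#' delta / t_d. Tear-film fluorescence must be multiplied by the ICF to
#' predict the fluorescence the same dye concentration would give in the
#' (optically thick) stroma. Reported rounded to the nearest integer for
#' display; full precision is used in every computation.
#'
#' @param config An [instrument_config()].
#' @return Dimensionless ICF (full precision).
#' @export
instrument_correction_factor <- function(config) {
  stopifnot(inherits(config, "instrument_config"))
  (config$focal_diamond_depth_um / 2) / config$tear_film_thickness_um
}

#' Multi-drop protocol configuration
#'
#' Bundles drop specifications, the assumed resident tear volume, the
#' protocol timeline and the instrument geometry. Defaults reproduce the
#' two-drop protocol: a 2 uL / 0.35% probe drop, two 6 uL / 2% loading
#' drops 10 min apart, wash 15 min after the second loading drop, stromal
#' reading ~5 min later. The resident tear volume V_d is an assumption of
#' the method (not measured); it defaults to the standard physiological
#' 7 uL and is echoed in every serialized protocol.
#'
#' @param probe,loading [drop_spec()]s of the probe and loading drops.
#' @param n_loading Number of loading drops (>= 1).
#' @param tear_volume_uL Assumed resident tear volume V_d in microlitres.
#' @param t1_s,t2_s,t3_s,ts_s Timeline in seconds: first and second loading
#'   drop instillations, ocular-surface wash, and the stromal reading.
#' @param instrument An [instrument_config()].
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(probe = drop_spec(2, 0.35),
                            loading = drop_spec(6, 2),
                            n_loading = 2,
                            tear_volume_uL = 7,
                            t1_s = 900, t2_s = 1500, t3_s = 2400, ts_s = 2700,
                            instrument = instrument_config()) {
  stopifnot(inherits(probe, "drop_spec"), inherits(loading, "drop_spec"),
            inherits(instrument, "instrument_config"))
  check_number(n_loading, "n_loading", 1)
  check_number(tear_volume_uL, "tear_volume_uL", 0, strict = TRUE)
  for (nm in c("t1_s", "t2_s", "t3_s", "ts_s")) {
    check_number(get(nm), nm, 0)
  }
  if (!(t1_s < t2_s && t2_s < t3_s && t3_s <= ts_s)) {
    stop_domain("protocol timeline must satisfy t1_s < t2_s < t3_s <= ts_s")
  }
  structure(
    list(probe = probe, loading = loading, n_loading = as.integer(n_loading),
         tear_volume_uL = tear_volume_uL,
         t1_s = t1_s, t2_s = t2_s, t3_s = t3_s, ts_s = ts_s,
         instrument = instrument),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf(
    paste0("<protocol_config> probe %g uL @ %g%%, %d loading drop(s) %g uL @ %g%%,",
           " V_d = %g uL, ICF = %.2f\n"),
    x$probe$volume_uL, x$probe$concentration_pct_wv, x$n_loading,
    x$loading$volume_uL, x$loading$concentration_pct_wv,
    x$tear_volume_uL, x$instrument$icf))
  invisible(x)
}

#' Serialize / deserialize a protocol configuration
#'
#' Protocols are stored as YAML or JSON with unit-suffixed keys so files are
#' auditable without the package. The format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param protocol A [protocol_config()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_protocol()` returns `path` invisibly; `read_protocol()`
#'   returns a [protocol_config()].
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "protocol_config"))
  x <- list(
    probe = list(volume_uL = protocol$probe$volume_uL,
                 concentration_pct_wv = protocol$probe$concentration_pct_wv),
    loading = list(volume_uL = protocol$loading$volume_uL,
                   concentration_pct_wv = protocol$loading$concentration_pct_wv),
    n_loading = protocol$n_loading,
    tear_volume_uL = protocol$tear_volume_uL,
    t1_s = protocol$t1_s, t2_s = protocol$t2_s,
    t3_s = protocol$t3_s, ts_s = protocol$ts_s,
    instrument = list(
      focal_diamond_depth_um = protocol$instrument$focal_diamond_depth_um,
      tear_film_thickness_um = protocol$instrument$tear_film_thickness_um,
      quench_threshold_pct = protocol$instrument$quench_threshold_pct,
      snr = protocol$instrument$snr
    )
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop_domain("unsupported protocol file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop_domain("protocol file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_domain("unsupported protocol file extension: ", path)
  }
  ins <- x$instrument %||% list()
  protocol_config(
    probe = drop_spec(x$probe$volume_uL, x$probe$concentration_pct_wv),
    loading = drop_spec(x$loading$volume_uL, x$loading$concentration_pct_wv),
    n_loading = x$n_loading %||% 2,
    tear_volume_uL = x$tear_volume_uL %||% 7,
    t1_s = x$t1_s %||% 900, t2_s = x$t2_s %||% 1500,
    t3_s = x$t3_s %||% 2400, ts_s = x$ts_s %||% 2700,
    instrument = instrument_config(
      focal_diamond_depth_um = ins$focal_diamond_depth_um %||% 280,
      tear_film_thickness_um = ins$tear_film_thickness_um %||% 3,
      quench_threshold_pct = ins$quench_threshold_pct %||% 0.38,
      snr = ins$snr %||% 44
    )
  )
}

#' Tear fluorescein concentration immediately after a drop
#'
#' Assumes no spillover and complete mixing of the instilled drop with the
#' resident tears: C0 = M / (V_i + V_d).
#'
#' @param mass_ug Dye mass instilled, micrograms.
#' @param instilled_uL Instilled drop volume V_i, microlitres.
#' @param tear_volume_uL Resident tear volume V_d, microlitres.
#' @return Concentration in ug/uL.
#' @export
initial_tear_concentration <- function(mass_ug, instilled_uL, tear_volume_uL) {
  check_number(mass_ug, "mass_ug", 0, allow_vector = TRUE)
  check_number(instilled_uL, "instilled_uL", 0, allow_vector = TRUE)
  check_number(tear_volume_uL, "tear_volume_uL", 0, allow_vector = TRUE)
  total <- instilled_uL + tear_volume_uL
  if (any(total <= 0)) stop_domain("instilled_uL + tear_volume_uL must be > 0")
  mass_ug / total
}

#' Area under the probe-drop tear fluorescence curve
#'
#' The tear trace decays as F0 * exp(-kd * t), so the AUC over `[0, T]` is
#' (F0/kd) * (1 - exp(-kd*T)); over an unbounded horizon it is F0/kd.
#'
#' @param F0_mV Fitted tear fluorescence at t = 0, millivolts.
#' @param kd_per_s Elimination rate constant, per second (> 0).
#' @param horizon_s Integration horizon in seconds, or `Inf` (default) for
#'   the complete decay.
#' @return AUC in mV * s.
#' @export
auc_probe <- function(F0_mV, kd_per_s, horizon_s = Inf) {
  check_number(F0_mV, "F0_mV", 0, allow_vector = TRUE)
  check_number(kd_per_s, "kd_per_s", 0, strict = TRUE, allow_vector = TRUE)
  if (!is.numeric(horizon_s) || any(is.na(horizon_s)) || any(horizon_s < 0)) {
    stop_domain("`horizon_s` must be >= 0 (possibly Inf)")
  }
  (F0_mV / kd_per_s) * (1 - exp(-kd_per_s * horizon_s))
}

#' Loading-drop initial fluorescence scaled from the probe drop
#'
#' Tear fluorescence after a loading drop cannot be measured directly (the
#' 2% drop quenches), so its t = 0 value is scaled from the probe drop using
#' drop masses and dilution volumes:
#' F0_dL = F0_dP * (M_L/M_P) * (V_iP + V_d) / (V_iL + V_d).
#'
#' @param F0dP_mV Probe-drop fluorescence at t = 0, mV.
#' @param probe,loading [drop_spec()]s.
#' @param tear_volume_uL Resident tear volume V_d, microlitres.
#' @return Predicted loading-drop fluorescence at instillation, mV.
#' @export
loading_f0_from_probe <- function(F0dP_mV, probe, loading, tear_volume_uL) {
  check_number(F0dP_mV, "F0dP_mV", 0, allow_vector = TRUE)
  stopifnot(inherits(probe, "drop_spec"), inherits(loading, "drop_spec"))
  check_number(tear_volume_uL, "tear_volume_uL", 0, strict = TRUE)
  if (probe$mass_ug <= 0) stop_domain("probe drop must carry a positive dye mass")
  F0dP_mV * (loading$mass_ug / probe$mass_ug) *
    (probe$volume_uL + tear_volume_uL) / (loading$volume_uL + tear_volume_uL)
}

#' Area under the loading-drop fluorescence curve
#'
#' Complete-decay AUC of one loading drop, obtained by scaling the probe
#' drop: AUC_dL = (F0_dP/kd) * (M_L/M_P) * (V_iP + V_d)/(V_iL + V_d). The
#' elimination rate kd is assumed shared between probe and loading drops.
#' Implemented as [auc_probe()] of [loading_f0_from_probe()].
#'
#' @inheritParams loading_f0_from_probe
#' @param kd_per_s Elimination rate constant, per second.
#' @return AUC in mV * s.
#' @export
auc_loading <- function(F0dP_mV, kd_per_s, probe, loading, tear_volume_uL) {
  auc_probe(
    loading_f0_from_probe(F0dP_mV, probe, loading, tear_volume_uL),
    kd_per_s
  )
}

#' Mean stromal thickness from central corneal thickness
#'
#' Q = 1.06 * CCT - 50 um, an OCT-derived relation that removes a nominal
#' 50 um epithelial thickness.
#'
#' @param cct_um Central corneal thickness in micrometres.
#' @return Stromal thickness Q in micrometres.
#' @export
stromal_thickness <- function(cct_um) {
  check_number(cct_um, "cct_um", 0, strict = TRUE, allow_vector = TRUE)
  q <- 1.06 * cct_um - 50
  if (any(q <= 0)) {
    stop_domain("cct_um yields non-positive stromal thickness (needs CCT > ",
                signif(50 / 1.06, 5), " um)")
  }
  q
}

#' Background- and gain-corrected stromal fluorescence
#'
#' Subtracts pre-dye stromal autofluorescence, then applies the
#' multiplicative correction for the change of slit width / PMT gain between
#' the stromal and tear channels. Noisy subtraction can undershoot zero, in
#' which case the value is clamped at 0 with a warning rather than erroring.
#'
#' @param uFs_mV Uncorrected stromal fluorescence, mV.
#' @param autofluorescence_mV Pre-dye stromal fluorescence, mV.
#' @param gain_correction Multiplicative channel correction (> 0).
#' @return Corrected stromal fluorescence, mV (>= 0).
#' @export
correct_stromal_fluorescence <- function(uFs_mV, autofluorescence_mV,
                                         gain_correction = 1) {
  check_number(uFs_mV, "uFs_mV", allow_vector = TRUE)
  check_number(autofluorescence_mV, "autofluorescence_mV", allow_vector = TRUE)
  check_number(gain_correction, "gain_correction", 0, strict = TRUE,
               allow_vector = TRUE)
  fs <- (uFs_mV - autofluorescence_mV) * gain_correction
  if (any(fs < 0)) {
    warning("corrected stromal fluorescence < 0 in ", sum(fs < 0),
            " reading(s); clamped to 0", call. = FALSE)
    fs <- pmax(fs, 0)
  }
  fs
}

#' Protocol drop-scaling ratio
#'
#' The factor (M_P/M_L) * (V_iL + V_d)/(V_iP + V_d) by which the permeability
#' equation rescales loading-drop driving force back to probe-drop
#' measurements (the reciprocal of the AUC scaling).
#'
#' @param protocol A [protocol_config()].
#' @return Dimensionless ratio.
#' @export
protocol_drop_ratio <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (protocol$loading$mass_ug <= 0) {
    stop_domain("loading drop must carry a positive dye mass")
  }
  (protocol$probe$mass_ug / protocol$loading$mass_ug) *
    (protocol$loading$volume_uL + protocol$tear_volume_uL) /
    (protocol$probe$volume_uL + protocol$tear_volume_uL)
}

#' Epithelial permeability from the multi-drop protocol
#'
#' Closed-form permeability of the corneal epithelium to fluorescein after
#' `n_loading` identical loading drops:
#'
#'   Pdc = kd * Q * ICF * Fs(T_{n+1}) / (n * F0_dP)
#'           * (M_P/M_L) * (V_iL + V_d)/(V_iP + V_d)
#'
#' where Fs is the corrected stromal fluorescence at the end-of-protocol
#' reading and ICF converts tear-channel fluorescence per unit concentration
#' to stromal-channel. Q is supplied in micrometres and converted to
#' nanometres internally so the result is in nm/s. With `n_loading = 2`
#' this is the canonical two-drop formula.
#'
#' @param kd_per_s Elimination rate constant, per second.
#' @param q_um Mean stromal thickness, micrometres.
#' @param icf Instrument correction factor (dimensionless).
#' @param fs_mV Corrected stromal fluorescence at the final reading, mV
#'   (tear-channel-equivalent units, i.e. after gain correction).
#' @param F0dP_mV Probe-drop fluorescence at t = 0, mV.
#' @param probe,loading [drop_spec()]s.
#' @param tear_volume_uL Resident tear volume V_d, microlitres.
#' @param n_loading Number of loading drops (>= 1).
#' @return Permeability Pdc in nm/s. Vectorized over the numeric arguments.
#' @export
pdc_multi_drop <- function(kd_per_s, q_um, icf, fs_mV, F0dP_mV,
                           probe = drop_spec(2, 0.35),
                           loading = drop_spec(6, 2),
                           tear_volume_uL = 7, n_loading = 2) {
  check_number(kd_per_s, "kd_per_s", 0, strict = TRUE, allow_vector = TRUE)
  check_number(q_um, "q_um", 0, strict = TRUE, allow_vector = TRUE)
  check_number(icf, "icf", 0, strict = TRUE, allow_vector = TRUE)
  check_number(fs_mV, "fs_mV", 0, allow_vector = TRUE)
  check_number(F0dP_mV, "F0dP_mV", 0, strict = TRUE, allow_vector = TRUE)
  check_number(n_loading, "n_loading", 1)
  stopifnot(inherits(probe, "drop_spec"), inherits(loading, "drop_spec"))
  check_number(tear_volume_uL, "tear_volume_uL", 0, strict = TRUE)
  if (probe$mass_ug <= 0 || loading$mass_ug <= 0) {
    stop_domain("probe and loading drops must carry positive dye mass")
  }
  ratio <- (probe$mass_ug / loading$mass_ug) *
    (loading$volume_uL + tear_volume_uL) / (probe$volume_uL + tear_volume_uL)
  q_nm <- q_um * 1000
  kd_per_s * q_nm * icf * fs_mV / (n_loading * F0dP_mV) * ratio
}
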