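#' Full processing-chain configuration
#'
#' Bundles every stage's parameters: scene synthesis (radar, motion,
#' interference), the MTI high-pass (specification plus optional
#' coefficient quantization), the CFAR presence gate, the physiological
#' search bands, and processing toggles. Serializable to YAML with
#' [write_pipeline_config()] / [read_pipeline_config()] with round-trip
#' equality.
#'
#' The pipeline's default false-alarm probability is 1e-6: over the few
#' thousand spectrum bins of a two-minute record the expected number of
#' noise-induced alarms stays far below one, so a static scene does not
#' trigger, while a breathing subject's spectral lines exceed the
#' threshold by orders of magnitude.
#'
#' @param radar [radar_params()]. @param motion [chest_motion()].
#' @param interference [interference_params()].
#' @param highpass [highpass_spec()] for the MTI design.
#' @param quantize_bits Optional coefficient word length (e.g. 5) for
#'   the MTI filter; `NULL` keeps full-precision coefficients.
#' @param cfar [cfar_config()] used as the presence gate.
#' @param bands [vital_bands()].
#' @param mti_enabled Run the MTI clutter filter? Default `TRUE`.
#' @param fixed_point Emulate the fixed-point FFT? Default `FALSE`.
#' @param fp_format [fixed_point_format()] used when `fixed_point` is on.
#' @param smooth Savitzky--Golay smoothing before rate spectra.
#' @param exclude_resp_harmonics Exclude respiration-harmonic bins from
#'   the heart-band search. Default `TRUE`.
#' @param n_channels Fast-time channels to synthesize.
#' @param input_file Optional I/Q text file; when given it is loaded
#'   with [read_iq()] instead of synthesizing.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(radar = radar_params(),
                            motion = chest_motion(),
                            interference = interference_params(),
                            highpass = highpass_spec(),
                            quantize_bits = NULL,
                            cfar = cfar_config(pfa = 1e-6),
                            bands = vital_bands(),
                            mti_enabled = TRUE,
                            fixed_point = FALSE,
                            fp_format = fixed_point_format(),
                            smooth = TRUE,
                            exclude_resp_harmonics = TRUE,
                            n_channels = 1L,
                            input_file = NULL) {
  stopifnot(inherits(radar, "radar_params"), inherits(motion, "chest_motion"),
            inherits(interference, "interference_params"),
            inherits(highpass, "highpass_spec"), inherits(cfar, "cfar_config"),
            inherits(bands, "vital_bands"),
            inherits(fp_format, "fixed_point_format"))
  structure(
    list(radar = radar, motion = motion, interference = interference,
         highpass = highpass, quantize_bits = quantize_bits, cfar = cfar,
         bands = bands, mti_enabled = isTRUE(mti_enabled),
         fixed_point = isTRUE(fixed_point), fp_format = fp_format,
         smooth = isTRUE(smooth),
         exclude_resp_harmonics = isTRUE(exclude_resp_harmonics),
         n_channels = as.integer(n_channels), input_file = input_file),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' Complex amplitudes are stored as separate real/imaginary fields so
#' the file stays a plain-text key-value document. Reading rebuilds the
#' configuration through the validating constructors; a written file
#' reads back equal to the original object.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- list(
    radar = unclass(config$radar)[c("carrier_freq", "c", "slow_sample_rate",
                                    "duration", "seed")],
    motion = unclass(config$motion),
    interference = list(
      noise_power = config$interference$noise_power,
      clutter_re = Re(config$interference$clutter_amp),
      clutter_im = Im(config$interference$clutter_amp),
      leakage_re = Re(config$interference$leakage_amp),
      leakage_im = Im(config$interference$leakage_amp)
    ),
    highpass = unclass(config$highpass),
    quantize_bits = config$quantize_bits,
    cfar = unclass(config$cfar),
    bands = list(heart = config$bands$heart, resp = config$bands$resp),
    mti_enabled = config$mti_enabled,
    fixed_point = config$fixed_point,
    fp_format = unclass(config$fp_format),
    smooth = config$smooth,
    exclude_resp_harmonics = config$exclude_resp_harmonics,
    n_channels = config$n_channels,
    input_file = config$input_file
  )
  yaml::write_yaml(lst, path, precision = 15)
  invisible(config)
}

#' @rdname write_pipeline_config
#' @return `read_pipeline_config()`: the restored [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  l <- yaml::read_yaml(path)
  pipeline_config(
    radar = do.call(radar_params, l$radar),
    motion = do.call(chest_motion, l$motion),
    interference = interference_params(
      noise_power = l$interference$noise_power,
      clutter_amp = complex(real = l$interference$clutter_re,
                            imaginary = l$interference$clutter_im),
      leakage_amp = complex(real = l$interference$leakage_re,
                            imaginary = l$interference$leakage_im)
    ),
    highpass = do.call(highpass_spec, l$highpass),
    quantize_bits = l$quantize_bits,
    cfar = do.call(cfar_config, l$cfar),
    bands = vital_bands(heart = l$bands$heart, resp = l$bands$resp),
    mti_enabled = l$mti_enabled,
    fixed_point = l$fixed_point,
    fp_format = do.call(fixed_point_format, l$fp_format),
    smooth = l$smooth,
    exclude_resp_harmonics = l$exclude_resp_harmonics,
    n_channels = l$n_channels,
    input_file = l$input_file
  )
}

#' Run the full vital-sign detection chain
#'
#' Stages, in order: synthesize the baseband scene (or load it from
#' `input_file`); MTI clutter filtering along slow time; spectrum of the
#' dominant channel plus CA-CFAR thresholding as a presence gate (a
#' purely static scene is filtered out and never triggers); phase
#' extraction (unwrap) and first differences of the selected channel;
#' band-limited rate estimation for respiration and then for the
#' heartbeat, with respiration harmonics optionally excluded from the
#' heart-band search. Deterministic for a given configuration.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `vital_sign_report`; see [tidy.vital_sign_report()].
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(radar = radar_params(duration = 60)))
#' glance(rep)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  sig <- stage("synthesize", {
    if (!is.null(config$input_file)) {
      read_iq(config$input_file)
    } else {
      synthesize_baseband(config$radar, config$motion, config$interference,
                          n_channels = config$n_channels)
    }
  })
  fs <- bb_sample_rate(sig)

  filt <- stage("mti", {
    if (config$mti_enabled) {
      f <- design_highpass(config$highpass$passband_cutoff)
      if (!is.null(config$quantize_bits)) {
        f <- quantize_coeffs(f, config$quantize_bits)
      }
      mti_apply(sig, f)
    } else {
      sig
    }
  })

  z <- bb_matrix(filt)
  ## frames = slow-time samples (rows), bins = fast-time channels (columns)
  target_ch <- stage("select_target_bin", select_target_bin(Mod(z)^2))
  series <- z[, target_ch]

  det <- stage("cfar", {
    n_fft <- next_power_of_two(length(series))
    x <- c(series, complex(n_fft - length(series)))
    fmt <- NULL
    if (config$fixed_point) {
      fmt <- config$fp_format
      peak_comp <- max(abs(Re(x)), abs(Im(x)))
      if (peak_comp > 0) x <- x * (fp_max(fmt) / 2) / peak_comp
    }
    spec <- fft_scaled(x, fmt = fmt, sample_rate = fs)
    cfar_detect(square_law(spec), config$cfar)
  })
  triggered <- any(det$detected)

  estimates <- NULL
  resp_rate <- NA_real_
  heart_rate <- NA_real_
  if (triggered) {
    phase <- stage("phase", phase_sequence(series))
    dphi <- stage("phase_diff", phase_diff(phase))
    resp <- stage("estimate_rate[resp]", estimate_rate(
      dphi, fs, config$bands$resp, smooth = config$smooth
    ))
    heart <- stage("estimate_rate[heart]", estimate_rate(
      dphi, fs, config$bands$heart, smooth = config$smooth,
      exclude_harmonics_of = if (config$exclude_resp_harmonics) resp$peak_freq_interp_hz
    ))
    estimates <- dplyr::bind_rows(
      dplyr::mutate(resp, band = "resp", .before = 1),
      dplyr::mutate(heart, band = "heart", .before = 1)
    )
    resp_rate <- round_half_up(resp$rate_per_min)
    heart_rate <- round_half_up(heart$rate_per_min)
  }

  structure(
    list(
      heart_rate = heart_rate,
      resp_rate = resp_rate,
      detection_triggered = triggered,
      estimates = estimates,
      detection = det,
      diagnostics = list(
        target_channel = target_ch,
        clutter_residual = Mod(mean(series)),
        n_detected_bins = sum(det$detected),
        sample_rate = fs,
        n_samples = nrow(z)
      ),
      config = config
    ),
    class = "vital_sign_report"
  )
}

#' @export
print.vital_sign_report <- function(x, ...) {
  cat("<vital_sign_report>\n")
  if (x$detection_triggered) {
    cat(sprintf("  detection: triggered (%d bin(s) above threshold)\n",
                x$diagnostics$n_detected_bins))
    cat(sprintf("  heart rate: %g per minute\n", x$heart_rate))
    cat(sprintf("  respiration rate: %g per minute\n", x$resp_rate))
  } else {
    cat("  detection: not triggered (no moving target); no rates reported\n")
  }
  invisible(x)
}

#' Tidy / summarize a vital-sign report
#'
#' `tidy()` returns one row per band with the raw (unrounded) rate, the
#' spectral peak and resolution, and the confidence flag; `glance()`
#' returns a one-row summary with the rounded per-minute rates.
#'
#' @param x A `vital_sign_report`.
#' @param ... Unused.
#' @method tidy vital_sign_report
#' @export
tidy.vital_sign_report <- function(x, ...) {
  if (is.null(x$estimates)) {
    return(tibble(band = character(), rate_per_min = numeric(),
                  peak_freq_hz = numeric(), resolution_hz = numeric(),
                  confident = logical()))
  }
  dplyr::select(as_tibble(x$estimates), "band", "rate_per_min",
                "peak_freq_hz", "resolution_hz", "confident")
}

#' @rdname tidy.vital_sign_report
#' @method glance vital_sign_report
#' @export
glance.vital_sign_report <- function(x, ...) {
  tibble(
    detection_triggered = x$detection_triggered,
    heart_rate = x$heart_rate,
    resp_rate = x$resp_rate,
    n_detected_bins = x$diagnostics$n_detected_bins,
    clutter_residual = x$diagnostics$clutter_residual,
    resolution_hz = if (is.null(x$estimates)) NA_real_ else x$estimates$resolution_hz[1]
  )
}
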