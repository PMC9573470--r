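#' Physiological search bands for heart and respiration rates
#'
#' Normal adult bands: heartbeat 0.6--2 Hz, respiration 0.1--0.5 Hz.
#' The bands must not overlap and the heart band must sit above the
#' respiration band.
#'
#' @param heart,resp Two-element numeric vectors `c(low, high)` in Hz.
#' @return An object of class `vital_bands`.
#' @export
vital_bands <- function(heart = c(0.6, 2), resp = c(0.1, 0.5)) {
  stopifnot(length(heart) == 2L, length(resp) == 2L)
  if (heart[1] >= heart[2] || resp[1] >= resp[2]) {
    abort("Each band must be c(low, high) with low < high.")
  }
  if (resp[2] > heart[1]) {
    abort("Bands must not overlap and the heart band must lie above the respiration band.")
  }
  structure(list(heart = heart, resp = resp), class = "vital_bands")
}

#' Select the dominant bin across a set of spectra
#'
#' Picks the bin with the largest mean power over a sequence of frames
#' (e.g. the range bin holding the subject, averaged along slow time).
#' Ties break to the lowest index.
#'
#' @param frames A complex or numeric matrix, one frame per row (a
#'   vector is treated as a single frame). Complex input is converted to
#'   power by squared modulus; numeric input is taken as power.
#' @return The selected bin (column) index.
#' @export
select_target_bin <- function(frames) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1)
  if (nrow(frames) == 0 || ncol(frames) == 0) abort("`frames` must be non-empty.")
  pow <- if (is.complex(frames)) Mod(frames)^2 else frames
  which.max(colMeans(pow)) # which.max takes the first maximum: lowest index
}

#' Phase sequence of a complex record, unwrapped
#'
#' Four-quadrant phase followed by phase expansion (unwrapping):
#' successive differences are forced into `(-pi, pi]` by adding
#' multiples of `2*pi`, so a displacement larger than half a wavelength
#' is recovered as a continuous phase excursion.
#'
#' @param values Complex vector with no zero-magnitude sample.
#' @return Unwrapped phase in radians, same length as `values`.
#' @export
phase_sequence <- function(values) {
  if (any(Mod(values) == 0)) {
    abort("Zero-magnitude sample: phase undefined.")
  }
  p <- Arg(values)
  if (length(p) == 1L) return(p)
  d <- diff(p)
  dw <- d - 2 * pi * ceiling(d / (2 * pi) - 0.5) # wraps into (-pi, pi]
  cumsum(c(p[1], dw))
}

#' First differences of a phase sequence
#'
#' A positive difference means the earlier sample's phase leads the
#' later one under the radar's sign convention; the differenced series
#' is proportional to chest-wall velocity.
#'
#' @param phase Numeric vector of (unwrapped) phase, length at least 2.
#' @return Differences `phase[n+1] - phase[n]`, one sample shorter.
#' @export
phase_diff <- function(phase) {
  if (length(phase) < 2L) abort("`phase` must have at least 2 samples.")
  diff(phase)
}

#' Estimate a per-minute rate from a real-valued series
#'
#' Optionally smooths the series with a Savitzky--Golay filter, removes
#' its mean, zero-pads to the next power of two, computes the magnitude
#' spectrum with the overflow-controlled FFT, and picks the strongest
#' bin inside the requested band. The rate is 60 times the peak
#' frequency; the spectral resolution `sample_rate / N` is reported
#' alongside. A low-confidence flag is raised when the band peak is
#' less than three times the band median (no clear line).
#'
#' @param series Real-valued series (e.g. unwrapped phase or its
#'   differences).
#' @param sample_rate Sampling rate of `series`, Hz.
#' @param band Two-element `c(low, high)` band in Hz to search.
#' @param smooth Apply Savitzky--Golay smoothing first? Default `TRUE`.
#' @param sg_window,sg_order Savitzky--Golay window length (odd) and
#'   polynomial order.
#' @param exclude_harmonics_of Optional fundamental frequency (Hz),
#'   typically the interpolated respiration peak. The nonlinear
#'   phase-to-I/Q map plus clutter filtering leaves a comb of
#'   distortion lines at integer multiples of the respiration
#'   fundamental, which can hide the much weaker heartbeat line. When
#'   the band peak falls within `harmonic_tol_bins` resolution bins of
#'   such a multiple, it is kept only if it exceeds
#'   `harmonic_peak_ratio` times the strongest sibling tooth of the
#'   comb (a genuine line dwarfs the distortion comb); otherwise the
#'   search is repeated with all comb positions excluded.
#' @param harmonic_tol_bins Half-width of each comb window, in
#'   resolution bins.
#' @param harmonic_peak_ratio Dominance factor over the sibling teeth
#'   required to keep an on-comb peak.
#' @return An object of class `rate_estimate`: a one-row tibble with
#'   `rate_per_min`, `peak_freq_hz` (on the bin grid),
#'   `peak_freq_interp_hz` (three-point parabolic refinement, metadata
#'   only), `resolution_hz`, `band_low_hz`, `band_high_hz`, `confident`.
#' @export
#' @examples
#' x <- sin(2 * pi * 1.3833 * seq(0, 120, by = 0.05))
#' estimate_rate(x, 20, band = c(0.6, 2))
estimate_rate <- function(series, sample_rate, band,
                          smooth = TRUE, sg_window = 11, sg_order = 3,
                          exclude_harmonics_of = NULL,
                          harmonic_tol_bins = 2,
                          harmonic_peak_ratio = 3) {
  stopifnot(is.numeric(series), length(band) == 2L, band[1] < band[2])
  if (length(series) < 2 / (band[1] / sample_rate)) {
    abort("Series too short: fewer than two spectral bins fall inside the band.")
  }
  if (smooth) {
    series <- signal::sgolayfilt(series, p = sg_order, n = sg_window)
  }
  series <- series - mean(series)
  n_fft <- next_power_of_two(length(series))
  padded <- c(series, numeric(n_fft - length(series)))
  spec <- fft_scaled(padded, sample_rate = sample_rate)
  freq <- fft_bin_freqs(n_fft, sample_rate)
  mag <- Mod(spec$bins)
  resolution <- sample_rate / n_fft

  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) {
    abort("Band is empty at the available spectral resolution.")
  }
  idx_band <- which(in_band)
  peak <- idx_band[which.max(mag[idx_band])]
  if (!is.null(exclude_harmonics_of) && exclude_harmonics_of > 0) {
    f0 <- exclude_harmonics_of
    k_all <- seq.int(max(1, floor(band[1] / f0)), ceiling(band[2] / f0))
    centers <- k_all * f0
    centers <- centers[centers >= band[1] - harmonic_tol_bins * resolution &
                         centers <= band[2] + harmonic_tol_bins * resolution]
    if (length(centers)) {
      win <- harmonic_tol_bins * resolution
      near_tooth <- function(f) any(abs(f - centers) <= win)
      if (near_tooth(freq[peak])) {
        ## the band peak sits on a harmonic of the fundamental: it is either
        ## a distortion tooth of the comb or a genuine line that happens to
        ## coincide. The other teeth of the comb calibrate how strong a
        ## distortion tooth can be here; a peak several times stronger than
        ## every sibling tooth is kept as a real line.
        own <- centers[which.min(abs(freq[peak] - centers))]
        sibs <- setdiff(centers, own)
        sib_mag <- vapply(sibs, function(fc) {
          sel <- abs(freq - fc) <= win & in_band
          if (any(sel)) max(mag[sel]) else NA_real_
        }, numeric(1))
        sib_mag <- sib_mag[!is.na(sib_mag)]
        comb_level <- if (length(sib_mag)) max(sib_mag) else stats::median(mag[idx_band])
        if (mag[peak] < harmonic_peak_ratio * comb_level) {
          eligible <- idx_band[vapply(freq[idx_band],
                                      function(f) !near_tooth(f), logical(1))]
          if (length(eligible)) peak <- eligible[which.max(mag[eligible])]
        }
      }
    }
  }
  band_mag <- mag[in_band]
  confident <- mag[peak] >= 3 * stats::median(band_mag)
  ## three-point parabolic refinement of the peak position (reported as
  ## metadata; the rate itself stays on the bin grid)
  interp <- freq[peak]
  if (peak > 1 && peak < length(mag)) {
    y <- mag[(peak - 1):(peak + 1)]
    den <- y[1] - 2 * y[2] + y[3]
    if (den < 0) interp <- freq[peak] + 0.5 * (y[1] - y[3]) / den * resolution
  }
  out <- tibble(
    rate_per_min = 60 * freq[peak],
    peak_freq_hz = freq[peak],
    peak_freq_interp_hz = interp,
    resolution_hz = resolution,
    band_low_hz = band[1],
    band_high_hz = band[2],
    confident = confident
  )
  class(out) <- c("rate_estimate", class(out))
  out
}
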