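#' Relative error between a radar rate and a reference rate
#'
#' `100 * |radar - reference| / denominator`, with the reference
#' (wrist-band) value as the default denominator --- the convention the
#' packaged session table follows. The magnitude is reported, matching
#' how such comparisons are printed.
#'
#' @param radar Radar-measured rate(s), per minute.
#' @param reference Reference rate(s), per minute; must be positive when
#'   used as the denominator.
#' @param denominator `"reference"` (default) or `"measured"`.
#' @return Relative error(s) in percent (not rounded).
#' @export
#' @examples
#' relative_error(85, 80) # 6.25 -> prints as 6.3
relative_error <- function(radar, reference,
                           denominator = c("reference", "measured")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "reference") reference else radar
  if (any(den <= 0)) abort("Denominator rate must be positive.")
  100 * abs(radar - reference) / den
}

#' Per-row relative errors for a table of rate pairs
#'
#' @param data A data frame with columns `radar` and `reference`
#'   (per-minute rates); extra columns pass through.
#' @param denominator See [relative_error()].
#' @return The input tibble with a `relative_error_pct` column appended
#'   (rounded half-up to 1 decimal, the printed style).
#' @export
evaluate_rates <- function(data, denominator = c("reference", "measured")) {
  stopifnot(all(c("radar", "reference") %in% names(data)))
  dplyr::mutate(
    as_tibble(data),
    relative_error_pct = round_half_up(
      relative_error(.data$radar, .data$reference, denominator), 1
    )
  )
}

#' Minimum and maximum relative error of a comparison set
#'
#' @param errors Either a numeric vector of relative errors in percent,
#'   or a data frame with columns `radar` and `reference` (errors are
#'   then computed with [relative_error()]).
#' @return A one-row tibble with `min_error_pct` and `max_error_pct`,
#'   each rounded half-up to 1 decimal.
#' @export
#' @examples
#' summarize_errors(data.frame(radar = c(85, 80), reference = c(80, 80)))
summarize_errors <- function(errors) {
  if (is.data.frame(errors)) {
    errors <- relative_error(errors$radar, errors$reference)
  }
  if (length(errors) == 0) abort("No comparisons supplied.")
  tibble(
    min_error_pct = round_half_up(min(errors), 1),
    max_error_pct = round_half_up(max(errors), 1)
  )
}

#' Bundled radar-versus-wristband rate sessions
#'
#' Fifteen paired measurement sessions of heart and respiration rates
#' taken simultaneously with a mm-wave radar and a sports wristband
#' under different exercise states, shipped as plain-text data for the
#' evaluation workflow. `printed_error_pct` is the relative error as
#' printed in the source table (reference denominator, one decimal).
#'
#' @return A tibble with columns `session`, `band` (`"heart"`/`"resp"`),
#'   `radar`, `reference`, `printed_error_pct`.
#' @export
#' @examples
#' sessions <- rate_sessions()
#' summarize_errors(dplyr::filter(sessions, band == "heart"))
rate_sessions <- function() {
  path <- system.file("extdata", "radar_bracelet_sessions.tsv",
                      package = "vitalradar", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    session = readr::col_integer(),
                    band = readr::col_character(),
                    radar = readr::col_double(),
                    reference = readr::col_double(),
                    printed_error_pct = readr::col_double()
                  ))
}
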