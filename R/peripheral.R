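#' ERB-number scale conversions
#'
#' The equivalent-rectangular-bandwidth (ERB) number scale of Glasberg & Moore
#' maps frequency in Hz onto a scale on which auditory filters are equally
#' spaced: `E(f) = 21.4 * log10(0.00437 * f + 1)`.
#'
#' @param f Frequency in Hz.
#' @param e ERB-number (dimensionless).
#' @return `erb_number()` returns ERB-numbers; `erb_number_to_hz()` its
#'   inverse; `erb_bandwidth()` the ERB in Hz at frequency `f`.
#' @export
erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_number
#' @export
erb_number_to_hz <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' @rdname erb_number
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' Auditory band grid on the ERB-number scale
#'
#' Constructs the center frequencies of an auditory filterbank spaced at equal
#' steps on the ERB-number scale, starting exactly at `f_low` and not exceeding
#' `f_high`. The default grid (700 Hz to 18 kHz, 1-ERB steps) is the band grid
#' used throughout the localization model.
#'
#' @param f_low,f_high Frequency range in Hz; `0 < f_low <= f_high`.
#' @param step Spacing in ERB-number units (default 1).
#' @return A tibble of class `erb_grid` with columns `band` (1-based index)
#'   and `cf_hz` (ascending center frequencies).
#' @examples
#' erb_bands()            # 28 bands between 700 Hz and 18 kHz
#' erb_bands(step = 0.5)  # twice the resolution
#' @export
erb_bands <- function(f_low = 700, f_high = 18000, step = 1) {
  if (!is.numeric(f_low) || !is.numeric(f_high) || f_low <= 0 || f_high < f_low)
    stop("invalid frequency range: need 0 < f_low <= f_high", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  e_lo <- erb_number(f_low)
  e_hi <- erb_number(f_high)
  e <- seq(e_lo, e_lo + floor((e_hi - e_lo) / step + 1e-9) * step, by = step)
  cf <- erb_number_to_hz(e)
  cf[1] <- f_low  # exact by construction
  out <- tibble::tibble(band = seq_along(cf), cf_hz = cf)
  class(out) <- c("erb_grid", class(out))
  out
}

#' Band magnitude profile of a filtered stimulus
#'
#' Computes the per-band spectral magnitude profile: the dB level of the
#' average squared amplitude of the stimulus after directional (DTF)
#' filtering, averaged within a rectangular window of one ERB centered on
#' each band's center frequency.
#'
#' @param freq_hz Frequency axis (Hz, ascending) on which `gain` and
#'   `stimulus_power` are sampled. Must cover every band window.
#' @param gain DTF magnitude response as linear gain on `freq_hz`.
#' @param grid An [erb_bands()] grid.
#' @param stimulus_power Stimulus power spectrum on `freq_hz`; `NULL` (the
#'   default) means a flat-spectrum (white-noise) stimulus of unit power.
#' @return Numeric vector, one dB value per band.
#' @export
magnitude_profile <- function(freq_hz, gain, grid, stimulus_power = NULL) {
  stopifnot(length(freq_hz) == length(gain))
  if (is.null(stimulus_power)) stimulus_power <- rep(1, length(freq_hz))
  stopifnot(length(stimulus_power) == length(freq_hz))
  cf <- grid$cf_hz
  half <- erb_bandwidth(cf) / 2
  lo <- cf - half
  hi <- cf + half
  if (min(freq_hz) > min(lo) || max(freq_hz) < max(hi))
    stop("frequency axis does not cover the band windows [",
         round(min(lo)), ", ", round(max(hi)), "] Hz", call. = FALSE)
  p <- gain^2 * stimulus_power
  vapply(seq_along(cf), function(b) {
    sel <- freq_hz >= lo[b] & freq_hz <= hi[b]
    if (!any(sel)) stop("no frequency samples inside band ", b, call. = FALSE)
    10 * log10(mean(p[sel]))
  }, numeric(1))
}

#' Positive spectral gradient profile
#'
#' Rectified first difference of a band magnitude profile:
#' `psg(xi)[b-1] = max(xi[b] - xi[b-1], 0)` for bands `b = 2..Nb`. The
#' rectification keeps rising spectral edges (the cue carried by spectral
#' notch flanks and peaks) and discards falling ones, making the profile
#' insensitive to broadband level and overall tilt direction.
#'
#' @param xi Numeric magnitude profile in dB (length >= 2).
#' @return Numeric vector of length `length(xi) - 1`, all entries >= 0.
#' @examples
#' psg(c(0, 5, 3, 10))  # 5 0 7
#' @export
psg <- function(xi) {
  if (length(xi) < 2) stop("profile needs at least 2 bands", call. = FALSE)
  if (any(!is.finite(xi))) stop("profile must be finite", call. = FALSE)
  pmax(diff(xi), 0)
}
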