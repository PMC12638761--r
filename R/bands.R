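#' @include utils.R
NULL

#' Default EEG frequency bands
#'
#' The five canonical resting-state bands used throughout the package:
#' delta 2-3 Hz, theta 4-7 Hz, low alpha 8-10 Hz, high alpha 11-13 Hz,
#' beta 16-30 Hz. Alpha is split into sub-bands because associations with
#' cognitive ability concentrate in upper alpha. The delta lower edge is
#' configurable (some conventions use 1 Hz).
#'
#' @param deltaLow lower edge of the delta band in Hz (default 2).
#' @return A data.frame with columns \code{name}, \code{fLo}, \code{fHi} (Hz).
#' @examples
#' defaultBands()
#' @export
defaultBands <- function(deltaLow = 2) {
  stopifnot(deltaLow > 0, deltaLow <= 3)
  data.frame(
    name = c("delta", "theta", "low_alpha", "high_alpha", "beta"),
    fLo = c(deltaLow, 4, 8, 11, 16),
    fHi = c(3, 7, 10, 13, 30),
    stringsAsFactors = FALSE
  )
}

# validate a single band row against a sampling rate
.checkBand <- function(band, sampleRate) {
  stopifnot(is.data.frame(band) || is.list(band))
  fLo <- band$fLo
  fHi <- band$fHi
  if (fLo <= 0 || fLo > fHi) stop("band must satisfy 0 < fLo <= fHi", call. = FALSE)
  if (fHi >= sampleRate / 2) {
    stop("band '", band$name, "' extends to or above the Nyquist frequency",
         call. = FALSE)
  }
  invisible(TRUE)
}
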