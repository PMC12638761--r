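#' @include bands.R
NULL

#' Epoch set
#'
#' ROI time series cut into fixed-length (possibly overlapping) epochs, the
#' unit over which cross-spectra are averaged.
#'
#' @slot epochs list of ROI x samples matrices, all the same shape.
#' @slot sampleRate sampling rate in Hz.
#' @slot epochLength epoch length in seconds.
#' @slot overlap fractional overlap in [0, 1).
#' @slot roiLabels ROI labels.
#' @seealso [segmentEpochs()]
#' @export
setClass("EpochSet",
  representation(
    epochs = "list",
    sampleRate = "numeric",
    epochLength = "numeric",
    overlap = "numeric",
    roiLabels = "character"
  )
)

setValidity("EpochSet", function(object) {
  if (!length(object@epochs)) return("at least one epoch required")
  dims <- vapply(object@epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    return("all epochs must have the same shape")
  }
  if (object@overlap < 0 || object@overlap >= 1) return("overlap must be in [0, 1)")
  TRUE
})

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", length(object@epochs), "epochs of", object@epochLength,
      "s,", nrow(object@epochs[[1]]), "ROIs,", object@sampleRate, "Hz,",
      object@overlap * 100, "% overlap\n")
})

#' Segment a continuous recording into overlapping epochs
#'
#' Cuts an ROI-by-samples matrix into epochs of \code{epochLength} seconds
#' starting every \code{epochLength * (1 - overlap)} seconds; a trailing
#' partial epoch is discarded. The defaults (8 s, 50\% overlap) match the
#' segmentation used for resting-state coherence estimation.
#'
#' @param timeseries numeric matrix, rows = ROIs, columns = samples.
#' @param sampleRate sampling rate in Hz.
#' @param epochLength epoch length in seconds (default 8).
#' @param overlap fractional overlap in [0, 1) (default 0.5).
#' @param roiLabels optional ROI labels.
#' @return An [EpochSet-class].
#' @examples
#' x <- matrix(rnorm(2 * 200 * 120), 2)   # 2 ROIs, 120 s at 200 Hz
#' length(segmentEpochs(x, 200)@epochs)   # 29 epochs
#' @export
segmentEpochs <- function(timeseries, sampleRate, epochLength = 8,
                          overlap = 0.5, roiLabels = NULL) {
  timeseries <- as.matrix(timeseries)
  L <- as.integer(round(epochLength * sampleRate))
  if (ncol(timeseries) < L) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  step <- as.integer(round(L * (1 - overlap)))
  if (step < 1L) stop("overlap too close to 1 for this epoch length", call. = FALSE)
  starts <- seq.int(1L, ncol(timeseries) - L + 1L, by = step)
  epochs <- lapply(starts, function(s) timeseries[, s:(s + L - 1L), drop = FALSE])
  if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(nrow(timeseries)))
  new("EpochSet", epochs = epochs, sampleRate = sampleRate,
      epochLength = epochLength, overlap = overlap,
      roiLabels = as.character(roiLabels))
}

# Welch-style averaged auto/cross spectra at the requested FFT bins.
# Returns bins x nRoi x nRoi complex array of epoch-summed cross-spectra.
.crossSpectra <- function(epochSet, bins) {
  eps <- epochSet@epochs
  n <- nrow(eps[[1]])
  L <- ncol(eps[[1]])
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann taper
  nb <- length(bins)
  V <- array(0 + 0i, dim = c(nb, length(eps), n))
  for (e in seq_along(eps)) {
    x <- t(eps[[e]])                      # samples x ROIs
    x <- sweep(x, 2L, colMeans(x))        # per-epoch mean removal
    if (any(apply(x, 2L, function(col) all(col == 0)))) {
      stop("constant (zero-variance) channel in epoch ", e, call. = FALSE)
    }
    F <- mvfft(x * win)
    V[, e, ] <- F[bins, , drop = FALSE]
  }
  S <- array(0 + 0i, dim = c(nb, n, n))
  for (k in seq_len(nb)) {
    Vk <- matrix(V[k, , ], nrow = length(eps), ncol = n)
    S[k, , ] <- crossprod(Conj(Vk), Vk)   # sum over epochs of conj(v) v^T
  }
  S
}

# FFT bin indices whose center frequencies fall inside [fLo, fHi] (closed)
.bandBins <- function(band, L, sampleRate) {
  freqs <- (seq_len(L) - 1) * sampleRate / L
  half <- seq_len(floor(L / 2) + 1L)
  idx <- half[freqs[half] >= band$fLo & freqs[half] <= band$fHi]
  if (!length(idx)) {
    stop("band '", band$name, "' contains no FFT bin at this resolution",
         call. = FALSE)
  }
  idx
}

#' Band-limited spectral coherence network
#'
#' Estimates all-to-all magnitude spectral coherence from an epoch set:
#' each epoch is demeaned and Hann-tapered, auto- and cross-spectra are
#' averaged across epochs, per-bin coherence is
#' \eqn{|S_{xy}| / \sqrt{S_{xx} S_{yy}}}, and the network weight is the mean
#' coherence over the FFT bins whose center frequency falls inside the band
#' (closed interval).
#'
#' @param epochSet an [EpochSet-class] with at least two epochs.
#' @param band one-row data.frame (or list) with \code{name}, \code{fLo},
#'   \code{fHi}; e.g. one row of [defaultBands()].
#' @param squared use squared coherence instead of magnitude coherence.
#' @return A [CoherenceNetwork-class] with session tag \code{"raw"}.
#' @examples
#' ts <- matrix(rnorm(3 * 200 * 60), 3)
#' ep <- segmentEpochs(ts, 200)
#' net <- bandCoherence(ep, defaultBands()[2, ])  # theta
#' @export
bandCoherence <- function(epochSet, band, squared = FALSE) {
  stopifnot(is(epochSet, "EpochSet"))
  if (length(epochSet@epochs) < 2L) {
    stop("coherence from a single epoch is degenerate; need >= 2 epochs",
         call. = FALSE)
  }
  .checkBand(band, epochSet@sampleRate)
  L <- ncol(epochSet@epochs[[1]])
  bins <- .bandBins(band, L, epochSet@sampleRate)
  S <- .crossSpectra(epochSet, bins)
  w <- .cohFromSpectra(S, squared = squared)
  coherenceNetwork(w, band = band$name, session = "raw",
                   roiLabels = epochSet@roiLabels)
}

# mean over bins of |Sxy|/sqrt(Sxx Syy) given a bins x n x n spectra array
.cohFromSpectra <- function(S, squared = FALSE) {
  nb <- dim(S)[1]
  n <- dim(S)[2]
  acc <- matrix(0, n, n)
  for (k in seq_len(nb)) {
    Sk <- matrix(S[k, , ], n, n)
    auto <- Re(diag(Sk))
    if (any(auto <= 0)) stop("zero auto-spectrum in band", call. = FALSE)
    coh <- Mod(Sk) / sqrt(outer(auto, auto))
    if (squared) coh <- coh^2
    acc <- acc + coh
  }
  w <- acc / nb
  w <- pmin(w, 1)
  diag(w) <- 0
  (w + t(w)) / 2
}

#' Coherence networks for several bands in one pass
#'
#' Shares the FFT across bands, which matters when computing five bands for
#' hundreds of participants.
#'
#' @inheritParams bandCoherence
#' @param bands band table as returned by [defaultBands()].
#' @return Named list of [CoherenceNetwork-class] objects, one per band.
#' @export
coherenceNetworks <- function(epochSet, bands = defaultBands(), squared = FALSE) {
  stopifnot(is(epochSet, "EpochSet"))
  if (length(epochSet@epochs) < 2L) {
    stop("coherence from a single epoch is degenerate; need >= 2 epochs",
         call. = FALSE)
  }
  L <- ncol(epochSet@epochs[[1]])
  fs <- epochSet@sampleRate
  binsPerBand <- lapply(seq_len(nrow(bands)), function(i) {
    .checkBand(bands[i, ], fs)
    .bandBins(bands[i, ], L, fs)
  })
  allBins <- sort(unique(unlist(binsPerBand)))
  S <- .crossSpectra(epochSet, allBins)
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (i in seq_len(nrow(bands))) {
    sel <- match(binsPerBand[[i]], allBins)
    w <- .cohFromSpectra(S[sel, , , drop = FALSE], squared = squared)
    out[[i]] <- coherenceNetwork(w, band = bands$name[i], session = "raw",
                                 roiLabels = epochSet@roiLabels)
  }
  out
}

#' Average two recording sessions into one network
#'
#' Elementwise mean of the two session networks (the conditions of the two
#' eyes-closed recordings are identical, so their coherence matrices are
#' averaged before graph analysis). Band and ROI labels must match.
#'
#' @param net1,net2 [CoherenceNetwork-class] objects of the same band/shape.
#' @return A [CoherenceNetwork-class] with session tag \code{"mean"}.
#' @export
averageSessions <- function(net1, net2) {
  stopifnot(is(net1, "CoherenceNetwork"), is(net2, "CoherenceNetwork"))
  if (!identical(dim(net1@weights), dim(net2@weights))) {
    stop("session networks differ in shape", call. = FALSE)
  }
  if (!identical(net1@band, net2@band)) {
    stop("session networks differ in band", call. = FALSE)
  }
  if (!identical(net1@roiLabels, net2@roiLabels)) {
    stop("session networks differ in ROI labels", call. = FALSE)
  }
  coherenceNetwork((net1@weights + net2@weights) / 2, band = net1@band,
                   session = "mean", roiLabels = net1@roiLabels)
}
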