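#' @include AllClasses.R
NULL

#' Amplitude from percent signal change
#'
#' The task-induced amplitude a implied by a percent signal change p over a
#' baseline b: `a = p * b / 100`.
#'
#' @param psc Percent signal change p.
#' @param baseline Baseline intensity b.
#' @return Amplitude in intensity units.
#' @examples
#' amplitudeFromPsc(1, 100)  # 1
#' amplitudeFromPsc(5, 100)  # 5
#' @export
amplitudeFromPsc <- function(psc, baseline) {
  psc * baseline / 100
}

#' Decibel conversions for amplitude-type ratios
#'
#' `toDb()` converts a linear amplitude-type ratio to decibels,
#' `20 * log10(ratio)`; `fromDb()` inverts it.  0 dB means the signal
#' measure equals the noise level; negative dB values indicate less signal
#' than noise.
#'
#' @param ratio Positive linear ratio.
#' @param db Value in decibels.
#' @return The converted value.
#' @examples
#' toDb(10)      # 20
#' fromDb(0)     # 1
#' toDb(0.5)     # -6.02
#' @export
toDb <- function(ratio) {
  stopIfNot(all(ratio > 0), "dB is undefined for ratios <= 0")
  20 * log10(ratio)
}

#' @rdname toDb
#' @export
fromDb <- function(db) {
  10^(db / 20)
}

checkMetricArgs <- function(signal, noise) {
  stopIfNot(is(signal, "ActivationSignal"),
            "signal must be an ActivationSignal")
  stopIfNot(is(noise, "NoiseModel"), "noise must be a NoiseModel")
  validObject(noise)
  stopIfNot(noise@sd > 0, "sigma_N must be > 0")
}

#' The six SNR/CNR definitions
#'
#' For an activation time course S(t) with baseline b, amplitude a and
#' activation standard deviation sigma_S, and noise standard deviation
#' sigma_N:
#' \describe{
#'   \item{`snrMean()` (Definition 1)}{mean of S(t), baseline included,
#'     divided by sigma_N.  A temporal-SNR-type quantity, dominated by the
#'     baseline.}
#'   \item{`cnrAmplitude()` (Definition 2)}{a / sigma_N.}
#'   \item{Definition 3}{Definition 2 in decibels (see [toDb()]).}
#'   \item{`cnrSd()` (Definition 4)}{sigma_S / sigma_N, with sigma_S the
#'     population SD of the baseline-subtracted samples.}
#'   \item{`cnrVar()` (Definition 5)}{sigma_S^2 / sigma_N^2, exactly
#'     Definition 4 squared.}
#'   \item{Definition 6}{Definition 4 in decibels.}
#' }
#'
#' @param signal An [ActivationSignal-class].
#' @param noise A [NoiseModel-class].
#' @return A single numeric value.
#' @seealso [metricSet()] for all six at once.
#' @examples
#' sig <- activationSignal(designSpec("block"), psc = 1)
#' nm <- noiseModel(0.1)
#' cnrAmplitude(sig, nm)     # 10
#' round(cnrSd(sig, nm), 2)  # 4.45
#' @export
snrMean <- function(signal, noise) {
  checkMetricArgs(signal, noise)
  mean(signal@samples) / noise@sd
}

#' @rdname snrMean
#' @export
cnrAmplitude <- function(signal, noise) {
  checkMetricArgs(signal, noise)
  stopIfNot(is.finite(signal@amplitude), "signal amplitude is undefined")
  signal@amplitude / noise@sd
}

#' @rdname snrMean
#' @export
cnrSd <- function(signal, noise) {
  checkMetricArgs(signal, noise)
  stopIfNot(length(signal@samples) >= 2, "need at least 2 samples")
  sdPop(signal@samples - signal@baseline) / noise@sd
}

#' @rdname snrMean
#' @export
cnrVar <- function(signal, noise) {
  cnrSd(signal, noise)^2
}

#' All six SNR/CNR values for one configuration
#'
#' Computes Definitions 1-6 for a signal/noise pair.  The decibel entries
#' (Definitions 3 and 6) are `NA` when the corresponding linear ratio is 0
#' (log of zero), e.g. for a zero-percent-signal-change signal.
#'
#' @inheritParams snrMean
#' @return A [MetricSet-class].
#' @examples
#' sig <- activationSignal(designSpec("block"), psc = 1)
#' metricSet(sig, noiseModel(0.1))
#' @export
metricSet <- function(signal, noise) {
  checkMetricArgs(signal, noise)
  amp <- cnrAmplitude(signal, noise)
  sdr <- cnrSd(signal, noise)
  new("MetricSet",
      snrMean  = snrMean(signal, noise),
      cnrAmp   = amp,
      cnrAmpDb = if (amp > 0) toDb(amp) else NA_real_,
      cnrSd    = sdr,
      cnrVar   = sdr^2,
      cnrSdDb  = if (sdr > 0) toDb(sdr) else NA_real_)
}
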