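#' @include AllClasses.R
NULL

# Sample-grid boxcar for one condition given per-sample block indices.
blockBoxcar <- function(timeGrid, blockLength, which, period) {
  as.numeric((floor(timeGrid / blockLength) %% period) %in% which)
}

# Place k non-overlapping events of `len` samples uniformly at random among
# n samples.  Uses the gap construction (choose k of n - k*(len-1) virtual
# slots, then re-expand), which samples uniformly over all admissible
# non-overlapping configurations.
placeEvents <- function(n, k, len, seed) {
  free <- n - k * (len - 1L)
  if (free < k)
    stop(sprintf(
      "cannot place %d non-overlapping events of %d sample(s) in %d samples",
      k, len, n), call. = FALSE)
  starts <- withSeed(seed, sort(sample.int(free, k)))
  starts + (seq_len(k) - 1L) * (len - 1L)
}

#' Stimulus boxcar function(s) for a design
#'
#' Returns the 0/1 stimulus function sampled on the design's time grid.
#' Block designs alternate task and rest epochs of `blockLength` seconds,
#' task first.  Event-related designs place `nEvents` non-overlapping events
#' uniformly at random (seeded through `rngSeed`).  Contrast designs follow
#' the repeating pattern condition1, condition2, condition1, condition2,
#' rest (one rest epoch closing each A-B-A-B sequence) and return a
#' two-column matrix, one column per condition.
#'
#' @param spec A [DesignSpec-class].
#' @param oversample Integer >= 1; evaluate the boxcar on a grid `oversample`
#'   times finer than the sampling interval (used internally for fine-grid
#'   convolution).
#' @return A numeric 0/1 vector, or a two-column matrix for contrast
#'   designs.  The time grid starts at 0 and has spacing
#'   `samplingInterval / oversample`.
#' @examples
#' b <- boxcar(designSpec("block"))
#' sum(b)         # 50: half of the 100 samples are task
#' @export
boxcar <- function(spec, oversample = 1L) {
  stopIfNot(is(spec, "DesignSpec"), "spec must be a DesignSpec")
  validObject(spec)
  oversample <- as.integer(oversample)
  stopIfNot(oversample >= 1L, "oversample must be a positive integer")
  dt <- spec@samplingInterval / oversample
  tg <- seq(0, spec@totalDuration - dt, by = dt)
  switch(spec@designType,
    block = blockBoxcar(tg, spec@blockLength, 0L, 2L),
    contrast = {
      m <- cbind(cond1 = blockBoxcar(tg, spec@blockLength, c(0L, 2L), 5L),
                 cond2 = blockBoxcar(tg, spec@blockLength, c(1L, 3L), 5L))
      m
    },
    event_related = {
      n <- as.integer(round(spec@totalDuration / spec@samplingInterval))
      evLen <- if (is.na(spec@eventDuration)) 1L
               else as.integer(max(1, round(spec@eventDuration /
                                              spec@samplingInterval)))
      starts <- placeEvents(n, spec@nEvents, evLen,
                            if (is.na(spec@rngSeed)) NULL else spec@rngSeed)
      x <- numeric(length(tg))
      fineLen <- if (is.na(spec@eventDuration)) oversample
                 else as.integer(max(1, round(spec@eventDuration / dt)))
      for (s in starts) {
        i0 <- (s - 1L) * oversample + 1L
        x[i0:min(length(x), i0 + fineLen - 1L)] <- 1
      }
      x
    })
}

#' Canonical HRF kernel on a time grid
#'
#' Evaluates the difference-of-gamma-variates canonical HRF on a uniform
#' time grid starting at 0.  The kernel is 0 at t = 0, peaks near
#' `peakDelay` and has a small negative undershoot near `undershootDelay`
#' (none if `undershootRatio` is 0).
#'
#' @param timeGrid Uniformly spaced times in seconds, starting at 0.
#' @param params An [HRFParams-class] (default [hrfParams()]).
#' @return Kernel values, one per grid point.
#' @examples
#' h <- canonicalHrf(seq(0, 30, by = 0.1))
#' seq(0, 30, by = 0.1)[which.max(h)]   # ~5.4 s
#' @export
canonicalHrf <- function(timeGrid, params = hrfParams()) {
  stopIfNot(is(params, "HRFParams"), "params must be an HRFParams")
  validObject(params)
  stopIfNot(length(timeGrid) >= 2 && abs(timeGrid[1]) < 1e-12,
            "timeGrid must start at 0 and have at least 2 points")
  steps <- diff(timeGrid)
  stopIfNot(all(abs(steps - steps[1]) < 1e-8 * max(steps[1], 1)),
            "timeGrid must be uniformly spaced")
  gammaVariate <- function(t, d, b) {
    v <- numeric(length(t))
    pos <- t > 0
    v[pos] <- (t[pos] / d)^(d / b) * exp(-(t[pos] - d) / b)
    v
  }
  gammaVariate(timeGrid, params@peakDelay, params@peakDispersion) -
    params@undershootRatio *
      gammaVariate(timeGrid, params@undershootDelay,
                   params@undershootDispersion)
}

# Discrete causal convolution of a stimulus with a kernel, truncated to the
# stimulus length.
convolveStimulus <- function(stim, kernel) {
  stats::convolve(stim, rev(kernel), type = "open")[seq_along(stim)]
}

# Build one peak-anchored signal from a stimulus function: convolve, rescale
# so that max == amp, add the baseline.  `oversample` controls the
# convolution grid; the returned samples are on the TR grid.
anchoredSignal <- function(stim, amp, baselineValue, spec, hrf, oversample,
                           psc) {
  dt <- spec@samplingInterval / oversample
  tg <- seq(0, spec@totalDuration - dt, by = dt)
  s <- convolveStimulus(stim, canonicalHrf(tg, hrf))
  peak <- max(s)
  if (psc > 0 && peak <= 1e-12)
    stop("convolved response is all zero; cannot scale to the requested ",
         "percent signal change", call. = FALSE)
  s <- if (psc > 0) s / peak * amp else numeric(length(s))
  s <- s[seq(1, length(s), by = oversample)]
  new("ActivationSignal", samples = s + baselineValue,
      baseline = as.numeric(baselineValue), amplitude = as.numeric(amp),
      percentSignalChange = as.numeric(psc),
      samplingInterval = spec@samplingInterval)
}

#' Noise-free activation signal for a design
#'
#' Convolves the design's stimulus function with the canonical HRF and
#' anchors the highest peak of the response to `baseline * psc / 100` above
#' the baseline (peak-anchored scaling), so the amplitude a equals
#' p b / 100 for every design.  For the two-condition contrast design the
#' response of condition 1 is anchored to a and that of condition 2 to a/2
#' (condition 1's effect twice condition 2's), and a list of the two
#' [ActivationSignal-class] objects is returned.
#'
#' @param spec A [DesignSpec-class].
#' @param hrf An [HRFParams-class] (default [hrfParams()]).
#' @param baseline Baseline intensity b (default 100).
#' @param psc Percent signal change p (>= 0; default 1).
#' @param oversample Convolution-grid refinement factor (default 1:
#'   convolution on the sampling grid).
#' @return An [ActivationSignal-class], or for contrast designs a list
#'   `list(cond1 = , cond2 = )` of two.
#' @examples
#' sig <- activationSignal(designSpec("block"), psc = 1)
#' amplitude(sig)          # 1
#' round(signalSd(sig), 3) # 0.445
#' @export
activationSignal <- function(spec, hrf = hrfParams(), baseline = 100,
                             psc = 1, oversample = 1L) {
  stopIfNot(is(spec, "DesignSpec"), "spec must be a DesignSpec")
  stopIfNot(psc >= 0, "psc must be >= 0")
  validObject(spec)
  oversample <- as.integer(oversample)
  amp <- amplitudeFromPsc(psc, baseline)
  stim <- boxcar(spec, oversample = oversample)
  if (spec@designType == "contrast") {
    list(cond1 = anchoredSignal(stim[, 1L], amp, baseline, spec, hrf,
                                oversample, psc),
         cond2 = anchoredSignal(stim[, 2L], amp / 2, baseline, spec, hrf,
                                oversample, psc))
  } else {
    anchoredSignal(stim, amp, baseline, spec, hrf, oversample, psc)
  }
}

#' Contrast signal: difference of two condition signals
#'
#' Subtracts the baseline-removed activation courses of two conditions.
#' The baselines cancel, so the stored baseline is 0; the amplitude of the
#' difference course is defined as its maximum minus its minimum.
#'
#' @param s1,s2 Two [ActivationSignal-class] objects of equal length and
#'   sampling interval (e.g. the two elements returned by
#'   [activationSignal()] for a contrast design).
#' @return An [ActivationSignal-class] with baseline 0.
#' @examples
#' sigs <- activationSignal(designSpec("contrast"), psc = 1)
#' cs <- contrastSignal(sigs$cond1, sigs$cond2)
#' amplitude(cs)   # max - min of the difference
#' @export
contrastSignal <- function(s1, s2) {
  stopIfNot(is(s1, "ActivationSignal") && is(s2, "ActivationSignal"),
            "s1 and s2 must be ActivationSignal objects")
  stopIfNot(length(s1@samples) == length(s2@samples),
            "condition signals differ in length")
  stopIfNot(abs(s1@samplingInterval - s2@samplingInterval) < 1e-9,
            "condition signals differ in sampling interval")
  d <- (s1@samples - s1@baseline) - (s2@samples - s2@baseline)
  new("ActivationSignal", samples = d, baseline = 0,
      amplitude = max(d) - min(d),
      percentSignalChange = s1@percentSignalChange,
      samplingInterval = s1@samplingInterval)
}
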