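#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# DesignSpec
# ---------------------------------------------------------------------------

#' Experimental design specification
#'
#' Declarative description of one of the three design templates: a block
#' design (alternating task and rest epochs, task first), an event-related
#' design (brief events scattered over the run), or a two-condition contrast
#' design (blocks of condition 1 and condition 2 alternating, with a rest
#' block closing each A-B-A-B sequence).
#'
#' @slot designType `"block"`, `"event_related"` or `"contrast"`.
#' @slot totalDuration Run length in seconds.
#' @slot samplingInterval Time between samples (the repetition time TR), in
#'   seconds.  `totalDuration / samplingInterval` must be a whole number of
#'   samples.
#' @slot blockLength Epoch length in seconds (block and contrast designs).
#' @slot nEvents Number of events (event-related design).
#' @slot eventDuration Event duration in seconds (event-related design);
#'   defaults to one sampling interval, i.e. an impulse on the sampling grid.
#' @slot rngSeed Integer seed for random event placement, or `NA` for an
#'   unseeded draw.
#'
#' @seealso [designSpec()], [boxcar()], [activationSignal()]
#' @export
setClass("DesignSpec",
  representation(
    designType       = "character",
    totalDuration    = "numeric",
    samplingInterval = "numeric",
    blockLength      = "numeric",
    nEvents          = "integer",
    eventDuration    = "numeric",
    rngSeed          = "integer"
  )
)

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (!object@designType %in% c("block", "event_related", "contrast"))
    msg <- c(msg, "designType must be 'block', 'event_related' or 'contrast'")
  if (object@totalDuration <= 0) msg <- c(msg, "totalDuration must be > 0")
  if (object@samplingInterval <= 0)
    msg <- c(msg, "samplingInterval must be > 0")
  n <- object@totalDuration / object@samplingInterval
  if (abs(n - round(n)) > 1e-8 || round(n) < 1)
    msg <- c(msg, "totalDuration/samplingInterval must be a positive integer")
  if (object@designType %in% c("block", "contrast") &&
      (is.na(object@blockLength) || object@blockLength <= 0))
    msg <- c(msg, "blockLength must be > 0 for block/contrast designs")
  if (object@designType == "event_related" &&
      (is.na(object@nEvents) || object@nEvents < 1L))
    msg <- c(msg, "nEvents must be >= 1 for event-related designs")
  if (length(msg)) msg else TRUE
})

#' Construct a design specification
#'
#' @param designType One of `"block"`, `"event_related"`, `"contrast"`.
#' @param totalDuration Run length in seconds (default 200, the template
#'   length used throughout the reference tables).
#' @param samplingInterval Sampling interval / TR in seconds (default 2).
#' @param blockLength Epoch length in seconds for block and contrast designs
#'   (default 20).
#' @param nEvents Number of events for event-related designs (default 25).
#' @param eventDuration Event duration in seconds; default `NA` means one
#'   sample on the sampling grid.
#' @param rngSeed Integer seed controlling random event placement; `NA`
#'   draws from the current RNG state.
#'
#' @return A [DesignSpec-class] object.
#' @examples
#' designSpec("block")
#' designSpec("event_related", nEvents = 25, rngSeed = 1)
#' @export
designSpec <- function(designType = c("block", "event_related", "contrast"),
                       totalDuration = 200, samplingInterval = 2,
                       blockLength = 20, nEvents = 25,
                       eventDuration = NA_real_, rngSeed = NA_integer_) {
  designType <- match.arg(designType)
  new("DesignSpec",
      designType = designType,
      totalDuration = as.numeric(totalDuration),
      samplingInterval = as.numeric(samplingInterval),
      blockLength = as.numeric(blockLength),
      nEvents = as.integer(nEvents),
      eventDuration = as.numeric(eventDuration),
      rngSeed = as.integer(rngSeed))
}

# ---------------------------------------------------------------------------
# HRFParams
# ---------------------------------------------------------------------------

#' Canonical haemodynamic response function parameters
#'
#' Parameters of the difference-of-gamma-variates kernel used as the
#' canonical HRF.  The kernel is
#' \deqn{h(t) = (t/d_1)^{d_1/b_1} e^{-(t-d_1)/b_1}
#'            - c\,(t/d_2)^{d_2/b_2} e^{-(t-d_2)/b_2}}
#' where \eqn{d_1} is the time-to-peak, \eqn{d_2} the time to the
#' post-stimulus undershoot, \eqn{b_1,b_2} the dispersions and \eqn{c} the
#' undershoot ratio.  The defaults (peak 5.4 s, undershoot 10.8 s,
#' dispersions 0.9, ratio 0.35) are the Glover parametrisation of the
#' canonical HRF that reproduces the package's reference tables; see the
#' methods vignette for the choice rationale.
#'
#' @slot peakDelay Time-to-peak \eqn{d_1} in seconds.
#' @slot undershootDelay Time to undershoot \eqn{d_2} in seconds.
#' @slot peakDispersion Dispersion \eqn{b_1} of the peak gamma variate.
#' @slot undershootDispersion Dispersion \eqn{b_2} of the undershoot.
#' @slot undershootRatio Relative undershoot amplitude \eqn{c \ge 0}.
#'
#' @seealso [hrfParams()], [canonicalHrf()]
#' @export
setClass("HRFParams",
  representation(
    peakDelay            = "numeric",
    undershootDelay      = "numeric",
    peakDispersion       = "numeric",
    undershootDispersion = "numeric",
    undershootRatio      = "numeric"
  )
)

setValidity("HRFParams", function(object) {
  msg <- character()
  if (object@peakDelay <= 0) msg <- c(msg, "peakDelay must be > 0")
  if (object@undershootDelay <= 0) msg <- c(msg, "undershootDelay must be > 0")
  if (object@peakDispersion <= 0) msg <- c(msg, "peakDispersion must be > 0")
  if (object@undershootDispersion <= 0)
    msg <- c(msg, "undershootDispersion must be > 0")
  if (object@undershootRatio < 0) msg <- c(msg, "undershootRatio must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct canonical HRF parameters
#'
#' @param peakDelay Time-to-peak in seconds (default 5.4).
#' @param undershootDelay Time to the undershoot in seconds (default 10.8).
#' @param peakDispersion,undershootDispersion Gamma-variate dispersions in
#'   seconds (default 0.9 each).
#' @param undershootRatio Undershoot amplitude relative to the peak term
#'   (default 0.35); 0 gives a single non-negative gamma variate.
#' @return An [HRFParams-class] object.
#' @examples
#' hrfParams()
#' hrfParams(undershootRatio = 0)
#' @export
hrfParams <- function(peakDelay = 5.4, undershootDelay = 10.8,
                      peakDispersion = 0.9, undershootDispersion = 0.9,
                      undershootRatio = 0.35) {
  new("HRFParams",
      peakDelay = peakDelay, undershootDelay = undershootDelay,
      peakDispersion = peakDispersion,
      undershootDispersion = undershootDispersion,
      undershootRatio = undershootRatio)
}

# ---------------------------------------------------------------------------
# ActivationSignal
# ---------------------------------------------------------------------------

#' Sampled activation time course
#'
#' A noise-free activation time course S(t) together with its baseline b,
#' amplitude a and nominal percent signal change p.  For peak-anchored
#' signals (all single-condition designs) the amplitude is the difference
#' between the highest peak and the baseline, a = max S(t) - b = p b / 100.
#' For contrast signals produced by [contrastSignal()] the stored baseline is
#' 0 and the amplitude is max - min of the difference course.
#'
#' @slot samples Signal values in image-intensity units, sampled every
#'   `samplingInterval` seconds.
#' @slot baseline Baseline intensity b.
#' @slot amplitude Amplitude a in intensity units.
#' @slot percentSignalChange Nominal percent signal change p.
#' @slot samplingInterval Sampling interval in seconds.
#'
#' @seealso [activationSignal()], [contrastSignal()], [signalSd()]
#' @export
setClass("ActivationSignal",
  representation(
    samples             = "numeric",
    baseline            = "numeric",
    amplitude           = "numeric",
    percentSignalChange = "numeric",
    samplingInterval    = "numeric"
  )
)

setValidity("ActivationSignal", function(object) {
  msg <- character()
  if (!length(object@samples)) msg <- c(msg, "samples must be non-empty")
  if (object@amplitude < -1e-12) msg <- c(msg, "amplitude must be >= 0")
  if (object@samplingInterval <= 0)
    msg <- c(msg, "samplingInterval must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# NoiseModel
# ---------------------------------------------------------------------------

#' Noise level description
#'
#' The noise entering every SNR/CNR denominator, treated as a single
#' composite residual series: either a known standard deviation sigma_N, or
#' an observed noise series from which sigma_N is estimated (mean removed,
#' population denominator).
#'
#' @slot sd Noise standard deviation sigma_N (> 0).
#' @slot noiseSamples Optional observed noise series.
#' @seealso [noiseModel()]
#' @export
setClass("NoiseModel",
  representation(sd = "numeric", noiseSamples = "numeric"))

setValidity("NoiseModel", function(object) {
  if (!length(object@sd) || is.na(object@sd) || object@sd <= 0)
    "sd must be a positive number" else TRUE
})

#' Construct a noise model
#'
#' @param sd Noise standard deviation sigma_N.  Ignored when `noiseSamples`
#'   is supplied.
#' @param noiseSamples Optional noise series; sigma_N is then its
#'   mean-removed population standard deviation.
#' @return A [NoiseModel-class] object.
#' @examples
#' noiseModel(0.1)
#' noiseModel(noiseSamples = rnorm(200, sd = 2))
#' @export
noiseModel <- function(sd = NULL, noiseSamples = NULL) {
  if (!is.null(noiseSamples)) {
    stopIfNot(length(noiseSamples) >= 2,
              "noiseSamples needs at least 2 values")
    sd <- sdPop(noiseSamples)
    return(new("NoiseModel", sd = sd, noiseSamples = as.numeric(noiseSamples)))
  }
  stopIfNot(!is.null(sd), "either sd or noiseSamples must be given")
  new("NoiseModel", sd = as.numeric(sd), noiseSamples = numeric())
}

# ---------------------------------------------------------------------------
# MetricSet
# ---------------------------------------------------------------------------

#' The six SNR/CNR values for one signal/noise configuration
#'
#' @slot snrMean Definition 1: temporal mean of the series (baseline
#'   included) over sigma_N.
#' @slot cnrAmp Definition 2: amplitude a over sigma_N.
#' @slot cnrAmpDb Definition 3: Definition 2 in decibels,
#'   20 log10(cnrAmp); `NA` when cnrAmp is 0.
#' @slot cnrSd Definition 4: activation SD sigma_S over sigma_N.
#' @slot cnrVar Definition 5: variance ratio, exactly cnrSd squared.
#' @slot cnrSdDb Definition 6: Definition 4 in decibels; `NA` when cnrSd
#'   is 0.
#' @seealso [metricSet()]
#' @export
setClass("MetricSet",
  representation(
    snrMean  = "numeric",
    cnrAmp   = "numeric",
    cnrAmpDb = "numeric",
    cnrSd    = "numeric",
    cnrVar   = "numeric",
    cnrSdDb  = "numeric"
  )
)

# ---------------------------------------------------------------------------
# SimConfig / PowerResult
# ---------------------------------------------------------------------------

#' Monte-Carlo simulation configuration
#'
#' @slot nReps Number of simulated time series per grid cell.
#' @slot alpha Test level of the GLM t-test.
#' @slot sidedness `"two"` or `"one"`.
#' @slot noiseSdGrid Noise standard deviations of the reference grid.
#' @slot pscGrid Percent-signal-change levels of the reference grid.
#' @slot rngSeed Base seed; each grid cell uses a derived sub-stream.
#' @seealso [simConfig()], [empiricalPower()], [referenceTable()]
#' @export
setClass("SimConfig",
  representation(
    nReps       = "integer",
    alpha       = "numeric",
    sidedness   = "character",
    noiseSdGrid = "numeric",
    pscGrid     = "numeric",
    rngSeed     = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!object@sidedness %in% c("two", "one"))
    msg <- c(msg, "sidedness must be 'two' or 'one'")
  if (!length(object@noiseSdGrid) || any(object@noiseSdGrid <= 0))
    msg <- c(msg, "noiseSdGrid must be non-empty and positive")
  if (!length(object@pscGrid) || any(object@pscGrid < 0))
    msg <- c(msg, "pscGrid must be non-empty and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults reproduce the reference-grid conditions: 1000 replicates per
#' cell, a two-sided t-test at alpha = 0.05, noise SD 0.1-10 and percent
#' signal change 1/2/5.
#'
#' @param nReps Replicates per cell (default 1000).
#' @param alpha Test level (default 0.05).
#' @param sidedness `"two"` (default) or `"one"`.
#' @param noiseSdGrid Noise SDs (default `c(0.1, 0.2, 0.5, 1, 2, 5, 10)`).
#' @param pscGrid Percent signal change levels (default `c(1, 2, 5)`).
#' @param rngSeed Base seed (default 1).
#' @return A [SimConfig-class] object.
#' @examples
#' simConfig(nReps = 200, rngSeed = 7)
#' @export
simConfig <- function(nReps = 1000, alpha = 0.05,
                      sidedness = c("two", "one"),
                      noiseSdGrid = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                      pscGrid = c(1, 2, 5), rngSeed = 1L) {
  sidedness <- match.arg(sidedness)
  new("SimConfig", nReps = as.integer(nReps), alpha = alpha,
      sidedness = sidedness, noiseSdGrid = as.numeric(noiseSdGrid),
      pscGrid = as.numeric(pscGrid), rngSeed = as.integer(rngSeed))
}

#' Empirical detection power with Monte-Carlo metadata
#'
#' @slot power Rejection proportion, `nRejections / nReps`.
#' @slot nReps,nRejections Replicate and rejection counts.
#' @slot alpha Test level used.
#' @slot designType Design template simulated.
#' @slot psc,noiseSd Cell coordinates.
#' @slot seed Seed of the cell's RNG sub-stream.
#' @seealso [empiricalPower()]
#' @export
setClass("PowerResult",
  representation(
    power       = "numeric",
    nReps       = "integer",
    nRejections = "integer",
    alpha       = "numeric",
    designType  = "character",
    psc         = "numeric",
    noiseSd     = "numeric",
    seed        = "integer"
  )
)

setValidity("PowerResult", function(object) {
  msg <- character()
  if (object@power < 0 || object@power > 1)
    msg <- c(msg, "power must lie in [0, 1]")
  if (object@nRejections != round(object@power * object@nReps))
    msg <- c(msg, "power must equal nRejections/nReps")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# VolumeSeries / RegionCnrSummary
# ---------------------------------------------------------------------------

#' 4D image time series
#'
#' A 4D intensity array with time as the last axis, its sampling interval,
#' and an optional 3D region-of-interest mask of matching spatial shape.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot samplingInterval Time between volumes, in seconds.
#' @slot mask 3D logical array, or `NULL` when absent.
#' @seealso [volumeSeries()], [synthVolume()], [voxelwiseTsnr()]
#' @export
setClassUnion("OptionalMask", c("array", "NULL"))

#' @export
setClass("VolumeSeries",
  representation(
    data             = "array",
    samplingInterval = "numeric",
    mask             = "OptionalMask"
  )
)

setValidity("VolumeSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  else if (d[4] < 2L) msg <- c(msg, "at least 2 time points are required")
  if (object@samplingInterval <= 0)
    msg <- c(msg, "samplingInterval must be > 0")
  if (!is.null(object@mask)) {
    md <- dim(object@mask)
    if (!is.logical(object@mask) || is.null(md) || length(md) != 3L ||
        !all(md == d[1:3]))
      msg <- c(msg, "mask must be a 3D logical array matching data")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a 4D volume series
#'
#' @param data A 4D array (x, y, z, t) or a path to a 4D NIfTI file.
#' @param samplingInterval Time between volumes in seconds; when reading
#'   from NIfTI, defaults to the file's TR.
#' @param mask A 3D logical/0-1 array, or a path to a 3D NIfTI mask.
#' @return A [VolumeSeries-class] object.
#' @export
volumeSeries <- function(data, samplingInterval = NULL, mask = NULL) {
  if (is.character(data)) {
    img <- RNifti::readNifti(data)
    if (is.null(samplingInterval))
      samplingInterval <- RNifti::pixdim(img)[4]
    data <- unclass(as.array(img))
  }
  if (is.character(mask)) mask <- unclass(as.array(RNifti::readNifti(mask)))
  if (!is.null(mask)) {
    mdim <- dim(mask)
    mask <- as.logical(mask != 0)
    dim(mask) <- mdim
  }
  if (is.null(samplingInterval) || !is.finite(samplingInterval) ||
      samplingInterval <= 0)
    samplingInterval <- 1
  storage.mode(data) <- "double"
  new("VolumeSeries", data = data,
      samplingInterval = as.numeric(samplingInterval), mask = mask)
}

#' Region CNR summary
#'
#' Mean, minimum and maximum of a per-voxel CNR metric over the voxels
#' inside and outside a region-of-interest mask.
#'
#' @slot metric `"cnr_amp"` (Definition 2) or `"cnr_sd"` (Definition 4).
#' @slot inMask,outMask Named numeric vectors `c(mean, min, max, n)`.
#' @seealso [regionCnr()]
#' @export
setClass("RegionCnrSummary",
  representation(metric = "character", inMask = "numeric",
                 outMask = "numeric"))

setValidity("RegionCnrSummary", function(object) {
  ok <- function(v) length(v) == 4L &&
    v[["min"]] - 1e-9 <= v[["mean"]] && v[["mean"]] <= v[["max"]] + 1e-9
  if (!ok(object@inMask) || !ok(object@outMask))
    "each region summary needs min <= mean <= max" else TRUE
})
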