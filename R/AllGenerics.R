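#' @include AllClasses.R
NULL

#' Accessors for activation signals and volume series
#'
#' `samples()`, `baseline()`, `amplitude()`, `percentSignalChange()` and
#' `samplingInterval()` extract the corresponding slots of an
#' [ActivationSignal-class]; `signalSd()` returns the activation standard
#' deviation sigma_S, the population SD of the baseline-subtracted samples
#' (invariant to the baseline value).  `noiseSd()` returns sigma_N of a
#' [NoiseModel-class].  `designType()` works on [DesignSpec-class] and
#' [PowerResult-class] objects.
#'
#' @param object The object to access.
#' @return A numeric vector or scalar.
#' @name accessors
#' @examples
#' sig <- activationSignal(designSpec("block"), psc = 1)
#' amplitude(sig)   # 1
#' signalSd(sig)    # ~0.445
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("baseline", function(object) standardGeneric("baseline"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setGeneric("percentSignalChange",
           function(object) standardGeneric("percentSignalChange"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval",
           function(object) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("signalSd", function(object) standardGeneric("signalSd"))
#' @rdname accessors
#' @export
setGeneric("noiseSd", function(object) standardGeneric("noiseSd"))
#' @rdname accessors
#' @export
setGeneric("designType", function(object) standardGeneric("designType"))

#' @rdname accessors
#' @export
setMethod("samples", "ActivationSignal", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("baseline", "ActivationSignal", function(object) object@baseline)
#' @rdname accessors
#' @export
setMethod("amplitude", "ActivationSignal", function(object) object@amplitude)
#' @rdname accessors
#' @export
setMethod("percentSignalChange", "ActivationSignal",
          function(object) object@percentSignalChange)
#' @rdname accessors
#' @export
setMethod("samplingInterval", "ActivationSignal",
          function(object) object@samplingInterval)
#' @rdname accessors
#' @export
setMethod("samplingInterval", "VolumeSeries",
          function(object) object@samplingInterval)
#' @rdname accessors
#' @export
setMethod("signalSd", "ActivationSignal",
          function(object) sdPop(object@samples - object@baseline))
#' @rdname accessors
#' @export
setMethod("noiseSd", "NoiseModel", function(object) object@sd)
#' @rdname accessors
#' @export
setMethod("designType", "DesignSpec", function(object) object@designType)
#' @rdname accessors
#' @export
setMethod("designType", "PowerResult", function(object) object@designType)

#' @describeIn accessors Rejection proportion of a power simulation.
#' @export
setGeneric("power", function(object) standardGeneric("power"))
#' @rdname accessors
#' @export
setMethod("power", "PowerResult", function(object) object@power)

# --------------------------------------------------------------------------
# show methods
# --------------------------------------------------------------------------

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf("DesignSpec: %s, %g s at TR %g s (%d samples)\n",
              object@designType, object@totalDuration,
              object@samplingInterval,
              as.integer(object@totalDuration / object@samplingInterval)))
  if (object@designType %in% c("block", "contrast"))
    cat(sprintf("  blocks of %g s\n", object@blockLength))
  if (object@designType == "event_related")
    cat(sprintf("  %d events%s%s\n", object@nEvents,
                if (is.na(object@eventDuration)) " (impulses)"
                else sprintf(" of %g s", object@eventDuration),
                if (is.na(object@rngSeed)) ""
                else sprintf(", seed %d", object@rngSeed)))
  invisible(NULL)
})

setMethod("show", "HRFParams", function(object) {
  cat(sprintf(paste0("Canonical HRF: peak %g s (disp %g), undershoot %g s",
                     " (disp %g), ratio %g\n"),
              object@peakDelay, object@peakDispersion,
              object@undershootDelay, object@undershootDispersion,
              object@undershootRatio))
  invisible(NULL)
})

setMethod("show", "ActivationSignal", function(object) {
  cat(sprintf(paste0("ActivationSignal: %d samples at TR %g s, baseline %g,",
                     " amplitude %.4g (psc %g%%), sigma_S %.4g\n"),
              length(object@samples), object@samplingInterval,
              object@baseline, object@amplitude,
              object@percentSignalChange, signalSd(object)))
  invisible(NULL)
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: sigma_N = %.4g%s\n", object@sd,
              if (length(object@noiseSamples))
                sprintf(" (estimated from %d samples)",
                        length(object@noiseSamples)) else ""))
  invisible(NULL)
})

setMethod("show", "MetricSet", function(object) {
  df <- as.data.frame(object)
  cat("MetricSet (Definitions 1-6):\n")
  print(df, row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d reps, alpha %g (%s-sided), %d x %d grid,",
                     " seed %d\n"),
              object@nReps, object@alpha, object@sidedness,
              length(object@pscGrid), length(object@noiseSdGrid),
              object@rngSeed))
  invisible(NULL)
})

setMethod("show", "PowerResult", function(object) {
  cat(sprintf(paste0("PowerResult: %s design, psc %g%%, sigma_N %g -> ",
                     "power %.3f (%d/%d at alpha %g)\n"),
              object@designType, object@psc, object@noiseSd, object@power,
              object@nRejections, object@nReps, object@alpha))
  invisible(NULL)
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %d x %d x %d voxels, %d time points, TR %g s\n",
              d[1], d[2], d[3], d[4], object@samplingInterval))
  if (!is.null(object@mask))
    cat(sprintf("  mask: %d in-mask voxels\n", sum(object@mask)))
  invisible(NULL)
})

setMethod("show", "RegionCnrSummary", function(object) {
  cat(sprintf("RegionCnrSummary (%s):\n", object@metric))
  m <- rbind(`in mask` = object@inMask, `out of mask` = object@outMask)
  print(round(m, 4))
  invisible(NULL)
})

#' Tabular form of a metric set
#'
#' One row with columns `def1` to `def6` in the reference-table column
#' order (mean SNR, amplitude CNR, amplitude CNR in dB, SD CNR, variance
#' CNR, SD CNR in dB).
#'
#' @param x A [MetricSet-class].
#' @param row.names,optional,... Ignored; present for the generic.
#' @return A one-row `data.frame`.
#' @method as.data.frame MetricSet
#' @export
as.data.frame.MetricSet <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(def1 = x@snrMean, def2 = x@cnrAmp, def3 = x@cnrAmpDb,
             def4 = x@cnrSd, def5 = x@cnrVar, def6 = x@cnrSdDb)
}
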