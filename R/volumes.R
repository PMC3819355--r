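#' @include AllClasses.R designs.R metrics.R
NULL

# Flatten a 4D array to voxels x time.
voxelMatrix <- function(vol) {
  d <- dim(vol@data)
  matrix(vol@data, prod(d[1:3]), d[4])
}

maskOrStop <- function(vol, mask) {
  if (is.null(mask)) {
    stopIfNot(!is.null(vol@mask), "no mask supplied and none in the volume")
    mask <- vol@mask
  }
  if (!is.logical(mask)) {
    md <- dim(mask); mask <- as.logical(mask != 0); dim(mask) <- md
  }
  stopIfNot(all(dim(mask) == dim(vol@data)[1:3]),
            "mask shape must equal the spatial shape of the volume")
  stopIfNot(any(mask) && any(!mask),
            "mask must contain at least one voxel in each region")
  mask
}

#' Voxelwise temporal SNR map
#'
#' For every voxel, the temporal mean of its time series divided by its
#' temporal standard deviation (population denominator), computed on the
#' raw series without detrending.  Voxels with zero temporal SD (e.g.
#' padded background) map to `NA` rather than infinity.
#'
#' @param vol A [VolumeSeries-class].
#' @return A 3D array of tSNR values.
#' @examples
#' vol <- synthVolume(noiseSd = 8, seed = 1)
#' mean(voxelwiseTsnr(vol))   # ~ 100/8
#' @export
voxelwiseTsnr <- function(vol) {
  stopIfNot(is(vol, "VolumeSeries"), "vol must be a VolumeSeries")
  validObject(vol)
  V <- voxelMatrix(vol)
  m <- rowMeans(V)
  s <- sqrt(pmax(rowMeans(V^2) - m^2, 0))
  out <- m / s
  out[s <= 1e-12] <- NA_real_
  array(out, dim(vol@data)[1:3])
}

#' ROI-average activation signals
#'
#' Averages the voxel time series inside and outside the mask to obtain one
#' activation course per region (the empirical average haemodynamic
#' response).  Each course is returned as an [ActivationSignal-class] whose
#' baseline is its temporal mean and whose amplitude is its maximum minus
#' that baseline.
#'
#' @param vol A [VolumeSeries-class].
#' @param mask 3D logical array; defaults to the volume's own mask.
#' @return `list(inMask = , outMask = )` of two [ActivationSignal-class]
#'   objects.
#' @export
roiActivationEstimate <- function(vol, mask = NULL) {
  stopIfNot(is(vol, "VolumeSeries"), "vol must be a VolumeSeries")
  validObject(vol)
  mask <- maskOrStop(vol, mask)
  V <- voxelMatrix(vol)
  mk <- as.vector(mask)
  asSignal <- function(course) {
    b <- mean(course)
    new("ActivationSignal", samples = course, baseline = b,
        amplitude = max(course) - b,
        percentSignalChange = if (abs(b) > 1e-12)
          100 * (max(course) - b) / b else NA_real_,
        samplingInterval = vol@samplingInterval)
  }
  list(inMask = asSignal(colMeans(V[mk, , drop = FALSE])),
       outMask = asSignal(colMeans(V[!mk, , drop = FALSE])))
}

#' Isolate per-voxel noise by subtracting the region-average signal
#'
#' Subtracts a region's average activation course from each voxel time
#' series in that region, removing the activation contribution so that the
#' residual series estimate the per-voxel noise.
#'
#' @param vol A [VolumeSeries-class].
#' @param activation The region's average course (an
#'   [ActivationSignal-class], e.g. from [roiActivationEstimate()]).
#' @param mask 3D logical array selecting the region's voxels; defaults to
#'   the volume's own mask.
#' @return A voxels-by-time matrix of residual (noise) series, one row per
#'   region voxel.
#' @export
roiNoiseIsolate <- function(vol, activation, mask = NULL) {
  stopIfNot(is(vol, "VolumeSeries"), "vol must be a VolumeSeries")
  stopIfNot(is(activation, "ActivationSignal"),
            "activation must be an ActivationSignal")
  if (is.null(mask)) mask <- vol@mask
  stopIfNot(!is.null(mask), "no mask supplied and none in the volume")
  if (!is.logical(mask)) {
    md <- dim(mask); mask <- as.logical(mask != 0); dim(mask) <- md
  }
  d <- dim(vol@data)
  stopIfNot(length(activation@samples) == d[4],
            "activation length must equal the number of time points")
  V <- voxelMatrix(vol)[as.vector(mask), , drop = FALSE]
  sweep(V, 2L, activation@samples)
}

#' Region CNR summary from a 4D volume
#'
#' Implements the ROI procedure for real data: the average activation
#' course of each region (in-mask, out-of-mask) provides the signal
#' parameters -- amplitude a for Definition 2 (`metric = "cnr_amp"`) or
#' activation SD sigma_S for Definition 4 (`metric = "cnr_sd"`) -- and each
#' voxel's own sigma_N is the SD of its residual series after the region
#' course is subtracted.  Per-voxel CNR values are summarised as mean, min
#' and max per region.
#'
#' @param vol A [VolumeSeries-class].
#' @param mask 3D logical array; defaults to the volume's own mask.
#' @param metric `"cnr_amp"` (Definition 2) or `"cnr_sd"` (Definition 4).
#' @return A [RegionCnrSummary-class].
#' @examples
#' vol <- synthVolume(design = designSpec("block"), psc = 1, noiseSd = 1,
#'                    nTime = 200, seed = 1)
#' regionCnr(vol, metric = "cnr_sd")
#' @export
regionCnr <- function(vol, mask = NULL, metric = c("cnr_amp", "cnr_sd")) {
  metric <- match.arg(metric)
  stopIfNot(is(vol, "VolumeSeries"), "vol must be a VolumeSeries")
  validObject(vol)
  mask <- maskOrStop(vol, mask)
  est <- roiActivationEstimate(vol, mask)
  summarise <- function(region, sig) {
    res <- roiNoiseIsolate(vol, sig, region)
    sn <- sqrt(pmax(rowMeans(res^2) - rowMeans(res)^2, 0))
    num <- if (metric == "cnr_amp") sig@amplitude
           else sdPop(sig@samples - sig@baseline)
    cnr <- num / sn
    cnr <- cnr[is.finite(cnr)]
    stopIfNot(length(cnr) > 0, "no finite CNR values in region")
    c(mean = mean(cnr), min = min(cnr), max = max(cnr), n = length(cnr))
  }
  new("RegionCnrSummary", metric = metric,
      inMask = summarise(mask, est$inMask),
      outMask = summarise(!mask, est$outMask))
}

#' Synthetic 4D volume with planted activation
#'
#' Generates a fully seeded 4D fixture emulating task-based or
#' resting-state acquisitions: constant baseline everywhere, white Gaussian
#' noise in every voxel, and -- in task mode (a `design` is given) -- a
#' planted activation course (the design convolved with the canonical HRF,
#' peak-anchored to `psc`) added to every in-mask voxel.
#'
#' @param shape Spatial dimensions, length-3 integer (default
#'   `c(10, 10, 10)`).
#' @param design A [DesignSpec-class] for task mode, or `NULL` (default)
#'   for resting mode.  `nTime` and `samplingInterval` are derived from the
#'   design when given.
#' @param psc Planted percent signal change (task mode; default 1).
#' @param noiseSd Noise SD in intensity units (default 1).
#' @param mask 3D logical array marking the activated region; default is a
#'   centred box spanning half of each dimension.
#' @param seed Integer seed; the same seed reproduces the volume exactly.
#' @param baseline Baseline intensity (default 100).
#' @param nTime Number of time points in resting mode (default 100).
#' @param samplingInterval TR in seconds in resting mode (default 2).
#' @param hrf An [HRFParams-class].
#' @return A [VolumeSeries-class] carrying the mask.
#' @examples
#' rest <- synthVolume(noiseSd = 8, seed = 1)
#' task <- synthVolume(design = designSpec("block"), psc = 2, seed = 1)
#' @export
synthVolume <- function(shape = c(10, 10, 10), design = NULL, psc = 1,
                        noiseSd = 1, mask = NULL, seed = NULL,
                        baseline = 100, nTime = 100, samplingInterval = 2,
                        hrf = hrfParams()) {
  stopIfNot(length(shape) == 3 && all(shape >= 1),
            "shape must be three positive integers")
  shape <- as.integer(shape)
  course <- NULL
  if (!is.null(design)) {
    stopIfNot(is(design, "DesignSpec"), "design must be a DesignSpec")
    sig <- activationSignal(design, hrf, baseline, psc)
    if (design@designType == "contrast")
      stop("synthVolume plants single-condition designs (block or ",
           "event_related)", call. = FALSE)
    course <- sig@samples - sig@baseline
    nTime <- length(course)
    samplingInterval <- design@samplingInterval
  }
  if (is.null(mask)) {
    mask <- array(FALSE, shape)
    idx <- lapply(shape, function(k) {
      half <- max(1L, floor(k / 4L))
      lo <- max(1L, floor(k / 2L) - half + 1L)
      lo:min(k, lo + 2L * half - 1L)
    })
    mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  } else {
    md <- dim(mask)
    stopIfNot(!is.null(md) && all(md == shape),
              "mask shape must equal `shape`")
    mask <- array(as.logical(mask != 0), shape)
  }
  nVox <- prod(shape)
  V <- withSeed(seed,
                matrix(rnorm(nVox * nTime, sd = noiseSd), nVox, nTime))
  V <- V + baseline
  if (!is.null(course))
    V[as.vector(mask), ] <- V[as.vector(mask), , drop = FALSE] +
      rep(course, each = sum(mask))
  new("VolumeSeries", data = array(V, c(shape, nTime)),
      samplingInterval = as.numeric(samplingInterval), mask = mask)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around \pkg{RNifti} used by the command-line interface:
#' `readVolume()` loads a 4D image (and optional 3D mask) into a
#' [VolumeSeries-class]; `writeVolume()` writes a 3D/4D array or the data
#' of a `VolumeSeries` to a NIfTI-1 file.
#'
#' @param imagePath Path to a 4D NIfTI image.
#' @param maskPath Optional path to a 3D NIfTI mask.
#' @param samplingInterval Override for the TR in seconds (defaults to the
#'   file header).
#' @return `readVolume()` returns a [VolumeSeries-class]; `writeVolume()`
#'   returns `path` invisibly.
#' @export
readVolume <- function(imagePath, maskPath = NULL, samplingInterval = NULL) {
  volumeSeries(imagePath, samplingInterval = samplingInterval,
               mask = maskPath)
}

#' @rdname readVolume
#' @param x A [VolumeSeries-class] or a numeric array.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @export
writeVolume <- function(x, path) {
  arr <- if (is(x, "VolumeSeries")) x@data else x
  tr <- if (is(x, "VolumeSeries")) x@samplingInterval else 1
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  if (length(dim(arr)) == 4L) {
    pd[4] <- tr
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}
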