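#' @include AllClasses.R designs.R metrics.R
NULL

# Gaussian noise series: white, or stationary AR(1) with marginal SD `sd`.
genNoise <- function(n, sd, type = c("white", "ar1"), rho = 0.2) {
  type <- match.arg(type)
  z <- rnorm(n)
  if (type == "white" || rho == 0) return(sd * z)
  e <- numeric(n)
  e[1] <- sd * z[1]
  fac <- sd * sqrt(1 - rho^2)
  for (i in 2:n) e[i] <- rho * e[i - 1] + fac * z[i]
  e
}

#' Add noise to an activation signal
#'
#' Adds zero-mean Gaussian noise of standard deviation `sd` to a time
#' course.  `type = "white"` (the default, and the model behind all
#' reference results) draws i.i.d. samples; `type = "ar1"` draws a
#' stationary first-order autoregressive series with the same marginal SD,
#' provided for studying the effect of temporal autocorrelation on
#' detection power.
#'
#' @param signal An [ActivationSignal-class] or a numeric vector.
#' @param sd Noise standard deviation (>= 0; 0 returns the input).
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param type `"white"` or `"ar1"`.
#' @param rho AR(1) coefficient when `type = "ar1"` (default 0.2).
#' @return A numeric vector of noisy samples.
#' @examples
#' sig <- activationSignal(designSpec("block"), psc = 1)
#' y <- addNoise(sig, sd = 2, seed = 1)
#' @export
addNoise <- function(signal, sd, seed = NULL, type = c("white", "ar1"),
                     rho = 0.2) {
  x <- if (is(signal, "ActivationSignal")) signal@samples
       else as.numeric(signal)
  stopIfNot(sd >= 0, "sd must be >= 0")
  if (sd == 0) return(x)
  type <- match.arg(type)
  x + withSeed(seed, genNoise(length(x), sd, type, rho))
}

#' Ordinary-least-squares GLM fit for one time series
#'
#' Fits `series ~ intercept + regressors` by OLS and returns coefficient
#' estimates, standard errors, t statistics (residual degrees of freedom
#' n - rank) and two-sided p-values.
#'
#' @param series Numeric response vector.
#' @param regressors Numeric vector or matrix of regressors (the intercept
#'   column is added internally).
#' @return A list of class `"fmriGlmFit"` with elements `coefficients`,
#'   `se`, `tstat`, `pvalue`, `df`, `sigma2`, `XtXinv` and `X`.
#' @examples
#' sig <- activationSignal(designSpec("block"), psc = 1)
#' fit <- fitGlm(samples(sig), samples(sig) - baseline(sig))
#' fit$coefficients   # intercept 100, slope 1
#' @export
fitGlm <- function(series, regressors) {
  X <- cbind(intercept = 1, regressors)
  if (is.null(colnames(X)) || any(colnames(X)[-1] == ""))
    colnames(X) <- c("intercept", paste0("x", seq_len(ncol(X) - 1L)))
  y <- as.numeric(series)
  stopIfNot(nrow(X) == length(y), "series and regressors differ in length")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- length(y) - qx$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- beta / se
  structure(list(coefficients = beta, se = se, tstat = tstat,
                 pvalue = 2 * pt(-abs(tstat), df), df = df,
                 sigma2 = sigma2, XtXinv = XtXinv, X = X),
            class = "fmriGlmFit")
}

#' Detection decision from a GLM fit
#'
#' Block and event-related designs test the task coefficient (the first
#' regressor after the intercept); contrast designs test the difference of
#' the two condition coefficients (contrast vector `c(0, 1, -1)`).
#'
#' @param fit An `"fmriGlmFit"` from [fitGlm()].
#' @param designType `"block"`, `"event_related"` or `"contrast"`.
#' @param alpha Test level (default 0.05).
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A list with `reject` (logical), `statistic` (the t value) and
#'   `pvalue`.
#' @export
testDetection <- function(fit, designType = c("block", "event_related",
                                              "contrast"),
                          alpha = 0.05, sidedness = c("two", "one")) {
  designType <- match.arg(designType)
  sidedness <- match.arg(sidedness)
  stopIfNot(inherits(fit, "fmriGlmFit"), "fit must come from fitGlm()")
  p <- length(fit$coefficients)
  cc <- if (designType == "contrast") {
    stopIfNot(p >= 3, "contrast designs need two condition regressors")
    c(0, 1, -1, rep(0, p - 3L))
  } else c(0, 1, rep(0, p - 2L))
  eff <- sum(cc * fit$coefficients)
  se <- sqrt(fit$sigma2 * drop(t(cc) %*% fit$XtXinv %*% cc))
  tval <- eff / se
  pval <- if (sidedness == "two") 2 * pt(-abs(tval), fit$df)
          else pt(tval, fit$df, lower.tail = FALSE)
  list(reject = pval < alpha, statistic = tval, pvalue = pval)
}

# Design matrix, mean course and test contrast for a design at a given
# percent signal change.  The regressors are the same convolved,
# peak-anchored responses used for generation (correctly specified model),
# anchored to unit amplitude so they remain defined at psc = 0 (null
# calibration); the generated mean course scales them by the amplitude.
designGlmParts <- function(spec, hrf, baselineValue, psc, oversample = 1L) {
  stopIfNot(baselineValue > 0, "baseline must be > 0")
  amp <- amplitudeFromPsc(psc, baselineValue)
  unit <- activationSignal(spec, hrf, baselineValue,
                           psc = 100 / baselineValue,
                           oversample = oversample)
  if (spec@designType == "contrast") {
    x1 <- unit$cond1@samples - unit$cond1@baseline        # amplitude 1
    x2 <- (unit$cond2@samples - unit$cond2@baseline) * 2  # amplitude 1
    X <- cbind(1, x1, x2)
    list(X = X, mu = baselineValue + amp * x1 + (amp / 2) * x2,
         cc = c(0, 1, -1), effect = amp - amp / 2)
  } else {
    x <- unit@samples - unit@baseline                     # amplitude 1
    X <- cbind(1, x)
    list(X = X, mu = baselineValue + amp * x, cc = c(0, 1), effect = amp)
  }
}

# Vectorised rejection count for a fixed design matrix: nReps series of
# mu + white noise, OLS t-test of the contrast cc at alpha/sidedness.
countRejectionsFixed <- function(X, cc, mu, sigma, nReps, alpha, sidedness,
                                 noiseType = "white", rho = 0.2,
                                 chunk = 5000L) {
  n <- nrow(X)
  df <- n - ncol(X)
  XtXinv <- solve(crossprod(X))
  A <- XtXinv %*% t(X)
  cvar <- drop(t(cc) %*% XtXinv %*% cc)
  tcrit <- if (sidedness == "two") qt(1 - alpha / 2, df) else qt(1 - alpha, df)
  rej <- 0L
  left <- nReps
  while (left > 0L) {
    m <- min(chunk, left)
    E <- if (noiseType == "white") matrix(rnorm(n * m), n, m) * sigma
         else vapply(seq_len(m), function(i) genNoise(n, sigma, "ar1", rho),
                     numeric(n))
    Y <- mu + E
    B <- A %*% Y
    R <- Y - X %*% B
    s2 <- colSums(R^2) / df
    tv <- drop(crossprod(cc, B)) / sqrt(s2 * cvar)
    rej <- rej + if (sidedness == "two") sum(abs(tv) > tcrit)
                 else sum(tv > tcrit)
    left <- left - m
  }
  as.integer(rej)
}

#' Empirical GLM detection power
#'
#' Simulates `nReps` independent noisy realisations of a design's
#' activation signal, fits the (correctly specified) OLS GLM to each and
#' reports the fraction of replicates in which the task effect is detected.
#' For event-related designs the event placement is redrawn independently
#' for every replicate by default, so the result estimates power averaged
#' over random event timings; set `redrawEvents = FALSE` to keep the
#' placement of `design@rngSeed` fixed across replicates.
#'
#' @param design A [DesignSpec-class].
#' @param psc Percent signal change.
#' @param noiseSd Noise standard deviation sigma_N.
#' @param config A [SimConfig-class]; `nReps`, `alpha`, `sidedness` and
#'   `rngSeed` are used.
#' @param hrf An [HRFParams-class].
#' @param baseline Baseline intensity (default 100).
#' @param redrawEvents Redraw event-related event placements per replicate
#'   (default `TRUE`).
#' @param noiseType `"white"` (default) or `"ar1"`.
#' @param rho AR(1) coefficient for `noiseType = "ar1"`.
#' @return A [PowerResult-class].
#' @examples
#' pr <- empiricalPower(designSpec("block"), psc = 1, noiseSd = 2,
#'                      config = simConfig(nReps = 200, rngSeed = 1))
#' power(pr)
#' @export
empiricalPower <- function(design, psc, noiseSd, config = simConfig(),
                           hrf = hrfParams(), baseline = 100,
                           redrawEvents = TRUE,
                           noiseType = c("white", "ar1"), rho = 0.2) {
  stopIfNot(is(design, "DesignSpec"), "design must be a DesignSpec")
  stopIfNot(is(config, "SimConfig"), "config must be a SimConfig")
  validObject(config)
  stopIfNot(noiseSd > 0, "noiseSd must be > 0")
  noiseType <- match.arg(noiseType)
  seed <- config@rngSeed
  n <- as.integer(round(design@totalDuration / design@samplingInterval))
  redraw <- redrawEvents && design@designType == "event_related"
  rej <- withSeed(seed, {
    if (!redraw) {
      parts <- designGlmParts(design, hrf, baseline, psc)
      countRejectionsFixed(parts$X, parts$cc, parts$mu, noiseSd,
                           config@nReps, config@alpha, config@sidedness,
                           noiseType, rho)
    } else {
      # one fresh placement per replicate; simple-regression closed form
      tg <- seq(0, design@totalDuration - design@samplingInterval,
                by = design@samplingInterval)
      kern <- canonicalHrf(tg, hrf)
      amp <- amplitudeFromPsc(psc, baseline)
      evLen <- if (is.na(design@eventDuration)) 1L
               else as.integer(max(1, round(design@eventDuration /
                                              design@samplingInterval)))
      tcrit <- if (config@sidedness == "two")
                 qt(1 - config@alpha / 2, n - 2L)
               else qt(1 - config@alpha, n - 2L)
      count <- 0L
      for (r in seq_len(config@nReps)) {
        starts <- placeEvents(n, design@nEvents, evLen, NULL)
        stim <- numeric(n)
        for (s in starts) stim[s:min(n, s + evLen - 1L)] <- 1
        x <- convolveStimulus(stim, kern)
        x <- x / max(x)
        y <- baseline + amp * x + genNoise(n, noiseSd, noiseType, rho)
        xc <- x - mean(x)
        sxx <- sum(xc^2)
        b1 <- sum(xc * y) / sxx
        res <- y - mean(y) - b1 * xc
        tval <- b1 / sqrt(sum(res^2) / (n - 2L) / sxx)
        hit <- if (config@sidedness == "two") abs(tval) > tcrit
               else tval > tcrit
        count <- count + hit
      }
      as.integer(count)
    }
  })
  new("PowerResult", power = rej / config@nReps, nReps = config@nReps,
      nRejections = rej, alpha = config@alpha,
      designType = design@designType, psc = as.numeric(psc),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Closed-form power for the OLS contrast (verification oracle)
#'
#' Noncentral-t power for the same design matrix, contrast and test that
#' [empiricalPower()] simulates under white noise: the noncentrality is
#' `effect / (sigma_N * sqrt(c' (X'X)^-1 c))`.  For event-related designs
#' with random event timing the power is averaged over `nDesigns` seeded
#' placements.  Intended as an independent check of the Monte-Carlo path.
#'
#' @inheritParams empiricalPower
#' @param alpha Test level (default 0.05).
#' @param sidedness `"two"` (default) or `"one"`.
#' @param nDesigns Placements to average over for event-related designs
#'   (default 50).
#' @param seed Seed for the placement draws (default 1).
#' @return Power as a proportion.
#' @examples
#' analyticPowerOracle(designSpec("block"), psc = 1, noiseSd = 2)
#' @export
analyticPowerOracle <- function(design, psc, noiseSd, alpha = 0.05,
                                sidedness = c("two", "one"),
                                hrf = hrfParams(), baseline = 100,
                                nDesigns = 50, seed = 1L) {
  sidedness <- match.arg(sidedness)
  stopIfNot(noiseSd > 0, "noiseSd must be > 0")
  onePower <- function(spec) {
    parts <- designGlmParts(spec, hrf, baseline, psc)
    df <- nrow(parts$X) - ncol(parts$X)
    cvar <- drop(t(parts$cc) %*% solve(crossprod(parts$X)) %*% parts$cc)
    ncp <- parts$effect / (noiseSd * sqrt(cvar))
    if (sidedness == "two") {
      tc <- qt(1 - alpha / 2, df)
      pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
    } else {
      tc <- qt(1 - alpha, df)
      pt(tc, df, ncp, lower.tail = FALSE)
    }
  }
  if (design@designType == "event_related" && is.na(design@rngSeed)) {
    # random event timing: average over seeded placements
    mean(vapply(seq_len(nDesigns), function(i) {
      spec <- design
      spec@rngSeed <- subSeed(seed, i)
      onePower(spec)
    }, numeric(1)))
  } else {
    onePower(design)
  }
}

#' Reference table: the six definitions and detection power over a grid
#'
#' For every percent-signal-change and noise-SD combination of `config`,
#' computes the six SNR/CNR definitions of the design's noise-free
#' activation signal and the empirical GLM detection power.  For
#' event-related designs the metric columns use a single seeded event
#' placement (the design's `rngSeed`, falling back to the config seed) --
#' so within the table sigma_S scales exactly with psc -- while the power
#' column redraws placements per replicate.  For contrast designs the
#' metric columns describe the contrast signal (difference of the two
#' condition courses, amplitude max - min; see [contrastSignal()]).
#'
#' @param design A [DesignSpec-class].
#' @param config A [SimConfig-class].
#' @param hrf An [HRFParams-class].
#' @param baseline Baseline intensity (default 100).
#' @param redrawEvents Passed to [empiricalPower()].
#' @return A `data.frame` with columns `psc`, `sigma_N`, `def1`..`def6`,
#'   `power`, and attributes `designType`, `alpha`, `nReps`, `rngSeed`.
#' @examples
#' tab <- referenceTable(designSpec("block"),
#'                       simConfig(nReps = 100, rngSeed = 1))
#' head(tab, 3)
#' @export
referenceTable <- function(design, config = simConfig(), hrf = hrfParams(),
                           baseline = 100, redrawEvents = TRUE) {
  stopIfNot(is(design, "DesignSpec"), "design must be a DesignSpec")
  stopIfNot(is(config, "SimConfig"), "config must be a SimConfig")
  validObject(design); validObject(config)
  stopIfNot(length(config@pscGrid) > 0 && length(config@noiseSdGrid) > 0,
            "empty simulation grid")
  metricSpec <- design
  if (design@designType == "event_related" && is.na(design@rngSeed))
    metricSpec@rngSeed <- config@rngSeed
  rows <- vector("list", length(config@pscGrid) * length(config@noiseSdGrid))
  i <- 0L
  for (psc in config@pscGrid) {
    sig <- activationSignal(metricSpec, hrf, baseline, psc)
    if (design@designType == "contrast") {
      cs <- contrastSignal(sig$cond1, sig$cond2)
      # the difference course has baseline 0, but the recorded series sits
      # on the common baseline; Definition 1 (mean/noise) is computed on
      # the re-seated course, Definitions 2-6 are unaffected by the shift
      sig <- new("ActivationSignal", samples = cs@samples + baseline,
                 baseline = baseline, amplitude = cs@amplitude,
                 percentSignalChange = cs@percentSignalChange,
                 samplingInterval = cs@samplingInterval)
    }
    for (sn in config@noiseSdGrid) {
      i <- i + 1L
      ms <- metricSet(sig, noiseModel(sn))
      cellCfg <- config
      cellCfg@rngSeed <- subSeed(config@rngSeed, i)
      pr <- empiricalPower(design, psc, sn, cellCfg, hrf, baseline,
                           redrawEvents = redrawEvents)
      rows[[i]] <- cbind(data.frame(psc = psc, sigma_N = sn),
                         as.data.frame(ms),
                         data.frame(power = pr@power))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "designType") <- design@designType
  attr(out, "alpha") <- config@alpha
  attr(out, "nReps") <- config@nReps
  attr(out, "rngSeed") <- config@rngSeed
  out
}
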