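## Allele-frequency autocorrelation, exponential decay fit (relaxation time
## T = 1/d) and classification of the dynamics as stable (fast exponential
## relaxation) versus neutral (slower-than-exponential, non-relaxing drift).

## biased sample ACF (single full-series mean, 1/n normalization) via FFT;
## the 1/n factors cancel in C(tau)/C(0)
.acfFFT <- function(x, maxLag) {
  n <- length(x)
  x <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, numeric(npad - n)))
  s <- Re(fft(Mod(f)^2, inverse = TRUE))
  s[seq_len(maxLag + 1L)] / s[1L]
}

## direct-sum reference implementation (oracle for the FFT path)
.acfDirect <- function(x, maxLag) {
  n <- length(x)
  x <- x - mean(x)
  c0 <- sum(x * x)
  vapply(0:maxLag, function(tau)
    sum(x[seq_len(n - tau)] * x[seq_len(n - tau) + tau]) / c0, numeric(1))
}

#' Autocorrelation function of a time series
#'
#' Mean-removed sample autocorrelation with the biased (1/n) normalization
#' and a single full-series mean, so \eqn{C(0) = 1} and \eqn{|C(\tau)| \le 1}
#' for every lag. Computed via FFT (an O(n log n) direct-sum equivalent).
#' The white-noise significance band \eqn{\pm 1.96/\sqrt{n}} is attached: a
#' value inside the band is statistically indistinguishable from zero.
#'
#' @param series numeric vector, e.g. \code{\link{alleleFreqSeries}} of a
#'   trajectory; its variance must be positive (a fixed population yields a
#'   constant series and an error).
#' @param maxLag largest lag; must satisfy \code{length(series) >= maxLag + 2}
#'   (at least twice that is recommended).
#' @return An \code{\link{AcfResult}}.
#' @examples
#' set.seed(1)
#' ar1 <- as.numeric(stats::filter(rnorm(5000), 0.9, "recursive"))
#' autocorrelation(ar1, 50)
#' @aliases AcfResult-class
#' @export
autocorrelation <- function(series, maxLag) {
  series <- as.numeric(series)
  n <- length(series)
  maxLag <- as.integer(maxLag)
  if (maxLag < 1)
    stop("'maxLag' must be at least 1")
  if (n < maxLag + 2)
    stop(sprintf("series of length %d is too short for maxLag = %d (need >= maxLag + 2)",
                 n, maxLag))
  if (var(series) == 0)
    stop("series has zero variance (constant allele frequency, e.g. after fixation); autocorrelation is undefined")
  vals <- .acfFFT(series, maxLag)
  vals <- pmin(pmax(vals, -1), 1)      # clip 1-ulp numerical overshoot
  vals[1L] <- 1
  new("AcfResult", lags = as.numeric(0:maxLag), values = vals,
      seriesLength = as.numeric(n), noiseBand = 1.96 / sqrt(n))
}

#' @describeIn AcfResult autocorrelation values \eqn{C(\tau)} for lags
#'   \eqn{0..maxLag}.
#' @export
setMethod("acfValues", "AcfResult", function(x) x@values)

#' @describeIn AcfResult half-width \eqn{1.96/\sqrt{n}} of the white-noise
#'   significance band.
#' @export
setMethod("noiseBand", "AcfResult", function(x) x@noiseBand)

#' @describeIn AcfResult smallest positive lag at which \eqn{C(\tau)} falls
#'   below the noise band (\code{NA} if it never does within \code{maxLag});
#'   the model's operational notion of "correlation has decayed to zero".
#' @export
setMethod("crossingLag", "AcfResult", function(x) {
  w <- which(x@values[-1L] < x@noiseBand)
  if (length(w)) x@lags[w[1L] + 1L] else NA_real_
})

#' Exponential decay fit of an autocorrelation function
#'
#' Fits \eqn{C(\tau) \approx e^{-d\tau}} by least squares of
#' \eqn{\log C(\tau)} against \eqn{\tau} over lags 1 up to (but not
#' including) the first crossing of \eqn{e^{-2}} or of the noise band,
#' whichever comes first -- the window over which an exponential decay is
#' both above the noise and not yet flattened into it. The relaxation time
#' is \eqn{T = 1/d}.
#'
#' @param acf an \code{\link{AcfResult}}.
#' @param minPoints smallest number of positive ACF values required in the
#'   fit window (default 5); fewer raises an error, which
#'   \code{\link{classifyDynamics}} interprets as a non-relaxing series.
#' @return List with \code{rate} (\eqn{d}), \code{relaxationTime}
#'   (\eqn{T = 1/d}, \code{Inf} when the fitted rate is not positive),
#'   \code{fitWindow} (range of lags used) and \code{goodness} (\eqn{R^2} of
#'   the log-linear fit).
#' @examples
#' a <- new("AcfResult", lags = as.numeric(0:100),
#'          values = exp(-0.05 * (0:100)), seriesLength = 1e4,
#'          noiseBand = 1.96 / sqrt(1e4))
#' fitExponentialDecay(a) # rate 0.05, relaxation time 20
#' @export
fitExponentialDecay <- function(acf, minPoints = 5) {
  v <- acf@values[-1L]
  lag <- acf@lags[-1L]
  below <- which(v < pmax(exp(-2), acf@noiseBand))
  end <- if (length(below)) below[1L] - 1L else length(v)
  use <- seq_len(end)
  use <- use[v[use] > 0]
  if (length(use) < minPoints)
    stop(sprintf("only %d positive autocorrelation values before the first crossing; series is noise-dominated or non-relaxing",
                 length(use)))
  y <- log(v[use])
  t <- lag[use]
  fit <- lm(y ~ t)
  rate <- -unname(coef(fit)[2L])
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(rate = rate,
       relaxationTime = if (rate > 0) 1 / rate else Inf,
       fitWindow = range(t),
       goodness = r2)
}

#' Classify dynamics as stable or neutral from the ACF
#'
#' A trajectory is labelled \code{stable_exponential} when its
#' autocorrelation both (i) crosses the white-noise band within a small
#' fraction of the series length (default 5\%) -- correlations decay within
#' a short transient -- and (ii) is well fitted by an exponential over the
#' decaying window (\eqn{R^2 \ge} \code{minGoodness}, default 0.9, with a
#' positive rate). Otherwise it is \code{neutral_subexponential}: the
#' correlation persists over a macroscopic fraction of the history, the
#' signature of neutral drift, for which equilibrium is never attained in
#' practice.
#'
#' @param acf an \code{\link{AcfResult}}.
#' @param fit optional result of \code{\link{fitExponentialDecay}}; when
#'   omitted it is attempted internally, a failure counting as evidence of
#'   non-relaxation.
#' A decay can also be too fast to resolve: when the ACF crosses the noise
#' band within the first \code{minPoints + 1} lags there are not enough
#' points to fit an exponential at all -- relaxation is complete within a
#' couple of generations (in this model the stationary regime of
#' fixed-probability mating regenerates the genotype composition afresh each
#' generation, so the decay is essentially instantaneous at large N). Such
#' series are labelled \code{stable_exponential} with
#' \code{evidence$resolved = FALSE} and the crossing lag as an upper bound on
#' the relaxation time.
#'
#' @param maxCrossFraction largest crossing lag, as a fraction of the series
#'   length, compatible with the stable label (default 0.05).
#' @param minGoodness smallest exponential-fit \eqn{R^2} compatible with the
#'   stable label (default 0.9).
#' @param minPoints passed to \code{\link{fitExponentialDecay}}; also the
#'   crossing lag below which an unfittable decay counts as unresolvably
#'   fast rather than non-exponential.
#' @return List with \code{label} (\code{"stable_exponential"} or
#'   \code{"neutral_subexponential"}), \code{crossingLag} (\code{NA} when
#'   the band is never crossed) and \code{evidence} (fitted rate, goodness,
#'   relaxation time, the crossing fraction, and \code{resolved} = was the
#'   decay slow enough to fit).
#' @export
classifyDynamics <- function(acf, fit = NULL, maxCrossFraction = 0.05,
                             minGoodness = 0.9, minPoints = 5) {
  if (is.null(fit))
    fit <- tryCatch(fitExponentialDecay(acf, minPoints),
                    error = function(e) NULL)
  cl <- crossingLag(acf)
  withinFraction <- !is.na(cl) && cl <= maxCrossFraction * acf@seriesLength
  fastUnresolved <- is.null(fit) && !is.na(cl) && cl <= minPoints + 1
  stable <- withinFraction &&
    (fastUnresolved ||
       (!is.null(fit) && fit$goodness >= minGoodness && fit$rate > 0))
  list(label = if (stable) "stable_exponential" else "neutral_subexponential",
       crossingLag = cl,
       evidence = list(rate = if (is.null(fit)) NA_real_ else fit$rate,
                       goodness = if (is.null(fit)) NA_real_ else fit$goodness,
                       relaxationTime = if (is.null(fit)) NA_real_
                                        else fit$relaxationTime,
                       crossingFraction = if (is.na(cl)) NA_real_
                                          else cl / acf@seriesLength,
                       resolved = !fastUnresolved))
}
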