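## Ensemble analysis of the Hardy-Weinberg chi-square: distribution of the
## statistic over L replicate populations observed at a fixed generation,
## tail probabilities (false-negative / false-positive rates of the
## chi-square criterion), exponential tail fits, two-sample comparison.

.chi2ValuesOf <- function(x) {
  if (is(x, "EnsembleResult")) x@chi2Values else as.numeric(x)
}

#' Chi-square values over an ensemble of replicate populations
#'
#' Evolves \code{replicates} independent populations from identical initial
#' conditions (one RNG substream per replicate, all derived from the master
#' seed in \code{config@base@seed}) and measures the Hardy-Weinberg
#' chi-square once per replicate at generation \code{observeAt} -- on the
#' whole population, or on one random subsample of \code{sampleSize}
#' individuals if configured. Bottlenecks scheduled before \code{observeAt}
#' are honoured.
#'
#' @param config an \code{\link{EnsembleConfig}}.
#' @param ... unused.
#' @return An \code{\link{EnsembleResult}} holding the \eqn{L} chi-square
#'   values; every value obeys \eqn{0 \le \chi^2 \le N}.
#' @seealso \code{\link{estimateTailProbability}},
#'   \code{\link{fitExponentialTail}}, \code{\link{compareDistributions}}
#' @aliases EnsembleResult-class
#' @export
setMethod("runChiSquareEnsemble", "EnsembleConfig", function(config, ...) {
  base <- config@base
  L <- config@replicates
  if (!is.na(base@seed)) set.seed(base@seed)
  repSeeds <- sample.int(2147483646L, L)
  bnGen <- vapply(base@bottlenecks, function(b) b@generation, numeric(1))
  bnProfiles <- lapply(base@bottlenecks, function(b) b@resetProfile@counts)
  k0 <- base@initial@counts
  vals <- numeric(L)
  for (i in seq_len(L)) {
    set.seed(repSeeds[i])
    k <- tryCatch(
      .evolve(k0, config@observeAt, base, bnGen, bnProfiles),
      error = function(e) stop(sprintf("replicate %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    if (!is.na(config@sampleSize)) k <- .mvhyper(k, config@sampleSize)
    vals[i] <- .chisq(k)
  }
  new("EnsembleResult", chi2Values = vals, config = config, seed = base@seed)
})

#' @describeIn EnsembleResult the \eqn{L} chi-square values.
#' @export
setMethod("chi2Values", "EnsembleResult", function(x) x@chi2Values)

#' Empirical tail probability of an ensemble
#'
#' Fraction of ensemble chi-square values strictly above (or strictly below)
#' a threshold, with the binomial Monte-Carlo standard error
#' \eqn{\sqrt{p(1-p)/L}}. With the 0.05 critical value as threshold this
#' estimates the false-negative rate of the Hardy-Weinberg test on
#' random-mating ensembles (direction \code{"above"}) and the false-positive
#' rate on non-random-mating ensembles (direction \code{"below"}).
#'
#' @param result an \code{\link{EnsembleResult}} or numeric vector of
#'   chi-square values.
#' @param threshold chi-square threshold; defaults to
#'   \code{chiSquareCriticalValue(0.05, 1)}.
#' @param direction \code{"above"} or \code{"below"} (strict inequality).
#' @return List with \code{threshold}, \code{direction}, \code{probability},
#'   \code{stdError} and \code{count}.
#' @export
estimateTailProbability <- function(result,
                                    threshold = chiSquareCriticalValue(0.05, 1),
                                    direction = c("above", "below")) {
  direction <- match.arg(direction)
  v <- .chi2ValuesOf(result)
  L <- length(v)
  if (L == 0)
    stop("empty ensemble")
  count <- if (direction == "above") sum(v > threshold) else sum(v < threshold)
  p <- count / L
  list(threshold = threshold, direction = direction, probability = p,
       stdError = sqrt(p * (1 - p) / L), count = count)
}

#' Exponential fit of the chi-square distribution tail
#'
#' Histograms the ensemble values above \code{xMin} with Freedman-Diaconis
#' equal-width bins, drops sparsely populated bins (whose log counts are
#' biased upward by Poisson noise; see \code{minCount}) and fits a least
#' squares line to log counts versus bin midpoints, all bins weighted
#' equally. The fitted rate is minus the slope; the goodness is the
#' \eqn{R^2} of the log-linear fit.
#'
#' @param result an \code{\link{EnsembleResult}} or numeric vector.
#' @param xMin lower cutoff; only values strictly above it enter the fit
#'   (default 0.4, below which the finite-population chi-square distribution
#'   visibly departs from an exponential).
#' @param minCount smallest bin count retained in the fit (default 5).
#' @return List with \code{xMin}, \code{rate}, \code{goodness},
#'   \code{bins} (data frame of retained midpoints and counts) and
#'   \code{nTail} (number of values above the cutoff).
#' @examples
#' set.seed(1)
#' fitExponentialTail(rexp(1e4))$rate # close to 1
#' @export
fitExponentialTail <- function(result, xMin = 0.4, minCount = 5) {
  v <- .chi2ValuesOf(result)
  tail <- v[v > xMin]
  nTail <- length(tail)
  if (nTail < 50)
    stop(sprintf("only %d values above xMin = %g; need at least 50 for a tail fit",
                 nTail, xMin))
  width <- 2 * IQR(tail) * nTail^(-1 / 3)
  if (width <= 0)
    width <- diff(range(tail)) / max(10, ceiling(sqrt(nTail)))
  breaks <- seq(xMin, max(tail) + width, by = width)
  h <- graphics::hist(tail, breaks = breaks, plot = FALSE)
  keep <- h$counts >= minCount
  if (sum(keep) < 3)
    stop("fewer than 3 adequately populated bins in the tail; cannot fit")
  mids <- h$mids[keep]
  counts <- h$counts[keep]
  y <- log(counts)
  fit <- lm(y ~ mids)
  list(xMin = xMin, rate = -unname(coef(fit)[2L]),
       goodness = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
       bins = data.frame(mid = mids, count = counts), nTail = nTail)
}

#' Two-sample comparison of ensemble distributions
#'
#' Kolmogorov-Smirnov statistic between two empirical chi-square
#' distributions, with matched deciles, to judge whether the random-mating
#' and non-random-mating ensembles are distinguishable.
#'
#' @param a,b \code{\link{EnsembleResult}}s or numeric vectors.
#' @return List with \code{ks} (the two-sample KS statistic) and
#'   \code{deciles} (a data frame of the 10\%..90\% quantiles of each
#'   sample).
#' @export
compareDistributions <- function(a, b) {
  va <- .chi2ValuesOf(a)
  vb <- .chi2ValuesOf(b)
  if (length(va) == 0 || length(vb) == 0)
    stop("both ensembles must be non-empty")
  ks <- suppressWarnings(ks.test(va, vb))$statistic
  probs <- seq(0.1, 0.9, by = 0.1)
  list(ks = unname(ks),
       deciles = data.frame(prob = probs,
                            a = unname(quantile(va, probs)),
                            b = unname(quantile(vb, probs))))
}
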