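## Hardy-Weinberg arithmetic and the chi-square goodness-of-fit statistic.
## Internal helpers (prefix .) operate on bare length-3 numeric count vectors
## in the order (AA, Aa, aa); exported methods wrap them with validation.

## frequency of allele A by allele counting: (2 n_AA + n_Aa) / (2N)
.afreq <- function(k) (2 * k[[1L]] + k[[2L]]) / (2 * sum(k))

## HW-expected counts N * (p^2, 2pq, q^2)
.hwExpected <- function(k) {
  N <- sum(k)
  p <- .afreq(k)
  q <- 1 - p
  c(N * p * p, N * 2 * p * q, N * q * q)
}

## whole-table chi-square over cells with expected > 0; 0 at fixation
.chisq <- function(k) {
  e <- .hwExpected(k)
  pos <- e > 0
  sum((k[pos] - e[pos])^2 / e[pos])
}

## multivariate hypergeometric draw of n individuals from classes k,
## realised as a chain of univariate rhyper draws (exact, O(#classes))
.mvhyper <- function(k, n) {
  kAA <- rhyper(1L, k[[1L]], k[[2L]] + k[[3L]], n)
  kAa <- rhyper(1L, k[[2L]], k[[3L]], n - kAA)
  c(kAA, kAa, n - kAA - kAa)
}

.assertNonEmpty <- function(k) {
  if (sum(k) <= 0)
    stop("empty population: allele frequencies are undefined", call. = FALSE)
}

#' @describeIn GenotypeCounts count of AA homozygotes.
#' @export
setMethod("nAA", "GenotypeCounts", function(x) unname(x@counts[1L]))
#' @describeIn GenotypeCounts count of Aa heterozygotes.
#' @export
setMethod("nAa", "GenotypeCounts", function(x) unname(x@counts[2L]))
#' @describeIn GenotypeCounts count of aa homozygotes.
#' @export
setMethod("naa", "GenotypeCounts", function(x) unname(x@counts[3L]))
#' @describeIn GenotypeCounts total population size \eqn{N}.
#' @export
setMethod("popSize", "GenotypeCounts", function(x) sum(x@counts))

#' Allele frequencies by allele counting
#'
#' \eqn{f_A = (2 N_{AA} + N_{Aa}) / (2N)} and \eqn{f_a = 1 - f_A}. No
#' continuity correction is applied anywhere in the package.
#'
#' @param x a \code{\link{GenotypeCounts}} with at least one individual.
#' @return Named numeric vector \code{c(f_A, f_a)}; the two entries sum to 1
#'   exactly (\code{f_a} is derived).
#' @examples
#' alleleFrequencies(GenotypeCounts(30, 50, 20)) # f_A = 0.55
#' @export
setMethod("alleleFrequencies", "GenotypeCounts", function(x) {
  .assertNonEmpty(x@counts)
  fA <- .afreq(x@counts)
  c(f_A = fA, f_a = 1 - fA)
})

#' Hardy-Weinberg expected genotype counts
#'
#' Expected counts \eqn{N (p^2, 2pq, q^2)} with \eqn{p = f_A} estimated from
#' the observed counts by allele counting. The three components always sum to
#' the observed total.
#'
#' @param x a \code{\link{GenotypeCounts}} with at least one individual.
#' @return Named numeric vector of expected counts for (AA, Aa, aa), with
#'   attribute \code{basisTotal} giving the total they are scaled to.
#' @examples
#' hwExpectedCounts(GenotypeCounts(30, 50, 20)) # 30.25 49.5 20.25
#' @export
setMethod("hwExpectedCounts", "GenotypeCounts", function(x) {
  .assertNonEmpty(x@counts)
  e <- .hwExpected(x@counts)
  names(e) <- .GENOTYPES
  attr(e, "basisTotal") <- sum(x@counts)
  e
})

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' The plain (uncorrected) chi-square statistic
#' \eqn{\sum (O - E)^2 / E} comparing observed genotype counts with the
#' Hardy-Weinberg expectation derived from the observed allele frequency.
#' Degrees of freedom are fixed at 1 (three cells, minus one constraint,
#' minus one estimated allele frequency). Cells with zero expected count
#' contribute zero, so a monomorphic (fixed) population scores exactly 0:
#' observed equals expected and fixation is a trivially stable state.
#'
#' For a population of size \eqn{N} the statistic is bounded above by
#' \eqn{N}; the bound is attained by the all-homozygote split at
#' \eqn{p = 1/2}, e.g. counts (50, 0, 50).
#'
#' @param x a \code{\link{GenotypeCounts}} with at least one individual.
#' @return An object of class \code{"htest"} with components
#'   \code{statistic} (the chi-square value), \code{parameter} (df = 1),
#'   \code{p.value}, \code{observed}, \code{expected} and \code{n} (the
#'   population or sample size the statistic was computed on).
#' @examples
#' hwChiSquare(GenotypeCounts(25, 50, 25))$statistic # 0
#' hwChiSquare(GenotypeCounts(50, 0, 50))$statistic  # 100 = N
#' @export
setMethod("hwChiSquare", "GenotypeCounts", function(x) {
  .assertNonEmpty(x@counts)
  k <- x@counts
  stat <- .chisq(k)
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = 1),
    p.value = chiSquarePValue(stat, 1L),
    method = "Hardy-Weinberg chi-square goodness of fit (df = 1, no continuity correction)",
    data.name = sprintf("genotype counts (AA = %g, Aa = %g, aa = %g)",
                        k[1L], k[2L], k[3L]),
    observed = unname(k),
    expected = .hwExpected(k),
    n = sum(k)), class = "htest")
})

#' Upper-tail p-value of the chi-square distribution
#'
#' @param statistic non-negative chi-square value(s).
#' @param df degrees of freedom (default 1, the one-locus/two-allele test).
#' @return \eqn{P(\chi^2_{df} > statistic)}, in \[0, 1\].
#' @examples
#' chiSquarePValue(3.841459, 1) # 0.05
#' @export
chiSquarePValue <- function(statistic, df = 1L) {
  if (any(!is.finite(statistic)) || any(statistic < 0))
    stop("'statistic' must be finite and non-negative")
  if (any(df < 1))
    stop("'df' must be >= 1")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Critical value of the chi-square distribution
#'
#' Inverse of \code{\link{chiSquarePValue}}: the value whose upper-tail
#' probability equals \code{alpha}. At \code{alpha = 0.05}, \code{df = 1}
#' this is the classical 3.8414... threshold of the Hardy-Weinberg test.
#'
#' @param alpha upper-tail probability, strictly between 0 and 1.
#' @param df degrees of freedom (default 1).
#' @return The critical value \eqn{x} with
#'   \eqn{P(\chi^2_{df} > x) = alpha}.
#' @examples
#' chiSquareCriticalValue(0.05, 1) # 3.841459...
#' @export
chiSquareCriticalValue <- function(alpha, df = 1L) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1))
    stop("'alpha' must lie strictly between 0 and 1")
  qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Random subsample of a population, without replacement
#'
#' Draws \code{n} individuals uniformly without replacement (multivariate
#' hypergeometric over the three genotype classes), e.g. to emulate genotyping
#' a random sample from a large population.
#'
#' @param x a \code{\link{GenotypeCounts}}.
#' @param n subsample size, \code{0 <= n <= popSize(x)}.
#' @return A \code{\link{GenotypeCounts}} with total \code{n}.
#' @examples
#' set.seed(1)
#' subsampleCounts(GenotypeCounts(500, 1000, 500), 50)
#' @export
setMethod("subsampleCounts", "GenotypeCounts", function(x, n) {
  n <- as.numeric(n)
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != floor(n))
    stop("'n' must be a non-negative integer")
  if (n > popSize(x))
    stop("cannot subsample more individuals than the population holds")
  GenotypeCounts(.mvhyper(x@counts, n))
})

#' @describeIn ReproductionSpec mean number of offspring per couple \eqn{m}.
#' @export
setMethod("meanOffspring", "ReproductionSpec", function(x) {
  if (x@mode == "deterministic") x@fixedCount else sum((1:4) * x@countProbs)
})
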