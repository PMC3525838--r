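## One reproductive cycle: draw the reproductive pool, pair consecutive
## draws into couples, produce Mendelian offspring, cull to capacity.
##
## Individuals within a genotype class are exchangeable under every rule of
## the model, so the simulator state is the count triple (AA, Aa, aa) and all
## sampling is done on counts. Two regimes share one contract:
##   * exact (pool <= poolThreshold): random mating draws the pool
##     composition from the multivariate hypergeometric and pairs a uniform
##     permutation; fixed-class mating reproduces the sequential renormalized
##     draw exactly (see .poolFixedExact).
##   * large-N (pool > poolThreshold): pool composition stays exact
##     (hypergeometric) under random mating and is multinomial under fixed
##     probabilities; couple-type counts are drawn multinomially from the
##     pool fractions, an O(1/pool) approximation of permutation pairing.

## Mendelian segregation: offspring genotype probabilities by couple type,
## rows in .COUPLE_TYPES order (AAxAA, AAxAa, AAxaa, AaxAa, Aaxaa, aaxaa)
.SEGREGATION <- matrix(c(
  1,    0,   0,
  0.5,  0.5, 0,
  0,    1,   0,
  0.25, 0.5, 0.25,
  0,    0.5, 0.5,
  0,    0,   1), nrow = 6L, byrow = TRUE,
  dimnames = list(.COUPLE_TYPES, .GENOTYPES))

## --- pool drawing ---------------------------------------------------------

## uniform permutation of the class multiset drawn without replacement
.poolRandomExact <- function(k, n) {
  comp <- .mvhyper(k, n)
  x <- rep.int(1:3, comp)
  x[sample.int(n)]
}

## Exact sequential fixed-probability draw, vectorized.
## The sequential process draws a class j with probability P_j renormalized
## over non-empty classes and removes one individual. While no class is
## empty the draws are iid with probabilities P. We therefore generate iid
## draws in bulk and truncate at the first draw that would overshoot a
## class's remaining count; draws generated after a class empties but before
## the truncation point are, by the geometric-thinning argument, distributed
## exactly as iid draws with that class excluded and renormalized -- i.e.
## exactly the sequential process. The loop re-enters only when a class
## empties, which for pools much smaller than every class never happens.
.poolFixedExact <- function(k, n, P) {
  out <- integer(n)
  pos <- 0L
  remaining <- k
  while (pos < n) {
    active <- remaining > 0
    pr <- P * active
    if (sum(pr) <= 0)
      stop("mating-class probabilities put no mass on the remaining individuals",
           call. = FALSE)
    m <- n - pos
    draw <- sample.int(3L, m, replace = TRUE, prob = pr)
    cut <- m + 1L
    for (j in 1:3) {
      if (!active[j] || remaining[j] >= m) next
      over <- which(cumsum(draw == j) > remaining[j])
      if (length(over)) cut <- min(cut, over[1L])
    }
    take <- if (cut > m) draw else draw[seq_len(cut - 1L)]
    out[pos + seq_along(take)] <- take
    pos <- pos + length(take)
    if (length(take)) remaining <- remaining - tabulate(take, 3L)
  }
  out
}

#' Draw the reproductive pool
#'
#' Sequentially selects \code{nIndividuals} individuals without replacement
#' from the population: under random mating every remaining individual is
#' equiprobable; under fixed-class mating a genotype class is chosen at each
#' draw with the configured probabilities, renormalized over classes that
#' still hold individuals. Two consecutive draws later form one couple, so
#' the pool order matters and is returned.
#'
#' @param counts a \code{\link{GenotypeCounts}}.
#' @param nIndividuals even pool size \eqn{2N_c \le N}.
#' @param scheme a \code{\link{MatingScheme}}.
#' @return Character vector of genotype labels in draw order.
#' @examples
#' set.seed(1)
#' drawReproductivePool(GenotypeCounts(3, 4, 3), 6, randomMating())
#' @export
drawReproductivePool <- function(counts, nIndividuals, scheme = randomMating()) {
  k <- counts@counts
  n <- as.numeric(nIndividuals)
  if (n < 0 || n != floor(n) || n %% 2 != 0)
    stop("'nIndividuals' must be a non-negative even integer")
  if (n > sum(k))
    stop("reproductive pool larger than the population")
  idx <- if (n == 0) integer(0)
         else if (scheme@mode == "random") .poolRandomExact(k, n)
         else .poolFixedExact(k, n, scheme@classProbs)
  .GENOTYPES[idx]
}

## --- pairing ---------------------------------------------------------------

## couple-type counts from an integer label sequence (1 = AA, 2 = Aa, 3 = aa)
.pairInt <- function(pool) {
  len <- length(pool)
  a <- pool[seq.int(1L, len, 2L)]
  b <- pool[seq.int(2L, len, 2L)]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  ## (1,1)(1,2)(1,3)(2,2)(2,3)(3,3) -> 1..6
  idx <- c(1L, 2L, 3L, 0L, 4L, 5L, 0L, 0L, 6L)[lo * 3L + hi - 3L]
  tabulate(idx, 6L)
}

#' Pair consecutive pool members into couples
#'
#' Consecutive elements of the (ordered) reproductive pool form couples; the
#' result is tallied over the six unordered couple types.
#'
#' @param pool character vector of genotype labels (\code{"AA"},
#'   \code{"Aa"}, \code{"aa"}), of even length, in draw order.
#' @return Named integer vector of counts over \code{AAxAA, AAxAa, AAxaa,
#'   AaxAa, Aaxaa, aaxaa}; the counts sum to \code{length(pool)/2}.
#' @examples
#' pairCouples(c("AA", "aa", "AA", "aa")) # two AAxaa couples
#' @export
pairCouples <- function(pool) {
  if (length(pool) %% 2 != 0)
    stop("pool length must be even")
  idx <- match(pool, .GENOTYPES)
  if (anyNA(idx))
    stop("pool labels must be \"AA\", \"Aa\" or \"aa\"")
  setNames(.pairInt(idx), .COUPLE_TYPES)
}

## --- reproduction ----------------------------------------------------------

## offspring counts (AA, Aa, aa) from couple-type counts
.reproduce <- function(cc, repro) {
  if (repro@mode == "deterministic") {
    totals <- repro@fixedCount * cc
  } else {
    totals <- numeric(6L)
    for (t in which(cc > 0)) {
      fam <- rmultinom(1L, cc[t], repro@countProbs)
      totals[t] <- sum((1:4) * fam)
    }
  }
  out <- numeric(3L)
  for (t in which(totals > 0)) {
    p <- .SEGREGATION[t, ]
    one <- which(p == 1)
    if (length(one)) {
      out[one] <- out[one] + totals[t]   # obligate genotype, no sampling
    } else {
      out <- out + as.vector(rmultinom(1L, totals[t], p))
    }
  }
  out
}

#' Mendelian reproduction of the paired couples
#'
#' Each couple independently draws its number of offspring from the
#' \code{\link{ReproductionSpec}}; every offspring receives one allele from
#' each parent, chosen uniformly and independently (so AAxaa couples produce
#' only Aa, AaxAa couples produce (AA, Aa, aa) with probabilities
#' (1/4, 1/2, 1/4), and so on).
#'
#' @param coupleCounts named counts over the six couple types, as returned by
#'   \code{\link{pairCouples}}.
#' @param reproduction a \code{\link{ReproductionSpec}}.
#' @return A \code{\link{GenotypeCounts}} of the offspring generation.
#' @examples
#' cc <- setNames(c(0, 0, 5, 0, 0, 0),
#'                c("AAxAA", "AAxAa", "AAxaa", "AaxAa", "Aaxaa", "aaxaa"))
#' reproduceCouples(cc, ReproductionSpec("deterministic", 4)) # 20 Aa
#' @export
reproduceCouples <- function(coupleCounts,
                             reproduction = ReproductionSpec("deterministic", 4)) {
  cc <- as.numeric(coupleCounts)
  if (length(cc) != 6L || any(cc < 0) || any(cc != floor(cc)))
    stop("'coupleCounts' must be 6 non-negative integer counts")
  if (!is.null(names(coupleCounts)) &&
      !identical(names(coupleCounts), .COUPLE_TYPES))
    stop("couple counts must be named ", paste(.COUPLE_TYPES, collapse = ", "))
  GenotypeCounts(.reproduce(cc, reproduction))
}

## --- culling ---------------------------------------------------------------

.cull <- function(k, capacity) {
  if (sum(k) <= capacity) k else .mvhyper(k, capacity)
}

#' Random culling of excess offspring
#'
#' If the offspring generation exceeds the carrying capacity, the survivors
#' are a uniform without-replacement selection of \code{capacity} individuals
#' (multivariate hypergeometric over genotype classes); otherwise the
#' population passes unchanged.
#'
#' @param offspring a \code{\link{GenotypeCounts}}.
#' @param capacity maximum surviving population size \eqn{N_{max} \ge 0}.
#' @return A \code{\link{GenotypeCounts}} with total
#'   \code{min(popSize(offspring), capacity)}.
#' @export
cullToCapacity <- function(offspring, capacity) {
  capacity <- as.numeric(capacity)
  if (length(capacity) != 1L || !is.finite(capacity) || capacity < 0 ||
      capacity != floor(capacity))
    stop("'capacity' must be a non-negative integer")
  GenotypeCounts(.cull(offspring@counts, capacity))
}

## --- one full generation ---------------------------------------------------

## pool size for the current population under a config
.poolSize <- function(N, config) {
  n <- if (!is.na(config@reproducingCount)) config@reproducingCount
       else floor(config@reproducingFraction * N)
  n <- n - n %% 2
  if (n < 2)
    stop("population too small to form a reproducing couple", call. = FALSE)
  if (n > N)
    stop(sprintf("reproductive pool (%g) exceeds the population (%g)", n, N),
         call. = FALSE)
  n
}

## multinomial pool composition for the large-N fixed-probability sampler;
## overshoot of a finite class (rare unless the pool is a sizeable share of
## the class) is capped and re-allocated among classes with headroom
.poolCompFixedApprox <- function(k, n, P) {
  pr <- P * (k > 0)
  if (sum(pr) <= 0)
    stop("mating-class probabilities put no mass on non-empty classes",
         call. = FALSE)
  comp <- as.vector(rmultinom(1L, n, pr))
  repeat {
    excess <- pmax(comp - k, 0)
    s <- sum(excess)
    if (s == 0) break
    comp <- pmin(comp, k)
    head <- k - comp
    pr2 <- pr * (head > 0)
    comp <- comp + as.vector(rmultinom(1L, s, pr2))
  }
  comp
}

.advance <- function(k, config) {
  N <- sum(k)
  n <- .poolSize(N, config)
  scheme <- config@mating
  if (n <= config@poolThreshold) {
    pool <- if (scheme@mode == "random") .poolRandomExact(k, n)
            else .poolFixedExact(k, n, scheme@classProbs)
    cc <- .pairInt(pool)
  } else {
    comp <- if (scheme@mode == "random") .mvhyper(k, n)
            else .poolCompFixedApprox(k, n, scheme@classProbs)
    f <- comp / n
    pairP <- c(f[1L]^2, 2 * f[1L] * f[2L], 2 * f[1L] * f[3L],
               f[2L]^2, 2 * f[2L] * f[3L], f[3L]^2)
    cc <- as.vector(rmultinom(1L, n / 2, pairP))
  }
  off <- .reproduce(cc, config@reproduction)
  .cull(off, config@capacity)
}

#' Advance the population by one generation
#'
#' One full reproductive cycle: draw the reproductive pool
#' (\code{\link{drawReproductivePool}}), pair consecutive draws
#' (\code{\link{pairCouples}}), produce Mendelian offspring
#' (\code{\link{reproduceCouples}}) and cull to capacity
#' (\code{\link{cullToCapacity}}). Monomorphic populations are absorbing:
#' without mutation a lost allele never reappears.
#'
#' @param counts a \code{\link{GenotypeCounts}}, the parent generation.
#' @param config a \code{\link{SimulationConfig}} (its \code{initial},
#'   \code{generations}, \code{bottlenecks} and \code{seed} are ignored
#'   here; only capacity, pool size, reproduction and mating are used).
#' @return A \code{\link{GenotypeCounts}} of the next generation, of size
#'   \code{min(offspring total, capacity)}.
#' @export
advanceGeneration <- function(counts, config) {
  GenotypeCounts(.advance(counts@counts, config))
}
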