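## Preset experiment configurations. Each preset fixes the full stated world
## of one published-style experiment; `scale` shrinks every population-sized
## quantity proportionally for desk-scale runs (the ensemble tail
## probabilities vary slowly over N = 1e4..1e6, which justifies the
## reduction), leaving founding/bottleneck profiles untouched.

.PRESETS <- c("fig2_random", "fig2_nonrandom", "fig3_bottleneck_random",
              "fig4_bottleneck_nonrandom", "fig5_acf_random",
              "fig6_acf_nonrandom")

.NONRANDOM_PROBS <- c(AA = 0.23, Aa = 0.54, aa = 0.23)

## equal thirds of N, remainder on the heterozygotes
.equalThirds <- function(N) {
  n3 <- floor(N / 3)
  c(n3, N - 2 * n3, n3)
}

## HW profile at f_a = 0.5: N * (1/4, 1/2, 1/4)
.hwHalf <- function(N) {
  n4 <- round(N / 4)
  c(n4, N - 2 * n4, n4)
}

.even <- function(n) n - n %% 2

#' Names of the built-in experiment presets
#'
#' @return Character vector of preset names accepted by
#'   \code{\link{presetConfig}}.
#' @export
presetNames <- function() .PRESETS

#' Built-in experiment configurations
#'
#' Fully specified configurations for the six canonical experiments:
#' \describe{
#'   \item{\code{fig2_random}, \code{fig2_nonrandom}}{chi-square ensembles:
#'     populations of \eqn{N = 3 \times 10^6} (at \code{scale = 1}) starting
#'     from equal genotype thirds, a fixed reproductive pool of
#'     \eqn{N_{rep} = 0.6N}, 4 offspring per couple, capacity \eqn{N};
#'     \eqn{L = 10^5} replicates observed at generation 30. The non-random
#'     variant draws couple members with fixed class probabilities
#'     (0.23, 0.54, 0.23).}
#'   \item{\code{fig3_bottleneck_random}, \code{fig4_bottleneck_nonrandom}}{
#'     growth-and-bottleneck trajectories: a founding profile of
#'     (10, 20, 10) grows at rate \eqn{2\epsilon m = 1.2} per generation
#'     (\eqn{\epsilon = 0.6}, 4 offspring per couple) to capacity
#'     \eqn{3 \times 10^7} (at \code{scale = 1}); scheduled bottlenecks
#'     reset the population to the founding profile. The random variant
#'     drifts to a new frequency after each bottleneck; the non-random
#'     variant returns to \eqn{f_a = 0.5}.}
#'   \item{\code{fig5_acf_random}}{a population held at
#'     \eqn{N = 3 \times 10^6} (at \code{scale = 1}), random mating,
#'     \eqn{3 \times 10^5} generations, for the allele-frequency
#'     autocorrelation of neutral drift.}
#'   \item{\code{fig6_acf_nonrandom}}{growth from (10, 20, 10) to
#'     \eqn{3 \times 10^7} under fixed class probabilities,
#'     \eqn{3 \times 10^5} generations, for the exponentially decaying
#'     autocorrelation of stable dynamics.}
#' }
#'
#' @param name one of \code{\link{presetNames}()}.
#' @param scale multiplicative desk-scale factor applied to capacities,
#'   pool sizes and (for the ensembles) the replicate count; founding and
#'   bottleneck profiles are absolute and not scaled. Default 1 = published
#'   scale.
#' @param seed master RNG seed stored in the configuration.
#' @param replicates override for the ensemble replicate count (the scaled
#'   default never drops below 2000).
#' @param generations override for the simulated horizon of the trajectory
#'   presets.
#' @return An \code{\link{EnsembleConfig}} for the \code{fig2_*} presets, a
#'   \code{\link{SimulationConfig}} otherwise.
#' @examples
#' presetConfig("fig2_nonrandom", scale = 1 / 300, seed = 1)
#' @export
presetConfig <- function(name, scale = 1, seed = NA_real_, replicates = NULL,
                         generations = NULL) {
  name <- match.arg(name, .PRESETS)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1)
    stop("'scale' must lie in (0, 1]")
  det4 <- ReproductionSpec("deterministic", 4)
  founders <- GenotypeCounts(10, 20, 10)

  if (name %in% c("fig2_random", "fig2_nonrandom")) {
    N <- round(3e6 * scale)
    if (N < 100)
      stop("'scale' too small: ensemble populations need at least 100 individuals")
    L <- if (is.null(replicates)) max(2000, round(1e5 * scale)) else replicates
    base <- SimulationConfig(
      initial = GenotypeCounts(.equalThirds(N)),
      capacity = N,
      reproducingCount = .even(round(0.6 * N)),
      reproduction = det4,
      mating = if (name == "fig2_random") randomMating()
               else fixedClassMating(.NONRANDOM_PROBS),
      generations = 30,
      seed = seed)
    return(EnsembleConfig(base, replicates = L, observeAt = 30))
  }

  if (name %in% c("fig3_bottleneck_random", "fig4_bottleneck_nonrandom")) {
    cap <- round(3e7 * scale)
    if (cap < 100)
      stop("'scale' too small for a growth-and-bottleneck run")
    random <- name == "fig3_bottleneck_random"
    gens <- if (is.null(generations)) (if (random) 1200 else 800) else generations
    bnAt <- if (random) c(400, 800) else 400
    bnAt <- bnAt[bnAt < gens]
    return(SimulationConfig(
      initial = founders, capacity = cap, reproducingFraction = 0.6,
      reproduction = det4,
      mating = if (random) randomMating()
               else fixedClassMating(.NONRANDOM_PROBS),
      generations = gens,
      bottlenecks = lapply(bnAt, BottleneckEvent, resetProfile = founders),
      seed = seed))
  }

  if (name == "fig5_acf_random") {
    N <- round(3e6 * scale)
    if (N < 100)
      stop("'scale' too small for the maintained-population preset")
    gens <- if (is.null(generations)) 3e5 else generations
    return(SimulationConfig(
      initial = GenotypeCounts(.hwHalf(N)), capacity = N,
      reproducingCount = .even(round(0.6 * N)), reproduction = det4,
      mating = randomMating(), generations = gens, seed = seed))
  }

  ## fig6_acf_nonrandom
  cap <- round(3e7 * scale)
  if (cap < 100)
    stop("'scale' too small for the growth preset")
  gens <- if (is.null(generations)) 3e5 else generations
  SimulationConfig(
    initial = founders, capacity = cap, reproducingFraction = 0.6,
    reproduction = det4, mating = fixedClassMating(.NONRANDOM_PROBS),
    generations = gens, seed = seed)
}
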