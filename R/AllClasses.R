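## S4 class definitions and validity. Constructors live next to the class;
## numeric work is done on plain length-3 count vectors internally (see
## genetics-core.R) -- the classes are the validated user-facing containers.

.GENOTYPES <- c("AA", "Aa", "aa")
.COUPLE_TYPES <- c("AAxAA", "AAxAa", "AAxaa", "AaxAa", "Aaxaa", "aaxaa")

#' @rdname GenotypeCounts
#' @export
setClass("GenotypeCounts", representation(counts = "numeric"))

setValidity("GenotypeCounts", function(object) {
  k <- object@counts
  if (length(k) != 3L || !identical(names(k), .GENOTYPES))
    return("'counts' must be a length-3 numeric vector named AA, Aa, aa")
  if (any(!is.finite(k)))
    return("genotype counts must be finite")
  if (any(k < 0))
    return("genotype counts must be non-negative")
  if (any(k != floor(k)))
    return("genotype counts must be whole numbers")
  TRUE
})

#' Genotype counts of a one-locus/two-allele population
#'
#' The entire state of the simulated population: the number of individuals of
#' each of the three genotypes AA, Aa and aa. The population size is the sum
#' of the three counts.
#'
#' @param nAA,nAa,naa non-negative integer counts of the three genotypes.
#'   Alternatively, \code{nAA} may be a single length-3 (optionally named)
#'   vector.
#' @return A \code{GenotypeCounts} object.
#' @examples
#' gc <- GenotypeCounts(10, 20, 10)
#' popSize(gc)           # 40
#' alleleFrequencies(gc) # f_A = f_a = 0.5
#' @aliases GenotypeCounts-class
#' @export
GenotypeCounts <- function(nAA, nAa, naa) {
  if (missing(nAa) && length(nAA) == 3L) {
    v <- as.numeric(nAA)
  } else {
    v <- as.numeric(c(nAA, nAa, naa))
  }
  names(v) <- .GENOTYPES
  new("GenotypeCounts", counts = v)
}

setMethod("show", "GenotypeCounts", function(object) {
  k <- object@counts
  cat(sprintf("GenotypeCounts (N = %s)\n",
              format(sum(k), big.mark = ",", scientific = FALSE)))
  cat(sprintf("  AA: %s  Aa: %s  aa: %s\n",
              format(k[1L], scientific = FALSE),
              format(k[2L], scientific = FALSE),
              format(k[3L], scientific = FALSE)))
  if (sum(k) > 0) {
    f <- .afreq(k)
    cat(sprintf("  f_A = %.6g, f_a = %.6g\n", f, 1 - f))
  }
  invisible(NULL)
})

#' @rdname MatingScheme
#' @export
setClass("MatingScheme",
         representation(mode = "character", classProbs = "numeric"))

setValidity("MatingScheme", function(object) {
  if (length(object@mode) != 1L || !object@mode %in% c("random", "fixed"))
    return("'mode' must be \"random\" or \"fixed\"")
  if (object@mode == "fixed") {
    p <- object@classProbs
    if (length(p) != 3L || !identical(names(p), .GENOTYPES))
      return("fixed mating needs 'classProbs' of length 3 named AA, Aa, aa")
    if (any(!is.finite(p)) || any(p < 0))
      return("class probabilities must be finite and non-negative")
    if (abs(sum(p) - 1) > 1e-12)
      return("class probabilities must sum to 1 (within 1e-12)")
  } else if (length(object@classProbs) != 0L) {
    return("random mating takes no class probabilities")
  }
  TRUE
})

#' Mating scheme: random or fixed genotype-class probabilities
#'
#' Controls how individuals enter the reproductive pool. Under random mating
#' every remaining individual is equally likely to be drawn (so the class
#' draw probabilities track the instantaneous genotype frequencies). Under
#' the fixed scheme a genotype class is selected at each draw with constant,
#' externally imposed probabilities \eqn{(P_{AA}, P_{Aa}, P_{aa})},
#' renormalized over the classes that still have individuals; this is the
#' model's non-random mating.
#'
#' @param mode \code{"random"} or \code{"fixed"}.
#' @param classProbs for \code{mode = "fixed"}: three non-negative
#'   probabilities for classes (AA, Aa, aa) summing to 1.
#' @return A \code{MatingScheme} object.
#' @seealso \code{\link{randomMating}}, \code{\link{fixedClassMating}}
#' @aliases MatingScheme-class
#' @export
MatingScheme <- function(mode = c("random", "fixed"), classProbs = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(classProbs))
      stop("fixed mating requires 'classProbs'")
    p <- as.numeric(classProbs)
    names(p) <- .GENOTYPES
  } else {
    p <- numeric(0)
  }
  new("MatingScheme", mode = mode, classProbs = p)
}

#' @rdname MatingScheme
#' @export
randomMating <- function() MatingScheme("random")

#' @rdname MatingScheme
#' @export
fixedClassMating <- function(classProbs) MatingScheme("fixed", classProbs)

setMethod("show", "MatingScheme", function(object) {
  if (object@mode == "random") {
    cat("MatingScheme: random (equiprobable individuals)\n")
  } else {
    cat(sprintf("MatingScheme: fixed class probabilities P(AA) = %g, P(Aa) = %g, P(aa) = %g\n",
                object@classProbs[1L], object@classProbs[2L],
                object@classProbs[3L]))
  }
  invisible(NULL)
})

#' @rdname ReproductionSpec
#' @export
setClass("ReproductionSpec",
         representation(mode = "character", fixedCount = "numeric",
                        countProbs = "numeric"))

setValidity("ReproductionSpec", function(object) {
  if (length(object@mode) != 1L ||
      !object@mode %in% c("deterministic", "stochastic"))
    return("'mode' must be \"deterministic\" or \"stochastic\"")
  if (object@mode == "deterministic") {
    k <- object@fixedCount
    if (length(k) != 1L || !k %in% 1:4)
      return("'fixedCount' must be one of 1, 2, 3, 4")
  } else {
    p <- object@countProbs
    if (length(p) != 4L || any(!is.finite(p)) || any(p < 0))
      return("'countProbs' must be 4 non-negative probabilities for 1..4 offspring")
    if (abs(sum(p) - 1) > 1e-12)
      return("'countProbs' must sum to 1 (within 1e-12)")
  }
  TRUE
})

#' Offspring-number specification for a reproducing couple
#'
#' Every couple produces between 1 and 4 offspring: either the same fixed
#' number for all couples (\code{"deterministic"}) or a number drawn
#' independently per couple from a distribution on \{1, 2, 3, 4\}
#' (\code{"stochastic"}). The mean \eqn{m} of that distribution is the mean
#' reproductive capacity; sustained growth needs \eqn{\epsilon m > 1}
#' offspring per parent, i.e. \eqn{m > 2} when the whole population
#' reproduces.
#'
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @param fixedCount offspring per couple in deterministic mode (1..4).
#' @param countProbs probabilities of 1, 2, 3, 4 offspring (stochastic mode).
#' @return A \code{ReproductionSpec}; \code{meanOffspring} returns \eqn{m}.
#' @examples
#' meanOffspring(ReproductionSpec("stochastic",
#'                                countProbs = c(0.1, 0.2, 0.3, 0.4)))
#' @aliases ReproductionSpec-class
#' @export
ReproductionSpec <- function(mode = c("deterministic", "stochastic"),
                             fixedCount = 4, countProbs = NULL) {
  mode <- match.arg(mode)
  if (mode == "deterministic") {
    new("ReproductionSpec", mode = mode, fixedCount = as.numeric(fixedCount),
        countProbs = numeric(0))
  } else {
    if (is.null(countProbs))
      stop("stochastic reproduction requires 'countProbs'")
    new("ReproductionSpec", mode = mode, fixedCount = numeric(0),
        countProbs = as.numeric(countProbs))
  }
}

setMethod("show", "ReproductionSpec", function(object) {
  if (object@mode == "deterministic") {
    cat(sprintf("ReproductionSpec: %d offspring per couple (m = %d)\n",
                as.integer(object@fixedCount), as.integer(object@fixedCount)))
  } else {
    cat(sprintf("ReproductionSpec: stochastic on {1,2,3,4}, probs (%s), m = %.3g\n",
                paste(format(object@countProbs), collapse = ", "),
                meanOffspring(object)))
  }
  invisible(NULL)
})

#' @rdname BottleneckEvent
#' @export
setClass("BottleneckEvent",
         representation(generation = "numeric", resetProfile = "GenotypeCounts"))

setValidity("BottleneckEvent", function(object) {
  g <- object@generation
  if (length(g) != 1L || !is.finite(g) || g < 1 || g != floor(g))
    return("'generation' must be a positive integer")
  TRUE
})

#' Scheduled population bottleneck
#'
#' At the scheduled generation (after that generation's state has been
#' recorded) the population is replaced by \code{resetProfile}, emulating an
#' imposed crash back to a small founding profile.
#'
#' @param generation positive integer; the generation after which the reset
#'   is applied.
#' @param resetProfile a \code{\link{GenotypeCounts}} the population is reset
#'   to.
#' @return A \code{BottleneckEvent}.
#' @aliases BottleneckEvent-class
#' @export
BottleneckEvent <- function(generation, resetProfile) {
  if (!is(resetProfile, "GenotypeCounts"))
    resetProfile <- GenotypeCounts(resetProfile)
  new("BottleneckEvent", generation = as.numeric(generation),
      resetProfile = resetProfile)
}

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
         representation(initial = "GenotypeCounts",
                        capacity = "numeric",
                        reproducingCount = "numeric",
                        reproducingFraction = "numeric",
                        reproduction = "ReproductionSpec",
                        mating = "MatingScheme",
                        generations = "numeric",
                        bottlenecks = "list",
                        seed = "numeric",
                        poolThreshold = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (length(object@capacity) != 1L || !is.finite(object@capacity) ||
      object@capacity < 1 || object@capacity != floor(object@capacity))
    return("'capacity' must be a positive integer")
  g <- object@generations
  if (length(g) != 1L || !is.finite(g) || g < 0 || g != floor(g))
    return("'generations' must be a non-negative integer")
  nc <- object@reproducingCount
  nf <- object@reproducingFraction
  if (is.na(nc) == is.na(nf))
    return("exactly one of 'reproducingCount' and 'reproducingFraction' must be set")
  if (!is.na(nc)) {
    if (nc < 2 || nc != floor(nc) || nc %% 2 != 0)
      return("'reproducingCount' must be an even integer >= 2")
    if (nc > object@capacity)
      return("'reproducingCount' cannot exceed 'capacity'")
  } else {
    if (!is.finite(nf) || nf <= 0 || nf >= 1)
      return("'reproducingFraction' must lie strictly between 0 and 1")
  }
  if (length(object@poolThreshold) != 1L || object@poolThreshold < 1)
    return("'poolThreshold' must be >= 1")
  for (b in object@bottlenecks) {
    if (!is(b, "BottleneckEvent"))
      return("'bottlenecks' must be a list of BottleneckEvent objects")
    if (b@generation > g)
      return("bottleneck generation lies beyond the simulated horizon")
    if (popSize(b@resetProfile) > object@capacity)
      return("bottleneck reset profile exceeds 'capacity'")
  }
  TRUE
})

#' Configuration of one forward simulation
#'
#' Bundles everything one run needs: the initial genotype profile, the
#' carrying capacity \eqn{N_{max}}, the size of the reproductive pool (either
#' a fixed even count \eqn{2N_c} or a fraction \eqn{\epsilon} of the current
#' population), the offspring-number rule, the mating scheme, the number of
#' generations, an optional bottleneck schedule, and the RNG seed.
#'
#' @param initial a \code{\link{GenotypeCounts}} (or length-3 vector), the
#'   population at generation 0.
#' @param capacity carrying capacity \eqn{N_{max}}; offspring in excess of it
#'   are randomly culled each generation.
#' @param reproducingCount fixed even number of reproducing individuals
#'   \eqn{2N_c} per generation (mutually exclusive with
#'   \code{reproducingFraction}).
#' @param reproducingFraction fraction \eqn{\epsilon \in (0,1)} of the
#'   current population that reproduces; the pool size is rounded down to an
#'   even number.
#' @param reproduction a \code{\link{ReproductionSpec}}.
#' @param mating a \code{\link{MatingScheme}}.
#' @param generations number of generation steps to simulate.
#' @param bottlenecks list of \code{\link{BottleneckEvent}}s.
#' @param seed integer RNG seed (\code{NA} = use the current RNG state).
#' @param poolThreshold pool size above which the O(1) large-population
#'   sampler replaces the exact individual-level sampler (see the package
#'   vignette); default \code{1e5}.
#' @return A validated \code{SimulationConfig}.
#' @seealso \code{\link{runTrajectory}}, \code{\link{presetConfig}}
#' @aliases SimulationConfig-class
#' @export
SimulationConfig <- function(initial, capacity,
                             reproducingCount = NA_real_,
                             reproducingFraction = NA_real_,
                             reproduction = ReproductionSpec("deterministic", 4),
                             mating = randomMating(),
                             generations = 0,
                             bottlenecks = list(),
                             seed = NA_real_,
                             poolThreshold = 1e5) {
  if (!is(initial, "GenotypeCounts"))
    initial <- GenotypeCounts(initial)
  new("SimulationConfig", initial = initial, capacity = as.numeric(capacity),
      reproducingCount = as.numeric(reproducingCount),
      reproducingFraction = as.numeric(reproducingFraction),
      reproduction = reproduction, mating = mating,
      generations = as.numeric(generations), bottlenecks = bottlenecks,
      seed = as.numeric(seed), poolThreshold = as.numeric(poolThreshold))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  initial: AA %g, Aa %g, aa %g (N = %g)\n",
              object@initial@counts[1L], object@initial@counts[2L],
              object@initial@counts[3L], popSize(object@initial)))
  cat(sprintf("  capacity N_max = %g; reproducing %s\n", object@capacity,
              if (!is.na(object@reproducingCount))
                sprintf("count 2Nc = %g", object@reproducingCount)
              else sprintf("fraction eps = %g", object@reproducingFraction)))
  show(object@reproduction)
  show(object@mating)
  cat(sprintf("  generations: %g; bottlenecks: %d; seed: %s\n",
              object@generations, length(object@bottlenecks),
              ifelse(is.na(object@seed), "<unset>",
                     format(object@seed, scientific = FALSE))))
  invisible(NULL)
})

#' @rdname Trajectory
#' @export
setClass("Trajectory",
         representation(records = "data.frame", config = "SimulationConfig",
                        seed = "numeric"))

setValidity("Trajectory", function(object) {
  need <- c("generation", "n_AA", "n_Aa", "n_aa", "f_A", "f_a", "chi2")
  if (!identical(colnames(object@records), need))
    return(sprintf("records must have columns %s", paste(need, collapse = ", ")))
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  r <- object@records
  cat(sprintf("Trajectory: %d generations (+ t = 0), N_final = %g, f_a final = %.6g\n",
              nrow(r) - 1L, sum(r[nrow(r), c("n_AA", "n_Aa", "n_aa")]),
              r$f_a[nrow(r)]))
  cat(sprintf("  mating: %s; capacity %g; seed %s\n", object@config@mating@mode,
              object@config@capacity,
              ifelse(is.na(object@seed), "<unset>",
                     format(object@seed, scientific = FALSE))))
  invisible(NULL)
})

#' @describeIn Trajectory per-generation records as a data frame with columns
#'   \code{generation}, \code{n_AA}, \code{n_Aa}, \code{n_aa}, \code{f_A},
#'   \code{f_a}, \code{chi2}.
#' @param x,row.names,optional,... see \code{\link[base]{as.data.frame}}.
#' @export
setMethod("as.data.frame", "Trajectory",
          function(x, row.names = NULL, optional = FALSE, ...) x@records)

#' @rdname EnsembleConfig
#' @export
setClass("EnsembleConfig",
         representation(base = "SimulationConfig", replicates = "numeric",
                        observeAt = "numeric", sampleSize = "numeric"))

setValidity("EnsembleConfig", function(object) {
  L <- object@replicates
  if (length(L) != 1L || !is.finite(L) || L < 1 || L != floor(L))
    return("'replicates' must be a positive integer")
  t <- object@observeAt
  if (length(t) != 1L || !is.finite(t) || t < 0 || t != floor(t))
    return("'observeAt' must be a non-negative integer")
  if (t > object@base@generations)
    return("'observeAt' lies beyond the base configuration's horizon")
  n <- object@sampleSize
  if (!is.na(n)) {
    if (n < 1 || n != floor(n))
      return("'sampleSize' must be a positive integer")
    if (n > object@base@capacity)
      return("'sampleSize' cannot exceed the base capacity")
  }
  TRUE
})

#' Configuration of a chi-square ensemble experiment
#'
#' An ensemble is \eqn{L} replicate populations evolved independently from
#' identical initial conditions; the Hardy-Weinberg chi-square is measured
#' once per replicate at generation \code{observeAt}, on the whole population
#' or (if \code{sampleSize} is set) on one random subsample per replicate.
#'
#' @param base the shared \code{\link{SimulationConfig}} (its \code{seed} is
#'   the ensemble master seed).
#' @param replicates number of replicate populations \eqn{L}.
#' @param observeAt generation at which chi-square is measured (default 30).
#' @param sampleSize optional subsample size \eqn{n}; \code{NA} measures the
#'   whole population.
#' @return An \code{EnsembleConfig}.
#' @seealso \code{\link{runChiSquareEnsemble}}
#' @aliases EnsembleConfig-class
#' @export
EnsembleConfig <- function(base, replicates, observeAt = 30,
                           sampleSize = NA_real_) {
  new("EnsembleConfig", base = base, replicates = as.numeric(replicates),
      observeAt = as.numeric(observeAt), sampleSize = as.numeric(sampleSize))
}

setMethod("show", "EnsembleConfig", function(object) {
  cat(sprintf("EnsembleConfig: L = %g replicates, observe at generation %g, %s\n",
              object@replicates, object@observeAt,
              if (is.na(object@sampleSize)) "whole-population chi-square"
              else sprintf("subsample n = %g", object@sampleSize)))
  show(object@base)
  invisible(NULL)
})

#' @rdname EnsembleResult
#' @export
setClass("EnsembleResult",
         representation(chi2Values = "numeric", config = "EnsembleConfig",
                        seed = "numeric"))

setValidity("EnsembleResult", function(object) {
  if (length(object@chi2Values) != object@config@replicates)
    return("number of chi-square values must equal the configured replicates")
  if (any(object@chi2Values < 0))
    return("chi-square values must be non-negative")
  TRUE
})

setMethod("show", "EnsembleResult", function(object) {
  v <- object@chi2Values
  cat(sprintf("EnsembleResult: L = %d chi-square values at generation %g\n",
              length(v), object@config@observeAt))
  cat(sprintf("  median %.4g, mean %.4g, max %.4g\n",
              stats::median(v), mean(v), max(v)))
  invisible(NULL)
})

#' @rdname AcfResult
#' @export
setClass("AcfResult",
         representation(lags = "numeric", values = "numeric",
                        seriesLength = "numeric", noiseBand = "numeric"))

setValidity("AcfResult", function(object) {
  if (length(object@lags) != length(object@values))
    return("'lags' and 'values' must have equal length")
  if (length(object@values) < 1L || abs(object@values[1L] - 1) > 1e-8)
    return("C(0) must equal 1")
  if (any(object@values > 1 + 1e-8) || any(object@values < -1 - 1e-8))
    return("autocorrelation values must lie in [-1, 1]")
  TRUE
})

setMethod("show", "AcfResult", function(object) {
  cat(sprintf("AcfResult: lags 0..%g on a series of length %g\n",
              max(object@lags), object@seriesLength))
  cl <- crossingLag(object)
  cat(sprintf("  noise band +/- %.4g; first crossing below band at lag %s\n",
              object@noiseBand,
              ifelse(is.na(cl), "<none within max lag>",
                     format(cl, scientific = FALSE))))
  invisible(NULL)
})

#' @describeIn AcfResult lags and autocorrelation values as a two-column
#'   data frame (\code{lag}, \code{C}).
#' @param x,row.names,optional,... see \code{\link[base]{as.data.frame}}.
#' @export
setMethod("as.data.frame", "AcfResult",
          function(x, row.names = NULL, optional = FALSE, ...)
            data.frame(lag = x@lags, C = x@values))
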