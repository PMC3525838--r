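## Whole-run simulation: iterate .advance, apply scheduled bottlenecks,
## record counts, allele frequencies and the whole-population chi-square at
## every generation (including t = 0).

## bare-bones evolution loop used by ensembles (no record assembly)
.evolve <- function(k, generations, config, bnGen = numeric(0),
                    bnProfiles = list()) {
  if (generations < 1) return(k)
  for (g in seq_len(generations)) {
    k <- tryCatch(.advance(k, config), error = function(e)
      stop(sprintf("generation %d: %s", g, conditionMessage(e)), call. = FALSE))
    hit <- which(bnGen == g)
    if (length(hit)) k <- bnProfiles[[hit[1L]]]
  }
  k
}

#' Run a forward simulation and record the trajectory
#'
#' Iterates \code{\link{advanceGeneration}} for the configured number of
#' generations starting from the initial profile. After the state of a
#' generation listed in the bottleneck schedule has been recorded, the
#' population is replaced by that event's reset profile before the next
#' cycle. Each record holds the genotype counts, the allele frequencies and
#' the whole-population Hardy-Weinberg chi-square. Identical configuration
#' and seed give a bit-identical trajectory.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param ... unused.
#' @return A \code{\link{Trajectory}}; use \code{as.data.frame} to obtain
#'   the \code{generations + 1} records (t = 0 included) and
#'   \code{\link{alleleFreqSeries}} for the frequency time series.
#' @examples
#' cfg <- SimulationConfig(GenotypeCounts(10, 20, 10), capacity = 1000,
#'                         reproducingFraction = 0.6, generations = 20,
#'                         seed = 1)
#' head(as.data.frame(runTrajectory(cfg)))
#' @aliases Trajectory-class
#' @export
setMethod("runTrajectory", "SimulationConfig", function(config, ...) {
  if (!is.na(config@seed)) set.seed(config@seed)
  gens <- config@generations
  bnGen <- vapply(config@bottlenecks, function(b) b@generation, numeric(1))
  bnProfiles <- lapply(config@bottlenecks, function(b) b@resetProfile@counts)

  nrec <- gens + 1L
  cnt <- matrix(0, nrow = nrec, ncol = 3L)
  fA <- numeric(nrec)
  x2 <- numeric(nrec)

  k <- config@initial@counts
  cnt[1L, ] <- k
  fA[1L] <- .afreq(k)
  x2[1L] <- .chisq(k)
  if (gens >= 1) {
    for (g in seq_len(gens)) {
      k <- tryCatch(.advance(k, config), error = function(e)
        stop(sprintf("generation %d: %s", g, conditionMessage(e)),
             call. = FALSE))
      cnt[g + 1L, ] <- k
      fA[g + 1L] <- .afreq(k)
      x2[g + 1L] <- .chisq(k)
      hit <- which(bnGen == g)
      if (length(hit)) k <- bnProfiles[[hit[1L]]]
    }
  }
  rec <- data.frame(generation = 0:gens, n_AA = cnt[, 1L], n_Aa = cnt[, 2L],
                    n_aa = cnt[, 3L], f_A = fA, f_a = 1 - fA, chi2 = x2)
  new("Trajectory", records = rec, config = config, seed = config@seed)
})

#' Allele-frequency time series of a trajectory
#'
#' @param x a \code{\link{Trajectory}}.
#' @param allele \code{"a"} (default, the series analysed by
#'   \code{\link{autocorrelation}}) or \code{"A"}.
#' @return Numeric vector of length \code{generations + 1}.
#' @export
alleleFreqSeries <- function(x, allele = c("a", "A")) {
  allele <- match.arg(allele)
  if (allele == "a") x@records$f_a else x@records$f_A
}

#' Configuration stored with a simulation product
#'
#' @param x a \code{\link{Trajectory}} or \code{\link{EnsembleResult}}.
#' @return The \code{\link{SimulationConfig}} or \code{\link{EnsembleConfig}}
#'   the object was produced from.
#' @export
simConfig <- function(x) x@config
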