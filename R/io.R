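## Serialization: TSV tables for trajectories / ensemble values / ACFs
## (header row, 10 significant digits), JSON for configurations, sidecars
## and summaries. Data go to files; logs belong to the caller.

.fmtNum <- function(x) sprintf("%.10g", x)

## ---- configuration <-> list (JSON shape) ----------------------------------

.countsToList <- function(gc) as.list(gc@counts)

.listToCounts <- function(l, field) {
  need <- .GENOTYPES
  if (!is.list(l) && !(is.numeric(l) && !is.null(names(l))))
    stop(sprintf("config field '%s' must be an object with AA, Aa, aa", field))
  l <- as.list(l)
  unknown <- setdiff(names(l), need)
  if (length(unknown))
    stop(sprintf("config field '%s': unknown keys %s", field,
                 paste(unknown, collapse = ", ")))
  if (!all(need %in% names(l)))
    stop(sprintf("config field '%s' must name all of AA, Aa, aa", field))
  GenotypeCounts(as.numeric(l$AA), as.numeric(l$Aa), as.numeric(l$aa))
}

#' Configuration as a plain list (the JSON schema)
#'
#' @param config a \code{\link{SimulationConfig}} or
#'   \code{\link{EnsembleConfig}}.
#' @return A list mirroring the JSON configuration schema accepted by
#'   \code{\link{loadConfig}}.
#' @export
configToList <- function(config) {
  if (is(config, "EnsembleConfig")) {
    out <- list(schema = "hwpopsim-ensemble-1",
                base = configToList(config@base),
                replicates = config@replicates,
                observeAt = config@observeAt)
    if (!is.na(config@sampleSize)) out$sampleSize <- config@sampleSize
    return(out)
  }
  stopifnot(is(config, "SimulationConfig"))
  out <- list(schema = "hwpopsim-simulation-1",
              initial = .countsToList(config@initial),
              capacity = config@capacity)
  if (!is.na(config@reproducingCount))
    out$reproducingCount <- config@reproducingCount
  else
    out$reproducingFraction <- config@reproducingFraction
  r <- config@reproduction
  out$reproduction <- if (r@mode == "deterministic")
    list(mode = "deterministic", fixedCount = r@fixedCount)
  else list(mode = "stochastic", countProbs = r@countProbs)
  m <- config@mating
  out$mating <- if (m@mode == "random") list(mode = "random")
                else list(mode = "fixed", classProbs = as.list(m@classProbs))
  out$generations <- config@generations
  if (length(config@bottlenecks))
    out$bottlenecks <- lapply(config@bottlenecks, function(b)
      list(generation = b@generation,
           resetProfile = .countsToList(b@resetProfile)))
  if (!is.na(config@seed)) out$seed <- config@seed
  if (config@poolThreshold != 1e5) out$poolThreshold <- config@poolThreshold
  out
}

.checkKeys <- function(l, allowed, where) {
  unknown <- setdiff(names(l), allowed)
  if (length(unknown))
    stop(sprintf("%s: unknown config keys: %s", where,
                 paste(unknown, collapse = ", ")))
}

.num1 <- function(l, field, where, default = NULL) {
  if (is.null(l[[field]])) {
    if (!is.null(default)) return(default)
    stop(sprintf("%s: required field '%s' is missing", where, field))
  }
  v <- l[[field]]
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop(sprintf("%s: field '%s' must be a single finite number", where, field))
  v
}

.listToSimConfig <- function(l, where = "simulation config") {
  .checkKeys(l, c("schema", "initial", "capacity", "reproducingCount",
                  "reproducingFraction", "reproduction", "mating",
                  "generations", "bottlenecks", "seed", "poolThreshold"),
             where)
  if (is.null(l$initial))
    stop(sprintf("%s: required field 'initial' is missing", where))
  initial <- .listToCounts(l$initial, "initial")
  capacity <- .num1(l, "capacity", where)

  repro <- ReproductionSpec("deterministic", 4)
  if (!is.null(l$reproduction)) {
    r <- l$reproduction
    .checkKeys(r, c("mode", "fixedCount", "countProbs"), "reproduction")
    mode <- r$mode
    if (is.null(mode) || !mode %in% c("deterministic", "stochastic"))
      stop("reproduction: field 'mode' must be \"deterministic\" or \"stochastic\"")
    repro <- if (mode == "deterministic")
      ReproductionSpec("deterministic", .num1(r, "fixedCount", "reproduction"))
    else ReproductionSpec("stochastic", countProbs = as.numeric(r$countProbs))
  }

  mating <- randomMating()
  if (!is.null(l$mating)) {
    m <- l$mating
    .checkKeys(m, c("mode", "classProbs"), "mating")
    if (is.null(m$mode) || !m$mode %in% c("random", "fixed"))
      stop("mating: field 'mode' must be \"random\" or \"fixed\"")
    mating <- if (m$mode == "random") randomMating()
              else fixedClassMating(unlist(m$classProbs))
  }

  bottlenecks <- list()
  if (!is.null(l$bottlenecks)) {
    if (is.data.frame(l$bottlenecks))
      l$bottlenecks <- split(l$bottlenecks, seq_len(nrow(l$bottlenecks)))
    bottlenecks <- lapply(l$bottlenecks, function(b) {
      b <- as.list(b)
      .checkKeys(b, c("generation", "resetProfile"), "bottleneck")
      BottleneckEvent(.num1(b, "generation", "bottleneck"),
                      .listToCounts(if (is.data.frame(b$resetProfile))
                        as.list(b$resetProfile) else b$resetProfile,
                        "resetProfile"))
    })
  }

  tryCatch(
    SimulationConfig(
      initial = initial, capacity = capacity,
      reproducingCount = if (is.null(l$reproducingCount)) NA_real_
                         else .num1(l, "reproducingCount", where),
      reproducingFraction = if (is.null(l$reproducingFraction)) NA_real_
                            else .num1(l, "reproducingFraction", where),
      reproduction = repro, mating = mating,
      generations = .num1(l, "generations", where, default = 0),
      bottlenecks = bottlenecks,
      seed = if (is.null(l$seed)) NA_real_ else .num1(l, "seed", where),
      poolThreshold = .num1(l, "poolThreshold", where, default = 1e5)),
    error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e)),
                             call. = FALSE))
}

#' Load a simulation or ensemble configuration from JSON
#'
#' Reads a JSON configuration document (the schema written by
#' \code{\link{configToList}} / \code{\link{writeConfigJSON}}), fills
#' documented defaults, validates every field and rejects unknown keys. A
#' document containing a \code{replicates} field (or \code{base} object) is
#' an ensemble configuration; anything else is a plain simulation.
#'
#' @param path path of a JSON file.
#' @return A \code{\link{SimulationConfig}} or \code{\link{EnsembleConfig}}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path))
  l <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(l$replicates) || !is.null(l$base)) {
    .checkKeys(l, c("schema", "base", "replicates", "observeAt", "sampleSize"),
               "ensemble config")
    if (is.null(l$base))
      stop("ensemble config: required field 'base' is missing")
    base <- .listToSimConfig(l$base, "ensemble config: base")
    tryCatch(
      EnsembleConfig(base,
                     replicates = .num1(l, "replicates", "ensemble config"),
                     observeAt = .num1(l, "observeAt", "ensemble config",
                                       default = 30),
                     sampleSize = if (is.null(l$sampleSize)) NA_real_
                                  else .num1(l, "sampleSize", "ensemble config")),
      error = function(e) stop(sprintf("ensemble config: %s",
                                       conditionMessage(e)), call. = FALSE))
  } else {
    .listToSimConfig(l)
  }
}

#' Write a configuration as JSON
#'
#' @param config a \code{\link{SimulationConfig}} or
#'   \code{\link{EnsembleConfig}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeConfigJSON <- function(config, path) {
  jsonlite::write_json(configToList(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- trajectory -----------------------------------------------------------

#' Write / read a trajectory table
#'
#' The trajectory is serialized as TSV with header
#' \code{generation n_AA n_Aa n_aa f_A f_a chi2}, one row per generation
#' (t = 0 included), floating-point columns at 10 significant digits. With
#' \code{sidecar = TRUE} the configuration (seed included) is written next
#' to it as \code{<path>.json}.
#'
#' @param traj a \code{\link{Trajectory}}.
#' @param path output TSV path.
#' @param sidecar write the JSON configuration sidecar (default TRUE).
#' @return \code{writeTrajectory}: \code{path}, invisibly;
#'   \code{readTrajectory}: the records as a data frame.
#' @export
writeTrajectory <- function(traj, path, sidecar = TRUE) {
  r <- traj@records
  out <- data.frame(generation = as.integer(r$generation),
                    n_AA = .fmtNum(r$n_AA), n_Aa = .fmtNum(r$n_Aa),
                    n_aa = .fmtNum(r$n_aa), f_A = .fmtNum(r$f_A),
                    f_a = .fmtNum(r$f_a), chi2 = .fmtNum(r$chi2))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    cfg <- configToList(traj@config)
    if (!is.na(traj@seed)) cfg$seed <- traj@seed
    jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = "numeric")
  need <- c("generation", "n_AA", "n_Aa", "n_aa", "f_A", "f_a", "chi2")
  if (!identical(colnames(d), need))
    stop(sprintf("not a trajectory table: expected columns %s",
                 paste(need, collapse = ", ")))
  d
}

## ---- ensemble -------------------------------------------------------------

#' Write / read ensemble chi-square values
#'
#' Values are serialized as a single-column TSV with header \code{chi2}, 10
#' significant digits. \code{writeEnsembleSummary} writes the companion JSON
#' summary: replicate count, observation generation, threshold, tail
#' probabilities with standard error, the exponential tail fit and the
#' configuration echo.
#'
#' @param result an \code{\link{EnsembleResult}}.
#' @param path output path.
#' @param threshold chi-square threshold used in the summary; defaults to
#'   the 0.05 critical value.
#' @param xMin tail-fit cutoff passed to \code{\link{fitExponentialTail}};
#'   the fit is omitted from the summary when it fails.
#' @return The written \code{path} (invisibly); \code{readEnsemble} returns
#'   the numeric chi-square values.
#' @export
writeEnsemble <- function(result, path) {
  write.table(data.frame(chi2 = .fmtNum(result@chi2Values)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnsemble
#' @export
readEnsemble <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", colClasses = "numeric")
  if (!identical(colnames(d), "chi2"))
    stop("not an ensemble table: expected the single column 'chi2'")
  d$chi2
}

#' @rdname writeEnsemble
#' @export
writeEnsembleSummary <- function(result, path,
                                 threshold = chiSquareCriticalValue(0.05, 1),
                                 xMin = 0.4) {
  above <- estimateTailProbability(result, threshold, "above")
  below <- estimateTailProbability(result, threshold, "below")
  fit <- tryCatch(fitExponentialTail(result, xMin), error = function(e) NULL)
  s <- list(L = length(result@chi2Values),
            observeAt = result@config@observeAt,
            threshold = threshold,
            pAbove = above$probability,
            pBelow = below$probability,
            stdError = above$stdError,
            tailFit = if (is.null(fit)) NULL
                      else list(xMin = fit$xMin, rate = fit$rate,
                                r2 = fit$goodness),
            seed = if (is.na(result@seed)) NULL else result@seed,
            config = configToList(result@config))
  jsonlite::write_json(s[!vapply(s, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- autocorrelation ------------------------------------------------------

#' Write / read an autocorrelation table
#'
#' TSV with header \code{lag C}. \code{writeAcfSummary} writes the decay
#' fit and classification as JSON (\code{rate}, \code{relaxation_time},
#' \code{goodness}, \code{crossing_lag}, \code{label}, \code{noise_band}).
#'
#' @param acf an \code{\link{AcfResult}}.
#' @param path output path.
#' @param fit,classification optional precomputed results of
#'   \code{\link{fitExponentialDecay}} / \code{\link{classifyDynamics}}.
#' @return The written \code{path} (invisibly); \code{readAcf} returns a
#'   data frame with columns \code{lag} and \code{C}.
#' @export
writeAcf <- function(acf, path) {
  write.table(data.frame(lag = as.integer(acf@lags), C = .fmtNum(acf@values)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAcf
#' @export
readAcf <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", colClasses = "numeric")
  if (!identical(colnames(d), c("lag", "C")))
    stop("not an autocorrelation table: expected columns 'lag' and 'C'")
  d
}

#' @rdname writeAcf
#' @export
writeAcfSummary <- function(acf, path, fit = NULL, classification = NULL) {
  if (is.null(fit))
    fit <- tryCatch(fitExponentialDecay(acf), error = function(e) NULL)
  if (is.null(classification))
    classification <- classifyDynamics(acf, fit)
  s <- list(rate = if (is.null(fit)) NULL else fit$rate,
            relaxation_time = if (is.null(fit)) NULL else fit$relaxationTime,
            goodness = if (is.null(fit)) NULL else fit$goodness,
            crossing_lag = if (is.na(classification$crossingLag)) NULL
                           else classification$crossingLag,
            label = classification$label,
            noise_band = acf@noiseBand,
            series_length = acf@seriesLength)
  jsonlite::write_json(s[!vapply(s, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
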