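## Independent brute-force oracles used by the property tests. These
## deliberately re-derive the model from first principles (explicit
## enumeration over ordered draws and pairings) and share no code with the
## package internals.

## Mendelian segregation table, re-stated independently: probability that a
## couple of (sorted) genotypes produces each offspring genotype.
oracleSegregation <- function(g1, g2) {
  pA <- function(g) switch(g, AA = 1, Aa = 0.5, aa = 0)
  p <- pA(g1)
  q <- pA(g2)
  c(AA = p * q, Aa = p * (1 - q) + q * (1 - p), aa = (1 - p) * (1 - q))
}

## Couple-type key of an ordered pool (consecutive pairing), as "g1|g2"
## with the pair sorted alphabetically-by-genotype-order.
oracleCoupleKey <- function(seqIdx) {
  g <- c("AA", "Aa", "aa")
  keys <- character(0)
  for (i in seq(1, length(seqIdx), by = 2)) {
    pair <- sort(seqIdx[i:(i + 1)])
    keys <- c(keys, paste(g[pair[1]], g[pair[2]], sep = "|"))
  }
  paste(sort(keys), collapse = ";")
}

## Exact distribution over couple-type multisets for a sequential draw of n
## individuals without replacement. probs = NULL is random mating (each
## remaining individual equiprobable, i.e. class probability proportional to
## its remaining count); otherwise fixed class probabilities renormalized
## over non-empty classes.
oraclePoolDist <- function(counts, n, probs = NULL) {
  tab <- new.env(parent = emptyenv())
  rec <- function(rem, seqIdx, p) {
    if (length(seqIdx) == n) {
      key <- oracleCoupleKey(seqIdx)
      prev <- if (is.null(tab[[key]])) 0 else tab[[key]]
      tab[[key]] <- prev + p
      return(invisible(NULL))
    }
    pr <- if (is.null(probs)) rem / sum(rem) else {
      w <- probs * (rem > 0)
      w / sum(w)
    }
    for (j in which(pr > 0)) {
      rem2 <- rem
      rem2[j] <- rem2[j] - 1
      rec(rem2, c(seqIdx, j), p * pr[j])
    }
  }
  rec(counts, integer(0), 1)
  as.list(tab)
}

## Exact one-generation outcome distribution (offspring genotype triple) for
## a tiny population: enumerate pools/pairings, then convolve the per-couple
## offspring multinomials; 'kids' offspring per couple, no culling.
oracleGenerationDist <- function(counts, n, kids, probs = NULL) {
  poolDist <- oraclePoolDist(counts, n, probs)
  out <- new.env(parent = emptyenv())
  addOutcome <- function(key, p) {
    prev <- if (is.null(out[[key]])) 0 else out[[key]]
    out[[key]] <- prev + p
  }
  enumOffspring <- function(coupleKeys, idx, acc, p) {
    if (idx > length(coupleKeys)) {
      addOutcome(paste(acc, collapse = ","), p)
      return(invisible(NULL))
    }
    gs <- strsplit(coupleKeys[idx], "|", fixed = TRUE)[[1]]
    seg <- oracleSegregation(gs[1], gs[2])
    ## all compositions of 'kids' offspring over the three genotypes
    for (a in 0:kids) for (b in 0:(kids - a)) {
      cc <- kids - a - b
      pr <- stats::dmultinom(c(a, b, cc), prob = seg)
      if (pr > 0)
        enumOffspring(coupleKeys, idx + 1, acc + c(a, b, cc), p * pr)
    }
  }
  for (key in names(poolDist)) {
    coupleKeys <- strsplit(key, ";", fixed = TRUE)[[1]]
    enumOffspring(coupleKeys, 1, c(0, 0, 0), poolDist[[key]])
  }
  as.list(out)
}

## total-variation distance between a named probability list and a table of
## observed frequencies (both keyed the same way)
oracleTV <- function(exact, observedCounts) {
  nTot <- sum(observedCounts)
  keys <- union(names(exact), names(observedCounts))
  tv <- 0
  for (k in keys) {
    pe <- if (is.null(exact[[k]])) 0 else exact[[k]]
    po <- if (is.na(observedCounts[k])) 0 else observedCounts[k] / nTot
    tv <- tv + abs(pe - po)
  }
  tv / 2
}
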