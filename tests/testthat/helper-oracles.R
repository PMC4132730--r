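# Independent oracles used across the test suite. These deliberately use a
# different formulation from the package internals: each spore molecule is
# followed individually along the bivalent, jumping to the partner
# chromatid at every crossover that involves the chromatid it currently
# rides.

# Alleles (4 spores x 3 markers) implied by a set of resolved crossover
# events for ONE meiosis, by per-molecule path following.
oracleTetradAlleles <- function(events, markers,
                                hap = rbind(c(TRUE, TRUE, TRUE),
                                            c(FALSE, FALSE, FALSE))) {
  events <- events[order(events$position), , drop = FALSE]
  al <- matrix(NA, 4L, 3L)
  for (mol in 1:4) {
    cur <- mol
    ei <- 1L
    for (m in seq_along(markers)) {
      while (ei <= nrow(events) && events$position[ei] < markers[m]) {
        a <- events$chromatidM[ei]
        b <- events$chromatidP[ei] + 2L
        if (cur == a) cur <- b else if (cur == b) cur <- a
        ei <- ei + 1L
      }
      al[mol, m] <- if (cur <= 2L) hap[1L, m] else hap[2L, m]
    }
  }
  al
}

# Tetrad class of one interval implied by chromatid tracing: the number of
# spore molecules whose origin differs between the two flanking markers
# (0 -> PD, 2 -> TT, 4 -> NPD).
oracleIntervalClass <- function(events, markers) {
  al <- oracleTetradAlleles(events, markers)
  nRec <- sum(al[, 1L] != al[, 2L])
  c(`0` = "PD", `2` = "TT", `4` = "NPD")[[as.character(nRec)]]
}

# Exact PD/TT/NPD probabilities for an interval carrying exactly k
# crossovers with uniform, independent chromatid choice: enumerate all 4^k
# ordered chromatid assignments.
oracleClassGivenK <- function(k) {
  if (k == 0L) return(c(PD = 1, TT = 0, NPD = 0))
  pairs <- expand.grid(a = 1:2, b = 1:2)
  idx <- expand.grid(rep(list(seq_len(4L)), k))
  tallies <- c(PD = 0, TT = 0, NPD = 0)
  for (r in seq_len(nrow(idx))) {
    ev <- data.frame(position = seq_len(k) / (k + 1),
                     chromatidM = pairs$a[unlist(idx[r, ])],
                     chromatidP = pairs$b[unlist(idx[r, ])])
    cls <- oracleIntervalClass(ev, markers = c(0, 1))
    tallies[cls] <- tallies[cls] + 1
  }
  tallies / 4^k
}

# Exact class probabilities of an interval of genetic length d Morgans
# under Poisson crossover placement (bivalent mean 2 d), truncated at
# kMax events (tail negligible for small d).
oracleClassPoisson <- function(d, kMax = 4L) {
  y <- 2 * d
  probs <- vapply(0:kMax, oracleClassGivenK, numeric(3))
  w <- dpois(0:kMax, y)
  p <- probs %*% w / sum(w)
  c(PD = p[1L], TT = p[2L], NPD = p[3L])
}

# Naive two-locus classifier from spore patterns, written independently of
# the package (string multisets).
naiveIntervalClass <- function(sporeMat, parental) {
  g <- paste0(sporeMat[, 1L] + 0L, sporeMat[, 2L] + 0L)
  par <- paste0(parental[, 1L] + 0L, parental[, 2L] + 0L)
  rec <- setdiff(c("00", "01", "10", "11"), par)
  tab <- table(factor(g, levels = c("00", "01", "10", "11")))
  if (all(tab[par] == 2L) && all(tab[rec] == 0L)) return("PD")
  if (all(tab[rec] == 2L) && all(tab[par] == 0L)) return("NPD")
  if (all(tab == 1L)) return("TT")
  NA_character_
}

# Build a TetradSet from an explicit list of 4 x 3 allele matrices.
makeTetradSet <- function(alleleList, phase = "coupling") {
  arr <- array(NA, dim = c(4L, 3L, length(alleleList)))
  for (i in seq_along(alleleList)) arr[, , i] <- alleleList[[i]]
  new("TetradSet", alleles = arr, meiosisId = seq_along(alleleList),
      markerPhase = phase)
}

# Spore rows for a given two-locus pattern in markers (i, j), with the
# third marker filled 2:2 parental.
sporesFromPairs <- function(pairs, markers = c(1L, 2L)) {
  al <- matrix(NA, 4L, 3L)
  other <- setdiff(1:3, markers)
  al[, markers[1L]] <- pairs[, 1L]
  al[, markers[2L]] <- pairs[, 2L]
  al[, other] <- c(TRUE, TRUE, FALSE, FALSE)
  al
}
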