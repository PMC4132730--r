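## PD/TT/NPD classification of three-marker tetrads.
##
## Each interval is classified from its two flanking markers only: reduce
## each spore to the two-locus genotype, then
##   PD  <=> both parental genotypes, twice each
##   NPD <=> both recombinant genotypes, twice each
##   TT  <=> all four genotypes once each
## Any other multiset is non-Mendelian (scoring noise); tetrads with an
## unscorable spore (NA channel) or a non-Mendelian pattern are excluded.

# Interval -> flanking marker columns.
.intervalMarkers <- function(interval) {
  if (is.character(interval)) {
    interval <- match(interval, c("I2a", "I2b"))
    if (is.na(interval)) stop("unknown interval; use 1/2 or 'I2a'/'I2b'")
  }
  interval <- as.integer(interval)
  if (!interval %in% c(1L, 2L)) stop("interval must be 1 or 2")
  c(interval, interval + 1L)
}

# Factor of PD/TT/NPD with NA for unscorable or non-Mendelian tetrads.
.intervalTypes <- function(alleles, markers, phase) {
  hap <- .parentalHaplotypes(phase)
  g <- 2L * alleles[, markers[1L], ] + alleles[, markers[2L], ]  # 4 x n
  g <- matrix(g, nrow = 4L)
  par1 <- 2L * hap[1L, markers[1L]] + hap[1L, markers[2L]]
  par2 <- 2L * hap[2L, markers[1L]] + hap[2L, markers[2L]]
  rec <- setdiff(0:3, c(par1, par2))
  nNA <- colSums(is.na(g))
  cnt <- function(v) colSums(g == v, na.rm = TRUE)
  nP1 <- cnt(par1); nP2 <- cnt(par2)
  nR1 <- cnt(rec[1L]); nR2 <- cnt(rec[2L])
  type <- rep(NA_character_, ncol(g))
  ok <- nNA == 0L
  type[ok & nP1 == 2L & nP2 == 2L] <- "PD"
  type[ok & nR1 == 2L & nR2 == 2L] <- "NPD"
  type[ok & nP1 == 1L & nP2 == 1L & nR1 == 1L & nR2 == 1L] <- "TT"
  factor(type, levels = .TYPES)
}

#' Classify one interval of each tetrad as PD, TT or NPD
#'
#' Reduces each spore to its two-locus genotype at the interval's flanking
#' markers and classifies the multiset: parental ditype (PD, only the two
#' parental genotypes, 2:2), non-parental ditype (NPD, only the two
#' recombinant genotypes, 2:2) or tetratype (TT, all four genotypes).
#' Parental genotypes are defined by the declared marker phase. Tetrads
#' with an unscorable spore or a non-2:2 multiset are `NA`.
#'
#' @param x a [TetradSet-class].
#' @param interval `1`/`2` or `"I2a"`/`"I2b"`.
#' @param ... unused.
#' @return Factor of length `nTetrads(x)` with levels PD, TT, NPD.
#' @examples
#' tet <- simulateTetrads(simulationConfig(nMeioses = 20, seed = 2))
#' table(intervalType(tet, "I2a"))
#' @rdname intervalType
#' @export
setMethod("intervalType", "TetradSet", function(x, interval, ...) {
  .intervalTypes(x@alleles, .intervalMarkers(interval), x@markerPhase)
})

#' Classify both intervals of every tetrad
#'
#' @param x a [TetradSet-class].
#' @param ... unused.
#' @return A data.frame with columns `meiosisId`, `I2a`, `I2b` (factors
#'   PD/TT/NPD, `NA` when unscorable or non-Mendelian).
#' @examples
#' tet <- simulateTetrads(simulationConfig(nMeioses = 10, seed = 2))
#' classifyTetrads(tet)
#' @rdname classifyTetrads
#' @export
setMethod("classifyTetrads", "TetradSet", function(x, ...) {
  data.frame(meiosisId = x@meiosisId,
             I2a = intervalType(x, 1L),
             I2b = intervalType(x, 2L))
})

#' Tally tetrads into the nine joint interval classes
#'
#' Counts the joint (interval 1 type, interval 2 type) categories over all
#' scorable tetrads. Tetrads with an unscorable spore or a non-Mendelian
#' (non-2:2) pattern in either interval are excluded entirely and counted
#' in `nExcluded()`; non-Mendelian patterns additionally raise a warning.
#'
#' @param x a [TetradSet-class].
#' @param intervals names for the two intervals.
#' @param ... unused.
#' @return A [TetradClassCounts-class].
#' @examples
#' tallyTetrads(simulateTetrads(simulationConfig(nMeioses = 200, seed = 5)))
#' @rdname tallyTetrads
#' @export
setMethod("tallyTetrads", "TetradSet",
          function(x, intervals = c("I2a", "I2b"), ...) {
  cls <- classifyTetrads(x)
  keep <- !is.na(cls$I2a) & !is.na(cls$I2b)
  nonMend <- .nonMendelianCount(x, cls)
  if (nonMend > 0L) {
    warning(nonMend, " tetrad(s) with non-Mendelian segregation excluded")
  }
  tab <- table(cls$I2a[keep], cls$I2b[keep])
  cm <- matrix(as.integer(tab), 3L, 3L, dimnames = list(.TYPES, .TYPES))
  new("TetradClassCounts",
      counts = cm,
      intervals = as.character(intervals),
      excluded = sum(!keep))
})

# Tetrads that are fully scorable yet fail 2:2 classification.
.nonMendelianCount <- function(x, cls) {
  scorable <- colSums(is.na(matrix(x@alleles, nrow = 4L * 3L))) == 0L
  sum(scorable & (is.na(cls$I2a) | is.na(cls$I2b)))
}

#' Construct joint class counts directly
#'
#' @param counts 3 x 3 matrix of joint counts (rows: first interval PD,
#'   TT, NPD; columns: second interval), or a length-9 vector in
#'   column-major order.
#' @param intervals names of the two intervals.
#' @param excluded number of excluded tetrads.
#' @return A [TetradClassCounts-class].
#' @examples
#' tetradClassCounts(matrix(c(700, 80, 2, 150, 60, 3, 3, 2, 0), 3, 3,
#'                          byrow = TRUE))
#' @export
tetradClassCounts <- function(counts, intervals = c("I2a", "I2b"),
                              excluded = 0L) {
  cm <- matrix(as.integer(counts), 3L, 3L, dimnames = list(.TYPES, .TYPES))
  new("TetradClassCounts", counts = cm,
      intervals = as.character(intervals), excluded = as.integer(excluded))
}

#' Marginal PD/TT/NPD counts of one interval
#'
#' @param x a [TetradClassCounts-class].
#' @param interval interval index or name.
#' @return Named integer(3) of PD, TT, NPD counts.
#' @export
marginalCounts <- function(x, interval) {
  stopifnot(is(x, "TetradClassCounts"))
  i <- if (is.character(interval)) match(interval, x@intervals)
       else as.integer(interval)
  if (is.na(i) || !i %in% c(1L, 2L)) stop("unknown interval: ", interval)
  m <- if (i == 1L) rowSums(x@counts) else colSums(x@counts)
  storage.mode(m) <- "integer"
  m
}
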