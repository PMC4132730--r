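#' Simulation configuration for the two-pathway crossover model
#'
#' Parameters of the crossover placement model used by [simulateTetrads()]
#' and [simulateMeiocytes()]. Class I crossovers are placed by a stationary
#' gamma-renewal process with shape `nu` (`nu = 1` is a Poisson process, no
#' interference; larger `nu` gives stronger positive interference) and mean
#' count `lambda1` per bivalent per meiosis. Class II crossovers are placed
#' by an independent homogeneous Poisson process with mean count `lambda2`.
#'
#' Positions are in Morgans on the genetic map. The map is calibrated so
#' that two crossovers per bivalent correspond to one Morgan; a marker
#' interval of length d Morgans therefore has a true Perkins distance of
#' 100 d cM exactly when `lambda1 + lambda2 = 2 * chromLength`.
#'
#' @slot markerPositions numeric(3), strictly increasing positions (Morgans)
#'   of the three marker loci on one chromosome.
#' @slot chromLength numeric(1), chromosome genetic length in Morgans.
#' @slot nu numeric(1) > 0, gamma-renewal shape for class I spacing.
#' @slot lambda1 numeric(1) >= 0, expected class I crossovers per bivalent.
#' @slot lambda2 numeric(1) >= 0, expected class II crossovers per bivalent.
#' @slot obligateCo logical(1); if TRUE, bivalents with no crossover are
#'   redrawn (rejection sampling) so every bivalent carries at least one.
#' @slot nChromPairs integer(1), chromosome pairs per meiocyte (5 for
#'   Arabidopsis).
#' @slot nMeioses integer(1), number of meioses to simulate.
#' @slot seed integer(1), RNG seed; fixed seed gives identical output.
#' @slot markerPhase "coupling" (all three transgenes on one homolog) or
#'   "repulsion" (middle marker on the opposite homolog).
#'
#' @seealso [simulationConfig()], [presetConfig()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    markerPositions = "numeric",
    chromLength     = "numeric",
    nu              = "numeric",
    lambda1         = "numeric",
    lambda2         = "numeric",
    obligateCo      = "logical",
    nChromPairs     = "integer",
    nMeioses        = "integer",
    seed            = "integer",
    markerPhase     = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  mp <- object@markerPositions
  if (length(mp) != 3L || anyNA(mp)) {
    msg <- c(msg, "markerPositions must be three non-missing values")
  } else {
    if (any(diff(mp) <= 0)) {
      msg <- c(msg, "markerPositions must be strictly increasing")
    }
    if (length(object@chromLength) == 1L && is.finite(object@chromLength) &&
        (mp[1L] < 0 || mp[3L] > object@chromLength)) {
      msg <- c(msg, "markerPositions must lie within [0, chromLength]")
    }
  }
  if (length(object@chromLength) != 1L || !is.finite(object@chromLength) ||
      object@chromLength <= 0) {
    msg <- c(msg, "chromLength must be a single positive number")
  }
  if (length(object@nu) != 1L || !is.finite(object@nu) || object@nu <= 0) {
    msg <- c(msg, "nu must be a single positive number")
  }
  for (lam in c("lambda1", "lambda2")) {
    v <- slot(object, lam)
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      msg <- c(msg, paste(lam, "must be a single finite non-negative number"))
    }
  }
  if (length(object@obligateCo) != 1L || is.na(object@obligateCo)) {
    msg <- c(msg, "obligateCo must be TRUE or FALSE")
  } else if (isTRUE(object@obligateCo) &&
             isTRUE(object@lambda1 + object@lambda2 <= 0)) {
    msg <- c(msg, "obligateCo requires lambda1 + lambda2 > 0")
  }
  if (length(object@nChromPairs) != 1L || is.na(object@nChromPairs) ||
      object@nChromPairs < 1L) {
    msg <- c(msg, "nChromPairs must be a positive integer")
  }
  if (length(object@nMeioses) != 1L || is.na(object@nMeioses) ||
      object@nMeioses < 1L) {
    msg <- c(msg, "nMeioses must be a positive integer")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "seed must be a single integer")
  }
  if (length(object@markerPhase) != 1L ||
      !object@markerPhase %in% c("coupling", "repulsion")) {
    msg <- c(msg, "markerPhase must be 'coupling' or 'repulsion'")
  }
  if (length(msg)) msg else TRUE
})

#' A set of simulated or ingested pollen tetrads
#'
#' Container for the atomic observations of tetrad analysis: for each
#' meiosis, the four spore genotypes over the three ordered marker loci.
#' Alleles are logical (fluorescence present/absent); `NA` marks an
#' unscorable channel. Simulated tetrads always satisfy 2:2 segregation at
#' every locus; ingested real data may not, and such tetrads are excluded
#' at classification time.
#'
#' @slot alleles logical array `4 x 3 x n` (spore x marker x tetrad).
#' @slot meiosisId integer(n), identifier of each meiosis.
#' @slot markerPhase declared parental phase, "coupling" or "repulsion".
#'
#' @seealso [simulateTetrads()], [readTetradTable()], [classifyTetrads()]
#' @exportClass TetradSet
setClass("TetradSet",
  slots = c(
    alleles     = "array",
    meiosisId   = "integer",
    markerPhase = "character"
  )
)

setValidity("TetradSet", function(object) {
  msg <- character()
  d <- dim(object@alleles)
  if (length(d) != 3L || d[1L] != 4L || d[2L] != 3L) {
    msg <- c(msg, "alleles must be a 4 x 3 x n array")
  } else if (d[3L] != length(object@meiosisId)) {
    msg <- c(msg, "length(meiosisId) must equal the number of tetrads")
  }
  if (!is.logical(object@alleles)) {
    msg <- c(msg, "alleles must be logical")
  }
  if (length(object@markerPhase) != 1L ||
      !object@markerPhase %in% c("coupling", "repulsion")) {
    msg <- c(msg, "markerPhase must be 'coupling' or 'repulsion'")
  }
  if (length(msg)) msg else TRUE
})

#' Joint tetrad class counts over two adjacent intervals
#'
#' The sufficient statistic for all map-distance and interference-ratio
#' computations: counts of the nine joint (interval 1 type, interval 2
#' type) categories with types PD, TT, NPD, plus the number of tetrads
#' excluded as unscorable or non-Mendelian.
#'
#' @slot counts 3 x 3 integer matrix; rows are the first interval's type,
#'   columns the second's, both ordered PD, TT, NPD.
#' @slot intervals character(2), names of the two intervals (default
#'   `c("I2a", "I2b")`, the adjacent chromosome 2 intervals of FTL I2ab).
#' @slot excluded integer(1), tetrads excluded from the tally.
#'
#' @seealso [tallyTetrads()], [readClassCounts()], [interferenceRatio()]
#' @exportClass TetradClassCounts
setClass("TetradClassCounts",
  slots = c(
    counts    = "matrix",
    intervals = "character",
    excluded  = "integer"
  )
)

.TYPES <- c("PD", "TT", "NPD")

setValidity("TetradClassCounts", function(object) {
  msg <- character()
  cm <- object@counts
  if (!identical(dim(cm), c(3L, 3L))) {
    msg <- c(msg, "counts must be a 3 x 3 matrix")
  } else {
    if (!identical(rownames(cm), .TYPES) || !identical(colnames(cm), .TYPES)) {
      msg <- c(msg, "counts dimnames must both be PD, TT, NPD in order")
    }
    if (anyNA(cm) || any(cm < 0) || any(cm != round(cm))) {
      msg <- c(msg, "counts must be non-negative integers")
    }
  }
  if (length(object@intervals) != 2L || anyNA(object@intervals) ||
      object@intervals[1L] == object@intervals[2L]) {
    msg <- c(msg, "intervals must be two distinct names")
  }
  if (length(object@excluded) != 1L || is.na(object@excluded) ||
      object@excluded < 0L) {
    msg <- c(msg, "excluded must be a single non-negative integer")
  }
  if (length(msg)) msg else TRUE
})

#' Perkins map-distance estimate
#'
#' A map distance in centiMorgans estimated from tetrad PD/TT/NPD counts
#' with the Perkins equation, together with its delta-method sampling
#' variance and the underlying counts.
#'
#' @slot cM numeric(1), estimated map distance in centiMorgans.
#' @slot var numeric(1), sampling variance of `cM` (multinomial delta
#'   method).
#' @slot n integer(1), number of scored tetrads.
#' @slot counts named integer(3), the PD, TT and NPD counts.
#' @slot interval character(1), interval label ("" if unnamed).
#'
#' @seealso [perkinsDistance()], [mapDistances()], [distanceZTest()]
#' @exportClass MapDistanceEstimate
setClass("MapDistanceEstimate",
  slots = c(
    cM       = "numeric",
    var      = "numeric",
    n        = "integer",
    counts   = "integer",
    interval = "character"
  )
)

setValidity("MapDistanceEstimate", function(object) {
  msg <- character()
  if (length(object@cM) != 1L || is.na(object@cM) || object@cM < 0) {
    msg <- c(msg, "cM must be a single non-negative number")
  }
  if (length(object@var) != 1L || is.na(object@var) || object@var < 0) {
    msg <- c(msg, "var must be a single non-negative number")
  }
  if (length(object@counts) != 3L || !identical(names(object@counts), .TYPES)) {
    msg <- c(msg, "counts must be named PD, TT, NPD")
  } else {
    if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
    if (sum(object@counts) != object@n) {
      msg <- c(msg, "PD + TT + NPD must equal n")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Interference-ratio estimate with test of no interference
#'
#' The interference ratio (IR) of a test interval conditioned on an
#' adjacent interval: the Perkins distance of the test interval among
#' tetrads recombinant (TT or NPD) in the conditioning interval, divided by
#' the distance among non-recombinant (PD) tetrads. IR = 1 under absence
#' of interference; IR near 0 indicates strong positive interference. The
#' Z statistic tests equality of the two stratified distances (H0: IR = 1).
#'
#' @slot dWithCO [MapDistanceEstimate-class] of the test interval among
#'   tetrads recombinant in the conditioning interval.
#' @slot dWithoutCO same among tetrads parental in the conditioning
#'   interval.
#' @slot IR numeric(1), `dWithCO` cM / `dWithoutCO` cM.
#' @slot z numeric(1), Z statistic for the distance difference.
#' @slot p numeric(1), two-sided normal p-value for H0: IR = 1.
#' @slot test,conditioning character(1), interval names.
#'
#' @seealso [interferenceRatio()]
#' @exportClass InterferenceResult
setClass("InterferenceResult",
  slots = c(
    dWithCO      = "MapDistanceEstimate",
    dWithoutCO   = "MapDistanceEstimate",
    IR           = "numeric",
    z            = "numeric",
    p            = "numeric",
    test         = "character",
    conditioning = "character"
  )
)

setValidity("InterferenceResult", function(object) {
  msg <- character()
  if (length(object@IR) != 1L || is.na(object@IR) || object@IR < 0) {
    msg <- c(msg, "IR must be a single non-negative number")
  }
  if (length(object@p) != 1L || is.na(object@p) ||
      object@p < 0 || object@p > 1) {
    msg <- c(msg, "p must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
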