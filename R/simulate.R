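## Two-pathway crossover simulator.
##
## Class I crossovers: stationary gamma-renewal process on the genetic map,
## shape nu, mean count lambda1 on [0, chromLength]. Class II crossovers:
## homogeneous Poisson process, mean count lambda2. The two point processes
## are superposed independently. Chromatid involvement is uniform and
## independent per event (no chromatid interference).

# Evaluate locally seeded code without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# First-event draw for a stationary gamma renewal process with shape nu and
# rate b: the equilibrium (stationary residual) distribution. For integer nu
# this is an equal-weight mixture of Gamma(j, b), j = 1..nu (exact). For
# non-integer nu the closed-form equilibrium CDF
#   Fe(x) = F(x; nu + 1, b) + (b x / nu) * (1 - F(x; nu, b))
# is inverted numerically on a fine grid.
.rEquilibriumGap <- function(n, nu, rate) {
  if (n == 0L) return(numeric())
  if (abs(nu - round(nu)) < 1e-8) {
    j <- sample.int(as.integer(round(nu)), n, replace = TRUE)
    return(rgamma(n, shape = j, rate = rate))
  }
  hi <- qgamma(1 - 1e-12, shape = nu + 1, rate = rate)
  xs <- seq(0, hi, length.out = 4096L)
  fe <- pgamma(xs, nu + 1, rate = rate) +
    (rate * xs / nu) * pgamma(xs, nu, rate = rate, lower.tail = FALSE)
  stats::approx(fe, xs, xout = runif(n), rule = 2)$y
}

# Events of one renewal/Poisson pathway for nMeioses independent bivalents.
# Returns list(meiosis, position), unsorted within meiosis for the Poisson
# pathway.
.drawClassI <- function(nMeioses, nu, lambda1, L) {
  if (lambda1 <= 0) return(list(meiosis = integer(), position = numeric()))
  rate <- nu * lambda1 / L
  cur <- .rEquilibriumGap(nMeioses, nu, rate)
  active <- which(cur <= L)
  mei <- vector("list", 0L)
  pos <- vector("list", 0L)
  while (length(active)) {
    mei[[length(mei) + 1L]] <- active
    pos[[length(pos) + 1L]] <- cur[active]
    cur[active] <- cur[active] +
      rgamma(length(active), shape = nu, rate = rate)
    active <- active[cur[active] <= L]
  }
  list(meiosis = unlist(mei, use.names = FALSE),
       position = unlist(pos, use.names = FALSE))
}

.drawClassII <- function(nMeioses, lambda2, L) {
  if (lambda2 <= 0) return(list(meiosis = integer(), position = numeric()))
  k <- rpois(nMeioses, lambda2)
  list(meiosis = rep.int(seq_len(nMeioses), k),
       position = runif(sum(k), 0, L))
}

.drawEvents <- function(config, nMeioses) {
  L <- config@chromLength
  c1 <- .drawClassI(nMeioses, config@nu, config@lambda1, L)
  c2 <- .drawClassII(nMeioses, config@lambda2, L)
  data.frame(
    meiosis  = c(c1$meiosis, c2$meiosis),
    position = c(c1$position, c2$position),
    pathway  = rep(c("class_I", "class_II"),
                   c(length(c1$meiosis), length(c2$meiosis))),
    stringsAsFactors = FALSE)
}

#' Place crossover events for a set of meioses
#'
#' Draws crossover positions for `nMeioses` independent bivalents under the
#' two-pathway model of `config`: class I events from a stationary
#' gamma-renewal process (shape `nu`, mean count `lambda1`), class II
#' events from a homogeneous Poisson process (mean count `lambda2`),
#' superposed. With `obligateCo = TRUE`, bivalents that drew no event are
#' redrawn until every bivalent has at least one (rejection sampling, i.e.
#' conditioning on >= 1 event).
#'
#' Uses the current RNG state; see [simulateTetrads()] for seeded runs.
#'
#' @param config a [SimulationConfig-class].
#' @param nMeioses number of bivalents to draw (default
#'   `config@nMeioses`).
#' @return A data.frame with one row per event, columns `meiosis`,
#'   `position` (Morgans) and `pathway` (`"class_I"` or `"class_II"`),
#'   sorted by meiosis then position.
#' @examples
#' set.seed(1)
#' placeCrossovers(simulationConfig(), nMeioses = 5)
#' @export
placeCrossovers <- function(config, nMeioses = config@nMeioses) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nMeioses <- as.integer(nMeioses)
  ev <- .drawEvents(config, nMeioses)
  if (config@obligateCo) {
    repeat {
      empty <- which(tabulate(ev$meiosis, nMeioses) == 0L)
      if (!length(empty)) break
      redo <- .drawEvents(config, length(empty))
      redo$meiosis <- empty[redo$meiosis]
      ev <- rbind(ev, redo)
    }
  }
  ev <- ev[order(ev$meiosis, ev$position), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Assign chromatids to crossover events
#'
#' Each crossover involves one of the two maternal and one of the two
#' paternal chromatids, chosen uniformly and independently per event (no
#' chromatid interference, no sister exchange).
#'
#' @param events event data.frame from [placeCrossovers()].
#' @return `events` with integer columns `chromatidM` and `chromatidP`
#'   (each 1 or 2).
#' @examples
#' set.seed(1)
#' resolveChromatids(placeCrossovers(simulationConfig(), nMeioses = 5))
#' @export
resolveChromatids <- function(events) {
  n <- nrow(events)
  events$chromatidM <- sample.int(2L, n, replace = TRUE)
  events$chromatidP <- sample.int(2L, n, replace = TRUE)
  events
}

.parentalHaplotypes <- function(phase) {
  top <- if (phase == "coupling") c(TRUE, TRUE, TRUE)
         else c(TRUE, FALSE, TRUE)
  rbind(top, !top)
}

#' Trace chromatids through crossovers and emit tetrads
#'
#' Given resolved crossover events for `nMeioses` meioses, traces the four
#' chromatids (two maternal carrying the phase-determined transgenic
#' alleles, two paternal) through the ordered exchange points and reads
#' each spore's allele at every marker locus.
#'
#' @param config a [SimulationConfig-class] (marker positions and phase).
#' @param events resolved events from [resolveChromatids()], sorted by
#'   meiosis then position.
#' @param nMeioses number of meioses represented (default
#'   `config@nMeioses`).
#' @return A [TetradSet-class] of `nMeioses` tetrads.
#' @examples
#' cfg <- simulationConfig(nMeioses = 3)
#' set.seed(1)
#' ev <- resolveChromatids(placeCrossovers(cfg))
#' generateTetrads(cfg, ev)
#' @export
generateTetrads <- function(config, events, nMeioses = config@nMeioses) {
  stopifnot(is(config, "SimulationConfig"))
  nMeioses <- as.integer(nMeioses)
  if (nrow(events) > 0) {
    if (is.unsorted(events$meiosis) ||
        any(diff(events$position)[diff(events$meiosis) == 0L] < 0)) {
      stop("events must be sorted by meiosis then position")
    }
    if (is.null(events$chromatidM) || is.null(events$chromatidP)) {
      stop("events must carry chromatid assignments; see resolveChromatids()")
    }
  }
  hap <- .parentalHaplotypes(config@markerPhase)
  counts <- tabulate(events$meiosis, nMeioses)
  maxk <- if (length(counts)) max(counts) else 0L
  # Padded per-meiosis event matrices: position, maternal chromatid (1-2),
  # paternal chromatid (3-4). Inf padding means "never before any marker".
  POS <- matrix(Inf, nMeioses, max(maxk, 1L))
  A <- B <- matrix(1L, nMeioses, max(maxk, 1L))
  if (nrow(events) > 0) {
    idx <- cbind(events$meiosis, sequence(counts[counts > 0L]))
    POS[idx] <- events$position
    A[idx] <- events$chromatidM
    B[idx] <- events$chromatidP + 2L
  }
  # Chromatids 1-2 are the maternal sisters, 3-4 the paternal sisters.
  # Each of the four spore DNA molecules starts on its own chromatid; a
  # crossover between chromatids (a, b) makes the molecules currently
  # riding a and b exchange chromatids from that point on. A spore's
  # allele at a marker is the allele of the chromatid its molecule rides
  # there. R[i, c] tracks which molecule rides chromatid c of meiosis i.
  alleles <- array(NA, dim = c(4L, 3L, nMeioses))
  rows <- seq_len(nMeioses)
  for (m in seq_len(3L)) {
    pm <- config@markerPositions[m]
    R <- matrix(rep(1:4, each = nMeioses), nMeioses, 4L)
    for (j in seq_len(maxk)) {
      act <- which(POS[, j] < pm)
      if (!length(act)) next
      ia <- cbind(act, A[act, j])
      ib <- cbind(act, B[act, j])
      tmp <- R[ia]
      R[ia] <- R[ib]
      R[ib] <- tmp
    }
    chromAllele <- c(hap[1L, m], hap[1L, m], hap[2L, m], hap[2L, m])
    am <- matrix(NA, nMeioses, 4L)
    for (cc in 1:4) {
      am[cbind(rows, R[, cc])] <- chromAllele[cc]
    }
    alleles[, m, ] <- t(am)
  }
  new("TetradSet",
      alleles     = alleles,
      meiosisId   = seq_len(nMeioses),
      markerPhase = config@markerPhase)
}

#' Simulate a population of pollen tetrads
#'
#' Runs the full chain [placeCrossovers()] -> [resolveChromatids()] ->
#' [generateTetrads()] for `config@nMeioses` meioses under the seed stored
#' in the configuration. Output is deterministic given the configuration
#' and leaves the caller's RNG state untouched.
#'
#' @param config a [SimulationConfig-class].
#' @return A [TetradSet-class].
#' @examples
#' tet <- simulateTetrads(simulationConfig(nMeioses = 100, seed = 42))
#' tallyTetrads(tet)
#' @export
simulateTetrads <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    ev <- placeCrossovers(config, config@nMeioses)
    ev <- resolveChromatids(ev)
    generateTetrads(config, ev, config@nMeioses)
  })
}

#' Simulate metaphase-I meiocyte outcomes
#'
#' For each meiosis, draws crossover events independently on each of
#' `config@nChromPairs` chromosome pairs; a pair with at least one
#' crossover forms a bivalent at metaphase I, a pair with none appears as
#' a pair of univalents. With `obligateCo = TRUE` every pair is guaranteed
#' a crossover, so every meiocyte shows `nChromPairs` bivalents.
#'
#' @param config a [SimulationConfig-class].
#' @return A data.frame with one row per meiocyte: `meiocyte`,
#'   `bivalents`, `univalentPairs` (summing to `nChromPairs`).
#' @examples
#' head(simulateMeiocytes(presetConfig("zmm", nMeioses = 20, seed = 3)))
#' @export
simulateMeiocytes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, {
    nPairs <- config@nChromPairs
    nTot <- config@nMeioses * nPairs
    ev <- placeCrossovers(config, nTot)
    hasCO <- tabulate(ev$meiosis, nTot) > 0L
    biv <- colSums(matrix(hasCO, nrow = nPairs))
    data.frame(meiocyte = seq_len(config@nMeioses),
               bivalents = as.integer(biv),
               univalentPairs = as.integer(nPairs - biv))
  })
}
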