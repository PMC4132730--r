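#' Perkins map distance from tetrad counts
#'
#' Estimates the genetic distance between two markers from tetrad PD/TT/NPD
#' counts with the Perkins equation,
#' \deqn{\hat d = 100 \, (TT/2 + 3\,NPD) / n \quad \mathrm{cM},}
#' which corrects for double crossovers through the NPD class. The
#' sampling variance is obtained by the multinomial delta method: with
#' \eqn{t = TT/n} and \eqn{q = NPD/n},
#' \deqn{\widehat{\mathrm{var}} = \frac{100^2}{n}\left[\tfrac14 t(1-t) +
#'   9\,q(1-q) - 3\,t\,q\right].}
#'
#' @param pd,tt,npd non-negative integer counts of parental ditypes,
#'   tetratypes and non-parental ditypes.
#' @param interval optional interval label stored in the result.
#' @return A [MapDistanceEstimate-class].
#' @examples
#' perkinsDistance(70, 26, 4)   # 100 * (13 + 12) / 100 = 25 cM
#' @export
perkinsDistance <- function(pd, tt, npd, interval = "") {
  counts <- c(PD = as.integer(pd), TT = as.integer(tt),
              NPD = as.integer(npd))
  if (anyNA(counts) || any(counts < 0L)) {
    stop("PD, TT and NPD counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1L) stop("undefined estimate: no scored tetrads (n = 0)")
  t <- counts[["TT"]] / n
  q <- counts[["NPD"]] / n
  d <- 100 * (t / 2 + 3 * q)
  v <- (100^2 / n) * (t * (1 - t) / 4 + 9 * q * (1 - q) - 3 * t * q)
  new("MapDistanceEstimate", cM = d, var = max(v, 0), n = n,
      counts = counts, interval = as.character(interval))
}

#' Map distances of both intervals from joint class counts
#'
#' Applies [perkinsDistance()] to the marginal PD/TT/NPD counts of each
#' interval of a joint class-count table.
#'
#' @param x a [TetradClassCounts-class].
#' @param ... unused.
#' @return Named list of two [MapDistanceEstimate-class] objects.
#' @examples
#' tet <- simulateTetrads(simulationConfig(nMeioses = 2000, seed = 11))
#' mapDistances(tallyTetrads(tet))
#' @rdname mapDistances
#' @export
setMethod("mapDistances", "TetradClassCounts", function(x, ...) {
  res <- lapply(1:2, function(i) {
    m <- marginalCounts(x, i)
    perkinsDistance(m[["PD"]], m[["TT"]], m[["NPD"]],
                    interval = x@intervals[i])
  })
  stats::setNames(res, x@intervals)
})

#' Z-test comparing two map-distance estimates
#'
#' Tests equality of two Perkins distances (e.g. the same interval in two
#' genotypes) with the normal approximation on their difference:
#' \eqn{z = (d_a - d_b)/\sqrt{\mathrm{var}_a + \mathrm{var}_b}}, two-sided
#' p-value from the standard normal.
#'
#' @param a,b [MapDistanceEstimate-class] objects.
#' @return An object of class `"htest"` with `statistic` (z), `p.value`
#'   and `estimate` (the two distances).
#' @examples
#' a <- perkinsDistance(700, 260, 40)
#' b <- perkinsDistance(800, 200, 0)
#' distanceZTest(a, b)
#' @export
distanceZTest <- function(a, b) {
  stopifnot(is(a, "MapDistanceEstimate"), is(b, "MapDistanceEstimate"))
  v <- a@var + b@var
  if (v <= 0) stop("degenerate test: both sampling variances are zero")
  z <- (a@cM - b@cM) / sqrt(v)
  structure(class = "htest", list(
    statistic = c(z = z),
    p.value = 2 * pnorm(-abs(z)),
    estimate = c(`cM a` = a@cM, `cM b` = b@cM),
    method = "Z-test on the difference of Perkins map distances",
    data.name = sprintf("a (n = %d) vs b (n = %d)", a@n, b@n)))
}

#' Percent change of a map distance relative to a reference
#'
#' @param mutant,reference [MapDistanceEstimate-class] objects (or single
#'   numbers in cM).
#' @return `100 * (mutant - reference) / reference`, in percent.
#' @examples
#' percentChange(perkinsDistance(680, 320, 0), perkinsDistance(800, 200, 0))
#' @export
percentChange <- function(mutant, reference) {
  m <- if (is(mutant, "MapDistanceEstimate")) mutant@cM else as.numeric(mutant)
  r <- if (is(reference, "MapDistanceEstimate")) reference@cM
       else as.numeric(reference)
  if (r == 0) stop("undefined percent change: reference distance is 0 cM")
  100 * (m - r) / r
}

#' Interference ratio between two adjacent intervals
#'
#' Quantifies crossover interference by stratifying tetrads on the
#' conditioning interval: tetrads recombinant there (TT or NPD, "with CO")
#' versus parental (PD, "without CO"). The Perkins distance of the test
#' interval is estimated within each stratum and the interference ratio is
#' \deqn{IR = d_{\mathrm{with\,CO}} / d_{\mathrm{without\,CO}}.}
#' IR = 1 when interference is absent; IR near 0 when a crossover in the
#' conditioning interval suppresses recombination in the test interval
#' (positive interference). H0: IR = 1 (equivalently, equal stratified
#' distances) is tested with
#' \eqn{z = (d_{with} - d_{without})/\sqrt{\mathrm{var}_{with} +
#' \mathrm{var}_{without}}} and a two-sided normal p-value.
#'
#' @param x a [TetradClassCounts-class].
#' @param test interval whose distance is measured (index or name;
#'   default the second interval).
#' @param conditioning interval used for stratification (default the
#'   first).
#' @param ... unused.
#' @return An [InterferenceResult-class].
#' @examples
#' tet <- simulateTetrads(simulationConfig(nu = 10, lambda1 = 2,
#'                                         nMeioses = 5000, seed = 9))
#' interferenceRatio(tallyTetrads(tet))
#' @rdname interferenceRatio
#' @export
setMethod("interferenceRatio", "TetradClassCounts",
          function(x, test = 2L, conditioning = 1L, ...) {
  ti <- if (is.character(test)) match(test, x@intervals)
        else as.integer(test)
  ci <- if (is.character(conditioning)) match(conditioning, x@intervals)
        else as.integer(conditioning)
  if (anyNA(c(ti, ci)) || ti == ci || !all(c(ti, ci) %in% 1:2)) {
    stop("test and conditioning must name the two distinct intervals")
  }
  cm <- if (ci == 1L) x@counts else t(x@counts)
  # rows now index the conditioning interval, columns the test interval
  withCO <- colSums(cm[c("TT", "NPD"), , drop = FALSE])
  withoutCO <- cm["PD", ]
  if (sum(withCO) == 0L || sum(withoutCO) == 0L) {
    stop("insufficient data: empty stratum in the conditioning interval")
  }
  dW <- perkinsDistance(withCO[["PD"]], withCO[["TT"]], withCO[["NPD"]],
                        interval = x@intervals[ti])
  dWo <- perkinsDistance(withoutCO[["PD"]], withoutCO[["TT"]],
                         withoutCO[["NPD"]], interval = x@intervals[ti])
  if (dWo@cM == 0) {
    stop("IR undefined: zero distance in the without-CO stratum")
  }
  v <- dW@var + dWo@var
  z <- if (v > 0) (dW@cM - dWo@cM) / sqrt(v) else 0
  new("InterferenceResult",
      dWithCO = dW, dWithoutCO = dWo,
      IR = dW@cM / dWo@cM,
      z = z, p = 2 * pnorm(-abs(z)),
      test = x@intervals[ti], conditioning = x@intervals[ci])
})

#' Standard error of an interference-ratio estimate
#'
#' First-order (delta-method) standard error of the ratio of the two
#' stratified distances, combining their delta-method variances.
#'
#' @param x an [InterferenceResult-class].
#' @return Numeric standard error of `irValue(x)`.
#' @export
irStandardError <- function(x) {
  stopifnot(is(x, "InterferenceResult"))
  x@IR * sqrt(x@dWithCO@var / x@dWithCO@cM^2 +
              x@dWithoutCO@var / x@dWithoutCO@cM^2)
}

#' Welch's t-test from group summary statistics
#'
#' Two-sample Welch t-test computed from means, standard deviations and
#' sample sizes only, for comparing published summaries (e.g. per-cell
#' recombination-focus counts) when raw data are unavailable:
#' \eqn{t = (m_1 - m_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch–Satterthwaite degrees of freedom.
#'
#' @param mean1,sd1,n1 summary of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 summary of group 2.
#' @return An object of class `"htest"` with `statistic` (t), `parameter`
#'   (df) and `p.value`. If both SDs are zero: p = 1 for equal means,
#'   p = 0 otherwise.
#' @examples
#' welchTFromSummary(9.2, 1.7, 21, 8.9, 1.4, 16)
#' @export
welchTFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  if (se2 == 0) {
    equal <- isTRUE(all.equal(mean1, mean2))
    t <- if (equal) 0 else sign(mean1 - mean2) * Inf
    df <- n1 + n2 - 2
    p <- if (equal) 1 else 0
  } else {
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(class = "htest", list(
    statistic = c(t = t),
    parameter = c(df = df),
    p.value = p,
    estimate = c(`mean 1` = mean1, `mean 2` = mean2),
    method = "Welch two-sample t-test from summary statistics",
    data.name = sprintf("groups of n = %d and n = %d", n1, n2)))
}
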