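#' @rdname tetracross-accessors
#' @aliases nTetrads,TetradSet-method
setMethod("nTetrads", "TetradSet", function(x) dim(x@alleles)[3L])

#' @rdname tetracross-accessors
setMethod("sporeAlleles", "TetradSet", function(x) x@alleles)

#' @rdname tetracross-accessors
setMethod("markerPhase", "TetradSet", function(x) x@markerPhase)

#' @rdname tetracross-accessors
setMethod("markerPhase", "SimulationConfig", function(x) x@markerPhase)

#' @rdname tetracross-accessors
setMethod("jointCounts", "TetradClassCounts", function(x) x@counts)

#' @rdname tetracross-accessors
setMethod("nScored", "TetradClassCounts", function(x) sum(x@counts))

#' @rdname tetracross-accessors
setMethod("nExcluded", "TetradClassCounts", function(x) x@excluded)

#' @rdname tetracross-accessors
setMethod("intervalNames", "TetradClassCounts", function(x) x@intervals)

#' @rdname tetracross-accessors
setMethod("cM", "MapDistanceEstimate", function(x) x@cM)

#' @rdname tetracross-accessors
setMethod("mapVar", "MapDistanceEstimate", function(x) x@var)

#' @rdname tetracross-accessors
setMethod("nTetrads", "MapDistanceEstimate", function(x) x@n)

#' @rdname tetracross-accessors
setMethod("typeCounts", "MapDistanceEstimate", function(x) x@counts)

#' @rdname tetracross-accessors
setMethod("irValue", "InterferenceResult", function(x) x@IR)

#' @rdname tetracross-accessors
setMethod("zValue", "InterferenceResult", function(x) x@z)

#' @rdname tetracross-accessors
setMethod("pValue", "InterferenceResult", function(x) x@p)

#' Subset a TetradSet
#'
#' @param x a [TetradSet-class].
#' @param i tetrad indices (numeric or logical).
#' @param j,...,drop ignored.
#' @return A [TetradSet-class] with the selected tetrads.
#' @export
setMethod("[", "TetradSet", function(x, i, j, ..., drop = FALSE) {
  new("TetradSet",
      alleles     = x@alleles[, , i, drop = FALSE],
      meiosisId   = x@meiosisId[i],
      markerPhase = x@markerPhase)
})

#' @describeIn TetradSet number of tetrads.
#' @param x a [TetradSet-class].
#' @export
setMethod("length", "TetradSet", function(x) nTetrads(x))

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  markers (Morgans): ",
      paste(format(object@markerPositions), collapse = ", "),
      " on [0, ", format(object@chromLength), "]\n", sep = "")
  cat("  class I : lambda1 =", object@lambda1, ", nu =", object@nu, "\n")
  cat("  class II: lambda2 =", object@lambda2, "\n")
  cat("  obligate CO:", object@obligateCo,
      "| pairs:", object@nChromPairs,
      "| meioses:", object@nMeioses,
      "| seed:", object@seed,
      "| phase:", object@markerPhase, "\n")
})

setMethod("show", "TetradSet", function(object) {
  cat("TetradSet with", nTetrads(object), "tetrads (",
      object@markerPhase, "phase )\n")
})

setMethod("show", "TetradClassCounts", function(object) {
  cat("TetradClassCounts over intervals",
      paste(object@intervals, collapse = " x "), "\n")
  m <- object@counts
  dimnames(m) <- stats::setNames(dimnames(m), object@intervals)
  print(m)
  cat("scored:", nScored(object), " excluded:", object@excluded, "\n")
})

setMethod("show", "MapDistanceEstimate", function(object) {
  lab <- if (nzchar(object@interval)) paste0(" [", object@interval, "]") else ""
  cat(sprintf("MapDistanceEstimate%s: %.3f cM (SD %.3f, n = %d; PD/TT/NPD = %d/%d/%d)\n",
              lab, object@cM, sqrt(object@var), object@n,
              object@counts["PD"], object@counts["TT"], object@counts["NPD"]))
})

setMethod("show", "InterferenceResult", function(object) {
  cat(sprintf("InterferenceResult: IR %s | %s = %.3f\n",
              object@test, object@conditioning, object@IR))
  cat(sprintf("  with CO in %s   : %.3f cM (n = %d)\n",
              object@conditioning, object@dWithCO@cM, object@dWithCO@n))
  cat(sprintf("  without CO in %s: %.3f cM (n = %d)\n",
              object@conditioning, object@dWithoutCO@cM, object@dWithoutCO@n))
  cat(sprintf("  H0 IR = 1: z = %.3f, p = %.3g\n", object@z, object@p))
})
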