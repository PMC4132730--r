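#' @name tetracross-accessors
#' @title Accessors for tetracross S4 objects
#'
#' @description
#' Small accessor generics for the package's containers: `nTetrads()` the
#' number of tetrads, `sporeAlleles()` the 4 x 3 x n allele array,
#' `markerPhase()` the declared parental phase, `jointCounts()` the 3 x 3
#' joint class-count matrix, `nScored()`/`nExcluded()` scored and excluded
#' tetrad counts, `intervalNames()` the two interval labels, `cM()` and
#' `mapVar()` a distance estimate and its sampling variance, `typeCounts()`
#' the PD/TT/NPD counts behind an estimate, and `irValue()`, `zValue()`,
#' `pValue()` the components of an interference result.
#'
#' @param x a tetracross object.
#' @return The corresponding component; see Description.
#' @examples
#' cfg <- simulationConfig(nMeioses = 50, seed = 1)
#' tet <- simulateTetrads(cfg)
#' nTetrads(tet)
#' counts <- tallyTetrads(tet)
#' jointCounts(counts)
#' cM(mapDistances(counts)[[1]])
NULL

#' @rdname tetracross-accessors
#' @export
setGeneric("nTetrads", function(x) standardGeneric("nTetrads"))

#' @rdname tetracross-accessors
#' @export
setGeneric("sporeAlleles", function(x) standardGeneric("sporeAlleles"))

#' @rdname tetracross-accessors
#' @export
setGeneric("markerPhase", function(x) standardGeneric("markerPhase"))

#' @rdname tetracross-accessors
#' @export
setGeneric("jointCounts", function(x) standardGeneric("jointCounts"))

#' @rdname tetracross-accessors
#' @export
setGeneric("nScored", function(x) standardGeneric("nScored"))

#' @rdname tetracross-accessors
#' @export
setGeneric("nExcluded", function(x) standardGeneric("nExcluded"))

#' @rdname tetracross-accessors
#' @export
setGeneric("intervalNames", function(x) standardGeneric("intervalNames"))

#' @rdname tetracross-accessors
#' @export
setGeneric("cM", function(x) standardGeneric("cM"))

#' @rdname tetracross-accessors
#' @export
setGeneric("mapVar", function(x) standardGeneric("mapVar"))

#' @rdname tetracross-accessors
#' @export
setGeneric("typeCounts", function(x) standardGeneric("typeCounts"))

#' @rdname tetracross-accessors
#' @export
setGeneric("irValue", function(x) standardGeneric("irValue"))

#' @rdname tetracross-accessors
#' @export
setGeneric("zValue", function(x) standardGeneric("zValue"))

#' @rdname tetracross-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
#' @rdname intervalType
setGeneric("intervalType", function(x, interval, ...)
  standardGeneric("intervalType"))

#' @export
#' @rdname classifyTetrads
setGeneric("classifyTetrads", function(x, ...)
  standardGeneric("classifyTetrads"))

#' @export
#' @rdname tallyTetrads
setGeneric("tallyTetrads", function(x, ...) standardGeneric("tallyTetrads"))

#' @export
#' @rdname mapDistances
setGeneric("mapDistances", function(x, ...) standardGeneric("mapDistances"))

#' @export
#' @rdname interferenceRatio
setGeneric("interferenceRatio", function(x, test = 2L, conditioning = 1L, ...)
  standardGeneric("interferenceRatio"), signature = "x")
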