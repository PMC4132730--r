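#' Summarise metaphase-I bivalent counts
#'
#' Mean and sample SD of the number of bivalents per meiocyte, and the
#' complementary mean number of univalent pairs
#' (`nChromPairs - mean(bivalents)`). A cell with a crossover-connected
#' homolog pair shows a bivalent; a pair without a crossover appears as
#' two univalents.
#'
#' @param values non-negative integer bivalent counts, one per meiocyte,
#'   each at most `nChromPairs`.
#' @param nChromPairs chromosome pairs of the species (5 for Arabidopsis).
#' @param label optional genotype label carried into the output.
#' @return A one-row data.frame: `label`, `meanBivalents`,
#'   `meanUnivalentPairs`, `sd`, `n`.
#' @examples
#' bivalentSummary(c(5, 5, 4, 5, 3), nChromPairs = 5)
#' @export
bivalentSummary <- function(values, nChromPairs = 5L, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    stop("values must be a non-empty vector of counts")
  }
  if (any(values < 0 | values > nChromPairs)) {
    stop("bivalent counts must lie in [0, nChromPairs]")
  }
  data.frame(label = label,
             meanBivalents = mean(values),
             meanUnivalentPairs = nChromPairs - mean(values),
             sd = if (length(values) > 1L) sd(values) else 0,
             n = length(values))
}

#' Summarise per-cell focus counts
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and n of per-cell counts
#' of recombination foci (e.g. MLH1 foci marking class I crossovers).
#'
#' @param values non-negative counts, one per cell.
#' @param label optional genotype label.
#' @return A one-row data.frame: `label`, `mean`, `sd`, `n`.
#' @examples
#' fociSummary(c(9, 11, 8, 10, 9))
#' @export
fociSummary <- function(values, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    stop("values must be a non-empty vector of counts")
  }
  if (any(values < 0)) stop("focus counts must be non-negative")
  data.frame(label = label,
             mean = mean(values),
             sd = if (length(values) > 1L) sd(values) else 0,
             n = length(values))
}
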