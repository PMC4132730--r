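#' Create a simulation configuration
#'
#' Builds a [SimulationConfig-class] for the two-pathway crossover
#' simulator. Defaults give an interference-free (Poisson) placement with
#' two adjacent 5 cM marker intervals near the middle of a 1 Morgan
#' chromosome, with total intensity calibrated to the position scale
#' (`lambda1 + lambda2 = 2 * chromLength`, i.e. two crossovers per bivalent
#' per Morgan).
#'
#' @param markerPositions strictly increasing numeric(3), marker positions
#'   in Morgans.
#' @param chromLength chromosome genetic length in Morgans.
#' @param nu gamma-renewal shape for class I crossover spacing; `nu = 1`
#'   gives a Poisson process (no interference), larger values give
#'   positive interference.
#' @param lambda1 expected class I crossovers per bivalent per meiosis.
#' @param lambda2 expected class II crossovers per bivalent per meiosis.
#' @param obligateCo if TRUE, draws with no crossover on a bivalent are
#'   rejected and redrawn, enforcing the obligate crossover.
#' @param nChromPairs chromosome pairs per meiocyte (5 for Arabidopsis).
#' @param nMeioses number of meioses to simulate.
#' @param seed RNG seed used by [simulateTetrads()] and
#'   [simulateMeiocytes()].
#' @param markerPhase `"coupling"` (all transgenes on one homolog) or
#'   `"repulsion"` (middle marker on the opposite homolog).
#' @return A validated [SimulationConfig-class].
#' @examples
#' simulationConfig(nu = 10, lambda1 = 2, lambda2 = 0, nMeioses = 100)
#' @export
simulationConfig <- function(markerPositions = c(0.425, 0.475, 0.525),
                             chromLength = 1,
                             nu = 1,
                             lambda1 = 2,
                             lambda2 = 0,
                             obligateCo = FALSE,
                             nChromPairs = 5L,
                             nMeioses = 1000L,
                             seed = 1L,
                             markerPhase = c("coupling", "repulsion")) {
  markerPhase <- match.arg(markerPhase)
  new("SimulationConfig",
      markerPositions = as.numeric(markerPositions),
      chromLength     = as.numeric(chromLength),
      nu              = as.numeric(nu),
      lambda1         = as.numeric(lambda1),
      lambda2         = as.numeric(lambda2),
      obligateCo      = as.logical(obligateCo),
      nChromPairs     = as.integer(nChromPairs),
      nMeioses        = as.integer(nMeioses),
      seed            = as.integer(seed),
      markerPhase     = markerPhase)
}

#' Named genotype-like simulation presets
#'
#' Illustrative parameter sets mimicking the qualitative genetic
#' architecture of common recombination genotypes: `"wild_type"` (strongly
#' interfering class I majority plus a small class II fraction, obligate
#' crossover), `"zmm"` (class I reduced to 10%, no obligate crossover, as
#' in zmm mutants that lose most class I crossovers), `"fancm_like"`
#' (class II released eight-fold, as when a strong anti-crossover factor is
#' lost) and `"mhf_like"` (class II released five-fold, a weaker
#' anti-crossover factor). The numbers are illustrative defaults, not fits
#' to any particular data set.
#'
#' @param name preset name.
#' @param ... overrides passed on to [simulationConfig()].
#' @return A [SimulationConfig-class].
#' @examples
#' presetConfig("wild_type", nMeioses = 200, seed = 7)
#' @export
presetConfig <- function(name = c("wild_type", "zmm", "fancm_like",
                                  "mhf_like"),
                         ...) {
  name <- match.arg(name)
  base <- switch(name,
    wild_type  = list(nu = 7, lambda1 = 1.8, lambda2 = 0.2,
                      obligateCo = TRUE),
    zmm        = list(nu = 7, lambda1 = 0.18, lambda2 = 0.2,
                      obligateCo = FALSE),
    fancm_like = list(nu = 7, lambda1 = 1.8, lambda2 = 1.6,
                      obligateCo = TRUE),
    mhf_like   = list(nu = 7, lambda1 = 1.8, lambda2 = 1.0,
                      obligateCo = TRUE))
  args <- utils::modifyList(base, list(...))
  do.call(simulationConfig, args)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file must contain exactly the [simulationConfig()] fields (missing
#' fields take the defaults; unknown fields are an error).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  stopifnot(file.exists(path))
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulationConfig))
  bad <- setdiff(names(lst), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(simulationConfig, lst)
}

#' Write a simulation configuration to YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}
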