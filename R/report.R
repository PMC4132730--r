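#' Run the full tetrad-analysis chain and report results
#'
#' Executes simulate (or ingest) -> classify -> map distances ->
#' interference ratio, and assembles a reproducible report: a tidy results
#' table, the joint class counts, both interference directions, and a run
#' manifest (seed, configuration hash, package version, per-stage row
#' counts, timestamp). When `outDir` is given the report is also written
#' to `results.csv`, `counts.csv` and `report.json`.
#'
#' The JSON report is byte-identical across runs with the same
#' configuration, except for the manifest timestamp.
#'
#' @param config a [SimulationConfig-class]; ignored for simulation when
#'   `tetrads` is supplied (but still recorded in the manifest).
#' @param tetrads optional [TetradSet-class] of ingested data; if `NULL`,
#'   tetrads are simulated from `config`.
#' @param outDir optional output directory (created if needed).
#' @return A list with elements `manifest`, `counts`
#'   ([TetradClassCounts-class]), `distances`, `interference` (both
#'   directions) and `results` (tidy data.frame), invisibly when writing.
#' @examples
#' rep <- runReport(simulationConfig(nMeioses = 2000, seed = 3))
#' rep$results
#' @export
runReport <- function(config, tetrads = NULL, outDir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(tetrads)) {
    tetrads <- simulateTetrads(config)
    source <- "simulation"
  } else {
    stopifnot(is(tetrads, "TetradSet"))
    source <- "ingested"
  }
  counts <- tallyTetrads(tetrads)
  dists <- mapDistances(counts)
  iv <- intervalNames(counts)
  infr <- list(
    interferenceRatio(counts, test = 2L, conditioning = 1L),
    interferenceRatio(counts, test = 1L, conditioning = 2L))
  names(infr) <- vapply(infr, function(r)
    paste0(r@test, "|", r@conditioning), "")

  results <- rbind(
    do.call(rbind, lapply(dists, function(d) data.frame(
      metric = "map_distance_cM", interval = d@interval,
      estimate = d@cM, sd = sqrt(d@var), z = NA_real_, p = NA_real_,
      n = d@n))),
    do.call(rbind, lapply(infr, function(r) data.frame(
      metric = "interference_ratio",
      interval = paste0(r@test, "|", r@conditioning),
      estimate = r@IR, sd = irStandardError(r), z = r@z, p = r@p,
      n = r@dWithCO@n + r@dWithoutCO@n))))
  rownames(results) <- NULL

  manifest <- list(
    package = "tetracross",
    version = as.character(packageVersion("tetracross")),
    source = source,
    seed = config@seed,
    configHash = .hashConfig(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = list(tetrads = nTetrads(tetrads),
                scored = nScored(counts),
                excluded = nExcluded(counts)))
  message("tetracross report: seed=", manifest$seed,
          " configHash=", manifest$configHash,
          " tetrads=", manifest$rows$tetrads,
          " scored=", manifest$rows$scored,
          " excluded=", manifest$rows$excluded)

  out <- list(manifest = manifest, counts = counts, distances = dists,
              interference = infr, results = results)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(outDir, "results.csv"), row.names = FALSE)
    writeClassCounts(counts, file.path(outDir, "counts.csv"))
    jsonlite::write_json(.reportAsJson(out), file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

.hashConfig <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(.configAsList(config), tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

.reportAsJson <- function(out) {
  distJson <- lapply(out$distances, function(d) list(
    cM = d@cM, var = d@var, sd = sqrt(d@var), n = d@n,
    counts = as.list(d@counts)))
  irJson <- lapply(out$interference, function(r) list(
    IR = r@IR, z = r@z, p = r@p, se = irStandardError(r),
    withCO = list(cM = r@dWithCO@cM, var = r@dWithCO@var, n = r@dWithCO@n),
    withoutCO = list(cM = r@dWithoutCO@cM, var = r@dWithoutCO@var,
                     n = r@dWithoutCO@n)))
  list(manifest = out$manifest,
       counts = list(
         joint = as.data.frame(as.table(jointCounts(out$counts)),
                               stringsAsFactors = FALSE),
         excluded = nExcluded(out$counts)),
       mapDistances = distJson,
       interference = irJson)
}
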