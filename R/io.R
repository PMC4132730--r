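## Table readers/writers. Per-tetrad tables are plain CSV with one row per
## spore (columns tetrad_id, spore_index, m1, m2, m3; marker values 0/1/NA
## and exactly four spores per tetrad). Class-count tables carry the nine
## joint categories plus '# n=' and '# excluded=' comment headers.

#' Read a per-tetrad fluorescence table
#'
#' Expects a CSV with columns `tetrad_id`, `spore_index` (1-4), `m1`,
#' `m2`, `m3` (fluorescence 0/1, or NA for an unscorable channel) and
#' exactly four spore rows per tetrad. Malformed input is reported with
#' the offending tetrad or row.
#'
#' @param path CSV path (LF or CRLF line endings).
#' @param markerPhase declared parental phase of the markers.
#' @return A [TetradSet-class].
#' @seealso [writeTetradTable()]
#' @export
readTetradTable <- function(path, markerPhase = c("coupling", "repulsion")) {
  markerPhase <- match.arg(markerPhase)
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tetrad_id", "spore_index", "m1", "m2", "m3")
  if (!all(need %in% names(df))) {
    stop("tetrad table must have columns ", paste(need, collapse = ", "))
  }
  for (m in c("m1", "m2", "m3")) {
    bad <- !(df[[m]] %in% c(0L, 1L) | is.na(df[[m]]))
    if (any(bad)) {
      stop("column ", m, ": values must be 0, 1 or NA (first bad row: ",
           which(bad)[1L], ")")
    }
  }
  ids <- unique(df$tetrad_id)
  cnt <- table(df$tetrad_id)
  bad <- names(cnt)[cnt != 4L]
  if (length(bad)) {
    stop("tetrad(s) without exactly 4 spore rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(df[c("tetrad_id", "spore_index")])) {
    i <- anyDuplicated(df[c("tetrad_id", "spore_index")])
    stop("duplicate (tetrad_id, spore_index) at row ", i)
  }
  if (!all(df$spore_index %in% 1:4)) {
    stop("spore_index must be 1, 2, 3 or 4")
  }
  df <- df[order(match(df$tetrad_id, ids), df$spore_index), ]
  n <- length(ids)
  alleles <- array(NA, dim = c(4L, 3L, n))
  for (m in 1:3) {
    alleles[, m, ] <- as.logical(df[[paste0("m", m)]])
  }
  mid <- suppressWarnings(as.integer(ids))
  if (anyNA(mid)) mid <- seq_len(n)
  new("TetradSet", alleles = alleles, meiosisId = mid,
      markerPhase = markerPhase)
}

#' Write a per-tetrad fluorescence table
#'
#' @param x a [TetradSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [readTetradTable()]
#' @export
writeTetradTable <- function(x, path) {
  stopifnot(is(x, "TetradSet"))
  n <- nTetrads(x)
  df <- data.frame(
    tetrad_id = rep(x@meiosisId, each = 4L),
    spore_index = rep(1:4, n),
    m1 = as.integer(matrix(x@alleles[, 1L, ], nrow = 4L)),
    m2 = as.integer(matrix(x@alleles[, 2L, ], nrow = 4L)),
    m3 = as.integer(matrix(x@alleles[, 3L, ], nrow = 4L)))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a joint class-count table
#'
#' Reads the nine-category (PD/TT/NPD x PD/TT/NPD) count table written by
#' [writeClassCounts()]: comment headers `# n=` and `# excluded=` followed
#' by CSV columns `type_<interval1>`, `type_<interval2>`, `count`. A file
#' missing some of the nine categories is an error unless
#' `allowSparse = TRUE`, in which case absent rows count 0.
#'
#' @param path CSV path.
#' @param allowSparse allow missing category rows (treated as zero).
#' @return A [TetradClassCounts-class].
#' @export
readClassCounts <- function(path, allowSparse = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  excluded <- 0L
  mx <- regmatches(meta, regexec("^#\\s*excluded=(\\d+)", meta))
  for (m in mx) if (length(m) == 2L) excluded <- as.integer(m[2L])
  df <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                 stringsAsFactors = FALSE)
  tcols <- grep("^type_", names(df), value = TRUE)
  if (length(tcols) != 2L || !"count" %in% names(df)) {
    stop("class-count table must have two type_* columns and a count column")
  }
  intervals <- sub("^type_", "", tcols)
  if (anyNA(df$count) || any(df$count < 0)) {
    stop("counts must be non-negative (row ",
         which(is.na(df$count) | df$count < 0)[1L], ")")
  }
  if (!all(df[[tcols[1L]]] %in% .TYPES) || !all(df[[tcols[2L]]] %in% .TYPES)) {
    stop("interval types must be PD, TT or NPD")
  }
  key <- paste(df[[tcols[1L]]], df[[tcols[2L]]])
  if (anyDuplicated(key)) stop("duplicate category row: ", key[duplicated(key)][1L])
  full <- expand.grid(a = .TYPES, b = .TYPES, stringsAsFactors = FALSE)
  missing <- setdiff(paste(full$a, full$b), key)
  if (length(missing) && !allowSparse) {
    stop("missing category row(s): ", paste(missing, collapse = ", "),
         " (use allowSparse = TRUE to default them to 0)")
  }
  cm <- matrix(0L, 3L, 3L, dimnames = list(.TYPES, .TYPES))
  cm[cbind(df[[tcols[1L]]], df[[tcols[2L]]])] <- as.integer(df$count)
  new("TetradClassCounts", counts = cm, intervals = intervals,
      excluded = excluded)
}

#' Write a joint class-count table
#'
#' @param x a [TetradClassCounts-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [readClassCounts()]
#' @export
writeClassCounts <- function(x, path) {
  stopifnot(is(x, "TetradClassCounts"))
  grid <- expand.grid(a = .TYPES, b = .TYPES, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$a, .TYPES), match(grid$b, .TYPES)), ]
  df <- data.frame(grid$a, grid$b,
                   count = x@counts[cbind(grid$a, grid$b)])
  names(df) <- c(paste0("type_", x@intervals), "count")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n=%d", nScored(x)),
               sprintf("# excluded=%d", x@excluded)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
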