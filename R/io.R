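#' @include AllClasses.R constructors.R
NULL

# atomic write: write to a sibling temp file, then rename over the target,
# so interrupted runs never leave truncated outputs.
.atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not write ", path)
  invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' Tab-delimited UTF-8 with a header row of column labels and a first
#' column of row labels. The parsed matrix is validated for its kind:
#' associations must be strictly binary, similarities symmetric with unit
#' diagonal and entries in \[0, 1\]. Violations are reported with the
#' offending row or column.
#'
#' @param path file path.
#' @param kind `"association"` or `"similarity"`.
#' @return an [AssociationMatrix-class] or [SimilarityMatrix-class].
#' @export
readLabeledMatrix <- function(path, kind = c("association", "similarity")) {
  kind <- match.arg(kind)
  M <- .readMatrixTSV(path)
  if (kind == "association") {
    if (!all(M == 0 | M == 1)) {
      bad <- which(!(M == 0 | M == 1), arr.ind = TRUE)[1, ]
      stop("invalid association matrix ", path, ": non-binary value at row '",
           rownames(M)[bad[1]], "', column '", colnames(M)[bad[2]], "'")
    }
    associationMatrix(M)
  } else {
    tryCatch(similarityMatrix(M), error = function(e)
      stop("invalid similarity matrix ", path, ": ", conditionMessage(e)))
  }
}

# parse a labeled TSV into a plain numeric matrix, no kind validation
.readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop("parse error in ", path, ": expected label column plus data")
  rlab <- as.character(raw[[1]])
  if (anyDuplicated(rlab))
    stop("parse error in ", path, ": duplicate row label '",
         rlab[duplicated(rlab)][1], "'")
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]]))
      stop("parse error in ", path, ": non-numeric cell in column '",
           colnames(vals)[j], "'")
    vals[[j]] <- v
  }
  M <- as.matrix(vals)
  rownames(M) <- rlab
  if (anyNA(M)) stop("parse error in ", path, ": missing values")
  M
}

#' Write a labeled matrix to TSV
#'
#' Header row and first column carry the labels; values are written with
#' 15 significant digits so a write/read round trip is an identity to
#' well below 1e-12. The write is atomic.
#'
#' @param x a matrix-backed object with dimnames.
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeLabeledMatrix <- function(x, path) {
  M <- as(x, "matrix")
  .atomically(path, function(tmp) {
    fmt <- matrix(sprintf("%.15g", M), nrow(M))
    df <- data.frame(rownames(M), fmt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("", colnames(M))
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  })
}

#' Write a candidate ranking to TSV
#'
#' Columns `rank` (1-based), `miRNA`, `score`, `status`
#' (known/candidate), in ranking order; atomic write.
#'
#' @param ranking data frame from [rankCandidates()].
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeRanking <- function(ranking, path) {
  if (!nrow(ranking)) stop("empty ranking")
  .atomically(path, function(tmp) {
    out <- ranking
    out$score <- sprintf("%.15g", out$score)
    utils::write.table(out, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  })
}

#' Echo a run configuration to an output directory
#'
#' Writes a flat `key=value` file (`run_config.txt`) recording every
#' setting and the seed, sufficient to reproduce the run.
#'
#' @param settings named list of atomic values.
#' @param dir output directory (created if absent).
#' @return the file path, invisibly.
#' @export
writeRunConfig <- function(settings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "run_config.txt")
  .atomically(path, function(tmp) {
    writeLines(sprintf("%s=%s", names(settings),
                       vapply(settings, function(v) paste(format(v), collapse = ","),
                              character(1))), tmp)
  })
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' @param path file path; blank lines and `#` comments ignored.
#' @return named character vector.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  stats::setNames(vapply(kv, function(x) trimws(x[2]), character(1)),
                  vapply(kv, function(x) trimws(x[1]), character(1)))
}
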