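#' @include AllClasses.R constructors.R
NULL

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between two miRNAs (rows of `Y`) or diseases (columns) as a
#' Gaussian of the distance between their association profiles:
#' `K(i, j) = exp(-gamma * ||y_i - y_j||^2)` with the bandwidth normalized
#' by the mean squared profile norm,
#' `gamma = bandwidthScale / mean_i ||y_i||^2`.
#'
#' @param Y an [AssociationMatrix-class] or labeled numeric matrix.
#' @param axis `"miRNA"` (profiles are rows) or `"disease"` (columns).
#' @param bandwidthScale positive bandwidth multiplier (default 1).
#' @return a [SimilarityMatrix-class] over the chosen axis's labels.
#' @export
gipKernel <- function(Y, axis = c("miRNA", "disease"), bandwidthScale = 1) {
  axis <- match.arg(axis)
  P <- as(Y, "matrix")
  if (!length(P)) stop("empty association matrix")
  if (bandwidthScale <= 0) stop("bandwidthScale must be positive")
  if (axis == "disease") P <- t(P)
  meanSq <- mean(rowSums(P^2))
  if (meanSq == 0)
    stop("degenerate input: all association profiles are zero")
  gamma <- bandwidthScale / meanSq
  d2 <- as.matrix(stats::dist(P))^2
  K <- exp(-gamma * d2)
  diag(K) <- 1
  dimnames(K) <- list(rownames(P), rownames(P))
  similarityMatrix(K)
}

#' Integrate a primary similarity with a GIP kernel
#'
#' `mode = "mean"`: elementwise average of the two sources (where the
#' primary is undefined, the GIP value is used alone). `mode = "gip_fill"`:
#' the primary value wherever it is defined, the GIP value elsewhere.
#' Undefined primary entries are `NA`s; `primary = NULL` means entirely
#' undefined.
#'
#' @param primary a [SimilarityMatrix-class], a labeled matrix possibly
#'   containing `NA`s, or `NULL`.
#' @param gip a complete [SimilarityMatrix-class].
#' @param mode `"mean"` or `"gip_fill"`.
#' @return a [SimilarityMatrix-class].
#' @export
integrateSimilarity <- function(primary, gip, mode = c("mean", "gip_fill")) {
  mode <- match.arg(mode)
  G <- as(gip, "matrix")
  if (is.null(primary)) return(similarityMatrix(G))
  P <- as(primary, "matrix")
  if (!identical(dim(P), dim(G)) || !identical(rownames(P), rownames(G)))
    stop("label mismatch between primary and GIP similarity")
  out <- switch(mode,
    mean = ifelse(is.na(P), G, (P + G) / 2),
    gip_fill = ifelse(is.na(P), G, P))
  dimnames(out) <- dimnames(G)
  similarityMatrix(out)
}
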