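#' Construct a SimilarityMatrix
#'
#' Small asymmetries and diagonal deviations within `1e-9` are repaired
#' (symmetrized, diagonal set to 1); anything larger is an error.
#'
#' @param values square numeric matrix with matching row/column labels.
#' @return a [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) == ncol(values) && !is.null(dimnames(values))) {
    if (max(abs(values - t(values))) <= .SYM_TOL)
      values <- (values + t(values)) / 2
    if (nrow(values) && max(abs(diag(values) - 1)) <= .SYM_TOL)
      diag(values) <- 1
    values[values < 0 & values >= -.SYM_TOL] <- 0
    values[values > 1 & values <= 1 + .SYM_TOL] <- 1
  }
  new("SimilarityMatrix", values)
}

#' Construct an AssociationMatrix
#'
#' @param values numeric matrix, miRNAs in rows, diseases in columns, with
#'   dimnames.
#' @param predicted `TRUE` for unbounded model scores.
#' @return an [AssociationMatrix-class].
#' @export
associationMatrix <- function(values, predicted = FALSE) {
  new("AssociationMatrix", as.matrix(values), predicted = predicted)
}

#' Is an association matrix strictly binary?
#'
#' The raw-input contract: every entry exactly 0 or 1.
#'
#' @param Y an [AssociationMatrix-class] or numeric matrix.
#' @return logical.
#' @export
isBinaryAssociation <- function(Y) {
  x <- as(Y, "matrix")
  all(x == 0 | x == 1)
}

#' Construct a DiseaseDAG
#'
#' @param edges two-column character matrix or data frame of
#'   (child, parent) pairs; may have zero rows.
#' @param terms optional character vector of terms; defaults to the edge
#'   endpoints. Terms absent from every edge are isolated nodes.
#' @return a [DiseaseDAG-class].
#' @export
diseaseDAG <- function(edges = NULL, terms = NULL) {
  if (is.null(edges)) {
    e <- matrix(character(), ncol = 2L,
                dimnames = list(NULL, c("child", "parent")))
  } else {
    e <- as.matrix(edges)
    storage.mode(e) <- "character"
    colnames(e) <- c("child", "parent")
  }
  if (is.null(terms)) terms <- unique(as.vector(e))
  terms <- unique(c(terms, as.vector(e)))
  new("DiseaseDAG", terms = as.character(terms), edges = e)
}

#' Semantic similarity configuration
#' @param delta decay factor in (0, 1]; default 0.5.
#' @return a [SemanticConfig-class].
#' @export
semanticConfig <- function(delta = 0.5) new("SemanticConfig", delta = delta)

#' WKNKN configuration
#' @param K nearest known neighbors (default 5).
#' @param p decay in (0, 1] (default 0.7).
#' @return a [WknknConfig-class].
#' @export
wknknConfig <- function(K = 5, p = 0.7) new("WknknConfig", K = as.integer(K), p = p)

#' Factorization configuration
#'
#' Defaults sit mid-grid of the usual search ranges: `lambdaL = 1` from
#' \{2^-2, 2^-1, 1, 2\} and `lambdaD = lambdaT = 0.01` from
#' \{0, 1e-4, 1e-3, 1e-2, 1e-1\}.
#'
#' @param lambdaL Tikhonov (and, unless decoupled, L2,1) weight.
#' @param lambdaD,lambdaT collaborative similarity weights.
#' @param k latent dimension; `NA` resolves to `min(n, m, 50)` at fit time.
#' @param maxIter iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param epsilon row-norm guard in the IRLS reweighting.
#' @param variant `"RCMF"` or `"CMF"`.
#' @param lambda21 optional separate L2,1 weight; `NA` shares `lambdaL`.
#' @return an [RcmfConfig-class].
#' @export
rcmfConfig <- function(lambdaL = 1, lambdaD = 0.01, lambdaT = 0.01, k = NA,
                       maxIter = 200, tol = 1e-6, epsilon = 1e-8,
                       variant = c("RCMF", "CMF"), lambda21 = NA) {
  variant <- match.arg(variant)
  new("RcmfConfig", lambdaL = lambdaL, lambdaD = lambdaD, lambdaT = lambdaT,
      lambda21 = as.numeric(lambda21), k = as.integer(k),
      maxIter = as.integer(maxIter), tol = tol, epsilon = epsilon,
      variant = variant)
}

#' Cross-validation plan
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats repeats (default 10; the full protocol uses 100).
#' @param seed integer seed.
#' @return a [CvPlan-class].
#' @export
cvPlan <- function(nFolds = 5, nRepeats = 10, seed = 1) {
  new("CvPlan", nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Construct a FactorPair
#' @param A,B latent factor matrices with k columns each.
#' @return a [FactorPair-class].
#' @export
factorPair <- function(A, B) {
  new("FactorPair", A = as.matrix(A), B = as.matrix(B),
      k = ncol(as.matrix(A)))
}
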