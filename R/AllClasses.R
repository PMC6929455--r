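#' @import methods
NULL

.SYM_TOL <- 1e-9

#' SimilarityMatrix: symmetric similarity with unit diagonal
#'
#' An S4 container for a square, symmetric, nonnegative similarity matrix
#' with unit diagonal and entries in \[0, 1\] — the shape both the miRNA
#' functional/GIP similarity `Sm` and the disease semantic/GIP similarity
#' `Sd` take. Extends `matrix`; labels live in the dimnames.
#'
#' @slot .Data the numeric matrix.
#' @export
setClass("SimilarityMatrix", contains = "matrix", validity = function(object) {
  x <- object@.Data
  if (!is.numeric(x) || length(dim(x)) != 2L) return("values must be a numeric matrix")
  if (nrow(x) != ncol(x)) return("similarity matrix must be square")
  dn <- dimnames(x)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    return("similarity matrix must carry row and column labels")
  if (!identical(dn[[1]], dn[[2]])) return("row and column labels must agree")
  if (anyDuplicated(dn[[1]])) return("duplicate labels")
  if (any(!is.finite(x))) return("non-finite entries")
  if (max(abs(x - t(x))) > .SYM_TOL) return("matrix is not symmetric (tolerance 1e-9)")
  if (max(abs(diag(x) - 1)) > .SYM_TOL) return("diagonal entries must equal 1")
  if (min(x) < -.SYM_TOL || max(x) > 1 + .SYM_TOL) return("entries must lie in [0, 1]")
  TRUE
})

#' AssociationMatrix: labeled miRNA-by-disease association scores
#'
#' Rows are miRNAs, columns are diseases. Raw input matrices are binary
#' (0/1 known associations); after WKNKN preprocessing or prediction the
#' entries are real scores. Validity only enforces the post-preprocessing
#' contract (\[0, 1\] unless `predicted`); use [isBinaryAssociation()] to
#' check the raw-input contract.
#'
#' @slot .Data the numeric matrix.
#' @slot predicted logical; `TRUE` for model score matrices, whose entries
#'   are unbounded reals.
#' @export
setClass("AssociationMatrix", contains = "matrix",
         representation(predicted = "logical"),
         prototype(predicted = FALSE),
         validity = function(object) {
  x <- object@.Data
  if (!is.numeric(x) || length(dim(x)) != 2L) return("values must be a numeric matrix")
  dn <- dimnames(x)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    return("association matrix must carry miRNA (row) and disease (column) labels")
  if (anyDuplicated(dn[[1]])) return("duplicate miRNA labels")
  if (anyDuplicated(dn[[2]])) return("duplicate disease labels")
  if (any(!is.finite(x))) return("non-finite entries")
  if (!isTRUE(object@predicted) && (min(x) < 0 || max(x) > 1))
    return("association values must lie in [0, 1]")
  TRUE
})

#' DiseaseDAG: directed acyclic graph of disease terms
#'
#' Edges point child -> parent (a term to its broader term). Acyclicity is
#' enforced at construction; isolated terms (no edges) are allowed.
#'
#' @slot terms character vector of term identifiers.
#' @slot edges two-column character matrix, columns child and parent.
#' @export
setClass("DiseaseDAG",
         representation(terms = "character", edges = "matrix"),
         validity = function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns (child, parent)")
  if (nrow(e) > 0L) {
    if (!is.character(e)) return("edges must be character identifiers")
    if (!all(e %in% object@terms)) return("every edge endpoint must be a known term")
    if (anyDuplicated(object@terms)) return("duplicate terms")
    g <- igraph::graph_from_edgelist(e, directed = TRUE)
    if (!igraph::is_dag(g)) return("graph contains a cycle")
  }
  TRUE
})

#' SemanticConfig: decay factor for DAG semantic similarity
#'
#' @slot delta semantic contribution decay factor in (0, 1]; default 0.5.
#' @export
setClass("SemanticConfig", representation(delta = "numeric"),
         prototype(delta = 0.5),
         validity = function(object) {
  if (length(object@delta) != 1L || !is.finite(object@delta) ||
      object@delta <= 0 || object@delta > 1)
    return("delta must be a single value in (0, 1]")
  TRUE
})

#' WknknConfig: parameters of the K-nearest-known-neighbor imputation
#'
#' @slot K number of nearest known neighbors (default 5).
#' @slot p decay applied to successive neighbors, in (0, 1] (default 0.7).
#' @export
setClass("WknknConfig", representation(K = "integer", p = "numeric"),
         prototype(K = 5L, p = 0.7),
         validity = function(object) {
  if (object@K < 1L) return("K must be >= 1")
  if (!is.finite(object@p) || object@p <= 0 || object@p > 1)
    return("p must lie in (0, 1]")
  TRUE
})

#' RcmfConfig: hyperparameters of the factorization
#'
#' `lambdaL` weights both the Tikhonov term and (for the RCMF variant) the
#' L2,1 row-sparsity penalty on the disease factor B; `lambda21`, when not
#' `NA`, decouples the L2,1 weight from `lambdaL`. `lambdaD` and `lambdaT`
#' weight the miRNA- and disease-similarity collaborative terms. `k = NA`
#' is resolved at fit time to `min(n, m, 50)`.
#'
#' @slot lambdaL,lambdaD,lambdaT nonnegative regularization weights.
#' @slot lambda21 optional separate L2,1 weight (`NA` = use `lambdaL`).
#' @slot k latent dimension (`NA` = resolve at fit time).
#' @slot maxIter,tol iteration cap and relative-objective convergence tolerance.
#' @slot epsilon row-norm guard for the IRLS reweighting.
#' @slot variant `"RCMF"` (with L2,1) or `"CMF"` (without).
#' @export
setClass("RcmfConfig",
         representation(lambdaL = "numeric", lambdaD = "numeric",
                        lambdaT = "numeric", lambda21 = "numeric",
                        k = "integer", maxIter = "integer", tol = "numeric",
                        epsilon = "numeric", variant = "character"),
         prototype(lambdaL = 1, lambdaD = 0.01, lambdaT = 0.01,
                   lambda21 = NA_real_, k = NA_integer_, maxIter = 200L,
                   tol = 1e-6, epsilon = 1e-8, variant = "RCMF"),
         validity = function(object) {
  for (s in c("lambdaL", "lambdaD", "lambdaT")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      return(sprintf("%s must be a single nonnegative value", s))
  }
  if (!is.na(object@lambda21) && object@lambda21 < 0)
    return("lambda21 must be nonnegative")
  if (!is.na(object@k) && object@k < 1L) return("k must be >= 1")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@tol <= 0) return("tol must be positive")
  if (object@epsilon <= 0) return("epsilon must be positive")
  if (!object@variant %in% c("RCMF", "CMF"))
    return("variant must be 'RCMF' or 'CMF'")
  TRUE
})

#' FactorPair: the latent factor matrices
#'
#' @slot A n-by-k miRNA latent factors (rownames = miRNA labels).
#' @slot B m-by-k disease latent factors (rownames = disease labels).
#' @slot k latent dimension.
#' @export
setClass("FactorPair",
         representation(A = "matrix", B = "matrix", k = "integer"),
         validity = function(object) {
  if (any(!is.finite(object@A)) || any(!is.finite(object@B)))
    return("factor entries must be finite")
  if (ncol(object@A) != object@k || ncol(object@B) != object@k)
    return("A and B must have k columns")
  if (object@k < 1L) return("k must be >= 1")
  TRUE
})

#' RcmfFit: a converged factorization
#'
#' @slot factors the [FactorPair-class] at convergence.
#' @slot objectiveTrace objective value after initialization and after each
#'   iteration.
#' @slot iterationsRun number of alternating updates performed.
#' @slot converged whether the relative-change criterion was met.
#' @slot config the [RcmfConfig-class] used.
#' @export
setClass("RcmfFit",
         representation(factors = "FactorPair", objectiveTrace = "numeric",
                        iterationsRun = "integer", converged = "logical",
                        config = "RcmfConfig"),
         validity = function(object) {
  if (any(!is.finite(object@objectiveTrace)))
    return("objective trace must be finite")
  TRUE
})

#' CvPlan: repeated pair-holdout cross-validation layout
#'
#' Known (1) entries of the association matrix are partitioned into
#' `nFolds` groups, `nRepeats` times, reproducibly from `seed` (the CV-p
#' protocol: pairs are held out, not whole rows or columns).
#'
#' @slot nFolds folds per repeat (default 5).
#' @slot nRepeats repeats (default 10 for desk-scale runs; the full
#'   protocol uses 100).
#' @slot seed integer seed driving per-repeat substreams.
#' @export
setClass("CvPlan",
         representation(nFolds = "integer", nRepeats = "integer",
                        seed = "integer"),
         prototype(nFolds = 5L, nRepeats = 10L, seed = 1L),
         validity = function(object) {
  if (object@nFolds < 2L) return("nFolds must be >= 2")
  if (object@nRepeats < 1L) return("nRepeats must be >= 1")
  TRUE
})

#' CvResult: AUC summary of a cross-validation run
#'
#' @slot aucMean,aucSd mean and standard deviation of the per-repeat AUCs.
#' @slot perRepeatAuc AUC of each repeat (mean over its folds).
#' @slot plan,config the [CvPlan-class] and [RcmfConfig-class] used.
#' @export
setClass("CvResult",
         representation(aucMean = "numeric", aucSd = "numeric",
                        perRepeatAuc = "numeric", plan = "CvPlan",
                        config = "RcmfConfig"),
         validity = function(object) {
  a <- object@perRepeatAuc
  if (length(a) && (min(a) < 0 || max(a) > 1)) return("AUC values must lie in [0, 1]")
  TRUE
})

#' PlantedInstance: synthetic low-rank association data
#'
#' A planted-truth fixture: `Y` is generated by thresholding the product of
#' nonnegative factors `trueA`, `trueB`, flipping a fraction of entries as
#' noise, and masking a fraction of true positives. `heldOut` lists the
#' masked pairs (1 under the truth, 0 in `Y`). `Sm`/`Sd` are GIP kernels of
#' the noiseless truth.
#'
#' @slot Y the observed [AssociationMatrix-class].
#' @slot Sm,Sd similarity matrices of the noiseless truth.
#' @slot trueA,trueB the planted factors.
#' @slot heldOut two-column integer matrix of masked (row, col) pairs.
#' @slot seed the generator seed.
#' @export
setClass("PlantedInstance",
         representation(Y = "AssociationMatrix", Sm = "SimilarityMatrix",
                        Sd = "SimilarityMatrix", trueA = "matrix",
                        trueB = "matrix", heldOut = "matrix",
                        seed = "integer"))

#' LineCloud: 2-D points on the line y = x plus off-line noise
#'
#' The fixture for the robustness comparison: `nInliers` points exactly on
#' y = x and `nNoise` points displaced off the line, in shuffled order.
#'
#' @slot points N-by-2 matrix of (x, y) coordinates.
#' @slot nInliers,nNoise point counts.
#' @slot spread half-width of the noise offset distribution.
#' @slot seed the generator seed.
#' @export
setClass("LineCloud",
         representation(points = "matrix", nInliers = "integer",
                        nNoise = "integer", spread = "numeric",
                        seed = "integer"),
         validity = function(object) {
  if (ncol(object@points) != 2L) return("points must be an N-by-2 matrix")
  if (nrow(object@points) != object@nInliers + object@nNoise)
    return("point count must equal nInliers + nNoise")
  TRUE
})
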