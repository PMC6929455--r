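#' @include AllClasses.R constructors.R
NULL

.rowNorms <- function(M) sqrt(rowSums(M^2))

# symmetric solve X G = R  (i.e. X = R G^-1) with pseudoinverse fallback
# when G is numerically singular (condition estimate > 1e12).
.solveRight <- function(R, G) {
  ok <- tryCatch(kappa(G, exact = FALSE) < 1e12, error = function(e) FALSE)
  if (ok) {
    out <- tryCatch(t(solve(G, t(R))), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  warning("singular system in factor update; using pseudoinverse")
  R %*% MASS::ginv(G)
}

#' SVD initialization of the latent factors
#'
#' Rank-k truncated SVD of `Y`; with singular values `s` the factors are
#' `A = U_k diag(sqrt(s_k))` and `B = V_k diag(sqrt(s_k))`, so `A B^T` is
#' the best rank-k approximation of `Y` in Frobenius norm.
#'
#' @param Y an [AssociationMatrix-class] or numeric matrix.
#' @param k latent dimension, `1 <= k <= min(n, m)`.
#' @return a [FactorPair-class] with row labels carried over from `Y`.
#' @export
svdInit <- function(Y, k) {
  Ym <- as(Y, "matrix")
  k <- as.integer(k)
  if (k < 1L || k > min(dim(Ym)))
    stop("k must lie in 1..min(n, m)")
  s <- svd(Ym, nu = k, nv = k)
  d <- s$d[seq_len(k)]
  if (any(d < 1e-12 * max(s$d[1], 1e-300)))
    warning("k exceeds the numerical rank of Y; zero singular values retained")
  sq <- sqrt(d)
  A <- s$u * rep(sq, each = nrow(Ym))
  B <- s$v * rep(sq, each = ncol(Ym))
  rownames(A) <- rownames(Ym)
  rownames(B) <- colnames(Ym)
  factorPair(A, B)
}

.lambda21 <- function(cfg) if (is.na(cfg@lambda21)) cfg@lambdaL else cfg@lambda21

#' Factorization objective
#'
#' `||Y - A B^T||_F^2 + lambdaL (||A||_F^2 + ||B||_F^2) + lambda21 ||B||_{2,1}
#'  + lambdaD ||Sm - A A^T||_F^2 + lambdaT ||Sd - B B^T||_F^2`,
#' where the L2,1 term (sum of row norms of B, weighted by `lambdaL`
#' unless decoupled) is present only for the RCMF variant.
#'
#' @param Y association matrix (n x m).
#' @param A,B latent factors (n x k, m x k).
#' @param Sm,Sd similarity matrices; may be `NULL` when the corresponding
#'   weight is zero.
#' @param cfg an [RcmfConfig-class].
#' @return the scalar objective value.
#' @export
rcmfObjective <- function(Y, A, B, Sm = NULL, Sd = NULL, cfg = rcmfConfig()) {
  Ym <- as(Y, "matrix")
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("non-finite factor entries")
  obj <- sum((Ym - tcrossprod(A, B))^2) +
    cfg@lambdaL * (sum(A^2) + sum(B^2))
  if (cfg@variant == "RCMF")
    obj <- obj + .lambda21(cfg) * sum(.rowNorms(B))
  if (cfg@lambdaD > 0) {
    if (is.null(Sm)) stop("Sm required when lambdaD > 0")
    obj <- obj + cfg@lambdaD * sum((as(Sm, "matrix") - tcrossprod(A))^2)
  }
  if (cfg@lambdaT > 0) {
    if (is.null(Sd)) stop("Sd required when lambdaT > 0")
    obj <- obj + cfg@lambdaT * sum((as(Sd, "matrix") - tcrossprod(B))^2)
  }
  obj
}

#' IRLS reweighting diagonal for the L2,1 penalty
#'
#' `d_ii = 1 / (2 max(||row i of B||_2, epsilon))`; the epsilon floor
#' smooths the derivative singularity at zero rows.
#'
#' @param B disease factor matrix (m x k).
#' @param epsilon positive row-norm guard.
#' @return vector of m strictly positive weights.
#' @export
reweightD <- function(B, epsilon = 1e-8) {
  if (epsilon <= 0) stop("epsilon must be positive")
  1 / (2 * pmax(.rowNorms(as.matrix(B)), epsilon))
}

#' Closed-form update of the miRNA factor A
#'
#' `A = (Y B + lambdaD Sm A_prev) (B^T B + lambdaL I_k +
#'  lambdaD A_prev^T A_prev)^{-1}` — the alternating least-squares step
#' with the previous iterate standing in for A on the right-hand side.
#'
#' @param Y association matrix (n x m).
#' @param Aprev previous iterate of A.
#' @param B current disease factors.
#' @param Sm miRNA similarity (ignored when `lambdaD = 0`).
#' @param cfg an [RcmfConfig-class].
#' @return the updated n x k matrix.
#' @export
updateA <- function(Y, Aprev, B, Sm = NULL, cfg = rcmfConfig()) {
  Ym <- as(Y, "matrix")
  k <- ncol(B)
  G <- crossprod(B) + diag(cfg@lambdaL, k)
  R <- Ym %*% B
  if (cfg@lambdaD > 0) {
    G <- G + cfg@lambdaD * crossprod(Aprev)
    R <- R + cfg@lambdaD * as(Sm, "matrix") %*% Aprev
  }
  .solveRight(R, G)
}

#' Row-wise update of the disease factor B
#'
#' With `M = Y^T A + lambdaT Sd B_prev` and
#' `G = A^T A + lambdaL I_k + lambdaT B_prev^T B_prev`, row i of B solves
#' `row_i(B) (G + lambda21 d_ii I_k) = row_i(M)` where `d_ii` is the IRLS
#' weight from [reweightD()]. The CMF variant uses `d_ii = 0` for all
#' rows. Solved through the eigendecomposition of `G` (one factorization,
#' a diagonal rescale per row); near-zero eigenvalues are treated as in a
#' pseudoinverse, with a warning.
#'
#' @param Y association matrix.
#' @param A current miRNA factors.
#' @param Bprev previous iterate of B.
#' @param Sd disease similarity (ignored when `lambdaT = 0`).
#' @param D vector of IRLS weights, usually `reweightD(Bprev, epsilon)`;
#'   `NULL` computes it from `Bprev` (or zeros for the CMF variant).
#' @param cfg an [RcmfConfig-class].
#' @return the updated m x k matrix.
#' @export
updateB <- function(Y, A, Bprev, Sd = NULL, D = NULL, cfg = rcmfConfig()) {
  Ym <- as(Y, "matrix")
  m <- ncol(Ym); k <- ncol(A)
  if (is.null(D))
    D <- if (cfg@variant == "CMF") rep(0, m) else reweightD(Bprev, cfg@epsilon)
  if (cfg@variant == "CMF") D <- rep(0, m)
  G <- crossprod(A) + diag(cfg@lambdaL, k)
  M <- crossprod(Ym, A)
  if (cfg@lambdaT > 0) {
    G <- G + cfg@lambdaT * crossprod(Bprev)
    M <- M + cfg@lambdaT * as(Sd, "matrix") %*% Bprev
  }
  eg <- eigen(G, symmetric = TRUE)
  shift <- outer(.lambda21(cfg) * D, eg$values, "+")  # m x k of per-row eigenvalues
  if (any(abs(shift) < 1e-12)) {
    warning("singular per-row system in B update; using pseudoinverse")
    inv <- ifelse(abs(shift) < 1e-12, 0, 1 / shift)
  } else inv <- 1 / shift
  ((M %*% eg$vectors) * inv) %*% t(eg$vectors)
}

#' Fit the factorization by alternating updates
#'
#' Initializes with [svdInit()], then alternates [updateA()], the IRLS
#' reweighting [reweightD()] and [updateB()] until the relative objective
#' change drops below `cfg@tol` or `cfg@maxIter` is reached. The solver is
#' deterministic: identical inputs give bit-identical traces. An
#' objective increase of more than 10% across one iteration aborts with a
#' diagnostic.
#'
#' @param Y an [AssociationMatrix-class] (binary or WKNKN-preprocessed).
#' @param Sm,Sd similarity matrices aligned with the rows/columns of `Y`;
#'   may be `NULL` when the corresponding weight is zero.
#' @param cfg an [RcmfConfig-class]; `k = NA` resolves to `min(n, m, 50)`.
#' @return an [RcmfFit-class].
#' @export
rcmf <- function(Y, Sm = NULL, Sd = NULL, cfg = rcmfConfig()) {
  Ym <- as(Y, "matrix")
  if (is.na(cfg@k)) cfg@k <- as.integer(min(dim(Ym), 50L))
  if (!is.null(Sm) && !identical(rownames(Ym), rownames(as(Sm, "matrix"))))
    stop("miRNA labels of Y and Sm do not align")
  if (!is.null(Sd) && !identical(colnames(Ym), rownames(as(Sd, "matrix"))))
    stop("disease labels of Y and Sd do not align")
  fp <- svdInit(Ym, cfg@k)
  A <- fp@A; B <- fp@B
  trace <- rcmfObjective(Ym, A, B, Sm, Sd, cfg)
  converged <- FALSE
  iters <- 0L
  # absolute floor so an exactly-factorizable Y (objective ~ 0) terminates
  floorChange <- 1e-15 * max(1, sum(Ym^2))
  objFun <- function(A_, B_) rcmfObjective(Ym, A_, B_, Sm, Sd, cfg)
  # the closed-form candidates are fixed-point steps, not guaranteed
  # descent steps when the similarity weights are large; damp toward the
  # previous iterate until the objective does not increase
  damp <- function(old, cand, objOf) {
    base <- objOf(old) * (1 + 1e-12)   # slack for roundoff-neutral steps
    step <- cand
    for (h in 1:30) {
      if (objOf(step) <= base) return(step)
      step <- old + (step - old) / 2
    }
    old
  }
  for (it in seq_len(cfg@maxIter)) {
    A <- damp(A, updateA(Ym, A, B, Sm, cfg), function(x) objFun(x, B))
    D <- if (cfg@variant == "CMF") rep(0, ncol(Ym)) else reweightD(B, cfg@epsilon)
    B <- damp(B, updateB(Ym, A, B, Sd, D, cfg), function(x) objFun(A, x))
    obj <- rcmfObjective(Ym, A, B, Sm, Sd, cfg)
    prev <- trace[length(trace)]
    if (obj > prev * 1.10 + 1e-12)
      stop(sprintf(
        "divergence: objective rose from %.6g to %.6g at iteration %d", prev, obj, it))
    trace <- c(trace, obj)
    iters <- it
    if (abs(prev - obj) < cfg@tol * abs(prev) + floorChange) {
      converged <- TRUE
      break
    }
  }
  rownames(A) <- rownames(Ym)
  rownames(B) <- colnames(Ym)
  new("RcmfFit", factors = factorPair(A, B), objectiveTrace = trace,
      iterationsRun = iters, converged = converged, config = cfg)
}

#' Predicted association scores
#'
#' The score matrix `Y* = A B^T`; higher scores mean stronger predicted
#' miRNA-disease association.
#'
#' @param x an [RcmfFit-class] or [FactorPair-class].
#' @return an [AssociationMatrix-class] with `predicted = TRUE`.
#' @export
predictScores <- function(x) {
  fp <- if (is(x, "RcmfFit")) x@factors else x
  associationMatrix(tcrossprod(fp@A, fp@B), predicted = TRUE)
}

#' Rank candidate miRNAs for one disease
#'
#' Orders the miRNAs by descending predicted score for the given disease,
#' ties broken by label order, and flags pairs already present in a known
#' association matrix.
#'
#' @param Ystar predicted score matrix (from [predictScores()]).
#' @param disease a disease (column) label.
#' @param known optional binary [AssociationMatrix-class]; pairs with a 1
#'   are flagged `"known"`, others `"candidate"`.
#' @return data frame with columns `rank`, `miRNA`, `score`, `status`.
#' @export
rankCandidates <- function(Ystar, disease, known = NULL) {
  Ym <- as(Ystar, "matrix")
  if (!disease %in% colnames(Ym))
    stop("unknown disease: ", disease)
  scores <- Ym[, disease]
  ord <- order(-scores, rownames(Ym))
  status <- rep("candidate", nrow(Ym))
  if (!is.null(known)) {
    Km <- as(known, "matrix")
    status[Km[rownames(Ym), disease] == 1] <- "known"
  }
  data.frame(rank = seq_len(nrow(Ym)), miRNA = rownames(Ym)[ord],
             score = unname(scores[ord]), status = status[ord],
             stringsAsFactors = FALSE)
}
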