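#' @include AllClasses.R constructors.R
NULL

# one-sided WKNKN estimate: for each profile (row of Y) build a
# decay-weighted average of the K most similar *known* profiles
# (profiles with >= 1 association), weights p^(t-1) * s_t, normalized by
# the plain similarity sum. Rows with no known neighbor, or with all-zero
# similarity to them, contribute 0.
.wknknSide <- function(Y, S, K, p) {
  n <- nrow(Y)
  est <- matrix(0, n, ncol(Y))
  known <- rowSums(Y) > 0
  shortfall <- FALSE
  for (i in seq_len(n)) {
    cand <- setdiff(which(known), i)
    if (!length(cand)) next
    sims <- S[i, cand]
    ord <- order(-sims, cand)      # ties broken by label (index) order
    if (length(cand) < K) shortfall <- TRUE
    take <- ord[seq_len(min(K, length(cand)))]
    idx <- cand[take]
    w <- p^(seq_along(idx) - 1) * sims[take]
    denom <- sum(sims[take])
    if (denom > 0)
      est[i, ] <- colSums(w * Y[idx, , drop = FALSE]) / denom
  }
  if (shortfall)
    warning("fewer than K known neighbors available; used all available")
  est
}

#' WKNKN: weighted K-nearest-known-neighbor imputation
#'
#' Replaces likely-missing zeros of a binary association matrix by
#' decay-weighted neighbor estimates before factorization. For each zero
#' entry, a miRNA-side estimate (over the K most similar miRNA rows that
#' have at least one known association) and a disease-side estimate
#' (symmetric, over columns) are averaged, and the entry becomes the
#' maximum of its original value and that average. Known 1 entries are
#' never changed; both sides read the original `Y`, so the operator is
#' order-independent.
#'
#' @param Y a binary [AssociationMatrix-class].
#' @param Sm miRNA similarity ([SimilarityMatrix-class], rows of `Y`).
#' @param Sd disease similarity (columns of `Y`).
#' @param cfg a [WknknConfig-class]; defaults K = 5, p = 0.7.
#' @return an [AssociationMatrix-class] with values in \[0, 1\].
#' @export
wknkn <- function(Y, Sm, Sd, cfg = wknknConfig()) {
  Ym <- as(Y, "matrix")
  Sm_ <- as(Sm, "matrix"); Sd_ <- as(Sd, "matrix")
  if (!identical(rownames(Ym), rownames(Sm_)))
    stop("miRNA labels of Y and Sm do not align")
  if (!identical(colnames(Ym), rownames(Sd_)))
    stop("disease labels of Y and Sd do not align")
  estM <- .wknknSide(Ym, Sm_, cfg@K, cfg@p)
  estD <- t(.wknknSide(t(Ym), Sd_, cfg@K, cfg@p))
  out <- pmax(Ym, (estM + estD) / 2)
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- dimnames(Ym)
  associationMatrix(out)
}
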