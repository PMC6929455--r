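# Independent brute-force oracles, written directly from the defining
# formulas with plain loops. They deliberately share no code with the
# package implementations they check.

# --- DAG semantic similarity ------------------------------------------------

# dag here is a plain list(terms =, edges = 2-col matrix child/parent)
bfAncestors <- function(edges, term) {
  anc <- term
  repeat {
    more <- unique(edges[edges[, 1] %in% anc, 2])
    more <- setdiff(more, anc)
    if (!length(more)) return(anc)
    anc <- c(anc, more)
  }
}

bfContribution <- function(edges, root, node, delta) {
  if (node == root) return(1)
  Tset <- bfAncestors(edges, root)
  kids <- intersect(edges[edges[, 2] == node, 1], Tset)
  delta * max(vapply(kids, function(k) bfContribution(edges, root, k, delta),
                     numeric(1)))
}

bfSemanticValue <- function(edges, term, delta) {
  sum(vapply(bfAncestors(edges, term), function(t)
    bfContribution(edges, term, t, delta), numeric(1)))
}

bfSemanticSimilarity <- function(edges, terms, delta) {
  n <- length(terms)
  S <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ti <- terms[i]; tj <- terms[j]
    shared <- intersect(bfAncestors(edges, ti), bfAncestors(edges, tj))
    num <- 0
    for (t in shared)
      num <- num + bfContribution(edges, ti, t, delta) +
        bfContribution(edges, tj, t, delta)
    S[i, j] <- num / (bfSemanticValue(edges, ti, delta) +
                        bfSemanticValue(edges, tj, delta))
  }
  diag(S) <- 1
  S
}

# random DAG: each node may take parents only among earlier nodes, so the
# graph is acyclic by construction; some nodes stay isolated
randomDag <- function(nNodes, pEdge = 0.4) {
  terms <- sprintf("t%02d", seq_len(nNodes))
  edges <- NULL
  for (i in seq_len(nNodes)[-1]) {
    parents <- which(stats::runif(i - 1) < pEdge)
    for (p in parents) edges <- rbind(edges, c(terms[i], terms[p]))
  }
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  list(terms = terms, edges = edges)
}

# --- GIP kernel -------------------------------------------------------------

bfGip <- function(Y, byRow = TRUE, scale = 1) {
  P <- if (byRow) Y else t(Y)
  n <- nrow(P)
  norm2 <- numeric(n)
  for (i in seq_len(n)) norm2[i] <- sum(P[i, ]^2)
  gamma <- scale / mean(norm2)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  dimnames(K) <- list(rownames(P), rownames(P))
  K
}

# --- WKNKN ------------------------------------------------------------------

# scalar-loop one-sided estimate, then the symmetric combination
bfWknknSide <- function(Y, S, K, p) {
  n <- nrow(Y); m <- ncol(Y)
  est <- matrix(0, n, m)
  for (i in seq_len(n)) {
    nb <- c()
    for (j in seq_len(n)) if (j != i && sum(Y[j, ]) > 0) nb <- c(nb, j)
    if (!length(nb)) next
    nb <- nb[order(-S[i, nb], nb)]
    nb <- nb[seq_len(min(K, length(nb)))]
    denom <- 0
    for (t in seq_along(nb)) denom <- denom + S[i, nb[t]]
    if (denom == 0) next
    for (jj in seq_len(m)) {
      num <- 0
      for (t in seq_along(nb))
        num <- num + p^(t - 1) * S[i, nb[t]] * Y[nb[t], jj]
      est[i, jj] <- num / denom
    }
  }
  est
}

bfWknkn <- function(Y, Sm, Sd, K, p) {
  em <- bfWknknSide(Y, Sm, K, p)
  ed <- t(bfWknknSide(t(Y), Sd, K, p))
  out <- Y
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y)))
    out[i, j] <- max(Y[i, j], (em[i, j] + ed[i, j]) / 2)
  out
}

# --- factorization objective ------------------------------------------------

bfObjective <- function(Y, A, B, Sm, Sd, ll, ld, lt, l21 = ll,
                        withL21 = TRUE) {
  recon <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y)))
    recon <- recon + (Y[i, j] - sum(A[i, ] * B[j, ]))^2
  obj <- recon + ll * (sum(A^2) + sum(B^2))
  if (withL21)
    for (i in seq_len(nrow(B))) obj <- obj + l21 * sqrt(sum(B[i, ]^2))
  if (ld > 0) obj <- obj + ld * sum((Sm - A %*% t(A))^2)
  if (lt > 0) obj <- obj + lt * sum((Sd - B %*% t(B))^2)
  obj
}

# --- AUC --------------------------------------------------------------------

bfAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}

# --- shared fixture helpers -------------------------------------------------

randomAssociation <- function(n, m, density = 0.3) {
  Y <- matrix(as.numeric(stats::runif(n * m) < density), n, m)
  if (all(Y == 0)) Y[sample(n * m, 1)] <- 1
  dimnames(Y) <- list(sprintf("m%02d", seq_len(n)), sprintf("d%02d", seq_len(m)))
  Y
}

randomSimilarity <- function(labels) {
  n <- length(labels)
  X <- matrix(stats::runif(n * 3), n)
  S <- exp(-as.matrix(stats::dist(X))^2)
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  S
}

# independent plain-CMF alternating solver (single-matrix B solve, no
# reweighting), used as the classical-CMF reference; applies the same
# backtracking safeguard rule as the package solver, coded separately
referenceCmf <- function(Y, Sm, Sd, k, ll, ld, lt, maxIter, tol) {
  s <- svd(Y, nu = k, nv = k)
  A <- s$u %*% diag(sqrt(s$d[1:k]), k)
  B <- s$v %*% diag(sqrt(s$d[1:k]), k)
  obj <- function(A, B) bfObjective(Y, A, B, Sm, Sd, ll, ld, lt, withL21 = FALSE)
  backtrack <- function(old, cand, f) {
    lim <- f(old) * (1 + 1e-12)
    for (h in 1:30) {
      if (f(cand) <= lim) return(cand)
      cand <- old + (cand - old) / 2
    }
    old
  }
  trace <- obj(A, B)
  for (it in seq_len(maxIter)) {
    candA <- (Y %*% B + ld * Sm %*% A) %*%
      solve(t(B) %*% B + ll * diag(k) + ld * t(A) %*% A)
    A <- backtrack(A, candA, function(x) obj(x, B))
    candB <- (t(Y) %*% A + lt * Sd %*% B) %*%
      solve(t(A) %*% A + ll * diag(k) + lt * t(B) %*% B)
    B <- backtrack(B, candB, function(x) obj(A, x))
    o <- obj(A, B)
    prev <- trace[length(trace)]
    trace <- c(trace, o)
    if (abs(prev - o) < tol * abs(prev)) break
  }
  list(A = A, B = B, trace = trace)
}
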