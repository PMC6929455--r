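test_that("SVD initialization attains the Eckart-Young optimum", {
  I2 <- diag(2); dimnames(I2) <- list(c("a", "b"), c("x", "y"))
  fp <- svdInit(I2, 2)
  expect_equal(tcrossprod(latentA(fp), latentB(fp)), I2, tolerance = 1e-12)

  Z <- matrix(0, 3, 2, dimnames = list(paste0("m", 1:3), paste0("d", 1:2)))
  fpz <- suppressWarnings(svdInit(Z, 1))
  expect_equal(latentA(fpz), matrix(0, 3, 1, dimnames = list(rownames(Z), NULL)))

  set.seed(21)
  for (rep in 1:20) {
    Y <- matrix(stats::rnorm(24), 6, 4,
                dimnames = list(paste0("m", 1:6), paste0("d", 1:4)))
    k <- sample(1:3, 1)
    fp <- svdInit(Y, k)
    err <- sqrt(sum((Y - tcrossprod(fp@A, fp@B))^2))
    d <- svd(Y)$d
    expect_equal(err, sqrt(sum(d[-seq_len(k)]^2)), tolerance = 1e-10)
  }
  expect_error(svdInit(Y, 7), "min")
})

test_that("objective matches hand evaluation and the brute-force oracle", {
  I2 <- diag(2); dimnames(I2) <- list(c("a", "b"), c("x", "y"))
  cfg0 <- rcmfConfig(lambdaL = 0, lambdaD = 0, lambdaT = 0, k = 2)
  expect_equal(rcmfObjective(I2, diag(2), diag(2), cfg = cfg0), 0)
  expect_equal(rcmfObjective(I2, matrix(0, 2, 2), matrix(0, 2, 2), cfg = cfg0),
               sum(I2^2))
  # lambdaL = 1, A = B = Y = Sm = Sd = I: 0 + 1*(2+2) + 1*2 + 0 + 0 = 6
  cfg1 <- rcmfConfig(lambdaL = 1, lambdaD = 0, lambdaT = 0, k = 2)
  expect_equal(rcmfObjective(I2, diag(2), diag(2), cfg = cfg1), 6)
  expect_error(rcmfObjective(I2, matrix(NaN, 2, 2), diag(2), cfg = cfg0),
               "finite")

  set.seed(22)
  for (rep in 1:60) {
    Y <- randomAssociation(5, 4)
    A <- matrix(stats::rnorm(10), 5, 2); B <- matrix(stats::rnorm(8), 4, 2)
    Sm <- randomSimilarity(rownames(Y)); Sd <- randomSimilarity(colnames(Y))
    ll <- stats::runif(1, 0, 2); ld <- stats::runif(1, 0, 0.1)
    lt <- stats::runif(1, 0, 0.1)
    for (variant in c("RCMF", "CMF")) {
      cfg <- rcmfConfig(ll, ld, lt, k = 2, variant = variant)
      expect_equal(rcmfObjective(Y, A, B, Sm, Sd, cfg),
                   bfObjective(Y, A, B, Sm, Sd, ll, ld, lt,
                               withL21 = variant == "RCMF"),
                   tolerance = 1e-12)
    }
  }
})

test_that("IRLS weights are positive, guarded and homogeneous", {
  B <- rbind(c(3, 4), c(0, 0))
  d <- reweightD(B, 1e-8)
  expect_equal(d[1], 1 / 10)
  expect_equal(d[2], 1 / (2e-8))
  expect_equal(reweightD(3 * B, 1e-8)[1], d[1] / 3)
  expect_error(reweightD(B, 0), "positive")
})

test_that("updateA solves the regularized least-squares subproblem", {
  set.seed(23)
  Y <- matrix(stats::rnorm(12), 4, 3)
  # orthonormal B, no regularization: A = Y B
  B <- qr.Q(qr(matrix(stats::rnorm(6), 3, 2)))
  cfg0 <- rcmfConfig(0, 0, 0, k = 2)
  expect_equal(updateA(Y, matrix(0, 4, 2), B, cfg = cfg0), Y %*% B,
               tolerance = 1e-12)

  # ridge solution: gradient of ||Y - AB'||^2 + ll ||A||^2 vanishes
  B2 <- matrix(stats::rnorm(6), 3, 2)
  cfgR <- rcmfConfig(0.7, 0, 0, k = 2)
  A <- updateA(Y, matrix(0, 4, 2), B2, cfg = cfgR)
  grad <- -2 * (Y - A %*% t(B2)) %*% B2 + 2 * 0.7 * A
  expect_lt(max(abs(grad)), 1e-10)

  # fixed point of the lambdaD-coupled map
  Sm <- randomSimilarity(paste0("m", 1:4))
  cfgD <- rcmfConfig(0.5, 0.05, 0, k = 2)
  Ai <- matrix(stats::rnorm(8), 4, 2)
  for (i in 1:200) Ai <- updateA(Y, Ai, B2, Sm, cfgD)
  expect_equal(updateA(Y, Ai, B2, Sm, cfgD), Ai, tolerance = 1e-10)
})

test_that("updateB satisfies the per-row stationarity of its surrogate", {
  set.seed(24)
  Y <- matrix(stats::rnorm(12), 4, 3)
  A <- qr.Q(qr(matrix(stats::rnorm(8), 4, 2)))
  cfg0 <- rcmfConfig(0, 0, 0, k = 2)
  expect_equal(updateB(Y, A, matrix(1, 3, 2), D = rep(0, 3), cfg = cfg0),
               t(Y) %*% A, tolerance = 1e-12)

  Bprev <- matrix(stats::rnorm(6), 3, 2)
  Sd <- randomSimilarity(paste0("d", 1:3))
  cfg <- rcmfConfig(0.8, 0, 0.05, k = 2)
  D <- reweightD(Bprev, 1e-8)
  B <- updateB(Y, A, Bprev, Sd, D, cfg)
  G <- t(A) %*% A + 0.8 * diag(2) + 0.05 * t(Bprev) %*% Bprev
  M <- t(Y) %*% A + 0.05 * Sd %*% Bprev
  for (i in 1:3) {
    resid <- B[i, ] %*% (G + 0.8 * D[i] * diag(2)) - M[i, ]
    expect_lt(max(abs(resid)), 1e-8)
  }
  # uniform weights coincide with the single-matrix solve
  Du <- rep(0.3, 3)
  Bu <- updateB(Y, A, Bprev, Sd, Du, cfg)
  expect_equal(Bu, M %*% solve(G + 0.8 * 0.3 * diag(2)), tolerance = 1e-10)
})

test_that("CMF updates equal the RCMF updates with all weights zero", {
  set.seed(25)
  Y <- randomAssociation(6, 5)
  Sm <- randomSimilarity(rownames(Y)); Sd <- randomSimilarity(colnames(Y))
  A <- matrix(stats::rnorm(12), 6, 2); Bp <- matrix(stats::rnorm(10), 5, 2)
  cfgR <- rcmfConfig(0.5, 0.01, 0.01, k = 2)
  cfgC <- rcmfConfig(0.5, 0.01, 0.01, k = 2, variant = "CMF")
  expect_identical(updateB(Y, A, Bp, Sd, rep(0, 5), cfgR),
                   updateB(Y, A, Bp, Sd, NULL, cfgC))
})

test_that("alternating fit converges, is monotone and deterministic", {
  # exact rank-k input with no regularization: immediate exact fit
  set.seed(26)
  L <- matrix(stats::rnorm(10), 5, 2); R <- matrix(stats::rnorm(8), 4, 2)
  Y <- L %*% t(R)
  dimnames(Y) <- list(paste0("m", 1:5), paste0("d", 1:4))
  f0 <- rcmf(associationMatrix(Y, predicted = TRUE),
             cfg = rcmfConfig(0, 0, 0, k = 2, variant = "CMF"))
  expect_lte(f0@iterationsRun, 2L)
  expect_lt(objectiveTrace(f0)[length(objectiveTrace(f0))], 1e-10)
  expect_equal(as(predictScores(f0), "matrix"), Y, tolerance = 1e-6,
               ignore_attr = TRUE)

  Yb <- randomAssociation(10, 8, 0.3)
  Sm <- similarityMatrix(as(gipKernel(Yb, "miRNA"), "matrix"))
  Sd <- similarityMatrix(as(gipKernel(Yb, "disease"), "matrix"))
  f1 <- rcmf(associationMatrix(Yb), Sm, Sd, rcmfConfig(k = 3))
  f2 <- rcmf(associationMatrix(Yb), Sm, Sd, rcmfConfig(k = 3))
  expect_identical(objectiveTrace(f1), objectiveTrace(f2))  # bit-identical
  tr <- objectiveTrace(f1)
  expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
  expect_lte(tr[length(tr)], tr[1])   # no worse than the SVD start
})

test_that("predicted scores are the factor product with labels", {
  set.seed(27)
  a <- stats::rnorm(4); b <- stats::rnorm(3)
  fp <- factorPair(matrix(a, 4, 1, dimnames = list(paste0("m", 1:4), NULL)),
                   matrix(b, 3, 1, dimnames = list(paste0("d", 1:3), NULL)))
  expect_equal(as(predictScores(fp), "matrix"), outer(a, b),
               ignore_attr = TRUE)
  zero <- factorPair(matrix(0, 4, 1, dimnames = list(paste0("m", 1:4), NULL)),
                     matrix(0, 3, 1, dimnames = list(paste0("d", 1:3), NULL)))
  expect_true(all(as(predictScores(zero), "matrix") == 0))
})

test_that("candidate ranking sorts by score with label-order ties", {
  Ystar <- matrix(c(0.9, 0.1, 0.5), 3, 1,
                  dimnames = list(c("a", "b", "c"), "dz"))
  r <- rankCandidates(associationMatrix(Ystar, predicted = TRUE), "dz")
  expect_equal(r$miRNA, c("a", "c", "b"))
  expect_equal(r$rank, 1:3)

  tied <- matrix(0.5, 3, 1, dimnames = dimnames(Ystar))
  rt <- rankCandidates(associationMatrix(tied, predicted = TRUE), "dz")
  expect_equal(rt$miRNA, c("a", "b", "c"))

  known <- matrix(c(1, 0, 0), 3, 1, dimnames = dimnames(Ystar))
  rk <- rankCandidates(associationMatrix(Ystar, predicted = TRUE), "dz",
                       associationMatrix(known))
  expect_equal(rk$status, c("known", "candidate", "candidate"))
  expect_error(rankCandidates(associationMatrix(Ystar, predicted = TRUE),
                              "missing"), "unknown disease")
})

test_that("planted associations resurface at the top of the ranking", {
  inst <- makePlanted(30, 20, 2, 0.15, 0, 0.1, seed = 5)
  Y <- inst@Y
  Sm <- integrateSimilarity(inst@Sm, gipKernel(Y, "miRNA"), "mean")
  Sd <- integrateSimilarity(inst@Sd, gipKernel(Y, "disease"), "mean")
  fit <- rcmf(wknkn(Y, Sm, Sd), Sm, Sd, rcmfConfig(0.5, 0.01, 0.01, k = 8))
  sc <- predictScores(fit)
  held <- heldOut(inst)
  hits <- 0
  for (i in seq_len(nrow(held))) {
    dis <- colnames(as(Y, "matrix"))[held[i, 2]]
    r <- rankCandidates(sc, dis, Y)
    mir <- rownames(as(Y, "matrix"))[held[i, 1]]
    cand <- r[r$status == "candidate", ]
    if (match(mir, cand$miRNA) <= ceiling(nrow(cand) * 0.2)) hits <- hits + 1
  }
  expect_gt(hits / nrow(held), 0.7)   # most masked pairs in the top 20%
})
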