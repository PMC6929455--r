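#' @include AllClasses.R constructors.R similarity.R factorization.R
NULL

#' Generate a planted low-rank association instance
#'
#' Draws nonnegative rank-`kTrue` factors, thresholds their product so
#' that exactly `round(n m density)` entries are 1, flips a fraction
#' `noiseRate` of entries, and masks a fraction `maskFraction` of the
#' positives that are true under the noiseless planted structure. The
#' similarity matrices are GIP kernels of the noiseless truth. A pure
#' function of its parameters and seed.
#'
#' @param n,m numbers of miRNAs (rows) and diseases (columns).
#' @param kTrue planted rank, `1 <= kTrue <= min(n, m)`.
#' @param density target fraction of 1 entries.
#' @param noiseRate fraction of entries flipped after thresholding.
#' @param maskFraction fraction of true positives masked to 0 and recorded
#'   as held out.
#' @param seed integer seed.
#' @return a [PlantedInstance-class].
#' @export
makePlanted <- function(n = 40, m = 30, kTrue = 2, density = 0.15,
                        noiseRate = 0.01, maskFraction = 0.1, seed = 1) {
  if (kTrue < 1 || kTrue > min(n, m)) stop("kTrue must lie in 1..min(n, m)")
  for (v in c(density, noiseRate, maskFraction))
    if (v < 0 || v > 1) stop("density, noiseRate and maskFraction must lie in [0, 1]")
  nOnes <- round(n * m * density)
  if (nOnes < 1 || nOnes >= n * m)
    stop("infeasible density: no (or only) positive entries")
  withr::with_seed(as.integer(seed), {
    trueA <- matrix(stats::rgamma(n * kTrue, shape = 2, rate = 2), n, kTrue)
    trueB <- matrix(stats::rgamma(m * kTrue, shape = 2, rate = 2), m, kTrue)
    scores <- tcrossprod(trueA, trueB)
    # exact density: the top nOnes scores become 1 (ties by index order)
    Ytrue <- matrix(0, n, m)
    Ytrue[order(-scores, seq_along(scores))[seq_len(nOnes)]] <- 1
    Y <- Ytrue
    nFlip <- round(noiseRate * n * m)
    if (nFlip > 0) {
      flip <- sample(n * m, nFlip)
      Y[flip] <- 1 - Y[flip]
    }
    # mask only pairs that are positive both under the truth and in Y
    maskable <- which(Y == 1 & Ytrue == 1)
    nMask <- round(maskFraction * length(maskable))
    held <- if (nMask > 0) sort(sample(maskable, nMask)) else integer(0)
    Y[held] <- 0
  })
  mirnas <- sprintf("mir-%03d", seq_len(n))
  diseases <- sprintf("dis-%03d", seq_len(m))
  dimnames(Y) <- dimnames(Ytrue) <- list(mirnas, diseases)
  rownames(trueA) <- mirnas
  rownames(trueB) <- diseases
  heldOut <- cbind(row = ((held - 1) %% n) + 1L,
                   col = ((held - 1) %/% n) + 1L)
  new("PlantedInstance", Y = associationMatrix(Y),
      Sm = gipKernel(Ytrue, "miRNA"), Sd = gipKernel(Ytrue, "disease"),
      trueA = trueA, trueB = trueB,
      heldOut = matrix(as.integer(heldOut), ncol = 2,
                       dimnames = list(NULL, c("row", "col"))),
      seed = as.integer(seed))
}

#' Generate a 2-D line cloud with off-line noise
#'
#' `nInliers` points exactly on the line y = x (x uniform on \[0, 20\])
#' plus `nNoise` points displaced off the line by a uniform positive
#' offset in `(0, spread)`; row order is shuffled. The one-sided offsets
#' give the noise a net pull on direction estimates, which is what the
#' robustness comparison probes (zero-mean noise would cancel for any
#' least-squares fit).
#'
#' @param nInliers number of on-line points (>= 2).
#' @param nNoise number of noise points.
#' @param spread half-width of the noise offset; default half the inlier
#'   coordinate range.
#' @param seed integer seed.
#' @return a [LineCloud-class].
#' @export
makeLineCloud <- function(nInliers = 200, nNoise = 0, spread = NULL,
                          seed = 1) {
  if (nInliers < 2) stop("need at least 2 inliers")
  withr::with_seed(as.integer(seed), {
    x <- stats::runif(nInliers, 0, 20)
    pts <- cbind(x, x)
    if (is.null(spread)) spread <- (max(x) - min(x)) / 2
    if (nNoise > 0) {
      u <- stats::runif(nNoise, min(x), max(x))
      off <- stats::runif(nNoise, 0, spread)
      pts <- rbind(pts, cbind(u, u + off))
    }
    pts <- pts[sample(nrow(pts)), , drop = FALSE]
  })
  dimnames(pts) <- list(NULL, c("x", "y"))
  new("LineCloud", points = pts, nInliers = as.integer(nInliers),
      nNoise = as.integer(nNoise), spread = spread, seed = as.integer(seed))
}

.subspaceAngle <- function(direction, target = c(1, 1) / sqrt(2)) {
  nd <- sqrt(sum(direction^2))
  if (nd == 0) return(90)
  cosang <- abs(sum(direction * target)) / nd
  acos(min(1, cosang)) * 180 / pi
}

#' Rank-1 subspace recovery under the two variants
#'
#' Treats the cloud as a data matrix (points as profiles), scale-
#' normalizes it to unit root-mean-square point norm, and fits a rank-1
#' factorization under each variant with the collaborative similarity
#' terms switched off (`lambdaD = lambdaT = 0`). The factorization sees
#' the 2-by-N orientation so that the L2,1-penalized factor B carries one
#' row per point — the row-sparsity mechanism that is supposed to
#' suppress outliers. Reports the angle (degrees) between the learned
#' one-dimensional subspace and the target direction (1, 1)/sqrt(2) for
#' each variant. The normalization makes the angle invariant to global
#' scaling of the cloud.
#'
#' @param cloud a [LineCloud-class].
#' @param cfgRcmf,cfgCmf configurations for the two variants; defaults
#'   use `k = 1`, `lambdaL = 1`, similarity terms off.
#' @return named numeric vector `c(rcmf = ..., cmf = ...)` of angles in
#'   degrees.
#' @export
robustnessExperiment <- function(cloud,
                                 cfgRcmf = rcmfConfig(lambdaL = 1, lambdaD = 0,
                                                      lambdaT = 0, k = 1),
                                 cfgCmf = rcmfConfig(lambdaL = 1, lambdaD = 0,
                                                     lambdaT = 0, k = 1,
                                                     variant = "CMF")) {
  P <- cloud@points
  if (!nrow(P)) stop("empty cloud")
  P <- P / sqrt(mean(rowSums(P^2)))
  Y <- t(P)   # 2 x N: columns are points, B holds one row per point
  dimnames(Y) <- list(c("x", "y"), sprintf("p%04d", seq_len(ncol(Y))))
  angle <- function(cfg) {
    fit <- rcmf(associationMatrix(Y, predicted = TRUE), cfg = cfg)
    .subspaceAngle(as.vector(fit@factors@A))
  }
  c(rcmf = angle(cfgRcmf), cmf = angle(cfgCmf))
}
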