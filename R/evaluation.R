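#' @include AllClasses.R constructors.R factorization.R wknkn.R similarity.R
NULL

#' Fold assignment for pair-holdout cross-validation
#'
#' Partitions the linear indices of the 1 entries of `Y` into `nFolds`
#' groups of near-equal size (differing by at most one), independently for
#' each repeat, reproducibly from the plan's seed.
#'
#' @param Y a binary [AssociationMatrix-class].
#' @param plan a [CvPlan-class].
#' @return list (one element per repeat) of lists of integer index vectors.
#' @export
makeFolds <- function(Y, plan = cvPlan()) {
  Ym <- as(Y, "matrix")
  if (!isBinaryAssociation(Ym)) stop("Y must be binary for fold assignment")
  ones <- which(Ym == 1)
  if (length(ones) < plan@nFolds)
    stop("fewer known pairs than folds")
  lapply(seq_len(plan@nRepeats), function(r) {
    perm <- withr::with_seed(plan@seed + r - 1L, sample(ones))
    grp <- rep(seq_len(plan@nFolds), length.out = length(perm))
    # rep() cycles 1..nFolds so sizes differ by at most one
    unname(split(perm, grp))
  })
}

#' Rank-based AUC
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, ties counted half — equal to the trapezoidal area under
#' the ROC curve (the Mann-Whitney statistic).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUC undefined: both classes must be present")
  if (np + nn != length(labels)) stop("labels must be 0 or 1")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

# one CV fold: mask the held-out pairs, rebuild similarities and WKNKN on
# the training matrix only, fit, and score held-out positives against all
# never-known pairs.
.cvFold <- function(Ym, holdIdx, negIdx, SmPrimary, SdPrimary, cfg, wk, mode) {
  Ytr <- Ym
  Ytr[holdIdx] <- 0
  Sm <- integrateSimilarity(SmPrimary, gipKernel(Ytr, "miRNA"), mode)
  Sd <- integrateSimilarity(SdPrimary, gipKernel(Ytr, "disease"), mode)
  Yw <- wknkn(associationMatrix(Ytr), Sm, Sd, wk)
  fit <- rcmf(Yw, Sm, Sd, cfg)
  scores <- tcrossprod(fit@factors@A, fit@factors@B)
  aucScore(c(scores[holdIdx], scores[negIdx]),
           c(rep(1L, length(holdIdx)), rep(0L, length(negIdx))))
}

#' Repeated pair-holdout cross-validation (CV-p)
#'
#' For each repeat and fold the held-out known pairs are zeroed in a
#' training copy of `Y`; GIP similarities and the WKNKN imputation are
#' recomputed from the training matrix only (no leakage of held-out
#' labels); the model is fitted and the held-out positives are scored
#' against all never-known pairs. The per-repeat AUC is the mean over
#' folds; the result reports mean and sd over repeats.
#'
#' @param Y binary [AssociationMatrix-class].
#' @param SmPrimary,SdPrimary primary similarity matrices (functional /
#'   semantic), or `NULL` to use the GIP kernels alone.
#' @param cfg an [RcmfConfig-class].
#' @param wk a [WknknConfig-class].
#' @param plan a [CvPlan-class].
#' @param integration similarity integration mode, `"mean"` or
#'   `"gip_fill"`.
#' @return a [CvResult-class].
#' @export
runCv <- function(Y, SmPrimary = NULL, SdPrimary = NULL, cfg = rcmfConfig(),
                  wk = wknknConfig(), plan = cvPlan(),
                  integration = c("mean", "gip_fill")) {
  integration <- match.arg(integration)
  Ym <- as(Y, "matrix")
  folds <- makeFolds(Y, plan)
  negIdx <- which(Ym == 0)
  perRepeat <- vapply(folds, function(rep_folds) {
    mean(vapply(rep_folds, .cvFold, numeric(1), Ym = Ym, negIdx = negIdx,
                SmPrimary = SmPrimary, SdPrimary = SdPrimary, cfg = cfg,
                wk = wk, mode = integration))
  }, numeric(1))
  new("CvResult", aucMean = mean(perRepeat),
      aucSd = stats::sd(c(perRepeat, recursive = TRUE)) %||% 0,
      perRepeatAuc = perRepeat, plan = plan, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Grid search over the regularization weights
#'
#' Evaluates every `(lambdaL, lambdaD, lambdaT)` combination by
#' cross-validation and returns the best configuration (highest mean AUC;
#' ties broken toward smaller weights) along with the full score table.
#'
#' @param Y,SmPrimary,SdPrimary,wk,plan,integration as in [runCv()].
#' @param lambdaL,lambdaD,lambdaT grids of candidate weights; defaults are
#'   the usual search ranges \{2^-2, 2^-1, 1, 2\} and
#'   \{0, 1e-4, 1e-3, 1e-2, 1e-1\}.
#' @param cfgBase template [RcmfConfig-class] supplying all other slots.
#' @return list with elements `best` (an [RcmfConfig-class]) and `table`
#'   (data frame: lambdaL, lambdaD, lambdaT, aucMean, aucSd).
#' @export
gridSearch <- function(Y, SmPrimary = NULL, SdPrimary = NULL,
                       lambdaL = 2^(-2:1),
                       lambdaD = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                       lambdaT = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
                       cfgBase = rcmfConfig(), wk = wknknConfig(),
                       plan = cvPlan(), integration = "mean") {
  if (!length(lambdaL) || !length(lambdaD) || !length(lambdaT))
    stop("empty grid")
  combos <- expand.grid(lambdaL = lambdaL, lambdaD = lambdaD,
                        lambdaT = lambdaT, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- cfgBase
    cfg@lambdaL <- combos$lambdaL[i]
    cfg@lambdaD <- combos$lambdaD[i]
    cfg@lambdaT <- combos$lambdaT[i]
    runCv(Y, SmPrimary, SdPrimary, cfg, wk, plan, integration)
  })
  tab <- cbind(combos,
               aucMean = vapply(res, aucMean, numeric(1)),
               aucSd = vapply(res, aucSd, numeric(1)))
  best <- order(-tab$aucMean, tab$lambdaL, tab$lambdaD, tab$lambdaT)[1]
  bestCfg <- cfgBase
  bestCfg@lambdaL <- tab$lambdaL[best]
  bestCfg@lambdaD <- tab$lambdaD[best]
  bestCfg@lambdaT <- tab$lambdaT[best]
  list(best = bestCfg, table = tab)
}

#' Sensitivity sweep over the WKNKN parameters
#'
#' One cross-validation run per `(K, p)` combination, emitting a
#' long-format table for sensitivity plots.
#'
#' @param Y,SmPrimary,SdPrimary,cfg,plan,integration as in [runCv()].
#' @param Kvalues,pvalues candidate neighbor counts and decay values.
#' @return data frame with columns `K`, `p`, `aucMean`, `aucSd`.
#' @export
sensitivitySweep <- function(Y, SmPrimary = NULL, SdPrimary = NULL,
                             cfg = rcmfConfig(), Kvalues = 1:10,
                             pvalues = seq(0.1, 1, by = 0.1),
                             plan = cvPlan(), integration = "mean") {
  if (!length(Kvalues) || !length(pvalues)) stop("empty value lists")
  combos <- expand.grid(K = Kvalues, p = pvalues, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    runCv(Y, SmPrimary, SdPrimary, cfg,
          wknknConfig(combos$K[i], combos$p[i]), plan, integration)
  })
  cbind(combos,
        aucMean = vapply(res, aucMean, numeric(1)),
        aucSd = vapply(res, aucSd, numeric(1)))
}
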