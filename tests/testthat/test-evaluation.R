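test_that("fold assignment partitions the known pairs evenly and reproducibly", {
  set.seed(30)
  Y <- matrix(0, 5, 4, dimnames = list(paste0("m", 1:5), paste0("d", 1:4)))
  Y[sample(20, 10)] <- 1
  plan <- cvPlan(5, 3, seed = 9)
  folds <- makeFolds(associationMatrix(Y), plan)
  expect_length(folds, 3)
  for (rep_folds in folds) {
    expect_length(rep_folds, 5)
    expect_true(all(lengths(rep_folds) == 2))   # 10 pairs / 5 folds
    expect_setequal(unlist(rep_folds), which(Y == 1))
    expect_equal(anyDuplicated(unlist(rep_folds)), 0L)
  }
  expect_identical(folds, makeFolds(associationMatrix(Y), plan))
  tiny <- matrix(c(1, 0, 0, 1), 2, 2,
                 dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_error(makeFolds(associationMatrix(tiny), cvPlan(5, 1, 1)),
               "fewer known pairs")
})

test_that("rank-based AUC matches hand values and the all-pairs oracle", {
  expect_equal(aucScore(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(aucScore(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")

  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    scores <- round(stats::runif(n), 2)   # duplicates force tie handling
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    expect_equal(aucScore(scores, labels), bfAuc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  scores <- stats::runif(60)
  labels <- stats::rbinom(60, 1, 0.3)
  expect_equal(aucScore(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("cross-validation recovers planted structure and nulls out on shuffles", {
  inst <- makePlanted(30, 20, 2, 0.15, 0.01, 0, seed = 3)
  cfg <- rcmfConfig(0.5, 0.01, 0.01, k = 8)
  plan <- cvPlan(5, 4, seed = 17)
  res <- runCv(inst@Y, inst@Sm, inst@Sd, cfg, wknknConfig(), plan)
  expect_length(perRepeatAuc(res), 4)
  expect_gt(aucMean(res), 0.7)          # far above chance on planted data
  expect_identical(perRepeatAuc(res),
                   perRepeatAuc(runCv(inst@Y, inst@Sm, inst@Sd, cfg,
                                      wknknConfig(), plan)))

  # permutation null: shuffling labels before scoring gives chance AUC
  set.seed(33)
  Ym <- as(inst@Y, "matrix")
  fit <- rcmf(inst@Y, inst@Sm, inst@Sd, cfg)
  sc <- as(predictScores(fit), "matrix")
  nulls <- replicate(10, aucScore(as.vector(sc),
                                  sample(as.vector(Ym))))
  expect_lt(abs(mean(nulls) - 0.5), 0.1)
})

test_that("no held-out label leaks into the training pipeline", {
  inst <- makePlanted(20, 15, 2, 0.2, 0, 0, seed = 8)
  Ym <- as(inst@Y, "matrix")
  folds <- makeFolds(inst@Y, cvPlan(5, 1, seed = 2))
  hold <- folds[[1]][[1]]
  Ytr <- Ym; Ytr[hold] <- 0
  # the fold scorer must equal a manual pipeline built from the masked
  # training matrix alone
  manualSm <- integrateSimilarity(inst@Sm, gipKernel(Ytr, "miRNA"), "mean")
  manualSd <- integrateSimilarity(inst@Sd, gipKernel(Ytr, "disease"), "mean")
  manualFit <- rcmf(wknkn(associationMatrix(Ytr), manualSm, manualSd),
                    manualSm, manualSd, rcmfConfig(k = 5))
  msc <- tcrossprod(latentA(manualFit), latentB(manualFit))
  neg <- which(Ym == 0)
  manualAuc <- aucScore(c(msc[hold], msc[neg]),
                        c(rep(1, length(hold)), rep(0, length(neg))))
  foldAuc <- rcmf:::.cvFold(Ym, hold, neg, inst@Sm, inst@Sd,
                            rcmfConfig(k = 5), wknknConfig(), "mean")
  expect_identical(foldAuc, manualAuc)
})

test_that("grid search honours its argmax contract", {
  inst <- makePlanted(15, 12, 2, 0.2, 0, 0, seed = 4)
  plan <- cvPlan(3, 1, seed = 5)
  single <- gridSearch(inst@Y, inst@Sm, inst@Sd, lambdaL = 1, lambdaD = 0.01,
                       lambdaT = 0.01, cfgBase = rcmfConfig(k = 4),
                       plan = plan)
  expect_equal(nrow(single$table), 1)
  expect_equal(single$best@lambdaL, 1)

  gs <- gridSearch(inst@Y, inst@Sm, inst@Sd,
                   lambdaL = c(0.5, 1), lambdaD = c(0, 0.01),
                   lambdaT = 0.01, cfgBase = rcmfConfig(k = 4), plan = plan)
  expect_equal(nrow(gs$table), 4)
  bestRow <- gs$table[gs$table$lambdaL == gs$best@lambdaL &
                        gs$table$lambdaD == gs$best@lambdaD &
                        gs$table$lambdaT == gs$best@lambdaT, ]
  expect_true(all(bestRow$aucMean >= gs$table$aucMean))
  expect_error(gridSearch(inst@Y, lambdaL = numeric(0)), "empty grid")
})

test_that("sensitivity sweep emits one row per K-p combination", {
  inst <- makePlanted(15, 12, 2, 0.2, 0, 0, seed = 6)
  plan <- cvPlan(3, 1, seed = 7)
  cfg <- rcmfConfig(k = 4)
  tab <- sensitivitySweep(inst@Y, inst@Sm, inst@Sd, cfg, Kvalues = c(2, 4),
                          pvalues = c(0.5, 0.9), plan = plan)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.finite(tab$aucMean)))

  one <- sensitivitySweep(inst@Y, inst@Sm, inst@Sd, cfg, 3, 0.7, plan)
  direct <- runCv(inst@Y, inst@Sm, inst@Sd, cfg, wknknConfig(3, 0.7), plan)
  expect_equal(one$aucMean, aucMean(direct))
  expect_error(sensitivitySweep(inst@Y, Kvalues = numeric(0)), "empty")
})
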