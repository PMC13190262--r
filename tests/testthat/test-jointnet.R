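smallSplit <- function(co, seed = 1) {
  plan <- makeStratifiedKFold(co, k = 4, seed = seed)
  plan@folds[[1]]
}

test_that("threshold selection maximizes F1 with the stated tie rule", {
  # exhaustive-sweep example
  p <- matrix(c(0.1, 0.4, 0.6, 0.9), ncol = 1)
  y <- matrix(c(0L, 0L, 1L, 1L), ncol = 1)
  thr <- selectThresholds(p, y)
  expect_gt(thr, 0.4); expect_lt(thr, 0.6)
  expect_equal(unname(thr), 0.5)   # largest midpoint with F1 = 1
  # perfectly separated: F1 = 1 at the chosen threshold
  calls <- as.integer(p >= thr)
  expect_equal(balancedAccuracy(calls, y), 1)
  # degenerate all-negative validation falls back to 0.5
  expect_warning(t2 <- selectThresholds(matrix(runif(5), ncol = 1),
                                        matrix(0L, 5, 1)), "positives")
  expect_equal(unname(t2), 0.5)
})

test_that("training recovers a separable planted condition and is deterministic", {
  co <- tinyCohort(n = 500, p = 60, planted = 8, seed = 13,
                   fold_change_range = c(3, 5))
  sp <- smallSplit(co)
  panel <- proteinIds(co)[proteinIds(co) %in%
                            unlist(groundTruth(co)$planted)]
  spec <- jointModelSpec(hidden = c(48, 32), embedding_dim = 16,
                         batch_size = 32, max_epochs = 60, seed = 3)
  m <- trainJointModel(co, panel, sp, spec)
  # near-perfect validation accuracy on tasks with enough positives to score
  Yv <- labelMatrix(co)[sp$validation, ]
  pv <- predict(m, co, ids = sp$validation)
  bca <- vapply(1:6, function(i)
    suppressWarnings(balancedAccuracy(pv$calls[, i], Yv[, i])), numeric(1))
  scored <- colSums(Yv == 1, na.rm = TRUE) >= 10
  expect_gt(min(bca[scored]), 0.85)
  expect_gt(mean(bca, na.rm = TRUE), 0.75)

  # inference-mode determinism and probability range
  pv2 <- predict(m, co, ids = sp$validation)
  expect_identical(pv$probabilities, pv2$probabilities)
  expect_true(all(pv$probabilities > 0 & pv$probabilities < 1))
  # embeddings have the configured dimension
  expect_equal(ncol(pv$embeddings), 16)
  expect_equal(ncol(extractEmbeddings(m, co, ids = sp$test)), 16)

  # end-to-end training determinism under a fixed seed
  m2 <- trainJointModel(co, panel, sp, spec)
  expect_identical(m$net$W, m2$net$W)
  expect_identical(m$thresholds, m2$thresholds)
})

test_that("an all-noise cohort yields chance-level test performance", {
  co <- simulateCohort(simulationConfig(
    n_participants = 400, n_proteins = 40, n_sites = 2,
    planted_per_condition = 0, fold_change_range = c(1, 1),
    site_shift_sd = 0, site_scale_sd = 0, age_effect_sd = 0,
    sex_effect_sd = 0, seed = 15))
  sp <- smallSplit(co)
  spec <- jointModelSpec(hidden = c(32), embedding_dim = 8,
                         max_epochs = 15, seed = 4)
  m <- trainJointModel(co, proteinIds(co), sp, spec)
  pt <- predict(m, co, ids = sp$test)
  Yt <- labelMatrix(co)[sp$test, ]
  auc <- vapply(1:6, function(i)
    aucScore(pt$probabilities[, i], Yt[, i]), numeric(1))
  expect_lt(abs(mean(auc, na.rm = TRUE) - 0.5), 0.08)
})

test_that("dropout intervals behave with rate and repetitions", {
  co <- tinyCohort(n = 200, p = 30, planted = 4, seed = 17)
  sp <- smallSplit(co)
  rows <- sp$test[1:20]
  base <- jointModelSpec(hidden = c(32), embedding_dim = 8,
                         max_epochs = 10, seed = 5)
  widths <- vapply(c(0, 0.1, 0.3, 0.5), function(rate) {
    spec <- base; spec$dropout <- rate
    m <- trainJointModel(co, proteinIds(co)[1:25], sp, spec)
    pd <- predictWithDropout(m, co, ids = rows, reps = 40, seed = 6)
    # interval contains the deterministic probability when rate is 0
    if (rate == 0) {
      det <- predict(m, co, ids = rows)$probabilities
      expect_true(all(pd$intervals$low <= det + 1e-12 &
                        pd$intervals$high >= det - 1e-12))
      expect_equal(max(pd$intervals$high - pd$intervals$low), 0)
    }
    mean(pd$intervals$high - pd$intervals$low)
  }, numeric(1))
  expect_false(is.unsorted(widths))  # width non-decreasing in dropout rate
})

test_that("probability normalization is the stated threshold ratio", {
  expect_equal(normalizeProbability(0.4, 0.4), 1)
  expect_equal(normalizeProbability(0.4, 0.4, log = TRUE), 0)
  expect_equal(normalizeProbability(0.8, 0.4), 2)
  p <- seq(0.05, 0.95, by = 0.1)
  expect_false(is.unsorted(normalizeProbability(p, 0.3)))
})

test_that("random search returns the sampled spec at budget one and logs trials", {
  co <- tinyCohort(n = 150, p = 25, planted = 4, seed = 19)
  sp <- smallSplit(co)
  base <- jointModelSpec(hidden = c(16), embedding_dim = 8, max_epochs = 5)
  res <- tuneHyperparameters(co, proteinIds(co)[1:20], sp, budget = 1,
                             seed = 2, baseSpec = base)
  expect_s3_class(res$best, "JointModelSpec")
  expect_equal(nrow(res$trials), 1)
  expect_equal(res$trials$val_bca, res$score)
})
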