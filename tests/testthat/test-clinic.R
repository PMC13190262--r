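test_that("two-cutoff search matches an exhaustive midpoint oracle", {
  p <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9)
  y <- c(0, 0, 0, 1, 0, 1)
  bruteForce <- function(p, y, tn, tp) {
    u <- sort(unique(p)); cand <- (u[-1] + u[-length(u)]) / 2
    npv <- sapply(cand, function(ct) if (any(p < ct)) mean(y[p < ct] == 0) else NA)
    ppv <- sapply(cand, function(ct) if (any(p >= ct)) mean(y[p >= ct] == 1) else NA)
    list(lower = suppressWarnings(max(cand[!is.na(npv) & npv >= tn])),
         upper = suppressWarnings(min(cand[!is.na(ppv) & ppv >= tp])))
  }
  # relaxed PPV target: the derivation set is separable enough to cross
  oracle <- bruteForce(p, y, 0.9, 0.5)
  expect_warning(tc <- fitTwoCutoff(p, y, target_npv = 0.9, target_ppv = 0.5),
                 "crossed")
  expect_equal(tc$lower, oracle$lower)
  expect_equal(tc$upper, oracle$upper)
  expect_true(tc$empty_indeterminate)

  # default targets give an honest indeterminate zone
  oracle9 <- bruteForce(p, y, 0.9, 0.9)
  tc9 <- fitTwoCutoff(p, y)
  expect_equal(tc9$lower, oracle9$lower)
  expect_equal(tc9$upper, oracle9$upper)
  expect_gte(tc9$derivation_npv, 0.9)
  expect_gte(tc9$derivation_ppv, 0.9)
  cls <- applyTwoCutoff(tc9, p)
  expect_s3_class(cls, "factor")
  # monotone in probability
  ord <- as.integer(cls[order(p)])
  expect_false(is.unsorted(ord))
  # perfectly separated probabilities: full coverage
  ps <- c(0.05, 0.1, 0.15, 0.85, 0.9, 0.95)
  ys <- c(0, 0, 0, 1, 1, 1)
  tcs <- fitTwoCutoff(ps, ys)
  expect_equal(tcs$derivation_npv, 1)
  expect_equal(tcs$derivation_ppv, 1)
  expect_equal(tcs$coverage, 1)
  expect_error(fitTwoCutoff(runif(5), rep(1, 5)), "both classes")
})

test_that("sampling Shapley attribution matches the linear-model oracle", {
  set.seed(13)
  d <- 8
  w <- rnorm(d, 0, 0.15)        # small weights keep the sigmoid ~linear
  net <- list(
    W = list(diag(d), matrix(rep(w, 6), d, 6)),
    b = list(rep(0, d), rep(0, 6)),
    dims = c(d, d, 6L), n_hidden = 0L)
  x <- rnorm(d)
  bg <- matrix(rnorm(60 * d), 60, d)
  contrib <- ProteoDx:::.shapleySampling(net, x, bg, nPermutations = 300,
                                         seed = 5)
  # efficiency: attributions sum to prediction minus background mean
  fx <- ProteoDx:::.forwardNet(net, matrix(x, 1))$probs
  fb <- ProteoDx:::.forwardNet(net, bg)$probs
  gap <- colSums(contrib) - (fx - colMeans(fb))
  expect_lt(max(abs(gap)), 0.02)
  # near-linear regime: contribution_j ~ sigma'(0) w_j (x_j - mean bg_j),
  # identical across the six heads since they share the weight vector
  oracle <- matrix(0.25 * w * (x - colMeans(bg)), d, 6)
  expect_lt(max(abs(contrib - oracle)), 0.02)
})

test_that("individual reports are complete, bounded and reproducible", {
  co <- tinyCohort(n = 220, p = 40, planted = 5, seed = 47,
                   fold_change_range = c(2.5, 3.5))
  plan <- makeStratifiedKFold(co, k = 4, seed = 1)
  sp <- plan@folds[[1]]
  m <- trainJointModel(co, proteinIds(co)[1:30], sp,
                       jointModelSpec(hidden = c(24), embedding_dim = 8,
                                      max_epochs = 10, seed = 3))
  traits <- data.frame(protein = proteinIds(co)[1:10],
                       trait = paste("trait", 1:10))
  rep1 <- individualReport(m, co, sp$test[1], backgroundIds = sp$train,
                           traitTable = traits, nPermutations = 24, seed = 9)
  for (cn in conditionNames()) {
    expect_lte(nrow(rep1$contributions[[cn]]$positive), 10)
    expect_lte(nrow(rep1$contributions[[cn]]$negative), 10)
    pos <- rep1$contributions[[cn]]$positive$value
    expect_false(is.unsorted(rev(pos)))       # sorted by signed value
    expect_true(all(pos > 0))
    expect_true(all(rep1$contributions[[cn]]$negative$value < 0))
  }
  expect_equal(rep1$normalized$AD,
               log(rep1$probabilities$AD / rep1$thresholds$AD))
  expect_true(all(traits$protein[traits$protein %in%
                                   rep1$traits$protein] %in% rep1$traits$protein))
  # regeneration with the same seed is byte-identical
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeIndividualReport(rep1, f1)
  rep2 <- individualReport(m, co, sp$test[1], backgroundIds = sp$train,
                           traitTable = traits, nPermutations = 24, seed = 9)
  writeIndividualReport(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_warning(individualReport(m, co, sp$test[1],
                                  backgroundIds = sp$train[1:5],
                                  nPermutations = 4, seed = 1),
                 "background")
})

test_that("progression task behaves at chance on shuffled labels and finds signal", {
  co <- tinyCohort(n = 500, p = 60, planted = 8, seed = 53,
                   fold_change_range = c(2, 3))
  pl <- makeProgressionLabels(co, progression_fraction = 0.25,
                              signal_strength = 2.5, seed = 2)
  co2 <- pl$cohort
  plan <- makeStratifiedKFold(co2, k = 4, seed = 1)
  sp <- plan@folds[[1]]
  panel <- unique(unlist(groundTruth(co2)$planted))
  m <- trainJointModel(co2, panel, sp,
                       jointModelSpec(hidden = c(32), embedding_dim = 12,
                                      max_epochs = 15, seed = 4))
  res <- progressionTask(m, co2, pl$labels, k = 5, seed = 6)
  expect_gt(res$auc, 0.65)
  expect_equal(res$n, nrow(res$predictions))
  # participants with decreasing CDR are excluded
  elig <- progressionEligible(co2)
  expect_true(all(res$predictions$participant %in% names(elig)[elig]))
  # shuffled labels: chance-level AUC
  shuf <- pl$labels
  set.seed(7)
  shuf$progressor <- sample(shuf$progressor)
  res0 <- progressionTask(m, co2, shuf, k = 5, seed = 6)
  expect_lt(abs(res0$auc - 0.5), 0.1)
})

test_that("k-shot transfer is reproducible and records skipped conditions", {
  co <- tinyCohort(n = 420, p = 50, planted = 6, seed = 59,
                   fold_change_range = c(2, 3), sites = 2)
  site <- unique(siteIds(co))
  plan <- makeLeaveOneSiteOut(co, test_sites = site[1], seed = 1)
  sp <- plan@folds[[1]]
  panel <- unique(unlist(groundTruth(co)$planted))
  m <- trainJointModel(co, panel, sp,
                       jointModelSpec(hidden = c(32), embedding_dim = 12,
                                      max_epochs = 12, seed = 5))
  sub <- co[, sp$test]
  ks <- kShotTransfer(m, sub, K = 60, repeats = 4, seed = 8)
  expect_true(all(c("FineTune", "Retrain") %in% ks$method))
  expect_true(all(ks$bca >= 0 & ks$bca <= 1, na.rm = TRUE))
  ks2 <- kShotTransfer(m, sub, K = 60, repeats = 4, seed = 8)
  expect_identical(ks, ks2)
  # conditions too rare in the K sample are skipped, not silently scored
  skipped <- attr(ks, "skipped")
  done <- unique(paste(ks$repeat_, ks$condition))
  if (nrow(skipped))
    expect_false(any(paste(skipped$repeat_, skipped$condition) %in% done))
})
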