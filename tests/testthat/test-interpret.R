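fitTinyModel <- function(seed = 41, n = 300, p = 40, planted = 5) {
  co <- tinyCohort(n = n, p = p, planted = planted, seed = seed,
                   fold_change_range = c(2.5, 3.5))
  plan <- makeStratifiedKFold(co, k = 4, seed = 1)
  sp <- plan@folds[[1]]
  panel <- proteinIds(co)[1:30]
  m <- trainJointModel(co, panel, sp,
                       jointModelSpec(hidden = c(32), embedding_dim = 8,
                                      max_epochs = 15, seed = 2))
  list(co = co, sp = sp, m = m, panel = panel)
}

test_that("permutation importance flags drivers and ignores unused inputs", {
  f <- fitTinyModel()
  gt <- groundTruth(f$co)
  imp <- permFit(f$m, f$co, f$sp$test, n_perm = 30, seed = 3)
  expect_s3_class(imp, "ImportanceReport")
  expect_setequal(unique(imp$protein), f$panel)  # only panel proteins
  driver <- intersect(gt$planted$AD, f$panel)
  if (length(driver)) {
    sub <- imp[imp$condition == "AD" & imp$protein %in% driver, ]
    expect_true(any(sub$p_adj < 0.05))
    expect_true(all(sub$z[sub$p_adj < 0.05] > 0))
  }
  # a protein never given to the model is simply not evaluated
  expect_false(any(setdiff(proteinIds(f$co), f$panel) %in% imp$protein))
  # permuting a constant-irrelevant column: cross-entropy unchanged within
  # machine precision when the first-layer weights for it are zeroed
  m0 <- f$m
  j <- 5
  m0$net$W[[1]][j, ] <- 0
  imp0 <- permFit(m0, f$co, f$sp$test, n_perm = 5, seed = 4)
  sub0 <- imp0[imp0$protein == f$panel[j], ]
  expect_true(all(abs(sub0$mean) < 1e-12))
  expect_true(all(sub0$flagged | sub0$sd < 1e-12))
})

test_that("importance aggregation counts folds and averages z", {
  mk <- function(pads, zs) {
    d <- data.frame(protein = "p1", condition = "AD", mean = 1, sd = 1,
                    z = zs, p = 0.5, flagged = FALSE, p_adj = pads)
    class(d) <- c("ImportanceReport", "data.frame")
    d
  }
  reps <- list(mk(0.01, 2), mk(0.2, 1), mk(0.04, 3))
  agg <- aggregateImportance(reps, allProteins = c("p1", "p2"))
  row <- agg$table[agg$table$protein == "p1" & agg$table$condition == "AD", ]
  expect_equal(row$fold_count, 2L)
  expect_equal(row$n_splits_present, 3L)
  expect_equal(row$mean_z, 2)
  expect_identical(agg$never_in_panel, "p2")
})

test_that("Haufe covariances match the closed form for a linear head", {
  set.seed(6)
  z <- matrix(rnorm(500 * 4), 500, 4)
  w <- c(0.8, -1.2, 0, 0.5)
  p <- plogis(z %*% w * 0.3)
  H <- haufeImportance(z, cbind(AD = p))
  # sign agreement with the head weights, ~0 for the unused dimension
  expect_equal(sign(H[c(1, 2, 4), 1]), sign(w[c(1, 2, 4)]),
               ignore_attr = TRUE)
  se0 <- sd(z[, 3] * p) / sqrt(500)
  expect_lt(abs(H[3, 1]), 3 * se0)
  # purely linear readout: cov(z, a z'w) = a w' var(z) exactly
  lin <- z %*% w
  Hl <- haufeImportance(z, cbind(AD = lin))
  expect_equal(Hl[, 1], as.numeric(cov(z) %*% w), tolerance = 1e-12)
  # bilinearity: scaling one dimension scales its covariance
  z2 <- z; z2[, 1] <- 3 * z[, 1]
  H2 <- haufeImportance(z2, cbind(AD = lin))
  expect_equal(H2[1, 1], 3 * Hl[1, 1], tolerance = 1e-12)
})

test_that("embedding signatures pick up the generating protein", {
  set.seed(7)
  X <- matrix(rnorm(400 * 20), 400, 20,
              dimnames = list(NULL, paste0("p", 1:20)))
  target <- 5 * X[, 7] + rnorm(400, 0, 0.1)
  sig <- embeddingProteinSignature(X, target, trainIdx = 1:300,
                                   valIdx = 301:400, gain_threshold = 50)
  expect_true("p7" %in% sig)
  gains <- attr(sig, "gain")
  expect_equal(names(which.max(gains)), "p7")
  # pure-noise target yields an empty or tiny signature
  sig0 <- embeddingProteinSignature(X, rnorm(400), trainIdx = 1:300,
                                    valIdx = 301:400, gain_threshold = 50)
  expect_lte(length(sig0), 8)
  # the generating protein's gain dwarfs anything a noise target produces
  expect_gt(max(gains), 10 * max(attr(sig0, "gain")))
})

test_that("the probability map separates distinct diagnosis profiles", {
  set.seed(9)
  n <- 120
  probs <- rbind(
    cbind(runif(n, 0, 0.1), runif(n, 0.8, 1), matrix(runif(n * 4, 0, 0.1), n)),
    cbind(runif(n, 0, 0.1), runif(n, 0, 0.1), runif(n, 0.8, 1),
          matrix(runif(n * 3, 0, 0.1), n)))
  colnames(probs) <- conditionNames()
  rownames(probs) <- sprintf("P%03d", seq_len(2 * n))
  dg <- factor(rep(c("AD", "PD"), each = n), levels = conditionNames())
  expect_warning(pm <- probabilityMap(probs, dg, perplexity = 1000, seed = 4),
                 "shrunk")
  expect_true(all(is.finite(pm$coords)))
  sw <- cluster::silhouette(as.integer(dg), dist(pm$coords))
  expect_gt(mean(sw[, "sil_width"]), 0.5)
  # deterministic coordinates under a fixed seed
  pm2 <- suppressWarnings(probabilityMap(probs, dg, perplexity = 1000, seed = 4))
  expect_identical(pm$coords, pm2$coords)
  # density contours exist for both diagnoses
  expect_true(all(c("AD", "PD") %in% names(pm$contours)))
  # out-of-sample projection lands near the matching group
  newp <- probs[c(1, n + 1), ]
  proj <- projectOntoMap(pm, newp)
  d_ad <- colMeans(pm$coords[1:n, ])
  d_pd <- colMeans(pm$coords[(n + 1):(2 * n), ])
  expect_lt(sum((proj[1, ] - d_ad)^2), sum((proj[1, ] - d_pd)^2))
  expect_lt(sum((proj[2, ] - d_pd)^2), sum((proj[2, ] - d_ad)^2))
})

test_that("map eligibility keeps exactly single-positive participants", {
  lm_ <- rbind(c(1, 0, 0, 0, 0, 0),
               c(0, 1, NA, 0, 0, 0),
               c(1, 1, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0),
               c(NA, NA, NA, NA, NA, 1))
  colnames(lm_) <- conditionNames()
  e <- mapEligibility(lm_)
  expect_equal(as.character(e),
               c("control", "AD", NA, NA, "stroke_TIA"))
})

test_that("cluster number selection recovers planted blobs", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(120, 0, 0.4), ncol = 2),
               matrix(rnorm(120, 6, 0.4), ncol = 2))
  rownames(pts) <- sprintf("P%03d", 1:120)
  fake <- structure(list(
    coords = pts,
    diagnosis = factor(rep("AD", 120), levels = conditionNames()),
    train_probs = matrix(runif(720), 120, 6)), class = "ProbabilityMap")
  cl <- clusterMap(fake, "AD", seed = 2)
  expect_equal(cl$k, 2)
  truth <- rep(1:2, each = 60)
  expect_gte(adjustedRand(cl$labels, truth), 0.99)
  # degenerate identical points refuse to cluster
  fake$coords[] <- 1
  expect_error(clusterMap(fake, "AD", seed = 2), "identical")
})

test_that("cluster differential abundance is calibrated and recovers shifts", {
  co <- tinyCohort(n = 400, p = 60, planted = 0, fold_change_range = c(1, 1),
                   seed = 43)
  ids <- participantIds(co)[1:200]
  set.seed(3)
  labels <- setNames(sample(1:2, 200, replace = TRUE), ids)
  dea0 <- clusterDifferentialAbundance(co, labels)
  expect_lte(mean(dea0$p_adj < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  # plant a cluster-specific 2x shift in 20 proteins
  shift <- proteinIds(co)[1:20]
  co2 <- co
  A <- SummarizedExperiment::assay(co2, "abundance")
  A[shift, names(labels)[labels == 2]] <-
    A[shift, names(labels)[labels == 2]] * 2
  SummarizedExperiment::assay(co2, "abundance") <- A
  dea <- clusterDifferentialAbundance(co2, labels)
  sig <- dea$protein[dea$p_adj < 0.05]
  expect_gte(mean(shift %in% sig), 0.8)
  up <- dea[dea$protein %in% shift, ]
  expect_true(all(up$logFC > 0))
  # small clusters are excluded with a warning
  labels3 <- labels; labels3[1:3] <- 3
  labels3 <- labels3[c(1:3, which(labels3 != 3)[1:100])]
  expect_warning(clusterDifferentialAbundance(co, labels3), "excluded")
})
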