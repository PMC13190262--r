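test_that("outlier masking follows the z rule and spares degenerate columns", {
  set.seed(1)
  X <- cbind(con = rep(5, 100), nor = rnorm(100))
  X[1, "nor"] <- 10            # |z| far beyond 6 for N(0,1) column
  expect_warning(M <- maskOutliers(cbind(X, few = c(1, NA, NA, rep(NA, 97))),
                                   z_cut = 6), "untouched")
  expect_true(is.na(M[1, "nor"]))
  expect_equal(sum(is.na(M[, "nor"])), 1)
  expect_false(anyNA(M[, "con"]))     # sd 0: nothing masked
  # direct z computation oracle
  mu <- mean(X[, "nor"]); s <- sd(X[, "nor"])
  expect_true(abs(X[1, "nor"] - mu) > 6 * s)
})

test_that("average-level normalization is exact per row", {
  X <- rbind(a = c(2, 4, NA), b = c(3, 3, 3))
  colnames(X) <- paste0("p", 1:3)
  N <- normalizeAverageLevel(X)
  expect_equal(unname(N["a", ]), c(2 / 3, 4 / 3, NA))
  expect_equal(unname(N["b", ]), c(1, 1, 1))
  expect_equal(unname(rowMeans(N, na.rm = TRUE)), c(1, 1))
  X2 <- rbind(X, c = c(NA, NA, NA))
  expect_error(normalizeAverageLevel(X2), "c")
})

test_that("knn imputation uses nearest training neighbours and is idempotent", {
  set.seed(2)
  tr <- matrix(rnorm(40 * 6, 20, 1), 40, 6,
               dimnames = list(NULL, paste0("p", 1:6)))
  tr[1:15, ] <- 7 + 0.01 * matrix(rnorm(15 * 6), 15, 6)  # tight cluster
  tr[1:15, 3] <- 7                      # cluster shares a constant value
  imp <- fitKnnImputer(tr, k = 10)
  X <- tr[1:15, , drop = FALSE]
  X[1, 3] <- NA
  out <- applyTransform(imp, X)
  expect_false(anyNA(out))
  # the 10 nearest training rows are the cluster -> imputed exactly 7
  expect_equal(unname(out[1, 3]), 7)
  expect_identical(out[-1, ], X[-1, ])  # observed cells untouched
  expect_identical(applyTransform(imp, out), out)   # idempotent
  # complete input passes through unchanged
  expect_identical(applyTransform(imp, tr), tr)
  # unfittable: protein never observed in training
  tr2 <- tr; tr2[, 2] <- NA
  expect_error(fitKnnImputer(tr2, k = 5), "entirely missing")
  expect_error(fitKnnImputer(tr, k = 100), "exceeds")
})

test_that("gaussian rank normalizer matches normal scores and clips held-out", {
  tr <- matrix(c(5, 1, 3), 3, 1, dimnames = list(NULL, "p1"))
  gr <- fitGaussianRank(tr)
  out <- applyTransform(gr, tr)
  expect_equal(sort(out[, 1]), qnorm(c(1, 3, 5) / 6), tolerance = 1e-6)
  expect_equal(unname(sort(round(out[, 1], 4))), c(-0.9674, 0, 0.9674))
  # held-out values: interpolation within range, clipping outside
  hv <- matrix(c(0, 2, 10), 3, 1, dimnames = list(NULL, "p1"))
  ho <- applyTransform(gr, hv)
  expect_equal(unname(ho[1, 1]), qnorm(0.5 / 3))  # below training minimum
  expect_equal(unname(ho[3, 1]), qnorm(2.5 / 3))  # above training maximum
  expect_true(ho[2, 1] > qnorm(1 / 6) && ho[2, 1] < 0)
  # monotone within column
  expect_false(is.unsorted(ho[, 1]))
  # large-n training column standardizes
  set.seed(3)
  big <- matrix(rexp(2000), ncol = 1, dimnames = list(NULL, "p1"))
  gb <- fitGaussianRank(big)
  ob <- applyTransform(gb, big)
  expect_lt(abs(mean(ob)), 0.01)
  expect_lt(abs(sd(ob) - 1), 0.02)
  # constant column warns and maps to zero
  expect_warning(gc_ <- fitGaussianRank(matrix(1, 5, 1,
                                               dimnames = list(NULL, "p1"))),
                 "constant")
  expect_equal(unname(applyTransform(gc_, matrix(2, 3, 1,
                                                 dimnames = list(NULL, "p1")))[, 1]),
               rep(0, 3))
})

test_that("z-scoring uses training statistics only", {
  set.seed(4)
  tr <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  z <- fitZScore(tr)
  out <- applyTransform(z, tr)
  expect_equal(unname(colMeans(out)), c(0, 0), tolerance = 1e-12)
  # held-out shifted by delta -> mean delta/sd
  delta <- 1.5
  ho <- applyTransform(z, tr + delta)
  expect_equal(unname(colMeans(ho)), unname(delta / apply(tr, 2, sd)),
               tolerance = 1e-10)
  expect_warning(zc <- fitZScore(matrix(3, 10, 1,
                                        dimnames = list(NULL, "a"))), "zero-sd")
  expect_equal(unname(applyTransform(zc, matrix(5, 2, 1,
                                                dimnames = list(NULL, "a")))[, 1]),
               c(0, 0))
})

test_that("fitted chains never use held-out rows and enforce protein lists", {
  co <- tinyCohort(n = 120, p = 20, seed = 8, missing_value_rate = 0.03)
  X <- abundance(co, participantsAsRows = TRUE)
  panel <- proteinIds(co)[1:10]
  tr <- 1:80; ho <- 81:120
  ch <- fitPreprocessChain(X[tr, ], panel, kind = "deep", knn_k = 5)
  # perturbing held-out rows cannot change the fitted transform
  X2 <- X
  X2[ho, ] <- X2[ho, ] * 3
  ch2 <- fitPreprocessChain(X2[tr, ], panel, kind = "deep", knn_k = 5)
  expect_identical(ch$transforms$gaussian_rank$maps,
                   ch2$transforms$gaussian_rank$maps)
  out <- applyPreprocessChain(ch, X[ho, ])
  expect_false(anyNA(out))
  expect_identical(colnames(out), panel)
  # mismatched protein list refuses
  bad <- X[ho, rev(colnames(X))]
  expect_error(applyTransform(ch$transforms$gaussian_rank,
                              bad[, rev(panel)]), "different protein list")
})
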