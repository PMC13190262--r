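test_that("cohort tables round-trip through delimited text", {
  co <- tinyCohort(n = 60, p = 15, seed = 3, missing_value_rate = 0.05)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  co2 <- readCohort(dir)
  expect_equal(abundance(co2), abundance(co), tolerance = 1e-12)
  expect_identical(labelMatrix(co2), labelMatrix(co))
  expect_equal(phenoTable(co2)$mmse, phenoTable(co)$mmse)
  # missing entries preserved as missing, not zero
  expect_identical(which(is.na(abundance(co2))), which(is.na(abundance(co))))
  # label-state counts conserved
  expect_identical(table(labelMatrix(co2), useNA = "always"),
                   table(labelMatrix(co), useNA = "always"))
})

test_that("malformed files raise parse and alignment errors", {
  co <- tinyCohort(n = 20, p = 6, seed = 4)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)

  lab <- readLines(file.path(dir, "labels.tsv"))
  lab[2] <- sub("positive|negative", "maybe", lab[2])
  writeLines(lab, file.path(dir, "labels.tsv"))
  expect_error(readCohort(dir), "unknown label state token")

  writeCohort(co, dir)
  ab <- readLines(file.path(dir, "abundance.tsv"))
  ab[3] <- sub("(\t)[0-9.]+$", "\\1oops", ab[3])
  writeLines(ab, file.path(dir, "abundance.tsv"))
  expect_error(readCohort(dir), "non-numeric")

  writeCohort(co, dir)
  ph <- readLines(file.path(dir, "phenotypes.tsv"))
  ph[2] <- sub("^[^\t]+", "SOMEONE_ELSE", ph[2])
  writeLines(ph, file.path(dir, "phenotypes.tsv"))
  expect_error(readCohort(dir), "align")
})

test_that("cognitive label derivation follows the MMSE/CDR rules", {
  ph <- data.frame(
    mmse = c(28, 23, NA, 12, 19, 26, 16),
    cdr  = c(NA, NA, NA, NA, NA, 1, 0))
  out <- deriveCognitiveLabels(ph)
  expect_equal(as.character(out),
               c("control", "MCI-SCI", "Unknown", "ComputedDementia",
                 "Unknown",           # MMSE 19 falls between the rules
                 "ComputedDementia",  # CDR stage wins over MMSE
                 "control"))          # CDR 0 wins
  # MMSE precedence variant
  out2 <- deriveCognitiveLabels(ph, cdr_precedence = FALSE)
  expect_equal(as.character(out2)[6], "control")
  # configurable dementia cutoff
  out3 <- deriveCognitiveLabels(data.frame(mmse = 12, cdr = NA),
                                dementia_mmse_cutoff = 11)
  expect_equal(as.character(out3), "Unknown")
})

test_that("site-stratified k-fold rotations partition the cohort", {
  co <- tinyCohort(n = 300, p = 10, sites = 3, seed = 5)
  plan <- makeStratifiedKFold(co, k = 10, seed = 2)
  expect_length(plan@folds, 10)
  ids <- participantIds(co)
  test_all <- unlist(lapply(plan@folds, `[[`, "test"))
  expect_setequal(test_all, ids)            # each participant tests once
  expect_equal(length(test_all), length(ids))
  for (f in plan@folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$validation), 0)
    expect_length(intersect(f$validation, f$test), 0)
    expect_setequal(c(f$train, f$validation, f$test), ids)
  }
  # per-site fold sizes differ by at most 1
  site <- siteIds(co)
  for (f in plan@folds) {
    perSite <- table(site[match(f$test, ids)])
    expect_true(all(perSite >= floor(min(table(site)) / 10)))
  }
  sizes <- table(site[match(plan@folds[[1]]$test, ids)])
  full <- table(site)
  expect_true(all(abs(sizes - full / 10) <= 1))
  # deterministic
  plan2 <- makeStratifiedKFold(co, k = 10, seed = 2)
  expect_identical(plan@folds, plan2@folds)
  # small sites warned and still distributed
  co2 <- tinyCohort(n = 40, p = 10, sites = 8, seed = 6)
  expect_warning(makeStratifiedKFold(co2, k = 10, seed = 1), "round-robin")
})

test_that("leave-one-site-out holds out whole sites", {
  co <- tinyCohort(n = 300, p = 10, sites = 3, seed = 7)
  site <- siteIds(co)
  ids <- participantIds(co)
  s1 <- unique(site)[2]
  plan <- makeLeaveOneSiteOut(co, test_sites = s1, val_fraction = 1 / 9,
                              seed = 3)
  f <- plan@folds[[1]]
  expect_setequal(f$test, ids[site == s1])
  nv <- length(f$validation); nrest <- sum(site != s1)
  expect_lt(abs(nv / nrest - 1 / 9), 0.03)
  expect_error(makeLeaveOneSiteOut(co, test_sites = "nope"), "unknown site")
  # all sites once: union of test sets is the cohort
  planAll <- makeLeaveOneSiteOut(co, seed = 3)
  expect_setequal(unlist(lapply(planAll@folds, `[[`, "test")), ids)
})

test_that("split plans round-trip through JSON", {
  co <- tinyCohort(n = 80, p = 8, seed = 9)
  plan <- makeStratifiedKFold(co, k = 4, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  writeSplitPlan(plan, path)
  plan2 <- readSplitPlan(path)
  expect_identical(plan2@scheme, plan@scheme)
  expect_identical(plan2@folds, plan@folds)
})
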