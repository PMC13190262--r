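#' Balanced classification accuracy
#'
#' Mean of sensitivity and specificity over observed labels — robust to the
#' heavy class imbalance across the six conditions (a constant classifier
#' scores exactly 0.5). Returns \code{NA} with a warning when a class is
#' absent.
#'
#' @param calls 0/1 predicted calls.
#' @param labels ternary labels (NA = missing, excluded).
#' @return scalar in [0, 1], or \code{NA}.
#' @export
balancedAccuracy <- function(calls, labels) {
  obs <- !is.na(labels)
  y <- labels[obs]; c_ <- calls[obs]
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    warning("a class is absent; balanced accuracy undefined")
    return(NA_real_)
  }
  sens <- sum(c_ == 1 & y == 1) / npos
  spec <- sum(c_ == 0 & y == 0) / nneg
  (sens + spec) / 2
}

#' Rank-based AUC
#'
#' Mann-Whitney area under the ROC curve; tied probabilities get half
#' credit. Invariant to monotone transforms of the probabilities.
#'
#' @param probs predicted probabilities or scores.
#' @param labels ternary labels (NA excluded).
#' @return scalar in [0, 1], or \code{NA} if a class is absent.
#' @export
aucScore <- function(probs, labels) {
  obs <- !is.na(labels)
  y <- labels[obs]; p <- probs[obs]
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Corrected resampled t-test for cross-validated model comparison
#'
#' Nadeau-Bengio variance correction: for per-split score differences
#' \eqn{d_1..d_k} and test/train size ratio \eqn{\rho},
#' \eqn{t = \bar d / \sqrt{(1/k + \rho)\, s_d^2}} with \eqn{k - 1} degrees
#' of freedom (two-sided p). All-zero differences give \eqn{t = 0, p = 1};
#' constant nonzero differences give \eqn{p = 0} with a degeneracy flag.
#'
#' @param diffs per-split score differences (length k >= 2).
#' @param ratio test/train size ratio (1/9 for the 9-1-1 tenfold usage; 0
#'   recovers the uncorrected test).
#' @return list with \code{t}, \code{df}, \code{p}, \code{degenerate}.
#' @export
correctedResampledTTest <- function(diffs, ratio = 1 / 9) {
  k <- length(diffs)
  if (k < 2) stop("need at least 2 splits")
  s2 <- stats::var(diffs)
  dbar <- mean(diffs)
  if (s2 == 0) {
    if (dbar == 0) return(list(t = 0, df = k - 1, p = 1, degenerate = FALSE))
    return(list(t = sign(dbar) * Inf, df = k - 1, p = 0, degenerate = TRUE))
  }
  t_ <- dbar / sqrt((1 / k + ratio) * s2)
  list(t = t_, df = k - 1, p = 2 * stats::pt(-abs(t_), k - 1),
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment with rejection set
#'
#' @param p raw p values.
#' @param alpha FDR level; default 0.05.
#' @return list with \code{p_adj} (monotone step-up adjusted values) and
#'   \code{reject} (logical).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, reject = !is.na(p_adj) & p_adj < alpha)
}

# ---- XGBoost per-condition baseline (thin reference hook) ----

#' Gradient-boosted baseline on the panel
#'
#' Six independent boosted-tree classifiers on z-scored panel proteins
#' (training-statistics scaling), tuned on the validation split over a small
#' depth/subsample grid with early stopping, thresholds by best validation
#' F1. Serves as the comparison arm and the second ensemble component.
#'
#' @inheritParams trainJointModel
#' @param grid list of hyperparameter sets (max_depth, subsample).
#' @param nrounds maximum boosting rounds.
#' @param seed integer seed.
#' @return a \code{XgbBaseline} model list.
#' @export
trainXgbBaseline <- function(cohort, panel, split, seed = 1L,
                             grid = list(list(max_depth = 3, subsample = 0.9)),
                             nrounds = 200) {
  proteins <- if (inherits(panel, "FeaturePanel")) panel$proteins else panel
  Xall <- abundance(cohort, participantsAsRows = TRUE)
  chain <- fitPreprocessChain(Xall[split$train, , drop = FALSE], proteins,
                              kind = "tree")
  Xtr <- applyPreprocessChain(chain, Xall[split$train, , drop = FALSE])
  Xva <- applyPreprocessChain(chain, Xall[split$validation, , drop = FALSE])
  Ytr <- labelMatrix(cohort)[split$train, , drop = FALSE]
  Yva <- labelMatrix(cohort)[split$validation, , drop = FALSE]
  boosters <- vector("list", 6)
  vp <- matrix(NA_real_, nrow(Xva), 6, dimnames = list(split$validation,
                                                       conditionNames()))
  for (i in seq_len(6)) {
    tr_obs <- !is.na(Ytr[, i]); va_obs <- !is.na(Yva[, i])
    dtr <- xgboost::xgb.DMatrix(Xtr[tr_obs, , drop = FALSE],
                                label = Ytr[tr_obs, i])
    dva <- xgboost::xgb.DMatrix(Xva[va_obs, , drop = FALSE],
                                label = Yva[va_obs, i])
    best <- NULL; bestAuc <- -Inf
    for (g in grid) {
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eval_metric = "auc",
                      max_depth = g$max_depth, subsample = g$subsample,
                      eta = 0.1, nthread = 1, seed = .subSeed(seed, i)),
        data = dtr, nrounds = nrounds, evals = list(val = dva),
        early_stopping_rounds = 20, verbose = 0)
      auc <- max(attributes(bst)$evaluation_log$val_auc)
      if (auc > bestAuc) { bestAuc <- auc; best <- bst }
    }
    boosters[[i]] <- best
    vp[, i] <- stats::predict(best, Xva)
  }
  thresholds <- selectThresholds(vp, Yva)
  structure(list(boosters = boosters, chain = chain, thresholds = thresholds,
                 conditions = conditionNames()),
            class = "XgbBaseline")
}

#' @export
predict.XgbBaseline <- function(object, newdata, ids = NULL, ...) {
  X <- if (is(newdata, "ProteoCohort"))
    abundance(newdata, participantsAsRows = TRUE) else as.matrix(newdata)
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  Xp <- applyPreprocessChain(object$chain, X)
  probs <- vapply(seq_len(6), function(i)
    stats::predict(object$boosters[[i]], Xp), numeric(nrow(Xp)))
  dimnames(probs) <- list(rownames(X), object$conditions)
  calls <- sweep(probs, 2, object$thresholds, ">=") + 0L
  structure(list(probabilities = probs, calls = calls, embeddings = NULL,
                 thresholds = object$thresholds, ids = rownames(X),
                 intervals = NULL),
            class = "PredictionSet")
}

# ---- Ensemble ----

#' Validation grid search for the two-model ensemble weight
#'
#' Per condition, sweeps \code{w} over \{0, step, ..., 1\}, mixes
#' \code{w * pA + (1 - w) * pB}, re-selects the F1 probability threshold on
#' the validation split for each mixture, and keeps the weight with the
#' highest validation balanced accuracy (ties to the smallest \code{w}).
#' Because the grid includes both endpoints, the ensemble's validation BCA
#' is never below either component's.
#'
#' @param valProbsA,valProbsB validation probability matrices of the two
#'   component models (same participants, conditions in order).
#' @param valLabels matching ternary label matrix.
#' @param step grid step; default 0.01.
#' @return an \code{EnsembleWeights}: list with \code{w}, \code{thresholds},
#'   \code{val_bca}, \code{endpoint_bca} (w = 1 and w = 0 scores) and
#'   \code{step}.
#' @export
ensembleSearch <- function(valProbsA, valProbsB, valLabels, step = 0.01) {
  grid <- seq(0, 1, by = step)
  K <- ncol(valProbsA)
  w <- thr <- bca <- stats::setNames(numeric(K), colnames(valProbsA))
  endpoints <- matrix(NA_real_, K, 2,
                      dimnames = list(colnames(valProbsA), c("A", "B")))
  for (i in seq_len(K)) {
    y <- valLabels[, i]
    scores <- vapply(grid, function(wi) {
      p <- wi * valProbsA[, i] + (1 - wi) * valProbsB[, i]
      ct <- selectThresholds(matrix(p, ncol = 1),
                             matrix(y, ncol = 1))
      suppressWarnings(balancedAccuracy(as.integer(p >= ct), y))
    }, numeric(1))
    best <- which(scores == max(scores, na.rm = TRUE))[1]  # smallest w wins ties
    w[i] <- grid[best]
    p <- w[i] * valProbsA[, i] + (1 - w[i]) * valProbsB[, i]
    thr[i] <- selectThresholds(matrix(p, ncol = 1), matrix(y, ncol = 1))
    bca[i] <- scores[best]
    endpoints[i, ] <- c(scores[length(grid)], scores[1])
  }
  structure(list(w = w, thresholds = thr, val_bca = bca,
                 endpoint_bca = endpoints, step = step),
            class = "EnsembleWeights")
}

#' Apply ensemble weights to new probabilities
#'
#' @param weights an \code{EnsembleWeights}.
#' @param probsA,probsB probability matrices of the two components.
#' @return list with mixed \code{probabilities} and \code{calls} at the
#'   ensemble's validation-selected thresholds.
#' @export
ensembleApply <- function(weights, probsA, probsB) {
  probs <- sweep(probsA, 2, weights$w, "*") +
    sweep(probsB, 2, 1 - weights$w, "*")
  calls <- sweep(probs, 2, weights$thresholds, ">=") + 0L
  list(probabilities = probs, calls = calls)
}

# ---- Cross-validation orchestration ----

#' Run the full pipeline over a split plan
#'
#' For every rotation: feature selection on train + validation only, fresh
#' preprocessing transforms, fresh models, metrics on the untouched test
#' split. Optionally fits the boosted-tree baseline and the two-model
#' ensemble. No stage ever sees test rows before evaluation.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param plan a \linkS4class{SplitPlan}.
#' @param spec \code{\link{jointModelSpec}} for the joint model.
#' @param models subset of \code{c("joint", "xgb", "ensemble")}.
#' @param seed integer seed (feature selection and model sub-seeds derive
#'   from it).
#' @param keepModels keep fitted models/predictions per rotation (needed for
#'   downstream interpretation).
#' @param featselect_args extra arguments for \code{\link{selectFeatures}}.
#' @param verbose print progress.
#' @return list with \code{metrics} (long \code{data.frame}: split,
#'   condition, model, metric, value, n_test, n_train) and \code{rotations}
#'   (per-rotation panels, models and predictions when kept).
#' @export
runCrossValidation <- function(cohort, plan, spec = jointModelSpec(),
                               models = c("joint", "xgb", "ensemble"),
                               seed = 1L, keepModels = FALSE,
                               featselect_args = list(), verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  if ("ensemble" %in% models &&
      !all(c("joint", "xgb") %in% models))
    stop("the ensemble needs both component models")
  metrics <- data.frame()
  rotations <- vector("list", length(plan@folds))
  Y <- labelMatrix(cohort)
  for (r in seq_along(plan@folds)) {
    split <- plan@folds[[r]]
    if (verbose) message("rotation ", r, "/", length(plan@folds))
    panel <- do.call(selectFeatures, c(
      list(cohort = cohort, ids = c(split$train, split$validation),
           seed = .subSeed(seed, r), split_id = r),
      featselect_args))
    fitted <- list(); preds_test <- list(); preds_val <- list()
    if ("joint" %in% models) {
      sp <- spec; sp$seed <- .subSeed(seed, 100 + r)
      fitted$joint <- trainJointModel(cohort, panel, split, sp)
      preds_test$joint <- predict(fitted$joint, cohort, ids = split$test)
      preds_val$joint <- predict(fitted$joint, cohort, ids = split$validation)
    }
    if ("xgb" %in% models) {
      fitted$xgb <- trainXgbBaseline(cohort, panel, split,
                                     seed = .subSeed(seed, 200 + r))
      preds_test$xgb <- predict(fitted$xgb, cohort, ids = split$test)
      preds_val$xgb <- predict(fitted$xgb, cohort, ids = split$validation)
    }
    if ("ensemble" %in% models) {
      ew <- ensembleSearch(preds_val$joint$probabilities,
                           preds_val$xgb$probabilities,
                           Y[split$validation, , drop = FALSE])
      mixed <- ensembleApply(ew, preds_test$joint$probabilities,
                             preds_test$xgb$probabilities)
      preds_test$ensemble <- structure(
        list(probabilities = mixed$probabilities, calls = mixed$calls,
             embeddings = NULL, thresholds = ew$thresholds,
             ids = split$test, intervals = NULL), class = "PredictionSet")
      fitted$ensemble <- ew
    }
    Yt <- Y[split$test, , drop = FALSE]
    for (m in names(preds_test)) {
      pr <- preds_test[[m]]
      for (i in seq_len(6)) {
        bca <- suppressWarnings(balancedAccuracy(pr$calls[, i], Yt[, i]))
        auc <- aucScore(pr$probabilities[, i], Yt[, i])
        metrics <- rbind(metrics, data.frame(
          split = r, condition = conditionNames()[i], model = m,
          metric = c("bca", "auc"), value = c(bca, auc),
          n_test = length(split$test),
          n_train = length(split$train) + length(split$validation)))
      }
    }
    rotations[[r]] <- list(
      panel = panel,
      models = if (keepModels) fitted else NULL,
      predictions = if (keepModels) list(test = preds_test,
                                         val = preds_val) else NULL,
      split = split)
  }
  list(metrics = metrics, rotations = rotations)
}
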