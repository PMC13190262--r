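#' Per-protein linear-model association analysis
#'
#' For one condition, fits an ordinary least-squares model per protein of
#' natural-log abundance on the condition indicator, age, sex and the
#' participant's average protein level (mean natural-log abundance over all
#' proteins, controlling individual expression level). Restricted to the
#' given participants with an observed label for the condition. Effects are
#' reported as multiplicative fold changes \code{exp(beta)} with
#' Benjamini-Hochberg adjustment across all proteins.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param condition one of \code{conditionNames()}.
#' @param ids participants to use (typically train + validation).
#' @return \code{data.frame} (class \code{AssociationResult}) with columns
#'   \code{protein}, \code{beta}, \code{fold_change}, \code{p}, \code{p_adj}.
#' @export
glmAssociation <- function(cohort, condition, ids = participantIds(cohort)) {
  condition <- match.arg(condition, conditionNames())
  lm_ <- labelMatrix(cohort)[ids, condition]
  keep <- ids[!is.na(lm_)]
  y <- lm_[!is.na(lm_)]
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("condition '", condition, "' needs >= 2 positives and >= 2 negatives")
  X <- abundance(cohort, participantsAsRows = TRUE)[keep, , drop = FALSE]
  logX <- log(X)
  ph <- phenoTable(cohort)[keep, ]
  avg <- rowMeans(logX, na.rm = TRUE)
  Z <- cbind(intercept = 1, condition = as.numeric(y),
             age = as.numeric(ph$age), sex = as.numeric(ph$sex == "M"),
             avg_protein_level = avg)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    drop_ <- colnames(Z)[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(drop_, collapse = ", "))
  }
  p <- ncol(logX)
  beta <- pval <- rep(NA_real_, p)
  complete <- !is.na(logX)
  for (j in seq_len(p)) {
    rows <- complete[, j]
    Zj <- Z[rows, , drop = FALSE]
    yj <- logX[rows, j]
    fit <- stats::lm.fit(Zj, yj)
    df <- length(yj) - fit$rank
    if (df < 1) next
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                 drop = FALSE])
    se <- sqrt(sigma2 * diag(XtXinv))[match("condition",
                                            colnames(Zj)[fit$qr$pivot])]
    b <- fit$coefficients["condition"]
    beta[j] <- b
    pval[j] <- 2 * stats::pt(-abs(b / se), df)
  }
  out <- data.frame(protein = colnames(logX), beta = beta,
                    fold_change = exp(beta), p = pval,
                    p_adj = stats::p.adjust(pval, method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Association-stage protein picks
#'
#' Keeps proteins whose fold change passes the effect filter
#' (\code{> fc_hi} or \code{< fc_lo}), then the \code{top_n} smallest
#' adjusted p values among the survivors (all survivors when fewer).
#'
#' @param assoc an \code{AssociationResult}.
#' @param fc_hi,fc_lo fold-change filter bounds; defaults 2 and 0.5.
#' @param top_n number of proteins kept; default 5.
#' @return character vector of protein ids.
#' @export
selectByAssociation <- function(assoc, fc_hi = 2, fc_lo = 0.5, top_n = 5) {
  ok <- which(!is.na(assoc$fold_change) &
                (assoc$fold_change > fc_hi | assoc$fold_change < fc_lo))
  if (!length(ok)) return(character())
  ord <- ok[order(assoc$p_adj[ok], assoc$p[ok], ok)]
  assoc$protein[utils::head(ord, top_n)]
}

.stratifiedSubfolds <- function(y, n_subfolds, seed) {
  .withSeed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_subfolds), length(idx))
    }
    fold
  })
}

#' Boosted-tree consensus protein selection
#'
#' Merges the given participants (typically train + validation), resplits
#' them into \code{n_subfolds} stratified subfolds, and trains one
#' gradient-boosted tree classifier per rotation (the held-out subfold
#' tunes depth/subsampling over a small grid and the stopping round). A
#' protein is selected iff it is used (positive cumulative split gain) by
#' the model of \emph{every} rotation.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param condition one of \code{conditionNames()}.
#' @param ids participants to use.
#' @param n_subfolds number of subfolds; default 10.
#' @param seed integer seed.
#' @param grid list of hyperparameter sets tried on each rotation's
#'   validation subfold (scored by held-subfold AUC); each a list with
#'   \code{max_depth} and \code{subsample}.
#' @param nrounds boosting rounds per model.
#' @param eta learning rate.
#' @param colsample per-tree column subsampling; strong subsampling spreads
#'   split usage across the informative proteins, which the all-rotations
#'   consensus then filters for stability.
#' @param max_bin histogram bins.
#' @return character vector of consensus protein ids.
#' @details The ten models of one condition share a single pre-binned
#'   matrix; each rotation excludes its held-out subfold by zeroing those
#'   rows' instance weights (a zero-weight row contributes no gradient, so
#'   it is excluded from fitting exactly). Classes are reweighted to
#'   balance (\code{scale_pos_weight}) so rare conditions drive as many
#'   splits as common ones.
#' @export
gbtPredictiveSelection <- function(cohort, condition,
                                   ids = participantIds(cohort),
                                   n_subfolds = 10, seed = 1L,
                                   grid = list(list(max_depth = 3,
                                                    subsample = 0.8)),
                                   nrounds = 60, eta = 0.2,
                                   colsample = 0.12, max_bin = 16) {
  condition <- match.arg(condition, conditionNames())
  lab <- labelMatrix(cohort)[ids, condition]
  keep <- ids[!is.na(lab)]
  y <- lab[!is.na(lab)]
  if (sum(y == 1) < n_subfolds)
    stop("condition '", condition, "' lacks positives for every subfold")
  X <- abundance(cohort, participantsAsRows = TRUE)[keep, , drop = FALSE]
  fold <- .stratifiedSubfolds(y, n_subfolds, seed)
  dq <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  spw <- sum(y == 0) / sum(y == 1)
  picks <- vector("list", n_subfolds)
  for (r in seq_len(n_subfolds)) {
    w <- as.numeric(fold != r)
    xgboost::setinfo(dq, "weight", w)
    best <- NULL; bestAuc <- -Inf
    for (g in grid) {
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = g$max_depth, subsample = g$subsample,
                      colsample_bytree = colsample, eta = eta,
                      max_bin = max_bin, tree_method = "hist",
                      scale_pos_weight = spw, nthread = 1,
                      seed = .subSeed(seed, r)),
        data = dq, nrounds = nrounds, verbose = 0)
      if (length(grid) == 1) {
        best <- bst
        break
      }
      pv <- stats::predict(bst, dq)[w == 0]
      auc <- aucScore(pv, y[w == 0])
      if (!is.na(auc) && auc > bestAuc) { bestAuc <- auc; best <- bst }
    }
    imp <- xgboost::xgb.importance(model = best)
    picks[[r]] <- imp$Feature[imp$Gain > 0]
  }
  Reduce(intersect, picks)
}

#' Assemble the split's feature panel
#'
#' Union of the association-stage and predictive-stage picks over all six
#' conditions, deduplicated, with provenance, ordered by the cohort's
#' protein order (stable and deterministic).
#'
#' @param assocPicks named list (per condition) of association picks.
#' @param predPicks named list (per condition) of predictive picks.
#' @param proteinOrder the cohort's full protein id vector.
#' @param split_id optional identifier of the train-validation-test split.
#' @return a \code{FeaturePanel}: list with \code{proteins} (ordered ids),
#'   \code{provenance} (\code{data.frame}: protein, stage, condition) and
#'   \code{split_id}.
#' @export
buildPanel <- function(assocPicks, predPicks, proteinOrder, split_id = NA) {
  prov <- rbind(
    do.call(rbind, lapply(names(assocPicks), function(cn)
      if (length(assocPicks[[cn]]))
        data.frame(protein = assocPicks[[cn]], stage = "association",
                   condition = cn, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(names(predPicks), function(cn)
      if (length(predPicks[[cn]]))
        data.frame(protein = predPicks[[cn]], stage = "predictive",
                   condition = cn, stringsAsFactors = FALSE))))
  if (is.null(prov))
    prov <- data.frame(protein = character(), stage = character(),
                       condition = character(), stringsAsFactors = FALSE)
  proteins <- intersect(proteinOrder, unique(prov$protein))
  structure(list(proteins = proteins, provenance = prov, split_id = split_id),
            class = "FeaturePanel")
}

#' @export
print.FeaturePanel <- function(x, ...) {
  cat("FeaturePanel:", length(x$proteins), "proteins (split ",
      as.character(x$split_id), ")\n")
  tab <- table(x$provenance$stage)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Run both selection stages for every condition
#'
#' Convenience wrapper producing the split's \code{FeaturePanel} from
#' training + validation participants only.
#'
#' @inheritParams gbtPredictiveSelection
#' @param ids train + validation participant ids.
#' @param fc_hi,fc_lo,top_n association-stage filter parameters.
#' @param split_id identifier stored in the panel.
#' @param ... passed to \code{\link{gbtPredictiveSelection}}.
#' @return a \code{FeaturePanel}.
#' @export
selectFeatures <- function(cohort, ids, fc_hi = 2, fc_lo = 0.5, top_n = 5,
                           n_subfolds = 10, seed = 1L, split_id = NA, ...) {
  assocPicks <- predPicks <- stats::setNames(
    vector("list", 6), conditionNames())
  for (cn in conditionNames()) {
    assoc <- glmAssociation(cohort, cn, ids)
    assocPicks[[cn]] <- selectByAssociation(assoc, fc_hi, fc_lo, top_n)
    predPicks[[cn]] <- gbtPredictiveSelection(
      cohort, cn, ids, n_subfolds = n_subfolds,
      seed = .subSeed(seed, match(cn, conditionNames())), ...)
  }
  buildPanel(assocPicks, predPicks, proteinIds(cohort), split_id = split_id)
}
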