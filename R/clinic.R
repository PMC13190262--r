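# Translation layer: few-shot transfer, the progression task, two-cutoff
# probability calibration and the per-individual diagnostic report.

.fitLogistic <- function(x, y, seed = NULL) {
  # regularized logistic head (ridge at the default-strength penalty)
  x <- as.matrix(x)
  glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                 alpha = 0, lambda = 1 / length(y), standardize = TRUE)
}

.predictLogistic <- function(fit, x) {
  as.numeric(stats::predict(fit, as.matrix(x), type = "response"))
}

#' Few-shot transfer of the joint model to a new site
#'
#' For each repeat, samples K participants from the new site (stratified on
#' the joint label pattern), then fits one regularized logistic classifier
#' per condition on (a) the frozen model's proteomic embeddings
#' ("FineTune") and (b) the model's panel proteins ("Retrain";
#' K-sample-mean imputation and K-statistics z-scoring), calibrating each
#' probability threshold by F1 on the K sample, and evaluates balanced
#' accuracy and AUC on the remaining participants. Conditions with fewer
#' than 2 positives or negatives in a K sample are skipped for that repeat
#' (logged in the result).
#'
#' @param model a \code{TrainedJointModel}.
#' @param newCohort the new site's \linkS4class{ProteoCohort}.
#' @param K number of adaptation participants; default 100.
#' @param repeats number of random K-shot repeats; default 20.
#' @param seed integer seed.
#' @param conditions conditions to evaluate.
#' @return \code{data.frame} with columns \code{repeat_}, \code{condition},
#'   \code{method} (FineTune/Retrain), \code{bca}, \code{auc}, \code{n_eval};
#'   skipped repeats recorded in \code{attr(, "skipped")}.
#' @export
kShotTransfer <- function(model, newCohort, K = 100, repeats = 20, seed = 1L,
                          conditions = conditionNames()) {
  ids <- participantIds(newCohort)
  Y <- labelMatrix(newCohort)
  if (length(ids) < K + 20)
    stop("new-site cohort must have at least K + 20 participants")
  emb <- extractEmbeddings(model, newCohort)
  Xraw <- abundance(newCohort, participantsAsRows = TRUE)[, model$proteins,
                                                          drop = FALSE]
  pattern <- apply(Y, 1, function(r) paste(ifelse(is.na(r), "m", r),
                                           collapse = ""))
  res <- list(); skipped <- list()
  for (rep_ in seq_len(repeats)) {
    sel <- .withSeed(.subSeed(seed, rep_), {
      sel <- character()
      for (pt in unique(pattern)) {
        cand <- ids[pattern == pt]
        nk <- round(K * length(cand) / length(ids))
        sel <- c(sel, sample(cand, min(nk, length(cand))))
      }
      # top up / trim to exactly K
      extra <- setdiff(ids, sel)
      if (length(sel) < K) sel <- c(sel, sample(extra, K - length(sel)))
      if (length(sel) > K) sel <- sample(sel, K)
      sel
    })
    rest <- setdiff(ids, sel)
    # Retrain representation: K-sample statistics only
    Xk <- Xraw[sel, , drop = FALSE]
    mu <- colMeans(Xk, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    sd_ <- apply(Xk, 2, stats::sd, na.rm = TRUE)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1
    zfun <- function(M) {
      M <- sweep(M, 2, mu); M <- sweep(M, 2, sd_, "/")
      M[is.na(M)] <- 0
      M
    }
    for (cn in conditions) {
      yk <- Y[sel, cn]; yr <- Y[rest, cn]
      ok <- !is.na(yk)
      if (sum(yk[ok] == 1) < 2 || sum(yk[ok] == 0) < 2) {
        skipped[[length(skipped) + 1]] <- data.frame(
          repeat_ = rep_, condition = cn)
        next
      }
      for (method in c("FineTune", "Retrain")) {
        tr_x <- if (method == "FineTune") emb[sel, , drop = FALSE][ok, ,
                                                                   drop = FALSE]
        else zfun(Xk)[ok, , drop = FALSE]
        te_x <- if (method == "FineTune") emb[rest, , drop = FALSE]
        else zfun(Xraw[rest, , drop = FALSE])
        fit <- .fitLogistic(tr_x, yk[ok])
        ptr <- .predictLogistic(fit, tr_x)
        thr <- selectThresholds(matrix(ptr, ncol = 1),
                                matrix(yk[ok], ncol = 1))
        pte <- .predictLogistic(fit, te_x)
        res[[length(res) + 1]] <- data.frame(
          repeat_ = rep_, condition = cn, method = method,
          bca = suppressWarnings(balancedAccuracy(as.integer(pte >= thr), yr)),
          auc = aucScore(pte, yr), n_eval = sum(!is.na(yr)))
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(repeat_ = integer(), condition = character())
  out
}

#' Progression prediction from baseline embeddings
#'
#' Among participants with baseline CDR 0 and non-decreasing follow-up CDR
#' (others are excluded), runs stratified k-fold cross-validation of a
#' default-configuration regularized logistic classifier on the frozen
#' baseline embeddings and reports pooled test balanced accuracy and AUC.
#'
#' @param model a \code{TrainedJointModel}.
#' @param cohort a \linkS4class{ProteoCohort} with follow-up CDR filled.
#' @param progressionLabels \code{data.frame} from
#'   \code{\link{makeProgressionLabels}} (columns participant, progressor).
#' @param k folds; default 10.
#' @param seed integer seed.
#' @return list with \code{bca}, \code{auc}, \code{n}, \code{n_progressors}
#'   and the pooled \code{predictions}.
#' @export
progressionTask <- function(model, cohort, progressionLabels, k = 10,
                            seed = 1L) {
  elig <- progressionEligible(cohort)
  lab <- progressionLabels[!is.na(progressionLabels$progressor), ]
  ids <- intersect(lab$participant, names(elig)[elig])
  y <- lab$progressor[match(ids, lab$participant)]
  if (length(ids) < 2 * k) stop("too few eligible participants")
  emb <- extractEmbeddings(model, cohort, ids = ids)
  fold <- .stratifiedSubfolds(y, k, seed)
  pooled <- rep(NA_real_, length(ids))
  calls <- rep(NA_integer_, length(ids))
  for (r in seq_len(k)) {
    tr <- fold != r
    fit <- .fitLogistic(emb[tr, , drop = FALSE], y[tr])
    ptr <- .predictLogistic(fit, emb[tr, , drop = FALSE])
    thr <- selectThresholds(matrix(ptr, ncol = 1), matrix(y[tr], ncol = 1))
    pte <- .predictLogistic(fit, emb[!tr, , drop = FALSE])
    pooled[!tr] <- pte
    calls[!tr] <- as.integer(pte >= thr)
  }
  list(bca = suppressWarnings(balancedAccuracy(calls, y)),
       auc = aucScore(pooled, y), n = length(ids), n_progressors = sum(y),
       predictions = data.frame(participant = ids, progressor = y,
                                probability = pooled, call = calls))
}

#' Two-cutoff probability calibration for predictive-value guarantees
#'
#' Searches the midpoints of sorted unique derivation-set probabilities for
#' the largest lower cutoff whose negative zone keeps NPV at or above
#' \code{target_npv}, and the smallest upper cutoff whose positive zone
#' keeps PPV at or above \code{target_ppv}; probabilities between the
#' cutoffs are indeterminate (confirmatory testing recommended). A side
#' with no attaining threshold is reported unattainable; crossed cutoffs
#' (fully separable derivation data) are returned with an
#' empty-indeterminate flag and a warning.
#'
#' @param probs derivation-set probabilities.
#' @param labels binary reference labels (both classes required).
#' @param target_npv,target_ppv targets; defaults 0.9 and 0.9 (a relaxed
#'   PPV such as 0.4 is supported for low-validity references).
#' @return a \code{TwoCutoff}: lower/upper cutoffs, targets, achieved
#'   derivation NPV/PPV, coverage, flags.
#' @export
fitTwoCutoff <- function(probs, labels, target_npv = 0.9, target_ppv = 0.9) {
  obs <- !is.na(labels)
  p <- probs[obs]; y <- labels[obs]
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both classes must be present in the derivation set")
  u <- sort(unique(p))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
  npv <- vapply(cand, function(ct) {
    below <- p < ct
    if (!any(below)) NA_real_ else mean(y[below] == 0)
  }, numeric(1))
  ppv <- vapply(cand, function(ct) {
    above <- p >= ct
    if (!any(above)) NA_real_ else mean(y[above] == 1)
  }, numeric(1))
  okN <- which(!is.na(npv) & npv >= target_npv)
  okP <- which(!is.na(ppv) & ppv >= target_ppv)
  lower <- if (length(okN)) cand[max(okN)] else NA_real_
  upper <- if (length(okP)) cand[min(okP)] else NA_real_
  emptyInd <- FALSE
  if (!is.na(lower) && !is.na(upper) && lower > upper) {
    warning("cutoffs crossed (separable derivation set); indeterminate zone empty")
    emptyInd <- TRUE
  }
  ach_npv <- if (is.na(lower)) NA_real_ else mean(y[p < lower] == 0)
  ach_ppv <- if (is.na(upper)) NA_real_ else mean(y[p >= upper] == 1)
  coverage <- if (is.na(lower) || is.na(upper)) NA_real_ else
    mean(p < min(lower, upper) | p >= upper)
  structure(list(lower = lower, upper = upper,
                 target_npv = target_npv, target_ppv = target_ppv,
                 derivation_npv = ach_npv, derivation_ppv = ach_ppv,
                 coverage = coverage, empty_indeterminate = emptyInd,
                 unattainable = c(npv = is.na(lower), ppv = is.na(upper))),
            class = "TwoCutoff")
}

#' @export
print.TwoCutoff <- function(x, ...) {
  cat(sprintf("TwoCutoff: lower %.4f (NPV %.3f >= %.2f), upper %.4f (PPV %.3f >= %.2f)\n",
              x$lower, x$derivation_npv, x$target_npv,
              x$upper, x$derivation_ppv, x$target_ppv))
  cat(sprintf("  coverage outside indeterminate zone: %.3f\n", x$coverage))
  if (x$empty_indeterminate) cat("  (indeterminate zone empty)\n")
  invisible(x)
}

#' Apply two-cutoff classification
#'
#' Monotone in the probability: at or above the upper cutoff is positive,
#' below the lower cutoff is negative, in between is indeterminate
#' (confirmatory testing recommended).
#'
#' @param cutoffs a \code{TwoCutoff}.
#' @param probs probabilities to classify.
#' @return factor with levels negative, indeterminate, positive.
#' @export
applyTwoCutoff <- function(cutoffs, probs) {
  out <- rep("indeterminate", length(probs))
  if (!is.na(cutoffs$upper)) out[probs >= cutoffs$upper] <- "positive"
  if (!is.na(cutoffs$lower)) out[probs < cutoffs$lower &
                                   out != "positive"] <- "negative"
  factor(out, levels = c("negative", "indeterminate", "positive"))
}

# sampling-based Shapley attribution on the model's input representation
.shapleySampling <- function(net, x, background, nPermutations, seed) {
  p <- length(x)
  .withSeed(seed, {
    contrib <- matrix(0, p, 6)
    for (m in seq_len(nPermutations)) {
      ord <- sample.int(p)
      b <- background[sample.int(nrow(background), 1), ]
      Z <- matrix(b, p + 1, p, byrow = TRUE)
      for (step in seq_len(p)) {
        Z[(step + 1):(p + 1), ord[step]] <- x[ord[step]]
      }
      P <- .forwardNet(net, Z)$probs
      contrib[ord, ] <- contrib[ord, ] + (P[-1, , drop = FALSE] -
                                            P[-(p + 1), , drop = FALSE])
    }
    contrib / nPermutations
  })
}

#' Per-individual diagnostic report
#'
#' Produces the self-contained report for one participant: the six
#' probabilities with their zero-centered normalized form
#' (\code{log(p / threshold)}), binary calls, sampling-based Shapley
#' attributions of each condition's probability against the background-set
#' mean prediction (top 10 positively and top 10 negatively contributing
#' proteins per condition), the participant's location on a fitted
#' probability map, and optional protein-trait annotations joined from a
#' user-supplied table.
#'
#' @param model a \code{TrainedJointModel}.
#' @param cohort a \linkS4class{ProteoCohort} containing the participant.
#' @param participant participant id.
#' @param backgroundIds reference participants (typically the training
#'   split); fewer than 30 triggers an attribution-variance warning.
#' @param map optional \code{ProbabilityMap} for localization.
#' @param traitTable optional \code{data.frame} with columns \code{protein}
#'   and \code{trait}.
#' @param nPermutations Shapley sampling permutations; default 128.
#' @param seed integer seed; regeneration with the same seed is identical.
#' @return an \code{IndividualReport} (list, JSON-serializable via
#'   \code{\link{writeIndividualReport}}).
#' @export
individualReport <- function(model, cohort, participant, backgroundIds,
                             map = NULL, traitTable = NULL,
                             nPermutations = 128, seed = 1L) {
  if (length(backgroundIds) < 30)
    warning("background set has < 30 rows; attribution variance will be high")
  Xall <- abundance(cohort, participantsAsRows = TRUE)
  Xp <- applyPreprocessChain(model$chain,
                             Xall[c(participant, backgroundIds), ,
                                  drop = FALSE])
  x <- Xp[1, ]
  bg <- Xp[-1, , drop = FALSE]
  pr <- predict(model, cohort, ids = participant)
  probs <- pr$probabilities[1, ]
  contrib <- .shapleySampling(model$net, x, bg, nPermutations, seed)
  rownames(contrib) <- colnames(Xp)
  colnames(contrib) <- conditionNames()
  topTables <- lapply(conditionNames(), function(cn) {
    v <- sort(contrib[, cn], decreasing = TRUE)
    pos <- v[v > 0][seq_len(min(10, sum(v > 0)))]
    neg <- rev(v[v < 0])[seq_len(min(10, sum(v < 0)))]
    list(positive = data.frame(protein = names(pos), value = unname(pos)),
         negative = data.frame(protein = names(neg), value = unname(neg)))
  })
  names(topTables) <- conditionNames()
  loc <- if (!is.null(map)) as.numeric(projectOntoMap(map, probs)) else NULL
  traits <- NULL
  if (!is.null(traitTable)) {
    used <- unique(unlist(lapply(topTables, function(t_)
      c(t_$positive$protein, t_$negative$protein))))
    traits <- traitTable[traitTable$protein %in% used, , drop = FALSE]
  }
  structure(list(
    participant = participant,
    probabilities = as.list(probs),
    normalized = as.list(normalizeProbability(probs, model$thresholds,
                                              log = TRUE)),
    calls = as.list(pr$calls[1, ]),
    thresholds = as.list(model$thresholds),
    contributions = topTables,
    map_location = loc,
    traits = traits,
    n_background = length(backgroundIds),
    seed = seed), class = "IndividualReport")
}

#' @rdname individualReport
#' @param report an \code{IndividualReport}.
#' @param path output JSON path.
#' @export
writeIndividualReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
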