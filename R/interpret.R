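# Model interpretation: permutation feature importance, Haufe covariances,
# embedding signatures, the diagnostic probability map and subtype analysis.

# run the trunk forward from the first layer's pre-activation (used to make
# single-column permutations cheap: a rank-one update to layer 1)
.forwardFromPre1 <- function(net, pre1) {
  nh <- net$n_hidden
  a <- .gelu(pre1)
  for (l in seq_len(nh)[-1]) {
    a <- .gelu(a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a)))
  }
  emb <- a %*% net$W[[nh + 1]] + rep(net$b[[nh + 1]], each = nrow(a))
  logits <- emb %*% net$W[[nh + 2]] + rep(net$b[[nh + 2]], each = nrow(emb))
  .sigmoid(logits)
}

.condCrossEntropy <- function(Y, P) {
  P <- .clipProb(P)
  vapply(seq_len(ncol(Y)), function(i) {
    obs <- !is.na(Y[, i])
    -mean(Y[obs, i] * log(P[obs, i]) + (1 - Y[obs, i]) * log(1 - P[obs, i]))
  }, numeric(1))
}

#' Permutation feature importance (single split)
#'
#' For every panel protein, permutes that protein's values across the test
#' participants (on the model's preprocessed input representation),
#' recomputes the per-condition cross-entropy, and records the increase
#' over the unpermuted baseline. Over \code{n_perm} permutations it reports
#' the mean and sd of the increases, \code{z = mean/sd}, a one-sided normal
#' p value (importance means increased loss), and Benjamini-Hochberg
#' adjusted p values across the panel within each condition. A zero-sd
#' protein gets p = 0.5 and is flagged.
#'
#' @param model a \code{TrainedJointModel}.
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param testIds test-split participant ids.
#' @param n_perm number of permutations; default 100.
#' @param seed integer seed.
#' @return \code{data.frame} (class \code{ImportanceReport}) with columns
#'   \code{protein}, \code{condition}, \code{mean}, \code{sd}, \code{z},
#'   \code{p}, \code{p_adj}, \code{flagged}.
#' @export
permFit <- function(model, cohort, testIds, n_perm = 100, seed = 1L) {
  Xall <- abundance(cohort, participantsAsRows = TRUE)[testIds, , drop = FALSE]
  Xp <- applyPreprocessChain(model$chain, Xall)
  Y <- labelMatrix(cohort)[testIds, , drop = FALSE]
  net <- model$net
  n <- nrow(Xp)
  base_ce <- .condCrossEntropy(Y, .forwardNet(net, Xp)$probs)
  pre1 <- Xp %*% net$W[[1]] + rep(net$b[[1]], each = n)
  prots <- colnames(Xp)
  out <- vector("list", length(prots))
  .withSeed(seed, {
    # one stacked forward per protein: n_perm rank-one updates to layer 1
    Yrep <- Y[rep(seq_len(n), n_perm), , drop = FALSE]
    for (jj in seq_along(prots)) {
      j <- jj
      xj <- Xp[, j]
      perms <- vapply(seq_len(n_perm), function(r) xj[sample.int(n)],
                      numeric(n))
      delta <- perms - xj                        # n x n_perm
      w1j <- net$W[[1]][j, ]
      big <- pre1[rep(seq_len(n), n_perm), , drop = FALSE] +
        as.vector(delta) %o% w1j
      Pbig <- .forwardFromPre1(net, big)
      diffs <- matrix(NA_real_, n_perm, 6)
      for (r in seq_len(n_perm)) {
        rows <- ((r - 1) * n + 1):(r * n)
        diffs[r, ] <- .condCrossEntropy(Y, Pbig[rows, , drop = FALSE]) - base_ce
      }
      m <- colMeans(diffs)
      s <- apply(diffs, 2, stats::sd)
      z <- ifelse(s > 0, m / s, 0)
      p <- ifelse(s > 0, stats::pnorm(z, lower.tail = FALSE), 0.5)
      out[[jj]] <- data.frame(
        protein = prots[j], condition = conditionNames(),
        mean = m, sd = s, z = z, p = p, flagged = s == 0,
        stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  for (cn in conditionNames()) {
    sel <- res$condition == cn
    res$p_adj[sel] <- stats::p.adjust(res$p[sel], method = "BH")
  }
  class(res) <- c("ImportanceReport", "data.frame")
  res
}

#' Aggregate permutation importance across splits
#'
#' Fold count is the number of splits in which a protein-condition pair was
#' significant (BH-adjusted p < 0.05 within its split); the averaged z
#' score is taken over the splits whose panel contained the protein.
#'
#' @param reports list of per-split \code{ImportanceReport}s.
#' @param allProteins optional full protein universe; proteins never present
#'   in any panel are then listed separately.
#' @param alpha significance level on adjusted p; default 0.05.
#' @return list with \code{table} (\code{data.frame}: protein, condition,
#'   fold_count, n_splits_present, mean_z) and \code{never_in_panel}.
#' @export
aggregateImportance <- function(reports, allProteins = NULL, alpha = 0.05) {
  all_ <- do.call(rbind, lapply(seq_along(reports), function(s) {
    r <- reports[[s]]
    r$split <- s
    r
  }))
  key <- paste(all_$protein, all_$condition, sep = "\r")
  agg <- data.frame(
    protein = tapply(all_$protein, key, `[`, 1),
    condition = tapply(all_$condition, key, `[`, 1),
    fold_count = as.integer(tapply(all_$p_adj < alpha, key, sum)),
    n_splits_present = as.integer(tapply(all_$split, key, length)),
    mean_z = as.numeric(tapply(all_$z, key, mean)),
    row.names = NULL, stringsAsFactors = FALSE)
  agg <- agg[order(match(agg$condition, conditionNames()),
                   -agg$fold_count, -agg$mean_z), ]
  rownames(agg) <- NULL
  never <- if (is.null(allProteins)) character() else
    setdiff(allProteins, unique(all_$protein))
  list(table = agg, never_in_panel = never)
}

#' Haufe covariance importance of embeddings
#'
#' Since the heads combine the embeddings linearly, embedding importance is
#' read from the covariance between embedding activations and predicted
#' probabilities over a reference population, which is more reliable than
#' the head weights themselves.
#'
#' @param embeddings participants-by-embedding matrix.
#' @param probs participants-by-condition probability matrix.
#' @return embedding-by-condition covariance matrix.
#' @export
haufeImportance <- function(embeddings, probs) {
  stats::cov(as.matrix(embeddings), as.matrix(probs))
}

#' Embedding-specific protein signature
#'
#' Gradient-boosted tree regression of one embedding dimension on the panel
#' proteins (hyperparameters picked on the validation split for lowest mean
#' squared error); proteins with cumulative split gain (total gain) above
#' \code{gain_threshold} form the signature.
#'
#' @param X participants-by-panel matrix (model input representation).
#' @param target embedding values (one dimension) for the same participants.
#' @param trainIdx,valIdx row indices for fitting and tuning.
#' @param gain_threshold total-gain cutoff; default 50.
#' @param grid hyperparameter sets tried (max_depth, subsample).
#' @param nrounds maximum boosting rounds.
#' @param seed integer seed.
#' @return character vector of signature protein ids (with their total gain
#'   as an attribute \code{"gain"} for all panel proteins used).
#' @export
embeddingProteinSignature <- function(X, target, trainIdx, valIdx,
                                      gain_threshold = 50,
                                      grid = list(list(max_depth = 3,
                                                       subsample = 0.9)),
                                      nrounds = 200, seed = 1L) {
  dtr <- xgboost::xgb.DMatrix(X[trainIdx, , drop = FALSE],
                              label = target[trainIdx])
  dva <- xgboost::xgb.DMatrix(X[valIdx, , drop = FALSE],
                              label = target[valIdx])
  best <- NULL; bestMse <- Inf
  for (g in grid) {
    bst <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eval_metric = "rmse",
                    max_depth = g$max_depth, subsample = g$subsample,
                    eta = 0.1, nthread = 1, seed = seed),
      data = dtr, nrounds = nrounds, evals = list(val = dva),
      early_stopping_rounds = 20, verbose = 0)
    mse <- min(attributes(bst)$evaluation_log$val_rmse)^2
    if (mse < bestMse) { bestMse <- mse; best <- bst }
  }
  tree <- xgboost::xgb.model.dt.tree(model = best)
  splits <- tree[tree$Feature != "Leaf", ]
  gain <- tapply(splits$Gain, splits$Feature, sum)
  sig <- names(gain)[gain > gain_threshold]
  attr(sig, "gain") <- gain
  sig
}

#' Single-diagnosis eligibility for the probability map
#'
#' Participants with exactly one positive label among the six conditions;
#' individuals with all negatives or multiple positives are excluded.
#'
#' @param labels participant-by-6 ternary label matrix.
#' @return factor of the single positive condition (NA = ineligible).
#' @export
mapEligibility <- function(labels) {
  npos <- rowSums(labels == 1L, na.rm = TRUE)
  diag_ <- rep(NA_character_, nrow(labels))
  one <- npos == 1
  diag_[one] <- conditionNames()[apply(labels[one, , drop = FALSE] == 1L,
                                       1, which.max)]
  factor(diag_, levels = conditionNames())
}

#' Diagnostic probability map
#'
#' Embeds the 6-dimensional predicted-probability vectors of
#' single-diagnosis participants into two dimensions with t-SNE (exact,
#' perplexity capped at n/4 for desk-scale maps; the default 1000 targets
#' consortium scale), draws a Gaussian KDE density contour per diagnosis at
#' the stated threshold, and supports out-of-sample projection of new
#' probability vectors onto the fitted map.
#'
#' @param probs participants-by-6 probability matrix (single-diagnosis
#'   positives only; see \code{\link{mapEligibility}}).
#' @param diagnosis factor of each participant's diagnosis.
#' @param perplexity requested perplexity; auto-shrunk (warning) when it
#'   reaches n/4.
#' @param seed integer seed; coordinates are deterministic given it.
#' @param max_iter t-SNE iterations.
#' @param kde_threshold density contour level relative to the per-diagnosis
#'   density maximum; default 0.01.
#' @return a \code{ProbabilityMap}: list with \code{coords}, \code{diagnosis},
#'   \code{contours}, \code{perplexity} and the training probabilities used
#'   for projection.
#' @export
probabilityMap <- function(probs, diagnosis, perplexity = 1000, seed = 1L,
                           max_iter = 500, kde_threshold = 0.01) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  if (n < 50) stop("need at least 50 eligible participants")
  stopifnot(length(diagnosis) == n)
  cap <- floor(n / 4)
  if (perplexity > cap) {
    warning("perplexity shrunk from ", perplexity, " to ", cap)
    perplexity <- cap
  }
  coords <- .tsne(probs, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  dimnames(coords) <- list(rownames(probs), c("tsne1", "tsne2"))
  contours <- list()
  for (cn in levels(factor(diagnosis))) {
    pts <- coords[which(diagnosis == cn), , drop = FALSE]
    if (nrow(pts) < 10) next
    # Scott's rule bandwidth per axis
    h <- apply(pts, 2, stats::sd) * nrow(pts)^(-1 / 6)
    kd <- MASS::kde2d(pts[, 1], pts[, 2], h = h * 2, n = 50)
    lev <- kde_threshold * max(kd$z)
    contours[[cn]] <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = lev)
  }
  structure(list(coords = coords, diagnosis = diagnosis, contours = contours,
                 perplexity = perplexity, seed = seed,
                 train_probs = probs, kde_threshold = kde_threshold),
            class = "ProbabilityMap")
}

#' Project new probability vectors onto a fitted map
#'
#' t-SNE has no native parametric transform; new participants are placed at
#' the Gaussian-kernel weighted average of their \code{k} nearest training
#' participants' map coordinates (distances in the 6-D probability space).
#'
#' @param map a \code{ProbabilityMap}.
#' @param newProbs matrix (or vector) of new 6-D probability vectors.
#' @param k neighbourhood size.
#' @return matrix of 2-D coordinates.
#' @export
projectOntoMap <- function(map, newProbs, k = 5) {
  P <- map$train_probs
  newProbs <- matrix(newProbs, ncol = ncol(P))
  out <- matrix(NA_real_, nrow(newProbs), 2,
                dimnames = list(rownames(newProbs), colnames(map$coords)))
  for (i in seq_len(nrow(newProbs))) {
    d2 <- colSums((t(P) - newProbs[i, ])^2)
    nn <- order(d2)[seq_len(min(k, length(d2)))]
    sig2 <- mean(d2[nn]) + 1e-12
    w <- exp(-d2[nn] / (2 * sig2))
    out[i, ] <- colSums(map$coords[nn, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' @export
print.ProbabilityMap <- function(x, ...) {
  cat("ProbabilityMap:", nrow(x$coords), "participants, perplexity",
      x$perplexity, "\n")
  print(table(x$diagnosis))
  invisible(x)
}

#' Within-diagnosis clustering on the probability map
#'
#' K-means on the 2-D map coordinates of one diagnosis's participants for
#' every k in \code{k_range}; the k with the highest mean silhouette width
#' is returned. Deterministic given the seed (multiple restarts, best
#' inertia).
#'
#' @param map a \code{ProbabilityMap}.
#' @param diagnosis which diagnosis to cluster.
#' @param k_range candidate cluster counts; default 2:10.
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return list with \code{labels} (named cluster assignment), \code{k},
#'   \code{silhouette} (mean width per candidate k).
#' @export
clusterMap <- function(map, diagnosis, k_range = 2:10, seed = 1L,
                       nstart = 10) {
  idx <- which(map$diagnosis == diagnosis)
  pts <- map$coords[idx, , drop = FALSE]
  if (nrow(unique(pts)) < 2)
    stop("all points identical; no clustering possible for ", diagnosis)
  k_range <- k_range[k_range < nrow(pts)]
  if (!length(k_range)) stop("too few participants for the requested k range")
  D <- stats::dist(pts)
  .withSeed(seed, {
    sil <- stats::setNames(numeric(length(k_range)), k_range)
    fits <- vector("list", length(k_range))
    for (ii in seq_along(k_range)) {
      km <- stats::kmeans(pts, centers = k_range[ii], nstart = nstart,
                          iter.max = 50)
      fits[[ii]] <- km
      sw <- cluster::silhouette(km$cluster, D)
      sil[ii] <- mean(sw[, "sil_width"])
    }
    bi <- which.max(sil)
    labels <- stats::setNames(fits[[bi]]$cluster, rownames(pts))
    list(labels = labels, k = k_range[bi], silhouette = sil)
  })
}

#' Differential protein abundance across map clusters
#'
#' Within one diagnosis's positives, fits per protein a linear model of
#' natural-log abundance on the cluster indicator variables plus age, sex,
#' site and average protein level; reports the log fold change and
#' BH-adjusted p per non-reference cluster. Clusters with fewer than 5
#' members are excluded with a warning.
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param clusterLabels named cluster assignment (one diagnosis's positives).
#' @param min_cluster minimum cluster size; default 5.
#' @return \code{data.frame} with protein, cluster, logFC, p, p_adj.
#' @export
clusterDifferentialAbundance <- function(cohort, clusterLabels,
                                         min_cluster = 5) {
  tab <- table(clusterLabels)
  small <- names(tab)[tab < min_cluster]
  if (length(small)) {
    warning("cluster(s) with < ", min_cluster, " members excluded: ",
            paste(small, collapse = ", "))
    clusterLabels <- clusterLabels[!clusterLabels %in% small]
  }
  ids <- names(clusterLabels)
  if (length(unique(clusterLabels)) < 2)
    stop("need at least two clusters of sufficient size")
  X <- abundance(cohort, participantsAsRows = TRUE)[ids, , drop = FALSE]
  logX <- log(X)
  ph <- phenoTable(cohort)[ids, ]
  avg <- rowMeans(logX, na.rm = TRUE)
  cl <- factor(clusterLabels)
  Z <- stats::model.matrix(~ cl + age + sexM + site + avg, data.frame(
    cl = cl, age = as.numeric(ph$age), sexM = as.numeric(ph$sex == "M"),
    site = factor(ph$site), avg = avg))
  clCols <- grep("^cl", colnames(Z), value = TRUE)
  p <- ncol(logX)
  res <- vector("list", p)
  complete <- !is.na(logX)
  for (j in seq_len(p)) {
    rows <- complete[, j]
    Zj <- Z[rows, , drop = FALSE]
    fit <- stats::lm.fit(Zj, logX[rows, j])
    df <- sum(rows) - fit$rank
    if (df < 1) next
    sigma2 <- sum(fit$residuals^2) / df
    R <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                            drop = FALSE])
    pivNames <- colnames(Zj)[fit$qr$pivot[seq_len(fit$rank)]]
    se <- sqrt(sigma2 * diag(R))
    names(se) <- pivNames
    b <- fit$coefficients[clCols]
    pv <- 2 * stats::pt(-abs(b / se[clCols]), df)
    res[[j]] <- data.frame(protein = colnames(logX)[j],
                           cluster = sub("^cl", "", clCols),
                           logFC = unname(b), p = unname(pv),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (cc in unique(out$cluster)) {
    sel <- out$cluster == cc
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  out
}
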