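# Multi-task joint diagnostic network: shared fully connected trunk with
# smooth (GELU) nonlinearities and dropout, a linear low-dimensional
# embedding layer, and six per-task linear heads with sigmoid outputs,
# trained on label-smoothed cross-entropy plus the pairwise rank loss with
# missing-label masking.

#' Joint model hyperparameter specification
#'
#' @param hidden integer vector of trunk layer widths.
#' @param embedding_dim width of the linear embedding layer feeding the
#'   per-task heads (and the representation used for transfer); default 32.
#' @param dropout dropout rate after each trunk layer, in [0, 1).
#' @param alpha label-smoothing factor in [0, 0.5).
#' @param epsilon rank-loss hinge margin; default 0.25.
#' @param lambda nonnegative rank-loss weight.
#' @param lr,weight_decay Adam learning rate and decoupled weight decay.
#' @param batch_size minibatch size.
#' @param max_epochs,patience epoch cap and early-stopping patience on
#'   validation loss.
#' @param includeEqualPairs literal rank-loss behaviour for equal-label
#'   pairs (see \code{\link{rankLoss}}).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return a \code{JointModelSpec}.
#' @export
jointModelSpec <- function(hidden = c(128, 64), embedding_dim = 32,
                           dropout = 0.1, alpha = 0.05, epsilon = 0.25,
                           lambda = 0.5, lr = 1e-3, weight_decay = 1e-4,
                           batch_size = 256, max_epochs = 60, patience = 8,
                           includeEqualPairs = TRUE, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, alpha >= 0, alpha < 0.5,
            epsilon >= 0, lambda >= 0, lr > 0, all(hidden >= 1),
            embedding_dim >= 1)
  structure(list(hidden = as.integer(hidden),
                 embedding_dim = as.integer(embedding_dim),
                 dropout = dropout, alpha = alpha, epsilon = epsilon,
                 lambda = lambda, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 includeEqualPairs = includeEqualPairs,
                 seed = as.integer(seed)),
            class = "JointModelSpec")
}

# smooth GELU-type gate via the fast sigmoid approximation x * sigma(1.702 x)
.gelu <- function(x) x / (1 + exp(-1.702 * x))
.geluGrad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s + 1.702 * x * s * (1 - s)
}

.initNet <- function(p, spec) {
  dims <- c(p, spec$hidden, spec$embedding_dim, 6L)
  W <- b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / fan_in)), dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims, n_hidden = length(spec$hidden))
}

# forward pass; masks: list of dropout masks per trunk layer or NULL
.forwardNet <- function(net, X, masks = NULL) {
  L <- length(net$W)
  nh <- net$n_hidden
  a <- X
  pre <- act <- vector("list", L)
  for (l in seq_len(nh)) {
    z <- a %*% net$W[[l]] + rep(net$b[[l]], each = nrow(a))
    h <- .gelu(z)
    if (!is.null(masks)) h <- h * masks[[l]]
    pre[[l]] <- z
    act[[l]] <- h
    a <- h
  }
  emb <- a %*% net$W[[nh + 1]] + rep(net$b[[nh + 1]], each = nrow(a))
  logits <- emb %*% net$W[[nh + 2]] + rep(net$b[[nh + 2]], each = nrow(emb))
  list(pre = pre, act = act, emb = emb, logits = logits,
       probs = .sigmoid(logits))
}

.backwardNet <- function(net, X, fw, Glogits, masks = NULL) {
  L <- length(net$W)
  nh <- net$n_hidden
  gW <- gb <- vector("list", L)
  delta <- Glogits
  # head layer
  gW[[L]] <- t(fw$emb) %*% delta
  gb[[L]] <- colSums(delta)
  delta <- delta %*% t(net$W[[L]])
  # embedding layer (linear)
  inp <- if (nh >= 1) fw$act[[nh]] else X
  gW[[L - 1]] <- t(inp) %*% delta
  gb[[L - 1]] <- colSums(delta)
  delta <- delta %*% t(net$W[[L - 1]])
  # trunk
  for (l in rev(seq_len(nh))) {
    if (!is.null(masks)) delta <- delta * masks[[l]]
    delta <- delta * .geluGrad(fw$pre[[l]])
    inp <- if (l > 1) fw$act[[l - 1]] else X
    gW[[l]] <- t(inp) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- delta %*% t(net$W[[l]])
  }
  list(W = gW, b = gb)
}

#' Train the multi-task joint diagnostic network
#'
#' Fits the preprocessing chain on the training split only, trains the
#' network with Adam on the combined label-smoothed cross-entropy and rank
#' loss (missing labels masked), early-stops on validation loss, and fixes
#' the per-task probability thresholds at the best validation F1 before any
#' test-set evaluation. Deterministic given \code{spec$seed} (at a fixed
#' BLAS thread count).
#'
#' @param cohort a \linkS4class{ProteoCohort}.
#' @param panel a \code{FeaturePanel} (or character vector of protein ids).
#' @param split list with character id vectors \code{train} and
#'   \code{validation} (one rotation of a \linkS4class{SplitPlan}).
#' @param spec a \code{\link{jointModelSpec}}.
#' @param knn_k imputer neighbourhood size for the preprocessing chain.
#' @param verbose print per-epoch losses.
#' @return a \code{TrainedJointModel}: fitted chain, weights, thresholds,
#'   panel and training history.
#' @export
trainJointModel <- function(cohort, panel, split, spec = jointModelSpec(),
                            knn_k = 10, verbose = FALSE) {
  proteins <- if (inherits(panel, "FeaturePanel")) panel$proteins else panel
  Xall <- abundance(cohort, participantsAsRows = TRUE)
  chain <- fitPreprocessChain(Xall[split$train, , drop = FALSE], proteins,
                              kind = "deep", knn_k = knn_k)
  Xtr <- applyPreprocessChain(chain, Xall[split$train, , drop = FALSE])
  Xva <- applyPreprocessChain(chain, Xall[split$validation, , drop = FALSE])
  Ytr <- labelMatrix(cohort)[split$train, , drop = FALSE]
  Yva <- labelMatrix(cohort)[split$validation, , drop = FALSE]

  fit <- .fitNet(Xtr, Ytr, Xva, Yva, spec, verbose = verbose)

  vp <- .forwardNet(fit$net, Xva)$probs
  colnames(vp) <- conditionNames()
  thresholds <- selectThresholds(vp, Yva)

  structure(list(net = fit$net, spec = spec, chain = chain,
                 panel = panel, proteins = proteins,
                 thresholds = thresholds, history = fit$history,
                 conditions = conditionNames()),
            class = "TrainedJointModel")
}

.fitNet <- function(Xtr, Ytr, Xva, Yva, spec, verbose = FALSE) {
  .withSeed(spec$seed, {
    net <- .initNet(ncol(Xtr), spec)
    L <- length(net$W)
    mW <- vW <- lapply(net$W, function(w) w * 0)
    mb <- vb <- lapply(net$b, function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
    step <- 0
    n <- nrow(Xtr)
    best <- Inf; bestNet <- net; wait <- 0
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      nb <- ceiling(n / spec$batch_size)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * spec$batch_size + 1):min(bi * spec$batch_size, n)]
        Xb <- Xtr[idx, , drop = FALSE]
        Yb <- Ytr[idx, , drop = FALSE]
        masks <- NULL
        if (spec$dropout > 0) {
          masks <- lapply(seq_len(net$n_hidden), function(l) {
            m <- matrix(stats::runif(length(idx) * net$dims[l + 1]) >=
                          spec$dropout, length(idx), net$dims[l + 1])
            m / (1 - spec$dropout)
          })
        }
        fw <- .forwardNet(net, Xb, masks)
        G <- .lossGradLogits(Yb, fw$probs, spec$alpha, spec$epsilon,
                             spec$lambda, spec$includeEqualPairs)
        gr <- .backwardNet(net, Xb, fw, G, masks)
        step <- step + 1
        lr_t <- spec$lr * sqrt(1 - beta2^step) / (1 - beta1^step)
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$W[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$W[[l]]^2
          net$W[[l]] <- net$W[[l]] - lr_t * mW[[l]] / (sqrt(vW[[l]]) + epsA) -
            spec$lr * spec$weight_decay * net$W[[l]]
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gr$b[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gr$b[[l]]^2
          net$b[[l]] <- net$b[[l]] - lr_t * mb[[l]] / (sqrt(vb[[l]]) + epsA)
        }
      }
      # monitor on a fixed training subsample to keep epoch overhead low
      sub <- seq_len(min(nrow(Xtr), 1000L))
      trLoss <- totalLoss(Ytr[sub, , drop = FALSE],
                          .forwardNet(net, Xtr[sub, , drop = FALSE])$probs,
                          spec$alpha, spec$epsilon, spec$lambda,
                          spec$includeEqualPairs)
      vaLoss <- totalLoss(Yva, .forwardNet(net, Xva)$probs, spec$alpha,
                          spec$epsilon, spec$lambda, spec$includeEqualPairs)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = trLoss,
                                           val_loss = vaLoss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, trLoss, vaLoss))
      if (vaLoss < best - 1e-6) {
        best <- vaLoss; bestNet <- net; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= spec$patience) break
      }
    }
    list(net = bestNet, history = history)
  })
}

#' Per-task probability thresholds by best validation F1
#'
#' Sweeps candidate thresholds at the midpoints of sorted unique validation
#' probabilities and picks the threshold with maximal F1; ties go to the
#' larger threshold. A task without validation positives (or without
#' negatives) falls back to 0.5 with a warning.
#'
#' @param probs validation participant-by-task probability matrix.
#' @param labels matching ternary label matrix.
#' @return named numeric vector of thresholds in (0, 1).
#' @export
selectThresholds <- function(probs, labels) {
  K <- ncol(probs)
  nm <- colnames(probs)
  if (is.null(nm)) nm <- colnames(labels)
  thr <- stats::setNames(rep(0.5, K), nm)
  for (i in seq_len(K)) {
    obs <- !is.na(labels[, i])
    p <- probs[obs, i]; y <- labels[obs, i]
    if (sum(y == 1) == 0 || sum(y == 0) == 0) {
      warning("no validation ", if (sum(y == 1) == 0) "positives" else "negatives",
              " for task ", nm[i], "; threshold defaults to 0.5")
      next
    }
    u <- sort(unique(p))
    if (length(u) < 2) next
    cand <- (u[-1] + u[-length(u)]) / 2
    f1 <- vapply(cand, function(ct) {
      tp <- sum(p >= ct & y == 1)
      fp <- sum(p >= ct & y == 0)
      fn <- sum(p < ct & y == 1)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    thr[i] <- max(cand[f1 == max(f1)])  # tie -> larger threshold
  }
  thr
}

#' Predict with a trained joint model
#'
#' Applies the model's fitted preprocessing chain and a deterministic
#' forward pass. Returns per-participant per-condition probabilities
#' (strictly inside (0,1)), binary calls at the stored thresholds, and the
#' embedding vectors (the pre-head layer activations).
#'
#' @param object a \code{TrainedJointModel}.
#' @param newdata a \linkS4class{ProteoCohort}, or a participants-by-ALL-
#'   proteins raw abundance matrix.
#' @param ids optional participant subset.
#' @param ... unused.
#' @return a \code{PredictionSet}: list with \code{probabilities},
#'   \code{calls}, \code{embeddings}, \code{thresholds}, \code{ids}.
#' @export
predict.TrainedJointModel <- function(object, newdata, ids = NULL, ...) {
  X <- if (is(newdata, "ProteoCohort"))
    abundance(newdata, participantsAsRows = TRUE) else as.matrix(newdata)
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  Xp <- applyPreprocessChain(object$chain, X)
  fw <- .forwardNet(object$net, Xp)
  probs <- .clipProb(fw$probs)
  dimnames(probs) <- list(rownames(X), object$conditions)
  calls <- sweep(probs, 2, object$thresholds, ">=") + 0L
  emb <- fw$emb
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("Z", seq_len(ncol(emb)))
  structure(list(probabilities = probs, calls = calls, embeddings = emb,
                 thresholds = object$thresholds, ids = rownames(X),
                 intervals = NULL),
            class = "PredictionSet")
}

#' @export
print.PredictionSet <- function(x, ...) {
  cat("PredictionSet:", nrow(x$probabilities), "participants x",
      ncol(x$probabilities), "conditions\n")
  cat("  calls positive:",
      paste(colnames(x$probabilities), colSums(x$calls), sep = "=",
            collapse = ", "), "\n")
  if (!is.null(x$intervals)) cat("  dropout intervals attached\n")
  invisible(x)
}

#' Embedding extraction
#'
#' The pre-head linear layer activations: a low-dimensional nonlinear
#' proteomic summary used for transfer and interpretation.
#'
#' @inheritParams predict.TrainedJointModel
#' @return participants-by-embedding matrix.
#' @export
extractEmbeddings <- function(object, newdata, ids = NULL) {
  predict(object, newdata, ids = ids)$embeddings
}

#' Stochastic-forward-pass prediction intervals
#'
#' Repeats prediction with dropout active at inference and summarizes the
#' per-probability empirical distribution as median and (2.5, 97.5)
#' percentile intervals; wide intervals flag unstable (overfit) predictions.
#' With dropout rate 0 the intervals have zero width.
#'
#' @inheritParams predict.TrainedJointModel
#' @param reps number of stochastic passes; default 100.
#' @param seed integer seed.
#' @return a \code{PredictionSet} whose \code{intervals} element holds
#'   arrays \code{low}, \code{median}, \code{high}.
#' @export
predictWithDropout <- function(object, newdata, ids = NULL, reps = 100,
                               seed = 1L) {
  base <- predict(object, newdata, ids = ids)
  X <- if (is(newdata, "ProteoCohort"))
    abundance(newdata, participantsAsRows = TRUE) else as.matrix(newdata)
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  Xp <- applyPreprocessChain(object$chain, X)
  rate <- object$spec$dropout
  net <- object$net
  .withSeed(seed, {
    draws <- array(NA_real_, c(nrow(Xp), 6, reps))
    for (r in seq_len(reps)) {
      masks <- lapply(seq_len(net$n_hidden), function(l) {
        m <- matrix(stats::runif(nrow(Xp) * net$dims[l + 1]) >= rate,
                    nrow(Xp), net$dims[l + 1])
        m / (1 - rate)
      })
      if (rate == 0) masks <- NULL
      draws[, , r] <- .forwardNet(net, Xp, masks)$probs
    }
    qs <- apply(draws, c(1, 2), stats::quantile, probs = c(0.025, 0.5, 0.975))
    base$intervals <- list(low = qs[1, , ], median = qs[2, , ],
                           high = qs[3, , ])
    base
  })
}

#' Normalized probability score
#'
#' Divides a probability by its task's decision threshold so the decision
#' boundary maps to 1; the report-facing form is \code{log(p / threshold)},
#' centered at zero.
#'
#' @param p probability (vector ok).
#' @param threshold the task's probability threshold.
#' @param log return the zero-centered logarithmic form.
#' @return numeric score, monotone in \code{p}.
#' @export
normalizeProbability <- function(p, threshold, log = FALSE) {
  s <- p / threshold
  if (log) base::log(s) else s
}

#' Random search over joint-model hyperparameters
#'
#' Seeded random search; each trial trains a model on the split and is
#' scored by validation balanced accuracy averaged over the six tasks (at
#' the trial's F1 thresholds). Returns the arg-max spec and the trial log.
#'
#' @inheritParams trainJointModel
#' @param budget number of trials; default 50.
#' @param space list of samplers: \code{width} choices, \code{depth}
#'   choices, and ranges for \code{dropout}, \code{alpha}, \code{lambda},
#'   \code{log10_lr}.
#' @param seed integer seed.
#' @param baseSpec spec supplying the non-searched fields.
#' @return list with \code{best} (a \code{JointModelSpec}), \code{score}
#'   and \code{trials} (data.frame log).
#' @export
tuneHyperparameters <- function(cohort, panel, split, budget = 50,
                                space = list(width = c(64, 128, 256, 512),
                                             depth = 1:3,
                                             dropout = c(0, 0.5),
                                             alpha = c(0, 0.2),
                                             lambda = c(0, 2),
                                             log10_lr = c(-4, -2)),
                                seed = 1L, baseSpec = jointModelSpec()) {
  budget <- .assertCount(budget, "budget", 1)
  Yva <- labelMatrix(cohort)[split$validation, , drop = FALSE]
  trials <- data.frame()
  best <- NULL; bestScore <- -Inf
  for (trial in seq_len(budget)) {
    sp <- .withSeed(.subSeed(seed, trial), {
      depth <- sample(space$depth, 1)
      widths <- sort(sample(space$width, depth, replace = TRUE),
                     decreasing = TRUE)
      sp <- baseSpec
      sp$hidden <- as.integer(widths)
      sp$dropout <- stats::runif(1, space$dropout[1], space$dropout[2])
      sp$alpha <- stats::runif(1, space$alpha[1], space$alpha[2])
      sp$lambda <- stats::runif(1, space$lambda[1], space$lambda[2])
      sp$lr <- 10^stats::runif(1, space$log10_lr[1], space$log10_lr[2])
      sp$seed <- .subSeed(seed, trial + budget)
      sp
    })
    model <- trainJointModel(cohort, panel, split, sp)
    vp <- predict(model, cohort, ids = split$validation)
    bca <- vapply(seq_len(6), function(i)
      balancedAccuracy(vp$calls[, i], Yva[, i]), numeric(1))
    score <- mean(bca, na.rm = TRUE)
    trials <- rbind(trials, data.frame(
      trial = trial, depth = length(sp$hidden),
      width1 = sp$hidden[1], dropout = sp$dropout, alpha = sp$alpha,
      lambda = sp$lambda, lr = sp$lr, val_bca = score))
    if (score > bestScore) { bestScore <- score; best <- sp }
  }
  list(best = best, score = bestScore, trials = trials)
}
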