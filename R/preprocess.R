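# Preprocessing transforms. All functions here take matrices in the
# machine-learning orientation (participants as rows, proteins as columns);
# every fitted transform stores the protein list it was fit on and refuses
# application to mismatched columns.

.checkProteins <- function(transform, X) {
  if (!identical(colnames(X), transform$proteins))
    stop("transform was fit on a different protein list", call. = FALSE)
}

#' Mask outlier abundance values
#'
#' Per protein, entries further than \code{z_cut} standard deviations from
#' that protein's mean (moments over its non-missing entries) are set
#' missing, in a single pass. This is the one dataset-wide step performed
#' before splitting, mirroring assay-level curation of aptamer panels.
#'
#' @param x a \linkS4class{ProteoCohort} or a participants-by-proteins matrix.
#' @param z_cut positive z cutoff; default 6.
#' @return object of the same type with outliers set to \code{NA}.
#' @export
maskOutliers <- function(x, z_cut = 6) {
  if (z_cut <= 0) stop("z_cut must be positive")
  if (is(x, "ProteoCohort")) {
    X <- abundance(x, participantsAsRows = TRUE)
    M <- maskOutliers(X, z_cut)
    SummarizedExperiment::assay(x, "abundance") <- t(M)
    return(x)
  }
  X <- x
  nobs <- colSums(!is.na(X))
  few <- nobs < 3
  if (any(few))
    warning(sum(few), " protein(s) with < 3 non-missing values left untouched")
  mu <- colMeans(X, na.rm = TRUE)
  sd_ <- apply(X, 2, stats::sd, na.rm = TRUE)
  Z <- abs(sweep(X, 2, mu)) > z_cut * rep(sd_, each = nrow(X))
  Z[, few] <- FALSE
  X[which(Z & !is.na(X))] <- NA_real_
  X
}

#' Normalize each participant by their average protein level
#'
#' Divides each row by that participant's mean over non-missing proteins,
#' removing overall per-sample intensity differences. Missing stays missing.
#'
#' @param X participants-by-proteins matrix.
#' @return normalized matrix with non-missing row means equal to 1.
#' @export
normalizeAverageLevel <- function(X) {
  rm_ <- rowMeans(X, na.rm = TRUE)
  bad <- !is.finite(rm_)
  if (any(bad))
    stop("all abundance values missing for participant(s): ",
         paste(utils::head(rownames(X)[bad], 5), collapse = ", "))
  X / rm_
}

#' Nearest-neighbour abundance imputer
#'
#' \code{fitKnnImputer} stores the training matrix; \code{applyTransform}
#' fills each missing cell with the mean of that protein over the \code{k}
#' nearest training participants. Distance is the mean squared difference
#' over mutually observed proteins; donors are restricted to training rows
#' with the protein observed (fewer than \code{k} donors uses all of them).
#' Observed cells are untouched, so imputation is idempotent.
#'
#' @param trainX training participants-by-proteins matrix.
#' @param k neighbourhood size; default 10.
#' @return a \code{FittedTransform} of kind \code{knn_imputer}.
#' @export
fitKnnImputer <- function(trainX, k = 10) {
  k <- .assertCount(k, "k", 1)
  if (k > nrow(trainX)) stop("k exceeds the number of training participants")
  allMissing <- colSums(!is.na(trainX)) == 0
  if (any(allMissing))
    stop("cannot fit imputer: protein(s) entirely missing in training: ",
         paste(utils::head(colnames(trainX)[allMissing], 5), collapse = ", "))
  structure(list(kind = "knn_imputer", k = k, reference = trainX,
                 proteins = colnames(trainX)),
            class = c("knn_imputer", "FittedTransform"))
}

# masked mean-squared-difference distances between rows of A and rows of B
.maskedDist2 <- function(A, B) {
  Wa <- !is.na(A); Wb <- !is.na(B)
  A0 <- A; A0[!Wa] <- 0
  B0 <- B; B0[!Wb] <- 0
  cnt <- Wa %*% t(Wb)
  d2 <- (A0^2) %*% t(Wb) + Wa %*% t(B0^2) - 2 * A0 %*% t(B0)
  d2 <- d2 / cnt
  d2[cnt == 0] <- Inf
  d2
}

#' @export
applyTransform <- function(transform, X, ...) UseMethod("applyTransform")

#' Apply a fitted preprocessing transform
#'
#' @param transform a \code{FittedTransform}.
#' @param X participants-by-proteins matrix with the same protein list the
#'   transform was fit on.
#' @param ... unused.
#' @return transformed matrix (the input is never mutated).
#' @rdname applyTransform
#' @export
applyTransform.knn_imputer <- function(transform, X, ...) {
  .checkProteins(transform, X)
  if (!anyNA(X)) return(X)
  ref <- transform$reference
  k <- transform$k
  need <- which(rowSums(is.na(X)) > 0)
  D <- .maskedDist2(X[need, , drop = FALSE], ref)
  out <- X
  for (ii in seq_along(need)) {
    r <- need[ii]
    ord <- order(D[ii, ])
    missCols <- which(is.na(X[r, ]))
    for (j in missCols) {
      donors <- ord[!is.na(ref[ord, j])]
      use <- donors[seq_len(min(k, length(donors)))]
      out[r, j] <- mean(ref[use, j])
    }
  }
  out
}

#' Gaussian rank normalizer
#'
#' \code{fitGaussianRank} maps each training column to normal scores
#' \eqn{\Phi^{-1}((r - 0.5)/n)} (average ranks for ties). Held-out values
#' are mapped by linear interpolation of the training empirical quantile
#' function and clipped to \eqn{[\Phi^{-1}(0.5/n), \Phi^{-1}((n-0.5)/n)]},
#' preserving monotone order within each column. Requires complete
#' (post-imputation) input. A constant training column maps everything to 0
#' with a warning.
#'
#' @param trainX complete training participants-by-proteins matrix.
#' @return a \code{FittedTransform} of kind \code{gaussian_rank}.
#' @export
fitGaussianRank <- function(trainX) {
  if (anyNA(trainX)) stop("gaussian rank normalizer requires complete input")
  n <- nrow(trainX)
  maps <- vector("list", ncol(trainX))
  const <- logical(ncol(trainX))
  for (j in seq_len(ncol(trainX))) {
    v <- trainX[, j]
    scores <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
    u <- sort(unique(v))
    if (length(u) == 1) {
      const[j] <- TRUE
      maps[[j]] <- list(x = u, y = 0)
    } else {
      s <- vapply(split(scores, match(v, u)), mean, numeric(1))
      maps[[j]] <- list(x = u, y = unname(s))
    }
  }
  if (any(const))
    warning(sum(const), " constant training column(s) map to 0")
  structure(list(kind = "gaussian_rank", n = n, maps = maps, const = const,
                 proteins = colnames(trainX)),
            class = c("gaussian_rank", "FittedTransform"))
}

#' @rdname applyTransform
#' @export
applyTransform.gaussian_rank <- function(transform, X, ...) {
  .checkProteins(transform, X)
  if (anyNA(X)) stop("gaussian rank normalizer requires complete input")
  out <- X
  lo <- stats::qnorm(0.5 / transform$n)
  hi <- stats::qnorm((transform$n - 0.5) / transform$n)
  for (j in seq_len(ncol(X))) {
    m <- transform$maps[[j]]
    if (transform$const[j]) {
      out[, j] <- 0
    } else {
      out[, j] <- pmin(pmax(
        stats::approx(m$x, m$y, xout = X[, j], rule = 2)$y, lo), hi)
    }
  }
  out
}

#' Column z-scoring with training statistics
#'
#' Used for the tree/forest model path. A zero-sd training column is scaled
#' to 0 with a warning. Missing entries stay missing (tree learners handle
#' them natively).
#'
#' @param trainX training participants-by-proteins matrix.
#' @return a \code{FittedTransform} of kind \code{zscore}.
#' @export
fitZScore <- function(trainX) {
  mu <- colMeans(trainX, na.rm = TRUE)
  sd_ <- apply(trainX, 2, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sd_) | sd_ == 0
  if (any(zero)) {
    warning(sum(zero), " zero-sd column(s) scaled to 0")
    sd_[zero] <- 1
    mu[zero] <- colMeans(trainX, na.rm = TRUE)[zero]
  }
  structure(list(kind = "zscore", mean = mu, sd = sd_, zero = zero,
                 proteins = colnames(trainX)),
            class = c("zscore", "FittedTransform"))
}

#' @rdname applyTransform
#' @export
applyTransform.zscore <- function(transform, X, ...) {
  .checkProteins(transform, X)
  Z <- sweep(sweep(X, 2, transform$mean), 2, transform$sd, "/")
  if (any(transform$zero)) Z[, transform$zero] <- 0
  Z
}

#' Fit the full preprocessing chain on a training split
#'
#' The deep-network path applies, in this fixed order: per-participant
#' average-level normalization (computed over \emph{all} proteins), panel
#' subsetting, nearest-neighbour imputation, Gaussian rank normalization.
#' The tree path applies panel subsetting then training-statistics
#' z-scoring. Order is enforced by the chain object itself; no transform
#' uses held-out rows in its fit statistics.
#'
#' @param trainX full training participants-by-ALL-proteins matrix (raw
#'   scale, missing allowed).
#' @param panel character vector of panel protein ids.
#' @param kind \code{"deep"} or \code{"tree"}.
#' @param knn_k imputer neighbourhood size (deep path).
#' @return a \code{PreprocessChain}.
#' @export
fitPreprocessChain <- function(trainX, panel, kind = c("deep", "tree"),
                               knn_k = 10) {
  kind <- match.arg(kind)
  stopifnot(all(panel %in% colnames(trainX)))
  if (kind == "deep") {
    Xn <- normalizeAverageLevel(trainX)[, panel, drop = FALSE]
    imp <- fitKnnImputer(Xn, k = knn_k)
    Xi <- applyTransform(imp, Xn)
    gr <- fitGaussianRank(Xi)
    transforms <- list(imputer = imp, gaussian_rank = gr)
  } else {
    transforms <- list(zscore = fitZScore(trainX[, panel, drop = FALSE]))
  }
  structure(list(kind = kind, panel = panel, transforms = transforms),
            class = "PreprocessChain")
}

#' Apply a fitted preprocessing chain
#'
#' @param chain a \code{PreprocessChain}.
#' @param X full participants-by-ALL-proteins matrix on the raw scale.
#' @return participants-by-panel matrix ready for the model.
#' @export
applyPreprocessChain <- function(chain, X) {
  stopifnot(inherits(chain, "PreprocessChain"))
  if (!all(chain$panel %in% colnames(X)))
    stop("input lacks panel proteins")
  if (chain$kind == "deep") {
    Xn <- normalizeAverageLevel(X)[, chain$panel, drop = FALSE]
    Xi <- applyTransform(chain$transforms$imputer, Xn)
    applyTransform(chain$transforms$gaussian_rank, Xi)
  } else {
    applyTransform(chain$transforms$zscore, X[, chain$panel, drop = FALSE])
  }
}
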