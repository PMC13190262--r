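# Training losses for the multi-task head. Labels are participant-by-6
# ternary matrices (1/0/NA); probabilities are clipped before logs.

#' Label-smoothed binary cross-entropy over observed labels
#'
#' \deqn{-\frac{1}{M}\sum_{(k,i)\ \mathrm{observed}}
#'   \left[(y_{k,i}(1-\alpha)+\alpha/2)\log\hat y_{k,i} +
#'   ((1-y_{k,i})(1-\alpha)+\alpha/2)\log(1-\hat y_{k,i})\right]}
#' where \eqn{M} is the number of observed label entries, so the loss scale
#' is comparable across label-missingness patterns. \eqn{\alpha = 0} reduces
#' exactly to unsmoothed binary cross-entropy.
#'
#' @param y participant-by-task label matrix (1/0/\code{NA}).
#' @param yhat matching matrix of predicted probabilities.
#' @param alpha label-smoothing factor in [0, 0.5).
#' @return scalar loss (finite).
#' @export
bceSmoothed <- function(y, yhat, alpha = 0) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  obs <- !is.na(y)
  M <- sum(obs)
  if (M == 0) stop("no observed labels")
  yh <- .clipProb(yhat)
  t_ <- y * (1 - alpha) + alpha / 2
  terms <- t_ * log(yh) + (1 - t_) * log(1 - yh)
  -sum(terms[obs]) / M
}

#' Pairwise rank loss across conditions
#'
#' Mean over participants of the hinge penalties over all condition pairs
#' \eqn{i < j} with both labels observed:
#' \deqn{\max\left[0, (\hat y_{k,i}-\hat y_{k,j})(y_{k,j}-y_{k,i}) +
#'   \varepsilon\right]}
#' The formula is kept literal: a pair with equal labels contributes exactly
#' \eqn{\varepsilon} and carries zero gradient; a discordant pair whose
#' probability gap already beats the margin contributes 0. The mean runs
#' over participants with at least one observed pair, so adding a
#' participant with all labels missing leaves the loss unchanged.
#'
#' @inheritParams bceSmoothed
#' @param epsilon hinge margin; default 0.25.
#' @param includeEqualPairs keep the constant \eqn{\varepsilon} contribution
#'   of equal-label pairs (the literal formula); set \code{FALSE} to drop
#'   such pairs.
#' @return scalar loss.
#' @export
rankLoss <- function(y, yhat, epsilon = 0.25, includeEqualPairs = TRUE) {
  y <- as.matrix(y); yhat <- as.matrix(yhat)
  stopifnot(epsilon >= 0)
  K <- ncol(y)
  nObs <- rowSums(!is.na(y))
  N <- sum(nObs >= 2)
  if (N == 0) return(0)
  total <- 0
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      obs <- !is.na(y[, i]) & !is.na(y[, j])
      if (!any(obs)) next
      s <- y[obs, j] - y[obs, i]
      if (!includeEqualPairs) {
        keep <- s != 0
        s <- s[keep]
        h <- pmax(0, (yhat[obs, i][keep] - yhat[obs, j][keep]) * s + epsilon)
      } else {
        h <- pmax(0, (yhat[obs, i] - yhat[obs, j]) * s + epsilon)
      }
      total <- total + sum(h)
    }
  }
  total / N
}

#' Combined training loss
#'
#' \code{bceSmoothed + lambda * rankLoss}; \code{lambda = 0} reduces to the
#' smoothed cross-entropy alone.
#'
#' @inheritParams rankLoss
#' @param alpha label-smoothing factor.
#' @param lambda nonnegative rank-loss weight.
#' @return scalar loss.
#' @export
totalLoss <- function(y, yhat, alpha = 0, epsilon = 0.25, lambda = 0,
                      includeEqualPairs = TRUE) {
  stopifnot(lambda >= 0)
  b <- bceSmoothed(y, yhat, alpha)
  if (lambda == 0) return(b)
  b + lambda * rankLoss(y, yhat, epsilon, includeEqualPairs)
}

# gradient of totalLoss wrt the head logits (used by the trainer)
.lossGradLogits <- function(y, yhat, alpha, epsilon, lambda,
                            includeEqualPairs = TRUE) {
  obs <- !is.na(y)
  M <- sum(obs)
  t_ <- y * (1 - alpha) + alpha / 2
  G <- (yhat - t_) / M           # d BCE / d logit
  G[!obs] <- 0
  if (lambda > 0) {
    K <- ncol(y)
    N <- max(1L, sum(rowSums(obs) >= 2))
    Gp <- matrix(0, nrow(y), K)  # d rank / d prob
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        ok <- obs[, i] & obs[, j]
        s <- y[, j] - y[, i]
        act <- ok & !is.na(s) & s != 0 &
          ((yhat[, i] - yhat[, j]) * s + epsilon > 0)
        if (!any(act)) next
        Gp[act, i] <- Gp[act, i] + s[act] / N
        Gp[act, j] <- Gp[act, j] - s[act] / N
      }
    }
    G <- G + lambda * Gp * yhat * (1 - yhat)
  }
  G
}
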