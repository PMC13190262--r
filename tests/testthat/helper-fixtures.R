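# shared fixture builders and independent oracles

tinyCohort <- function(n = 250, p = 60, sites = 3, planted = 6, seed = 7,
                       ...) {
  simulateCohort(simulationConfig(
    n_participants = n, n_proteins = p, n_sites = sites,
    planted_per_condition = min(planted, p %/% 6), seed = seed, ...))
}

# brute-force triple-loop total loss, independent of the vectorized path
loopTotalLoss <- function(y, yhat, alpha, epsilon, lambda) {
  N <- nrow(y)
  bce_sum <- 0; m <- 0
  for (k in seq_len(N)) for (i in seq_len(ncol(y))) {
    if (is.na(y[k, i])) next
    m <- m + 1
    ykt <- y[k, i] * (1 - alpha) + alpha / 2
    ph <- min(max(yhat[k, i], 1e-7), 1 - 1e-7)
    bce_sum <- bce_sum + ykt * log(ph) + (1 - ykt) * log(1 - ph)
  }
  rl <- 0; nPaired <- 0
  for (k in seq_len(N)) {
    had <- FALSE
    for (i in seq_len(ncol(y) - 1)) for (j in (i + 1):ncol(y)) {
      if (is.na(y[k, i]) || is.na(y[k, j])) next
      had <- TRUE
      rl <- rl + max(0, (yhat[k, i] - yhat[k, j]) * (y[k, j] - y[k, i]) +
                       epsilon)
    }
    if (had) nPaired <- nPaired + 1
  }
  -bce_sum / m + if (nPaired > 0) lambda * rl / nPaired else 0
}

# brute-force pairwise AUC
pairAuc <- function(p, y) {
  obs <- !is.na(y); p <- p[obs]; y <- y[obs]
  pos <- p[y == 1]; neg <- p[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

randomLossInstance <- function(n, seed) {
  set.seed(seed)
  y <- matrix(sample(c(0L, 1L, NA), n * 6, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3)), n, 6)
  if (all(is.na(y))) y[1, 1] <- 1L
  yhat <- matrix(runif(n * 6, 0.01, 0.99), n, 6)
  list(y = y, yhat = yhat)
}

adjustedRand <- function(a, b) {
  # Hubert-Arabie adjusted Rand index
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expec <- ai * bj / choose(n, 2)
  (sumij - expec) / ((ai + bj) / 2 - expec)
}
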