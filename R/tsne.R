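# Exact t-distributed stochastic neighbour embedding, dense O(n^2) variant.
# Input dimensionality here is tiny (6 probability axes), and map sizes are
# desk scale, so the exact gradient is both simplest and fast enough.

.tsnePerplexityP <- function(D2, perplexity, tol = 1e-5, max_tries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (tr in seq_len(max_tries)) {
      Pi <- exp(-Di * beta)
      sumPi <- sum(Pi)
      if (sumPi == 0) { Pi <- rep(1 / length(Di), length(Di)); break }
      H <- log(sumPi) + beta * sum(Di * Pi) / sumPi
      Pi <- Pi / sumPi
      if (abs(H - logU) < tol) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

.tsne <- function(X, perplexity = 30, max_iter = 500, seed = 1L,
                  momentum = 0.5, final_momentum = 0.8, mom_switch = 250,
                  exaggeration = 12, stop_lying = 100, eta = 200) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3)
    perplexity <- max(2, floor((n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsnePerplexityP(D2, perplexity)
  .withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    Pex <- P * exaggeration
    for (iter in seq_len(max_iter)) {
      Pi <- if (iter <= stop_lying) Pex else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), .Machine$double.xmin)
      L <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (iter < mom_switch) momentum else final_momentum
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
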