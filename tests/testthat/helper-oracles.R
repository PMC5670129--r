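# Independent oracle implementations used to check the package's own
# algorithms. These deliberately use different algorithms/code paths.

# NIPALS PLS1 scores (unit-normalized). Univariate response.
nipalsPlsScores <- function(X, y, k) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  TT <- matrix(0, nrow(X), k)
  for (a in seq_len(k)) {
    w <- crossprod(Xc, yc)
    w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w)
    p <- crossprod(Xc, t) / sum(t^2)
    q <- sum(yc * t) / sum(t^2)
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - q * t
    TT[, a] <- t
  }
  sweep(TT, 2, sqrt(colSums(TT^2)), "/")
}

# Align column signs of A to B, then return max abs difference.
maxScoreDiff <- function(A, B) {
  for (j in seq_len(ncol(A))) {
    if (sum(A[, j] * B[, j]) < 0) A[, j] <- -A[, j]
  }
  max(abs(A - B))
}

# Biased scatter matrices, recomputed independently of the package.
oracleScatter <- function(X, y) {
  n <- nrow(X)
  mu <- colMeans(X)
  Sb <- matrix(0, ncol(X), ncol(X))
  Sw <- matrix(0, ncol(X), ncol(X))
  for (cl in unique(y)) {
    idx <- y == cl
    mc <- colMeans(X[idx, , drop = FALSE])
    Sb <- Sb + (sum(idx) / n) * tcrossprod(mc - mu)
    Xc <- sweep(X[idx, , drop = FALSE], 2, mc)
    Sw <- Sw + crossprod(Xc) / n
  }
  list(Sb = Sb, Sw = Sw)
}

# Best value of w' (Sb - Sw) w over nRand random unit vectors.
bruteForceMmcMax <- function(X, y, nRand = 1e5, seed = 42) {
  sc <- oracleScatter(X, y)
  M <- sc$Sb - sc$Sw
  set.seed(seed)
  R <- matrix(rnorm(nRand * ncol(X)), nRand, ncol(X))
  R <- R / sqrt(rowSums(R^2))
  max(rowSums((R %*% M) * R))
}

# Direct Fisher LDA axes (no PCA step); requires nonsingular Sw.
directLdaAxes <- function(X, y) {
  sc <- oracleScatter(X, y)
  eg <- eigen(solve(sc$Sw) %*% sc$Sb)
  k <- length(unique(y)) - 1L
  W <- Re(eg$vectors[, seq_len(k), drop = FALSE])
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

# Exhaustive Otsu split search over all histogram break candidates.
bruteForceOtsu <- function(x, nbins = 256L) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  best <- -Inf
  bestT <- h$breaks[2]
  total <- sum(h$counts)
  for (s in seq_len(nbins - 1L)) {
    w0 <- sum(h$counts[1:s]) / total
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h$counts[1:s] * h$mids[1:s]) / sum(h$counts[1:s])
    mu1 <- sum(h$counts[(s + 1):nbins] * h$mids[(s + 1):nbins]) /
      sum(h$counts[(s + 1):nbins])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) {
      best <- v
      bestT <- h$breaks[s + 1L]
    }
  }
  bestT
}

# Naive local-maximum peak count on a smoothed trace.
naiveLocalMaxCount <- function(sm, eps = 1e-9) {
  n <- length(sm)
  sum(sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n] &
      sm[2:(n - 1)] > eps)
}
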