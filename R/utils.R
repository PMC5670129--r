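# Internal helpers shared across modules.

# Derive a 32-bit safe child seed from a base seed and one or more indices.
.childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i * 7919 + 1) %% 2147483647
  as.integer(s)
}

# Run expr with a local RNG state seeded at `seed`; global stream untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: samples of each class are shuffled and dealt
# round-robin into folds. The effective fold count is min(k, smallest class),
# mirroring the rule of adjusting CV rounds to the minimum class size.
.stratifiedFolds <- function(labels, k, seed, warnShrink = TRUE) {
  labels <- as.character(labels)
  sizes <- table(labels)
  kEff <- min(k, min(sizes))
  if (kEff < k && warnShrink) {
    warning(sprintf(
      "fold count reduced from %d to %d to match the smallest class (n = %d)",
      k, kEff, min(sizes)), call. = FALSE)
  }
  if (kEff < 2L) stop("smallest class has fewer than 2 samples", call. = FALSE)
  folds <- integer(length(labels))
  .withSeed(seed, {
    for (cl in names(sizes)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(kEff), length(idx))
    }
  })
  folds
}

# Per-column sign convention: the element of largest magnitude is positive,
# so projections are reproducible across linear-algebra backends.
.signFix <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

# Biased (divide-by-n) between- and within-class scatter matrices.
.scatterPair <- function(X, y) {
  y <- as.character(y)
  n <- nrow(X)
  mu <- colMeans(X)
  d <- ncol(X)
  Sb <- matrix(0, d, d)
  Sw <- matrix(0, d, d)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    mc <- colMeans(X[idx, , drop = FALSE])
    dc <- mc - mu
    Sb <- Sb + (length(idx) / n) * tcrossprod(dc)
    Xc <- sweep(X[idx, , drop = FALSE], 2, mc)
    Sw <- Sw + crossprod(Xc) / n
  }
  list(Sb = (Sb + t(Sb)) / 2, Sw = (Sw + t(Sw)) / 2,
       mean = mu, classes = unique(y))
}

# Binary logistic fit on a small score matrix. Unpenalized IRLS first.
# Under perfect separation (common at well-separated nodes) the MLE diverges
# and glm.fit stops at the iteration cap with finite, deterministic
# coefficients pointing along the separating direction; those are kept.
# Only collinear designs (NA coefficients) fall back to a small ridge.
.fitLogistic <- function(S, y, ridge = 1e-8) {
  X <- cbind(1, S)
  fit <- suppressWarnings(stats::glm.fit(X, y,
    family = stats::binomial(), control = list(maxit = 25)))
  beta <- fit$coefficients
  if (any(is.na(beta)) || any(!is.finite(beta))) {
    beta <- .ridgeLogistic(X, y, lambda = ridge)
  }
  unname(beta)
}

.ridgeLogistic <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  P <- diag(lambda, p)
  P[1, 1] <- 0  # intercept unpenalized
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X * w, X) + P
    betaNew <- tryCatch(drop(solve(H, crossprod(X * w, z))),
                        error = function(e) beta)
    if (max(abs(betaNew - beta)) < tol) {
      beta <- betaNew
      break
    }
    beta <- betaNew
  }
  beta
}

.predictLogistic <- function(beta, S) {
  stats::plogis(drop(cbind(1, S) %*% beta))
}

.assertMatrix <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("input matrix contains missing values", call. = FALSE)
  X
}
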