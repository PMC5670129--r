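#' @include AllClasses.R AllGenerics.R utils.R
NULL

.oneHot <- function(y) {
  y <- as.character(y)
  cls <- unique(y)
  Y <- matrix(0, length(y), length(cls), dimnames = list(NULL, cls))
  Y[cbind(seq_along(y), match(y, cls))] <- 1
  Y
}

#' Fit a SIMPLS partial least squares model
#'
#' Direct-deflation PLS (de Jong's SIMPLS): components maximize covariance
#' with class membership without considering within-class variance. Score
#' vectors are mutually orthogonal and unit norm; results are deterministic
#' up to column sign, which is fixed by making each weight column's
#' largest-magnitude element positive.
#'
#' @param X numeric matrix, samples x features (centered internally).
#' @param y class labels (factor/character), or a 0/1 one-hot indicator
#'   matrix.
#' @param k number of components; truncated with a warning when it exceeds
#'   the rank of the centered predictor matrix.
#' @return a [ReducedModel-class] with weights `W` (features x k); training
#'   scores are in `extra$scores`.
#' @export
fitSimpls <- function(X, y, k) {
  X <- .assertMatrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  if (k < 1) stop("k must be >= 1")
  Y <- if (is.matrix(y)) y else .oneHot(y)
  cls <- colnames(Y)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  if (all(abs(Xc) < 1e-12)) stop("zero-variance input")
  Yc <- sweep(Y, 2, colMeans(Y))
  d <- ncol(Xc)
  S <- crossprod(Xc, Yc)
  R <- matrix(0, d, k)
  TT <- matrix(0, n, k)
  P <- matrix(0, d, k)
  V <- matrix(0, d, k)
  a <- 0L
  for (j in seq_len(k)) {
    sv <- svd(S, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12) break
    r <- S %*% sv$v[, 1]
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt
    r <- r / nt
    p <- crossprod(Xc, t)
    v <- p
    if (a > 0) {
      Va <- V[, seq_len(a), drop = FALSE]
      v <- v - Va %*% crossprod(Va, p)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v %*% crossprod(v, S)
    a <- a + 1L
    R[, a] <- r; TT[, a] <- t; P[, a] <- p; V[, a] <- v
  }
  if (a == 0L) stop("zero-variance input")
  if (a < k) {
    warning(sprintf("k truncated from %d to %d (rank of centered X/Y)", k, a),
            call. = FALSE)
  }
  R <- R[, seq_len(a), drop = FALSE]
  TT <- TT[, seq_len(a), drop = FALSE]
  flip <- vapply(seq_len(a), function(j) {
    i <- which.max(abs(R[, j])); R[i, j] < 0
  }, TRUE)
  R[, flip] <- -R[, flip, drop = FALSE]
  # training scores via the same operation scoreSamples uses, so rescoring
  # the training matrix reproduces them exactly
  TT <- Xc %*% R
  new("ReducedModel", method = "PLS", W = R, center = center,
      k = a, classes = cls, intercepts = numeric(0),
      extra = list(scores = TT, loadings = P[, seq_len(a), drop = FALSE]))
}

#' Fit maximum margin criterion LDA
#'
#' Projects onto the top-k eigenvectors of the difference `S_b - S_w` of
#' biased between- and within-class scatter matrices: directions maximize
#' between-class variance while minimizing within-class variance, without
#' inverting `S_w` (so a single sample per class is allowed). Eigenvectors
#' are orthonormal and returned with eigenvalues in non-increasing order.
#'
#' @param X samples x features matrix.
#' @param y class labels; at least 2 classes.
#' @param k number of components (default: number of classes - 1).
#' @return a [ReducedModel-class]; eigenvalues in `extra$values`.
#' @export
fitMmcLda <- function(X, y, k = NULL) {
  X <- .assertMatrix(X)
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) < 2) stop("need at least 2 classes")
  if (is.null(k)) k <- length(cls) - 1L
  sc <- .scatterPair(X, y)
  eg <- eigen(sc$Sb - sc$Sw, symmetric = TRUE)
  k <- min(k, ncol(X))
  W <- .signFix(eg$vectors[, seq_len(k), drop = FALSE])
  new("ReducedModel", method = "MMC-LDA", W = W, center = sc$mean,
      k = as.integer(k), classes = cls, intercepts = numeric(0),
      extra = list(values = eg$values[seq_len(k)]))
}

# Generalized eigenproblem Sb w = lambda Sw w via Cholesky whitening of Sw
# (with a tiny ridge if Sw is numerically singular).
.fisherAxes <- function(Sb, Sw, k) {
  d <- ncol(Sw)
  ridge <- 1e-10 * (sum(diag(Sw)) / d + 1e-30)
  Rch <- tryCatch(chol(Sw), error = function(e) chol(Sw + diag(ridge * 1e4, d)))
  Ri <- backsolve(Rch, diag(d))
  M <- t(Ri) %*% Sb %*% Ri
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Ri %*% eg$vectors[, seq_len(k), drop = FALSE]
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  list(W = W, values = eg$values[seq_len(k)])
}

#' Fit Fisherfaces PCA-LDA
#'
#' Fisher discriminant analysis preceded by a PCA projection retaining
#' `min(n - c, d)` components, which keeps the within-class scatter
#' nonsingular when features outnumber samples (the classic small-sample-size
#' evasion). The LDA step then maximizes the ratio of between- to
#' within-class variation; the returned composite projection has `c - 1`
#' axes.
#'
#' @param X samples x features matrix.
#' @param y class labels; at least 2 classes and `n > c` samples.
#' @return a [ReducedModel-class] with `k = c - 1`.
#' @export
fitPcaLda <- function(X, y) {
  X <- .assertMatrix(X)
  y <- as.character(y)
  cls <- unique(y)
  c <- length(cls)
  if (c < 2) stop("need at least 2 classes")
  n <- nrow(X)
  if (n <= c) stop("insufficient samples for Fisherfaces (need n > c)")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nv = min(n - 1L, ncol(X)))
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  q <- min(n - c, ncol(X), rank)
  if (q < 1) stop("zero-variance input")
  Wp <- sv$v[, seq_len(q), drop = FALSE]
  Z <- Xc %*% Wp
  sc <- .scatterPair(Z, y)
  k <- c - 1L
  fa <- .fisherAxes(sc$Sb, sc$Sw, min(k, q))
  W <- Wp %*% fa$W
  W <- .signFix(sweep(W, 2, sqrt(colSums(W^2)), "/"))
  new("ReducedModel", method = "PCA-LDA", W = W, center = center,
      k = ncol(W), classes = cls, intercepts = numeric(0),
      extra = list(values = fa$values, pcaRank = q))
}

#' Fit one-vs-all linear support vector machines
#'
#' One linear SVM per class (that class against the rest), maximizing the
#' margin of separation. The stored model keeps only the explicit hyperplane
#' normal and offset per class, so scoring is a plain affine map of the
#' centered data and the model serializes like the projection methods.
#'
#' @param X samples x features matrix.
#' @param y class labels; at least 2 classes.
#' @param C regularization (cost) parameter, default 1.
#' @return a [ReducedModel-class]; `W` holds hyperplane normals (features x
#'   classes) and `intercepts` the matching offsets, giving signed decision
#'   values per class.
#' @export
fitLinearSvm <- function(X, y, C = 1) {
  X <- .assertMatrix(X)
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) < 2) stop("need at least 2 classes")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  W <- matrix(0, ncol(X), length(cls), dimnames = list(NULL, cls))
  b <- numeric(length(cls))
  for (j in seq_along(cls)) {
    yj <- factor(ifelse(y == cls[j], "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(Xc, yj, kernel = "linear", cost = C, scale = FALSE)
    w <- drop(crossprod(fit$SV, fit$coefs))
    bj <- -fit$rho
    # libsvm orients decision values toward the first training instance's
    # class; flip so positive always means this one-vs-all target class
    if (fit$labels[1] != which(fit$levels == "pos")) {
      w <- -w
      bj <- -bj
    }
    W[, j] <- w
    b[j] <- bj
  }
  new("ReducedModel", method = "SVM", W = W, center = center,
      k = as.integer(length(cls)), classes = cls, intercepts = b,
      extra = list(cost = C))
}

#' @rdname scoreSamples
#' @export
setMethod("scoreSamples", "ReducedModel", function(object, X) {
  X <- .assertMatrix(X)
  if (ncol(X) != length(object@center)) {
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 length(object@center), ncol(X)))
  }
  Xc <- sweep(X, 2, object@center)
  S <- Xc %*% object@W
  if (object@method == "SVM") {
    S <- sweep(S, 2, object@intercepts, "+")
  }
  S
})

setMethod("show", "ReducedModel", function(object) {
  cat(sprintf("ReducedModel(%s): %d features -> %d components, %d classes\n",
              object@method, nrow(object@W), object@k,
              length(object@classes)))
})
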