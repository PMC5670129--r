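test_that("SIMPLS scores match an independent NIPALS PLS oracle", {
  for (i in 1:20) {
    set.seed(i)
    X <- matrix(rnorm(200), 20, 10)
    y <- rep(c("a", "b"), each = 10)
    m <- fitSimpls(X, y, k = 2)
    TT <- m@extra$scores
    # score orthogonality
    G <- crossprod(TT)
    expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-8)
    # equality with NIPALS up to per-component sign
    TN <- nipalsPlsScores(X, as.numeric(y == "a"), 2)
    expect_lt(maxScoreDiff(TT, TN), 1e-8)
  }
})

test_that("SIMPLS handles rank deficiency and degenerate input", {
  set.seed(5)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c("a", "b"), 5)
  expect_warning(m <- fitSimpls(X, y, k = 8), "truncated")
  expect_lte(m@k, 4L)
  expect_error(fitSimpls(matrix(1, 10, 3), y, 2), "zero-variance")

  # a zero-variance column changes nothing on the remaining dimensions
  Xz <- cbind(X, 5)
  mz <- fitSimpls(Xz, y, k = 2)
  m2 <- fitSimpls(X, y, k = 2)
  expect_equal(mz@extra$scores, m2@extra$scores, tolerance = 1e-10)

  # two 1-D classes at -5 / +5: first score orders the classes perfectly
  X1 <- matrix(c(rnorm(10, -5, .1), rnorm(10, 5, .1)), ncol = 1)
  y1 <- rep(c("lo", "hi"), each = 10)
  m1 <- fitSimpls(X1, y1, k = 1)
  s <- m1@extra$scores[, 1]
  expect_true(max(s[1:10]) < min(s[11:20]) || min(s[1:10]) > max(s[11:20]))
  nm <- fitNode(X1, y1, "PLS")
  P <- predictNodeProba(nm, X1)
  expect_equal(colnames(P)[max.col(P)], y1)
})

test_that("MMC-LDA attains the maximum margin criterion optimum", {
  set.seed(11)
  d <- 5
  X <- rbind(matrix(rnorm(20 * d), 20, d),
             sweep(matrix(rnorm(20 * d), 20, d), 2, c(3, 1, 0, 0, 0), "+"))
  y <- rep(c("a", "b"), each = 20)
  m <- fitMmcLda(X, y)
  # orthonormal directions
  expect_lt(max(abs(crossprod(m@W) - diag(ncol(m@W)))), 1e-10)
  # leading direction's criterion vs brute-force random search
  sc <- oracleScatter(X, y)
  lead <- drop(t(m@W[, 1]) %*% (sc$Sb - sc$Sw) %*% m@W[, 1])
  brute <- bruteForceMmcMax(X, y, nRand = 1e5)
  expect_gte(lead, brute - 1e-6)
  expect_equal(lead, m@extra$values[1], tolerance = 1e-8)
})

test_that("MMC-LDA degenerate geometries behave as the criterion dictates", {
  set.seed(12)
  # identical class means: S_b = 0, leading eigenvalue = -lambda_min(S_w) <= 0
  X <- matrix(rnorm(200), 40, 5)
  y <- rep(c("a", "b"), 20)
  X[y == "b", ] <- X[y == "b", ] - rep(colMeans(X[y == "b", , drop = FALSE]) -
                                       colMeans(X[y == "a", , drop = FALSE]),
                                       each = 20)
  m <- fitMmcLda(X, y, k = 3)
  expect_lte(m@extra$values[1], 1e-8)
  expect_lt(max(abs(crossprod(m@W) - diag(3))), 1e-10)

  # separation only along axis 1, isotropic noise: leading axis near e1
  X2 <- rbind(matrix(rnorm(200 * 5), 200, 5),
              sweep(matrix(rnorm(200 * 5), 200, 5), 2, c(6, 0, 0, 0, 0), "+"))
  y2 <- rep(c("a", "b"), each = 200)
  m2 <- fitMmcLda(X2, y2)
  ang <- acos(min(1, abs(m2@W[1, 1]))) * 180 / pi
  expect_lt(ang, 5)

  # one sample per class is allowed (S_w = 0)
  m3 <- fitMmcLda(rbind(c(0, 0), c(1, 1)), c("a", "b"))
  expect_equal(abs(m3@W[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-8)
})

test_that("between- and within-class scatter sum to the total scatter", {
  set.seed(19)
  X <- matrix(rnorm(120), 30, 4)
  y <- rep(c("a", "b", "c"), each = 10)
  sc <- HiClassify:::.scatterPair(X, y)
  Xt <- sweep(X, 2, colMeans(X))
  St <- crossprod(Xt) / nrow(X)
  expect_equal(sc$Sb + sc$Sw, St, tolerance = 1e-12)
  expect_equal(sc$Sb, t(sc$Sb))
  expect_true(min(eigen(sc$Sw, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-12)
})

test_that("PCA-LDA equals direct LDA when S_w is nonsingular", {
  set.seed(21)
  d <- 4
  X <- rbind(matrix(rnorm(30 * d), 30, d),
             sweep(matrix(rnorm(30 * d), 30, d), 2, c(2, -1, 0.5, 0), "+"))
  y <- rep(c("a", "b"), each = 30)
  m <- fitPcaLda(X, y)
  expect_equal(m@k, 1L)  # c = 2 gives exactly one discriminant axis
  wd <- directLdaAxes(X, y)[, 1]
  cosang <- abs(sum(m@W[, 1] * wd))
  expect_gt(cosang, 1 - 1e-6)
})

test_that("PCA-LDA evades the small-sample-size singularity", {
  set.seed(22)
  X <- rbind(matrix(rnorm(15 * 500), 15, 500),
             matrix(rnorm(15 * 500, 1), 15, 500))
  y <- rep(c("a", "b"), each = 15)
  m <- fitPcaLda(X, y)  # n = 30 << d = 500: must not error
  expect_equal(dim(m@W), c(500L, 1L))
  expect_true(all(is.finite(m@W)))
  expect_error(fitPcaLda(X[c(1, 16), ], y[c(1, 16)]), "insufficient samples")
})

test_that("linear SVM separates and respects symmetry", {
  set.seed(31)
  tg <- twoGaussians(n = 25, d = 2, sep = 8)
  m <- fitLinearSvm(tg$X, tg$y)
  S <- scoreSamples(m, tg$X)
  pred <- colnames(S)[max.col(S)]
  expect_equal(mean(pred == tg$y), 1)

  # two mirrored points: normal along x, margin midpoint at x = 0
  Xp <- rbind(c(-1, 0), c(1, 0), c(-1, 0.01), c(1, 0.01))
  yp <- c("neg", "pos", "neg", "pos")
  mp <- fitLinearSvm(Xp, yp, C = 1000)
  w <- mp@W[, "pos"]
  expect_gt(abs(w[1]), 1000 * abs(w[2]))
  # decision value at the midpoint is zero
  mid <- scoreSamples(mp, matrix(c(0, 0.005), 1))
  expect_lt(abs(mid[1, "pos"]), 1e-6)

  # binary decision values are antisymmetric under label swap
  for (i in 1:20) {
    set.seed(i)
    X <- matrix(rnorm(60), 20, 3)
    y <- rep(c("a", "b"), 10)
    d1 <- scoreSamples(fitLinearSvm(X, y), X)
    d2 <- scoreSamples(fitLinearSvm(X, ifelse(y == "a", "b", "a")), X)
    # swapping the labels mirrors the hyperplane of each named class
    expect_equal(unname(d1[, "a"]), -unname(d2[, "a"]), tolerance = 1e-6)
    expect_equal(unname(d1[, "a"]), -unname(d1[, "b"]), tolerance = 1e-6)
  }
  expect_error(fitLinearSvm(matrix(rnorm(10), 5), rep("a", 5)), "2 classes")
})

test_that("scoreSamples applies stored centering deterministically", {
  set.seed(41)
  tg <- twoGaussians(n = 15, d = 6, sep = 4)
  for (fit in list(fitSimpls(tg$X, tg$y, 3), fitMmcLda(tg$X, tg$y),
                   fitPcaLda(tg$X, tg$y))) {
    S <- scoreSamples(fit, tg$X)
    if (fit@method == "PLS") expect_identical(unname(S),
                                              unname(fit@extra$scores))
    # zero vector scores as the projection of minus the centering vector
    z <- scoreSamples(fit, matrix(0, 1, 6))
    expect_equal(drop(z), drop(-fit@center %*% fit@W), tolerance = 1e-12)
    # affine equivariance under a common shift
    mu <- rnorm(6)
    fit2 <- switch(fit@method,
      "PLS" = fitSimpls(sweep(tg$X, 2, mu, "+"), tg$y, 3),
      "MMC-LDA" = fitMmcLda(sweep(tg$X, 2, mu, "+"), tg$y),
      "PCA-LDA" = fitPcaLda(sweep(tg$X, 2, mu, "+"), tg$y))
    S2 <- scoreSamples(fit2, sweep(tg$X, 2, mu, "+"))
    expect_equal(S2, S, tolerance = 1e-6)
    expect_error(scoreSamples(fit, matrix(0, 1, 5)), "mismatch")
  }
})

test_that("all four methods reach >= 99% training accuracy on separated data", {
  tg <- twoGaussians(n = 40, d = 10, sep = 6, seed = 77)
  for (method in c("PLS", "MMC-LDA", "PCA-LDA", "SVM")) {
    nm <- fitNode(tg$X, tg$y, method)
    P <- predictNodeProba(nm, tg$X)
    acc <- mean(colnames(P)[max.col(P, ties.method = "first")] == tg$y)
    expect_gte(acc, 0.99)
  }
})
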