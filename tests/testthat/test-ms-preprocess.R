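test_that("binning follows the half-open convention and range limits", {
  cfg <- binningConfig(0.001, c(150, 2000))
  # points outside the mass range are discarded
  sp <- Spectrum(c(149.9, 500.0005, 2000.5), c(10, 20, 30))
  v <- binSpectrum(sp, cfg)
  expect_equal(sum(v), 20)
  axis <- mzAxis(cfg)
  hit <- which(v > 0)
  expect_gte(500.0005, axis[hit] - 0.0005)
  expect_lt(500.0005, axis[hit] + 0.0005)  # in bin [500.000, 500.001)

  # two points in the same bin are summed
  cfg2 <- binningConfig(0.5, c(0, 10))
  v2 <- binSpectrum(Spectrum(c(3.1, 3.3), c(1, 2)), cfg2)
  expect_equal(max(v2), 3)
  expect_warning(v0 <- binSpectrum(Spectrum(numeric(0), numeric(0)), cfg2),
                 "empty")
  expect_equal(v0, numeric(20))
})

test_that("adaptive thresholding matches an exhaustive Otsu search", {
  set.seed(1)
  v <- c(abs(rnorm(5000, 1, 0.2)), abs(rnorm(300, 1000, 100)))
  dn <- denoiseThreshold(v)
  expect_equal(log(dn$threshold), bruteForceOtsu(log(v[v > 0])),
               tolerance = 1e-12)
  # the threshold separates the two intensity modes: the signal survives
  # and (essentially all of) the noise is zeroed
  expect_lt(dn$threshold, 500)
  expect_equal(sum(dn$values > 500), 300)
  expect_gt(mean(dn$values[1:5000] == 0), 0.99)
  expect_true(all(dn$values[dn$values > 0] > dn$threshold))

  # all-zero input is unchanged
  z <- denoiseThreshold(numeric(10))
  expect_equal(z$values, numeric(10))
  expect_equal(z$threshold, 0)

  # equal positive values are never partially corrupted
  cst <- denoiseThreshold(rep(3, 50))
  expect_true(all(cst$values == 3) || all(cst$values == 0))
  expect_lte(cst$threshold, 3)
})

test_that("TIC replicate selection keeps the top spectra, stably", {
  vecs <- lapply(c(5, 8, 1, 8, 3, 9, 2, 7), function(t) rep(t / 10, 10))
  keep <- selectTopTic(vecs, k = 5)
  expect_length(keep, 5)
  expect_setequal(keep, c(6, 2, 4, 8, 1))
  expect_lt(which(keep == 2), which(keep == 4))  # tie: earlier replicate first

  expect_warning(keepAll <- selectTopTic(vecs[1:3], k = 5), "keeping all")
  expect_length(keepAll, 3)
})

test_that("derivative peak detection finds apexes where they belong", {
  cfg <- binningConfig(0.001, c(100, 101))
  axis <- mzAxis(cfg)
  gauss <- function(mu, sigma, amp = 100) amp * exp(-(axis - mu)^2 /
                                                    (2 * sigma^2))
  # single Gaussian, sigma = 5 bins: exactly one apex within +/- 1 bin
  v1 <- gauss(100.5, 0.005)
  p1 <- detectPeaks(v1, axis)
  expect_length(p1@mz, 1)
  expect_lt(abs(p1@mz - 100.5), 0.0015)

  # two Gaussians 4 sigma apart resolve into two apexes, agreeing with a
  # naive local-maximum count on the smoothed trace
  v2 <- gauss(100.4, 0.005) + gauss(100.42, 0.005)
  p2 <- detectPeaks(v2, axis)
  expect_length(p2@mz, 2)
  sm <- signal::sgolayfilt(v2, p = 3, n = 11)
  expect_equal(length(p2@mz), naiveLocalMaxCount(sm, eps = 1e-6))

  # flat input yields no peaks; bad window errors
  expect_length(detectPeaks(numeric(500), axis[1:500])@mz, 0)
  expect_error(detectPeaks(v1, axis, window = 10), "odd")
  expect_error(detectPeaks(numeric(5), axis[1:5], window = 11), "shorter")
})

test_that("peak detection is idempotent on isolated apexes", {
  cfg <- binningConfig(0.001, c(100, 101))
  axis <- mzAxis(cfg)
  v <- 100 * exp(-(axis - 100.3)^2 / (2 * 0.005^2)) +
       80 * exp(-(axis - 100.7)^2 / (2 * 0.005^2))
  p <- detectPeaks(v, axis)
  expect_length(p@mz, 2)
  p2 <- detectPeaks(v, axis)
  expect_identical(p@mz, p2@mz)
})

test_that("KDE matching pools jittered apexes into common m/z features", {
  mk <- function(mz, int, s, r) new("PeakList", mz = mz, intensity = int,
                                    sample = s, replicate = as.integer(r))
  # jittered apexes around one position collapse to a single feature
  pls <- list(mk(500.000, 10, "a", 1), mk(500.002, 12, "a", 2),
              mk(499.998, 9, "b", 1))
  al <- kdeMatch(pls, bandwidth = 0.003)
  expect_length(al$features, 1)
  expect_lte(abs(al$features - 500.000), 0.003)
  expect_equal(dim(al$matrix), c(3L, 1L))
  expect_true(all(al$matrix[, 1] > 0))

  # distant apexes stay distinct with no cross-assignment
  pls2 <- list(mk(500.0, 10, "a", 1), mk(600.0, 20, "b", 1))
  al2 <- kdeMatch(pls2, bandwidth = 0.003)
  expect_equal(al2$features, c(500, 600))
  expect_equal(unname(al2$matrix), rbind(c(10, 0), c(0, 20)))

  # within one density mode the highest peak count wins
  pls3 <- list(mk(c(500.000), 5, "a", 1), mk(c(500.000), 6, "b", 1),
               mk(c(500.004), 7, "c", 1))
  al3 <- kdeMatch(pls3, bandwidth = 0.003)
  expect_length(al3$features, 1)
  expect_equal(al3$features, 500.000)

  expect_length(kdeMatch(list(mk(numeric(0), numeric(0), "a", 1)))$features,
                0)
})

test_that("replicate means and transforms behave elementwise", {
  expect_equal(sampleMeanSpectrum(rbind(c(0, 2), c(2, 0))), c(1, 1))
  M <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(sampleMeanSpectrum(M), c(1, 2, 3))
  expect_equal(sampleMeanSpectrum(M[2:1, ]), sampleMeanSpectrum(M))

  expect_equal(logTransform(matrix(0)), matrix(0))
  expect_equal(logTransform(matrix(exp(1) - 1)), matrix(1))
  x <- matrix(runif(20), 4)
  expect_true(all(order(logTransform(x)) == order(x)))
  expect_error(logTransform(matrix(-1)), "negative")
  expect_equal(log2Transform(matrix(1)), matrix(1))
})

test_that("median-fold-change normalization recovers dilution factors", {
  set.seed(4)
  M <- matrix(rexp(20 * 30, 1 / 100), 20, 30)
  M[sample(length(M), 100)] <- 0
  # a sample that is a 3x dilution of another: factor ratio exactly 3 and
  # identical normalized profiles
  M2 <- rbind(M, 3 * M[7, ])
  norm <- mfcNormalize(M2)
  expect_equal(norm$factors[21] / norm$factors[7], 3, tolerance = 1e-9)
  expect_equal(norm$matrix[21, ], norm$matrix[7, ], tolerance = 1e-9)

  # a matrix of scaled copies of one profile normalizes to identical rows,
  # and renormalizing it yields unit factors
  p <- rexp(30, 1 / 100)
  S <- exp(runif(9, -2, 2)) %o% p
  nS <- mfcNormalize(S)
  again <- mfcNormalize(nS$matrix)
  expect_true(all(abs(again$factors - 1) < 1e-12))

  # the defining property: post-normalization median nonzero ratio to the
  # returned reference is 1 for every sample
  for (rep in 1:3) {
    set.seed(rep)
    R <- matrix(rexp(15 * 25, 1 / 50), 15, 25) *
      rep(exp(runif(15, -2, 2)), 25)
    R[sample(length(R), 40)] <- 0
    nm <- mfcNormalize(R)
    for (i in seq_len(nrow(R))) {
      ok <- nm$matrix[i, ] > 0 & nm$reference > 0
      expect_equal(stats::median(nm$matrix[i, ok] / nm$reference[ok]), 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(mfcNormalize(matrix(0, 3, 3)), "nonzero median")
})

test_that("the full spectral pipeline recovers planted peaks end-to-end", {
  peaks <- list(A = c(200.10, 200.20, 200.30, 200.40, 200.50),
                B = c(200.10, 200.20, 200.62, 200.72, 200.82))
  gen <- genSyntheticSpectra(peaks, nSamples = 3, replicates = 3,
                             jitterSd = 0.0, noiseLevel = 0,
                             scaleRange = c(1, 1), seed = 5)
  out <- preprocessSpectra(gen$spectra, binningConfig(0.001, c(199.5, 201.5)),
                          topK = 3)
  planted <- sort(unique(unlist(peaks)))
  expect_equal(length(out$mz), length(planted))
  # zero jitter, zero noise: features land on the planted bin centers
  expect_true(all(abs(out$mz - planted) <= 0.0015))
  # class-distinct peaks separate the classes after normalization + log
  fA <- out$features[startsWith(rownames(out$features), "A"), ]
  fB <- out$features[startsWith(rownames(out$features), "B"), ]
  distinctA <- which.min(abs(out$mz - 200.30))
  expect_true(min(fA[, distinctA]) > max(fB[, distinctA]))
})
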