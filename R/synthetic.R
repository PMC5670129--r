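#' @include AllClasses.R utils.R hierarchy.R ms_preprocess.R
NULL

#' Generate hierarchical Gaussian class data with a known taxonomy
#'
#' Class means are drawn recursively: each node's children scatter around
#' the parent mean at a level-specific separation (in units of the
#' within-class standard deviation), and samples are isotropic Gaussians
#' around their leaf mean. The generator is a pure function of its
#' arguments and the seed.
#'
#' @param branching integer vector of per-level branching factors, e.g.
#'   `c(2, 3, 2)` gives a depth-3 tree with 12 leaves.
#' @param samplesPerLeaf samples drawn per terminal class (default 30).
#' @param nFeatures feature dimension (default 50).
#' @param separation per-level separation multipliers (recycled to the tree
#'   depth); the distance between a child mean and its parent mean in units
#'   of `sigma`.
#' @param sigma within-class standard deviation (default 1).
#' @param seed integer seed.
#' @param heteroscedastic if `TRUE`, noise sd scales with the mean signal
#'   (`sd = sigma * sqrt(1 + |mu|)`), mimicking the intensity-dependent
#'   technical variance of spectral data.
#' @param orthogonalMeans if `TRUE`, sibling offsets use mutually distinct
#'   coordinate axes; requires `nFeatures >=` number of leaves.
#' @return list with `X` (samples x features, rownames = sample ids),
#'   `labels` (lineage strings per sample), `tree` (the
#'   [HierarchyTree-class]) and `means` (leaf means).
#' @export
genHierarchicalGaussians <- function(branching, samplesPerLeaf = 30L,
                                     nFeatures = 50L, separation = 6,
                                     sigma = 1, seed = 1L,
                                     heteroscedastic = FALSE,
                                     orthogonalMeans = FALSE) {
  stopifnot(all(branching >= 1), sigma > 0, all(separation >= 0))
  depth <- length(branching)
  separation <- rep_len(separation, depth)
  nLeaves <- prod(branching)
  if (orthogonalMeans && nFeatures < nLeaves) {
    stop("orthogonal means need nFeatures >= number of leaves")
  }
  .withSeed(seed, {
    axisCounter <- 0L
    grow <- function(prefix, mean, level) {
      if (level > depth) {
        return(list(list(lineage = .pathId(prefix), mean = mean)))
      }
      out <- list()
      for (b in seq_len(branching[level])) {
        if (orthogonalMeans) {
          axisCounter <<- axisCounter + 1L
          dir <- numeric(nFeatures)
          dir[axisCounter] <- 1
        } else {
          dir <- stats::rnorm(nFeatures)
          dir <- dir / sqrt(sum(dir^2))
        }
        childMean <- mean + separation[level] * sigma * dir
        # display names repeat across parents; the full path is the identity
        name <- sprintf("n%d_%d", level, b)
        out <- c(out, grow(c(prefix, name), childMean, level + 1L))
      }
      out
    }
    leaves <- grow(character(0), numeric(nFeatures), 1L)
    X <- matrix(0, nLeaves * samplesPerLeaf, nFeatures)
    labels <- character(nrow(X))
    means <- matrix(0, nLeaves, nFeatures)
    for (i in seq_along(leaves)) {
      rows <- (i - 1L) * samplesPerLeaf + seq_len(samplesPerLeaf)
      mu <- leaves[[i]]$mean
      sd <- if (heteroscedastic) sigma * sqrt(1 + abs(mu)) else
        rep(sigma, nFeatures)
      noise <- matrix(stats::rnorm(samplesPerLeaf * nFeatures),
                      samplesPerLeaf, nFeatures)
      X[rows, ] <- matrix(mu, samplesPerLeaf, nFeatures, byrow = TRUE) +
        sweep(noise, 2, sd, "*")
      labels[rows] <- leaves[[i]]$lineage
      means[i, ] <- mu
    }
    rownames(X) <- sprintf("s%04d", seq_len(nrow(X)))
    colnames(X) <- sprintf("f%d", seq_len(nFeatures))
    rownames(means) <- vapply(leaves, `[[`, "", "lineage")
    list(X = X, labels = labels, tree = buildTree(unique(labels)),
         means = means)
  })
}

#' Generate synthetic multi-peak profile spectra with known truth
#'
#' Emulates replicate profile mass spectra: each class has a planted set of
#' peak positions; every replicate renders them as Gaussian peaks with m/z
#' jitter, a multiplicative per-spectrum scale factor and additive baseline
#' noise, on a fixed-resolution m/z grid.
#'
#' @param classPeaks named list: class -> numeric vector of planted peak
#'   m/z positions (Da, within the binning range).
#' @param amplitudes per-class list (or single vector, recycled) of peak
#'   amplitudes; default 1000 for every peak.
#' @param nSamples samples per class (default 3).
#' @param replicates replicate spectra per sample (default 5).
#' @param jitterSd m/z jitter sd in Da per replicate and peak
#'   (default 0.002).
#' @param noiseLevel sd of the half-normal additive baseline (default 1).
#' @param scaleRange range of the log-uniform per-spectrum multiplicative
#'   scale (default `c(1, 1)`, i.e. none).
#' @param peakSigma Gaussian peak width in Da (default 0.005).
#' @param resolution grid resolution in Da (default 0.001).
#' @param range m/z grid range; default spans the planted peaks +/- 0.5 Da.
#' @param seed integer seed.
#' @return list with `spectra` (list of [Spectrum-class]), `truth`
#'   (data.frame of planted class/m/z/amplitude), `scales` (per-spectrum
#'   factors), `sampleScales` (per-sample mean replicate scale) and
#'   `labels` (sample id -> class).
#' @export
genSyntheticSpectra <- function(classPeaks, amplitudes = NULL,
                                nSamples = 3L, replicates = 5L,
                                jitterSd = 0.002, noiseLevel = 1,
                                scaleRange = c(1, 1), peakSigma = 0.005,
                                resolution = 0.001, range = NULL,
                                seed = 1L) {
  stopifnot(is.list(classPeaks), length(classPeaks) >= 1)
  allPeaks <- unlist(classPeaks)
  if (is.null(range)) {
    range <- c(floor(min(allPeaks)) - 0.5, ceiling(max(allPeaks)) + 0.5)
  }
  if (is.null(amplitudes)) {
    amplitudes <- lapply(classPeaks, function(p) rep(1000, length(p)))
  } else if (!is.list(amplitudes)) {
    amplitudes <- lapply(classPeaks, function(p) rep_len(amplitudes,
                                                         length(p)))
  }
  grid <- seq(range[1], range[2] - resolution / 2, by = resolution) +
    resolution / 2
  .withSeed(seed, {
    spectra <- list()
    scales <- numeric(0)
    scaleIds <- character(0)
    labels <- character(0)
    for (cl in names(classPeaks)) {
      mus <- classPeaks[[cl]]
      amps <- amplitudes[[cl]]
      for (s in seq_len(nSamples)) {
        sid <- sprintf("%s_s%d", cl, s)
        labels[sid] <- cl
        for (r in seq_len(replicates)) {
          sc <- exp(stats::runif(1, log(scaleRange[1]), log(scaleRange[2])))
          inten <- numeric(length(grid))
          for (j in seq_along(mus)) {
            mu <- mus[j] + stats::rnorm(1, 0, jitterSd)
            lo <- findInterval(mu - 5 * peakSigma, grid)
            hi <- findInterval(mu + 5 * peakSigma, grid) + 1L
            win <- max(1L, lo):min(length(grid), hi)
            inten[win] <- inten[win] +
              amps[j] * exp(-(grid[win] - mu)^2 / (2 * peakSigma^2))
          }
          inten <- sc * inten +
            noiseLevel * abs(stats::rnorm(length(grid)))
          spectra[[length(spectra) + 1L]] <-
            Spectrum(grid, inten, sample = sid, replicate = r)
          scales <- c(scales, sc)
          scaleIds <- c(scaleIds, sid)
        }
      }
    }
    truth <- do.call(rbind, lapply(names(classPeaks), function(cl) {
      data.frame(class = cl, mz = classPeaks[[cl]],
                 amplitude = amplitudes[[cl]], stringsAsFactors = FALSE)
    }))
    sampleScales <- tapply(scales, scaleIds, mean)
    list(spectra = spectra, truth = truth, scales = scales,
         sampleScales = sampleScales[unique(scaleIds)], labels = labels)
  })
}
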