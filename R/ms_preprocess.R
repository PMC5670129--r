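#' @include AllClasses.R utils.R
NULL

#' Spectrum and binning constructors
#'
#' `Spectrum()` wraps a raw profile (m/z, intensity) pair;
#' `binningConfig()` holds the import resolution and mass range. Defaults
#' follow the REIMS import convention: 0.001 Da resolution within
#' 150-2000 m/z.
#'
#' @param mz ascending m/z values in Da.
#' @param intensity non-negative intensities.
#' @param sample sample id.
#' @param replicate replicate index within the sample.
#' @return a [Spectrum-class].
#' @export
Spectrum <- function(mz, intensity, sample = "s1", replicate = 1L) {
  new("Spectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      sample = as.character(sample), replicate = as.integer(replicate))
}

#' @rdname Spectrum
#' @param resolution bin width in Da.
#' @param range two-element m/z range.
#' @export
binningConfig <- function(resolution = 0.001, range = c(150, 2000)) {
  new("BinningConfig", resolution = resolution, range = as.numeric(range))
}

#' @rdname Spectrum
#' @param cfg a [BinningConfig-class].
#' @return `mzAxis()`: the bin-center m/z coordinates.
#' @export
mzAxis <- function(cfg) {
  nb <- ceiling((cfg@range[2] - cfg@range[1]) / cfg@resolution)
  cfg@range[1] + (seq_len(nb) - 0.5) * cfg@resolution
}

#' Bin a raw spectrum onto a fixed-resolution axis
#'
#' Intensities are summed into half-open bins `[lo, lo + resolution)`;
#' points outside the configured mass range are discarded.
#'
#' @param spec a [Spectrum-class].
#' @param cfg a [BinningConfig-class].
#' @return numeric intensity vector of length `ceiling(range / resolution)`.
#' @export
binSpectrum <- function(spec, cfg = binningConfig()) {
  nb <- ceiling((cfg@range[2] - cfg@range[1]) / cfg@resolution)
  out <- numeric(nb)
  if (length(spec@mz) == 0) {
    warning("empty spectrum: returning zero vector", call. = FALSE)
    return(out)
  }
  keep <- spec@mz >= cfg@range[1] & spec@mz < cfg@range[2]
  if (any(keep)) {
    idx <- floor((spec@mz[keep] - cfg@range[1]) / cfg@resolution) + 1L
    idx[idx > nb] <- nb
    sums <- rowsum(spec@intensity[keep], idx)
    out[as.integer(rownames(sums))] <- sums[, 1]
  }
  out
}

# Otsu's between-class-variance-maximizing split of a histogram.
.otsuThreshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(-Inf)
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[length(mu)]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  h$breaks[which.max(sigmaB) + 1L]
}

#' Adaptive histogram-based noise thresholding
#'
#' Chooses the optimum intensity threshold by maximizing the between-class
#' variance of the histogram of nonzero log-intensities (Otsu's criterion)
#' and zeroes every entry at or below it. A constant-valued vector is left
#' untouched (threshold 0): equal values are never partially removed.
#'
#' @param binned non-negative binned intensity vector.
#' @param nbins histogram bins (default 256).
#' @return list with `values` (denoised vector) and `threshold` (on the
#'   intensity scale).
#' @export
denoiseThreshold <- function(binned, nbins = 256L) {
  if (any(binned < 0)) stop("intensities must be non-negative")
  nz <- binned[binned > 0]
  if (length(nz) == 0) return(list(values = binned, threshold = 0))
  tLog <- .otsuThreshold(log(nz), nbins = nbins)
  thr <- if (is.finite(tLog)) exp(tLog) else 0
  out <- binned
  out[out <= thr] <- 0
  list(values = out, threshold = thr)
}

#' Select the top replicate spectra of a sample by total ion intensity
#'
#' Ranks post-threshold binned replicate spectra by TIC (the vector sum) and
#' keeps the `k` largest; ties keep the earlier replicate (stable order).
#'
#' @param vectors list of binned (denoised) intensity vectors for one sample.
#' @param k number to keep (default 5).
#' @return integer indices of the retained replicates, in rank order.
#' @export
selectTopTic <- function(vectors, k = 5L) {
  if (length(vectors) == 0) stop("at least one spectrum is required")
  tic <- vapply(vectors, sum, 0)
  if (length(vectors) <= k) {
    if (length(vectors) < k) {
      warning(sprintf("only %d spectra available (k = %d): keeping all",
                      length(vectors), k), call. = FALSE)
    }
    return(order(-tic, method = "radix"))
  }
  order(-tic, method = "radix")[seq_len(k)]
}

#' Savitzky-Golay derivative peak detection
#'
#' Smooths the binned trace with a Savitzky-Golay polynomial filter and
#' locates apexes as positive-to-negative zero crossings of the smoothed
#' first derivative with positive smoothed intensity. Apex m/z is the bin
#' center.
#'
#' @param denoised binned (denoised) intensity vector.
#' @param mz bin-center coordinates (same length), e.g. from [mzAxis()].
#' @param window odd filter window length in bins (default 11).
#' @param polyorder polynomial order (default 3); must be < `window`.
#' @param sample,replicate provenance recorded in the peak list.
#' @return a [PeakList-class].
#' @export
detectPeaks <- function(denoised, mz, window = 11L, polyorder = 3L,
                        sample = "s1", replicate = 1L) {
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder")
  }
  if (window >= length(denoised)) {
    stop("window must be shorter than the intensity vector")
  }
  stopifnot(length(mz) == length(denoised))
  sm <- signal::sgolayfilt(denoised, p = polyorder, n = window)
  dv <- signal::sgolayfilt(denoised, p = polyorder, n = window, m = 1)
  n <- length(dv)
  cross <- which(dv[-n] > 0 & dv[-1] <= 0)
  if (length(cross)) {
    apex <- ifelse(sm[cross + 1L] > sm[cross], cross + 1L, cross)
    keep <- sm[apex] > 0
    apex <- apex[keep]
  } else {
    apex <- integer(0)
  }
  new("PeakList", mz = mz[apex], intensity = pmax(sm[apex], 0),
      sample = as.character(sample), replicate = as.integer(replicate))
}

#' Kernel-density peak matching across spectra
#'
#' Pools apex m/z values from all peak lists, smooths them by Gaussian
#' kernel density estimation, and segments the pool at density minima. In
#' each density mode the m/z value attracting the highest peak count is
#' taken as the common m/z feature for all spectra. Each spectrum's peaks
#' are then assigned to the nearest feature within `tolFactor * bandwidth`;
#' a spectrum with no matching peak gets 0 for that feature.
#'
#' @param peaklists list of [PeakList-class].
#' @param bandwidth Gaussian KDE bandwidth in Da (default 0.003).
#' @param tolFactor assignment tolerance in bandwidth units (default 3).
#' @return list with `features` (increasing common m/z vector), `matrix`
#'   (spectra x features aligned intensities, max over multiply matched
#'   peaks) and `ids` (per-row sample/replicate table).
#' @export
kdeMatch <- function(peaklists, bandwidth = 0.003, tolFactor = 3) {
  pool <- unlist(lapply(peaklists, function(p) p@mz))
  ids <- data.frame(
    sample = vapply(peaklists, function(p) p@sample, ""),
    replicate = vapply(peaklists, function(p) p@replicate, 1L),
    stringsAsFactors = FALSE)
  if (length(pool) == 0) {
    return(list(features = numeric(0),
                matrix = matrix(0, length(peaklists), 0), ids = ids))
  }
  if (length(unique(pool)) == 1L) {
    features <- unique(pool)
  } else {
    span <- diff(range(pool)) + 6 * bandwidth
    ngrid <- min(2^16, max(512, 2^ceiling(log2(span / (bandwidth / 4)))))
    den <- stats::density(pool, bw = bandwidth, n = ngrid)
    y <- den$y
    m <- length(y)
    isMax <- c(FALSE, y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m],
               FALSE)
    maxIdx <- which(isMax)
    if (length(maxIdx) == 0) maxIdx <- which.max(y)
    # segment boundaries at the density minima between consecutive modes
    bounds <- numeric(0)
    if (length(maxIdx) > 1) {
      for (i in seq_len(length(maxIdx) - 1L)) {
        lo <- maxIdx[i]
        hi <- maxIdx[i + 1L]
        bounds <- c(bounds, den$x[lo + which.min(y[lo:hi]) - 1L])
      }
    }
    seg <- findInterval(pool, bounds) + 1L
    features <- vapply(sort(unique(seg)), function(s) {
      vals <- pool[seg == s]
      cnt <- table(vals)
      as.numeric(names(cnt)[which.max(cnt)])  # ties: lowest m/z wins
    }, 0)
    features <- sort(unique(features))
  }
  tol <- tolFactor * bandwidth
  M <- matrix(0, length(peaklists), length(features))
  for (i in seq_along(peaklists)) {
    p <- peaklists[[i]]
    if (length(p@mz) == 0) next
    fi <- findInterval(p@mz, features) # nearest feature via neighbors
    for (j in seq_along(p@mz)) {
      cand <- unique(pmin(pmax(c(fi[j], fi[j] + 1L), 1L), length(features)))
      d <- abs(features[cand] - p@mz[j])
      b <- cand[which.min(d)]
      if (min(d) <= tol) M[i, b] <- max(M[i, b], p@intensity[j])
    }
  }
  colnames(M) <- formatC(features, format = "f", digits = 6)
  list(features = features, matrix = M, ids = ids)
}

#' Mean spectrum across a sample's replicates
#'
#' @param aligned replicates x features aligned intensity matrix.
#' @return numeric vector: the arithmetic feature-wise mean.
#' @export
sampleMeanSpectrum <- function(aligned) {
  colMeans(aligned)
}

#' Median-fold-change normalization
#'
#' The reference profile is the feature-wise median spectrum of the input.
#' Each sample is divided by the median of its nonzero ratios to the
#' reference (zeros are excluded as a division guard), so the
#' post-normalization median fold change of every sample to the returned
#' reference is exactly 1.
#'
#' @param M non-negative samples x features matrix.
#' @return list with `matrix` (normalized), `factors` (per-sample dilution
#'   factors) and `reference` (the input's median spectrum).
#' @export
mfcNormalize <- function(M) {
  M <- .assertMatrix(M)
  if (any(M < 0)) stop("matrix must be non-negative")
  ref <- apply(M, 2, stats::median)
  if (all(ref == 0)) stop("no feature with nonzero median")
  factors <- vapply(seq_len(nrow(M)), function(i) {
    ok <- M[i, ] > 0 & ref > 0
    if (!any(ok)) {
      warning(sprintf(
        "sample %d shares no nonzero features with the reference", i),
        call. = FALSE)
      return(1)
    }
    stats::median(M[i, ok] / ref[ok])
  }, 0)
  names(factors) <- rownames(M)
  list(matrix = M / factors, factors = factors, reference = ref)
}

#' Variance-stabilizing log transforms
#'
#' `logTransform()` applies `log(1 + x)` elementwise (natural log, used for
#' mass spectra); `log2Transform()` applies `log2(1 + x)` (expression
#' tables). Both are monotone and map 0 to 0.
#'
#' @param M non-negative matrix.
#' @return transformed matrix.
#' @export
logTransform <- function(M) {
  if (any(M < 0)) stop("matrix has negative entries")
  log1p(M)
}

#' @rdname logTransform
#' @export
log2Transform <- function(M) {
  if (any(M < 0)) stop("matrix has negative entries")
  log2(1 + M)
}

#' Full spectra-to-feature-matrix preprocessing pipeline
#'
#' Runs, per replicate spectrum: fixed-resolution binning, adaptive
#' histogram denoising; then per sample: top-`topK` TIC replicate selection
#' and Savitzky-Golay peak detection; then across all retained spectra:
#' kernel-density peak matching to a common m/z vector, per-sample replicate
#' averaging, median-fold-change normalization and log transformation.
#'
#' @param spectra list of [Spectrum-class] (several replicates per sample).
#' @param cfg a [BinningConfig-class].
#' @param window,polyorder Savitzky-Golay parameters (see [detectPeaks()]).
#' @param topK replicates retained per sample by TIC (default 5).
#' @param bandwidth,tolFactor KDE matching parameters (see [kdeMatch()]).
#' @param log apply the final log transform (default TRUE).
#' @return list with `features` (samples x common-m/z matrix), `mz`
#'   (feature coordinates), `factors` (per-sample normalization factors),
#'   `thresholds` (per retained spectrum) and `retained` (sample/replicate
#'   table).
#' @export
preprocessSpectra <- function(spectra, cfg = binningConfig(),
                              window = 11L, polyorder = 3L, topK = 5L,
                              bandwidth = 0.003, tolFactor = 3,
                              log = TRUE) {
  samples <- vapply(spectra, function(s) s@sample, "")
  axis <- mzAxis(cfg)
  peaklists <- list()
  thresholds <- numeric(0)
  for (sm in unique(samples)) {
    idx <- which(samples == sm)
    den <- lapply(idx, function(i) {
      denoiseThreshold(binSpectrum(spectra[[i]], cfg))
    })
    keep <- selectTopTic(lapply(den, `[[`, "values"), k = topK)
    for (j in keep) {
      i <- idx[j]
      pl <- detectPeaks(den[[j]]$values, axis, window = window,
                        polyorder = polyorder, sample = sm,
                        replicate = spectra[[i]]@replicate)
      peaklists[[length(peaklists) + 1L]] <- pl
      thresholds <- c(thresholds, den[[j]]$threshold)
    }
  }
  al <- kdeMatch(peaklists, bandwidth = bandwidth, tolFactor = tolFactor)
  sampleIds <- unique(al$ids$sample)
  Fm <- t(vapply(sampleIds, function(sm) {
    sampleMeanSpectrum(al$matrix[al$ids$sample == sm, , drop = FALSE])
  }, numeric(ncol(al$matrix))))
  rownames(Fm) <- sampleIds
  colnames(Fm) <- colnames(al$matrix)
  norm <- mfcNormalize(Fm)
  out <- if (log) logTransform(norm$matrix) else norm$matrix
  list(features = out, mz = al$features, factors = norm$factors,
       thresholds = thresholds, retained = al$ids)
}

#' Read a two-column m/z-intensity text spectrum
#'
#' Whitespace-delimited, optionally with `#` comment lines.
#'
#' @param path file path.
#' @param sample,replicate provenance attached to the spectrum.
#' @return a [Spectrum-class].
#' @export
readSpectrumText <- function(path, sample = NULL, replicate = 1L) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("mz", "intensity"))
  o <- order(df$mz)
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  Spectrum(df$mz[o], df$intensity[o], sample = sample,
           replicate = replicate)
}

#' Read a spectrum from an mzML file
#'
#' Thin wrapper over `mzR` (suggested dependency); each scan in the file
#' (profile or centroid) becomes one replicate spectrum.
#'
#' @param path mzML file path.
#' @param sample sample id (default: file stem).
#' @return list of [Spectrum-class], one per scan.
#' @export
readSpectrumMzML <- function(path, sample = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  n <- nrow(mzR::header(h))
  lapply(seq_len(n), function(i) {
    pk <- mzR::peaks(h, i)
    o <- order(pk[, 1])
    pk <- pk[o, , drop = FALSE]
    keep <- !duplicated(pk[, 1])
    Spectrum(pk[keep, 1], pmax(pk[keep, 2], 0), sample = sample,
             replicate = i)
  })
}

#' Read spectra listed in a manifest
#'
#' The manifest is a TSV with columns `file`, `sample_id` and optionally
#' `replicate`; paths are resolved relative to the manifest. Files ending
#' in `.mzML` go through [readSpectrumMzML()]; anything else is read as
#' two-column m/z-intensity text.
#'
#' @param manifestPath path to the manifest TSV.
#' @return list of [Spectrum-class].
#' @export
readSpectraManifest <- function(manifestPath) {
  mf <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  if (!all(c("file", "sample_id") %in% names(mf))) {
    stop(sprintf("manifest '%s' needs columns file, sample_id", manifestPath))
  }
  if (is.null(mf$replicate)) mf$replicate <- stats::ave(
    seq_len(nrow(mf)), mf$sample_id, FUN = seq_along)
  base <- dirname(manifestPath)
  out <- lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$file[i]
    if (!file.exists(p)) p <- file.path(base, p)
    if (grepl("\\.mzml$", p, ignore.case = TRUE)) {
      readSpectrumMzML(p, sample = mf$sample_id[i])
    } else {
      list(readSpectrumText(p, sample = mf$sample_id[i],
                            replicate = mf$replicate[i]))
    }
  })
  unlist(out, recursive = FALSE)
}
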