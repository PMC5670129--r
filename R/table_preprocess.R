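#' @include AllClasses.R utils.R ms_preprocess.R
NULL

#' Annotated expression table constructor
#'
#' @param counts samples x genes non-negative matrix; rownames are sample
#'   ids (set from `meta$sample_id` when missing).
#' @param meta data.frame with columns `sample_id`, `patient_id`,
#'   `tissue_status` (`"tumor"`/`"normal"`), `type` and `subtype`.
#' @return an [AnnotatedTable-class].
#' @export
annotatedTable <- function(counts, meta) {
  counts <- .assertMatrix(counts)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(rownames(counts))) rownames(counts) <- meta$sample_id
  counts <- counts[match(meta$sample_id, rownames(counts)), , drop = FALSE]
  new("AnnotatedTable", counts = counts, meta = meta)
}

setMethod("show", "AnnotatedTable", function(object) {
  cat(sprintf("AnnotatedTable: %d samples x %d genes, %d types / %d subtypes\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@meta$type)),
              length(unique(object@meta$subtype))))
})

#' @rdname lineages
#' @export
setMethod("lineages", "AnnotatedTable", function(object, ...) {
  paste(object@meta$type, object@meta$subtype, sep = ";")
})

#' Normalize an expression table
#'
#' Median-fold-change normalization (shared with the spectral pipeline)
#' followed by a variance-stabilizing `log2(1 + x)` transformation, so a
#' sample whose counts are uniformly doubled normalizes to the identical
#' profile.
#'
#' @param table an [AnnotatedTable-class].
#' @return the table with normalized, transformed counts; normalization
#'   factors in `attr(, "factors")`.
#' @export
normalizeLog2 <- function(table) {
  norm <- mfcNormalize(table@counts)
  out <- annotatedTable(log2Transform(norm$matrix), table@meta)
  attr(out, "factors") <- norm$factors
  out
}

#' Filter an expression table by the sample/gene inclusion rules
#'
#' Applies, in order: (1) removal of normal-tissue samples and of dubiously
#' annotated genes (those matching `genePattern`); (2) retention of a single
#' random (seeded) sample per patient; (3) removal of subtypes with fewer
#' than `minSubtypeN` samples. The order means subtype sizes are counted on
#' deduplicated (patient-level) samples. The operation is idempotent.
#'
#' @param table an [AnnotatedTable-class].
#' @param minSubtypeN minimum samples per subtype (default 15).
#' @param seed seed for the random per-patient sample choice.
#' @param genePattern regular expression matching genes to drop (default
#'   `"^\\?"`, i.e. `?`-prefixed symbols); `NULL` disables the gene filter.
#' @param normalLabel `tissue_status` value marking normal samples.
#' @return the filtered [AnnotatedTable-class].
#' @export
filterSamples <- function(table, minSubtypeN = 15L, seed = 1L,
                          genePattern = "^\\?", normalLabel = "normal") {
  counts <- table@counts
  meta <- table@meta
  keepS <- meta$tissue_status != normalLabel
  counts <- counts[keepS, , drop = FALSE]
  meta <- meta[keepS, , drop = FALSE]
  if (!is.null(genePattern) && !is.null(colnames(counts))) {
    counts <- counts[, !grepl(genePattern, colnames(counts)), drop = FALSE]
  }
  keep <- logical(nrow(meta))
  for (p in unique(meta$patient_id)) {
    idx <- which(meta$patient_id == p)
    pick <- if (length(idx) == 1L) idx else {
      .withSeed(.childSeed(seed, match(p, unique(meta$patient_id))),
                idx[sample.int(length(idx), 1L)])
    }
    keep[pick] <- TRUE
  }
  counts <- counts[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  sizes <- table(meta$subtype)
  okSub <- meta$subtype %in% names(sizes)[sizes >= minSubtypeN]
  counts <- counts[okSub, , drop = FALSE]
  meta <- meta[okSub, , drop = FALSE]
  if (nrow(meta) == 0) stop("filtering removed every sample")
  rownames(meta) <- NULL
  annotatedTable(counts, meta)
}

#' Read an annotated expression table from disk
#'
#' @param countsPath CSV/TSV counts matrix, samples in rows (first column =
#'   sample ids).
#' @param metaPath TSV sample metadata with the columns listed in
#'   [annotatedTable()].
#' @return an [AnnotatedTable-class].
#' @export
readAnnotatedTable <- function(countsPath, metaPath) {
  sep <- if (grepl("\\.tsv$", countsPath)) "\t" else ","
  counts <- utils::read.table(countsPath, header = TRUE, sep = sep,
                              row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  annotatedTable(as.matrix(counts), meta)
}
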