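#' @include AllClasses.R hierarchy.R selection_cv.R
NULL

#' Read / write a sample-by-feature matrix
#'
#' CSV (or TSV) with samples in rows; the first column holds sample ids and
#' the header holds feature names (e.g. common m/z values).
#'
#' @param path file path (`.tsv` switches to tab separation).
#' @return numeric matrix with sample-id rownames.
#' @export
readFeatureMatrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname readFeatureMatrix
#' @param X numeric matrix, samples in rows.
#' @export
writeFeatureMatrix <- function(X, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(data.frame(sample_id = rownames(X), X,
                                check.names = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.matToList <- function(M) {
  list(dim = dim(M), dimnames = dimnames(M), values = as.vector(M))
}

.listToMat <- function(L) {
  M <- matrix(unlist(L$values), L$dim[[1]], L$dim[[2]])
  if (!is.null(L$dimnames) && length(L$dimnames)) {
    dn <- lapply(L$dimnames, function(d) if (length(d)) unlist(d) else NULL)
    if (any(!vapply(dn, is.null, TRUE))) dimnames(M) <- dn
  }
  M
}

.reducerToList <- function(r) {
  list(method = r@method, W = .matToList(r@W), center = r@center, k = r@k,
       classes = r@classes, intercepts = r@intercepts)
}

.listToReducer <- function(L) {
  new("ReducedModel", method = L$method, W = .listToMat(L$W),
      center = unlist(L$center), k = as.integer(L$k),
      classes = as.character(unlist(L$classes)),
      intercepts = as.numeric(unlist(L$intercepts)), extra = list())
}

#' Serialize / restore a trained hierarchical model
#'
#' Writes a single JSON archive holding the taxonomy (as lineage strings),
#' the method map with its inner-CV accuracy tables, every node's projection
#' matrix and logistic coefficients, and the configuration, so a model can
#' be trained once and reused for prediction.
#'
#' @param model an [HCModel-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeHCModel <- function(model, path) {
  obj <- list(
    format = "HiClassify-model",
    version = as.character(utils::packageVersion("HiClassify")),
    lineages = treeLeaves(model@tree),
    methodMap = list(map = model@methodMap@map,
                     tables = lapply(model@methodMap@tables, .matToList)),
    nodeModels = lapply(model@nodeModels, function(nm) {
      list(node = nm@node, method = nm@method,
           reducer = .reducerToList(nm@reducer), coef = .matToList(nm@coef),
           children = nm@children, classes = nm@classes,
           singleOffspring = nm@singleOffspring)
    }),
    featureNames = model@featureNames,
    config = list(kOuter = model@config@kOuter, kInner = model@config@kInner,
                  reps = model@config@reps, seed = model@config@seed)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHCModel
#' @export
readHCModel <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "HiClassify-model")) {
    stop(sprintf("'%s' is not a HiClassify model archive", path))
  }
  tree <- buildTree(as.character(unlist(obj$lineages)))
  mapDf <- do.call(rbind, lapply(obj$methodMap$map, function(r) {
    data.frame(node = r$node, method = r$method,
               k = if (is.null(r$k)) NA_integer_ else as.integer(r$k),
               singleOffspring = isTRUE(r$singleOffspring),
               meanAccuracy = as.numeric(r$meanAccuracy),
               stringsAsFactors = FALSE)
  }))
  mm <- new("MethodMap", map = mapDf,
            tables = lapply(obj$methodMap$tables, .listToMat))
  models <- lapply(obj$nodeModels, function(L) {
    new("NodeModel", node = L$node, method = L$method,
        reducer = .listToReducer(L$reducer), coef = .listToMat(L$coef),
        children = as.character(unlist(L$children)),
        classes = as.character(unlist(L$classes)),
        singleOffspring = isTRUE(L$singleOffspring))
  })
  names(models) <- vapply(models, function(m) m@node, "")
  cfg <- cvConfig(obj$config$kOuter, obj$config$kInner, obj$config$reps,
                  obj$config$seed)
  new("HCModel", tree = tree, methodMap = mm, nodeModels = models,
      featureNames = as.character(unlist(obj$featureNames)), config = cfg)
}

#' Write a reproducibility manifest next to run artifacts
#'
#' @param dir artifact directory.
#' @param config named list of run parameters (paths, folds, thresholds).
#' @param seed the seed used.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, config, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(package = "HiClassify",
         version = as.character(utils::packageVersion("HiClassify")),
         seed = seed, config = config),
    p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}
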