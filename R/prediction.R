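#' @include AllClasses.R AllGenerics.R utils.R hierarchy.R selection_cv.R
NULL

#' Prediction configuration constructor
#'
#' @param delta probability-difference non-classification threshold in
#'   `[0, 1]` (default 0.05): a sample halts as non-classified at a node when
#'   the gap between its highest and second-highest child probabilities falls
#'   below `delta`.
#' @param maxDepth deepest level to descend to (default `Inf`, i.e. leaves).
#' @return a [PredictionConfig-class].
#' @export
predictionConfig <- function(delta = 0.05, maxDepth = Inf) {
  new("PredictionConfig", delta = delta, maxDepth = maxDepth)
}

#' Top-down probabilistic classification of new samples
#'
#' Starting at the root, each sample is assigned to the child with the
#' highest probability and descends recursively. When the top-two
#' probability gap is below `cfg@delta` the sample stops as non-classified
#' at that level; single-offspring nodes instead stop any sample whose
#' highest-probability class is not the single child. The full trajectory,
#' including per-node probabilities, is returned.
#'
#' @param model a trained [HCModel-class].
#' @param X samples x features matrix (or a single feature vector).
#' @param cfg a [PredictionConfig-class].
#' @return a list of [PredictionPath-class], one per sample.
#' @export
predictTopdown <- function(model, X, cfg = predictionConfig()) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- .assertMatrix(X)
  if (ncol(X) != length(model@featureNames)) {
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 length(model@featureNames), ncol(X)))
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(X)))
  tree <- model@tree
  lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, , drop = FALSE]
    node <- ROOT_ID
    steps <- list()
    probs <- list()
    status <- "leaf"
    finalClass <- ROOT_ID
    repeat {
      lv <- nodeLevel(tree, node)
      kids <- treeChildren(tree, node)
      if (length(kids) == 0 || lv >= cfg@maxDepth) break
      nm <- model@nodeModels[[node]]
      if (is.null(nm)) stop(sprintf("untrained node '%s' encountered", node))
      P <- drop(predictNodeProba(nm, x))
      ord <- order(P, decreasing = TRUE)
      p1 <- P[ord[1]]
      p2 <- if (length(P) > 1) P[ord[2]] else 0
      if (nm@singleOffspring) {
        ok <- names(P)[ord[1]] == nm@children[1]
        assigned <- if (ok) nm@children[1] else NA_character_
      } else {
        ok <- (p1 - p2) >= cfg@delta
        assigned <- if (ok) nm@children[ord[1]] else NA_character_
      }
      steps[[length(steps) + 1L]] <- data.frame(
        node = node, assigned = assigned, p1 = unname(p1), p2 = unname(p2),
        stringsAsFactors = FALSE)
      probs[[length(probs) + 1L]] <- P
      if (!ok) {
        status <- "non_classified"
        break
      }
      finalClass <- assigned
      node <- assigned
    }
    stepDf <- if (length(steps)) do.call(rbind, steps) else
      data.frame(node = character(0), assigned = character(0),
                 p1 = numeric(0), p2 = numeric(0))
    new("PredictionPath", sample = ids[i], steps = stepDf, probs = probs,
        status = status,
        level = if (finalClass == ROOT_ID) 0L else nodeLevel(tree, finalClass),
        finalClass = finalClass)
  })
}

setMethod("show", "PredictionPath", function(object) {
  cat(sprintf("PredictionPath[%s]: %s at level %d (%s)\n", object@sample,
              object@finalClass, object@level, object@status))
})

#' Flatten prediction paths to a per-sample table
#'
#' @param paths list of [PredictionPath-class] as returned by
#'   [predictTopdown()].
#' @param depth number of levels to report (default: deepest seen).
#' @return data.frame: sample, per-level assignment with the top-two
#'   probabilities of each level's decision, terminal status, and the
#'   top-two probabilities of the last decision taken.
#' @export
pathTable <- function(paths, depth = NULL) {
  if (is.null(depth)) {
    depth <- max(1L, max(vapply(paths, function(p) p@level, 0L)))
  }
  do.call(rbind, lapply(paths, function(p) {
    lev <- rep(NA_character_, depth)
    p1 <- p2 <- rep(NA_real_, depth)
    ns <- nrow(p@steps)
    if (ns) {
      take <- seq_len(min(ns, depth))
      lev[take] <- p@steps$assigned[take]
      p1[take] <- p@steps$p1[take]
      p2[take] <- p@steps$p2[take]
    }
    out <- data.frame(sample = p@sample, stringsAsFactors = FALSE)
    for (l in seq_len(depth)) {
      out[[paste0("level", l)]] <- lev[l]
      out[[paste0("p1_level", l)]] <- p1[l]
      out[[paste0("p2_level", l)]] <- p2[l]
    }
    out$status <- p@status
    out$last_p1 <- if (ns) p@steps$p1[ns] else NA_real_
    out$last_p2 <- if (ns) p@steps$p2[ns] else NA_real_
    out
  }))
}

#' Leave-one-class-out prediction of an unknown terminal class
#'
#' Removes every sample of `targetLeaf` from the data, prunes ancestors left
#' childless, re-derives the method map and retrains the hierarchical model
#' on the remaining subset, then routes the held-out samples top-down. The
#' per-ancestor-level accuracy is the fraction of held-out samples whose
#' trajectory passes through the true ancestor at that level; the headline
#' accuracy is read at [highestPredictionLevel()] of the leaf (which moves
#' up automatically when the leaf is an only child). The whole procedure is
#' repeated `cvCfg@reps` times with re-randomized inner folds.
#'
#' @param tree a [HierarchyTree-class] over the full data.
#' @param X samples x features matrix.
#' @param labels lineage strings per sample.
#' @param targetLeaf leaf id to hold out.
#' @param cvCfg a [CVConfig-class].
#' @param predCfg a [PredictionConfig-class] (its `delta` applies).
#' @param svmCost SVM cost parameter.
#' @return list with `leaf`, `evalNode`, `evalLevel`, `perLevel`
#'   (reps x ancestor-levels percent accuracy matrix), `accuracy` (mean at
#'   the evaluation level) and `nonClassified` (mean percent halted before
#'   the evaluation level).
#' @export
leaveOneClassOut <- function(tree, X, labels, targetLeaf,
                             cvCfg = cvConfig(),
                             predCfg = predictionConfig(), svmCost = 1) {
  X <- .assertMatrix(X)
  ids <- vapply(labels, function(x) .pathId(.parseLineage(x)), "",
                USE.NAMES = FALSE)
  held <- ids == targetLeaf
  if (!any(held)) stop(sprintf("no samples labeled '%s'", targetLeaf))
  if (all(held)) stop("removing the leaf empties the tree")
  evalNode <- highestPredictionLevel(tree, targetLeaf)
  evalLevel <- nodeLevel(tree, evalNode)
  if (evalLevel == 0L) {
    stop(sprintf("leaf '%s' is not predictable above the root", targetLeaf))
  }
  subTree <- buildTree(unique(labels[!held]),
                       ragged = length(unique(nchar(gsub("[^;]", "",
                         labels)))) > 1)
  leafLevel <- nodeLevel(tree, targetLeaf)
  ancLevels <- seq_len(leafLevel - 1L)
  trueAnc <- vapply(ancLevels, .ancestorAtLevel, "", id = targetLeaf)
  perLevel <- matrix(NA_real_, cvCfg@reps, length(ancLevels),
                     dimnames = list(paste0("rep", seq_len(cvCfg@reps)),
                                     paste0("level", ancLevels)))
  ncRate <- numeric(cvCfg@reps)
  leafIdx <- match(targetLeaf, treeLeaves(tree))
  for (rep in seq_len(cvCfg@reps)) {
    seed <- .childSeed(cvCfg@seed, leafIdx, rep)
    mm <- deriveMethodMap(subTree, X[!held, , drop = FALSE], labels[!held],
                          cvCfg, seed = seed, svmCost = svmCost)
    model <- trainHCModel(subTree, X[!held, , drop = FALSE], labels[!held],
                          mm, cvCfg, svmCost = svmCost)
    res <- .assignTopdown(model, X[held, , drop = FALSE],
                          delta = predCfg@delta, maxDepth = predCfg@maxDepth)
    for (j in seq_along(ancLevels)) {
      l <- ancLevels[j]
      if (l <= ncol(res$assign)) {
        perLevel[rep, j] <- 100 * mean(!is.na(res$assign[, l]) &
                                       res$assign[, l] == trueAnc[j])
      } else {
        perLevel[rep, j] <- 0
      }
    }
    ncRate[rep] <- 100 * mean(res$status == "non_classified" &
                              (is.na(res$stopLevel) |
                               res$stopLevel <= evalLevel))
  }
  list(leaf = targetLeaf, evalNode = evalNode, evalLevel = evalLevel,
       perLevel = perLevel,
       accuracy = mean(perLevel[, paste0("level", evalLevel)]),
       nonClassified = mean(ncRate))
}
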