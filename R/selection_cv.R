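#' @include AllClasses.R AllGenerics.R utils.R hierarchy.R node_model.R
NULL

HC_METHODS <- c("PLS", "MMC-LDA", "PCA-LDA", "SVM")

#' Cross-validation configuration constructor
#'
#' @param kOuter outer stratified folds (default 5).
#' @param kInner nested inner folds used for method selection (default 5).
#' @param reps repetitions with re-randomized fold assignment (default 5).
#' @param seed integer seed; every fold assignment is derived from it plus
#'   the repetition / node index, so identical seeds reproduce runs exactly.
#' @return a [CVConfig-class].
#' @export
cvConfig <- function(kOuter = 5L, kInner = 5L, reps = 5L, seed = 1L) {
  new("CVConfig", kOuter = as.integer(kOuter), kInner = as.integer(kInner),
      reps = as.integer(reps), seed = as.integer(seed))
}

setMethod("show", "CVConfig", function(object) {
  cat(sprintf("CVConfig: %d outer x %d inner folds, %d reps, seed %d\n",
              object@kOuter, object@kInner, object@reps, object@seed))
})

# Accuracy of argmax assignment, given a probability matrix and true labels.
.argmaxAccuracy <- function(P, truth) {
  pred <- colnames(P)[max.col(P, ties.method = "first")]
  mean(pred == truth)
}

#' Select the best discriminant method for one node by inner cross-validation
#'
#' Trains all four methods on identical stratified inner folds and evaluates
#' argmax accuracy of the full node classifier (reducer plus logistic layer)
#' on each held-out inner fold. The winner has the highest mean accuracy;
#' ties go to the fixed priority PLS > MMC-LDA > PCA-LDA > SVM, which orders
#' the methods by computational cost. For PLS the component count is tuned
#' on the same folds (ties to the smaller count). The effective fold count
#' shrinks to the smallest class size when needed.
#'
#' @param X samples x features matrix for the node.
#' @param childLabels child class per sample; every class needs >= 2 samples.
#' @param cfg a [CVConfig-class]; `kInner` and `seed` are used.
#' @param children ordered child ids (default: order of appearance).
#' @param seed optional override of the fold seed.
#' @param svmCost SVM cost parameter.
#' @return list with `method` (winner tag), `k` (selected PLS components),
#'   `table` (methods x folds inner accuracy matrix) and `meanAccuracy`.
#' @export
selectNodeMethod <- function(X, childLabels, cfg = cvConfig(), children = NULL,
                         seed = cfg@seed, svmCost = 1) {
  X <- .assertMatrix(X)
  y <- as.character(childLabels)
  if (is.null(children)) children <- unique(y)
  folds <- .stratifiedFolds(y, cfg@kInner, seed, warnShrink = FALSE)
  kEff <- max(folds)
  acc <- matrix(NA_real_, length(HC_METHODS), kEff,
                dimnames = list(HC_METHODS, paste0("fold", seq_len(kEff))))
  kMax <- max(1L, min(15L, ncol(X)))
  kGrid <- unique(pmin(c(1L, 2L, 3L, 4L, 6L, 8L, 10L, 12L, 15L), kMax))
  plsAcc <- matrix(NA_real_, length(kGrid), kEff,
                   dimnames = list(paste0("k", kGrid), NULL))
  for (f in seq_len(kEff)) {
    tr <- folds != f
    te <- !tr
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    Xte <- X[te, , drop = FALSE]
    yte <- y[te]
    # PLS: fit once at the cap, then evaluate nested component counts
    red <- tryCatch(suppressWarnings(
      fitSimpls(Xtr, ytr, min(kMax, nrow(Xtr) - 1L))),
      error = function(e) NULL)
    if (!is.null(red)) {
      Str <- scoreSamples(red, Xtr)
      Ste <- scoreSamples(red, Xte)
      for (ki in seq_along(kGrid)) {
        kk <- min(kGrid[ki], red@k)
        coef <- .fitLogisticLayer(Str[, seq_len(kk), drop = FALSE], ytr,
                                  children)
        P <- .layerProba(coef, Ste[, seq_len(kk), drop = FALSE], children)
        plsAcc[ki, f] <- .argmaxAccuracy(P, yte)
      }
    }
    for (m in c("MMC-LDA", "PCA-LDA", "SVM")) {
      nm <- tryCatch(suppressWarnings(
        fitNode(Xtr, ytr, m, children = children, svmCost = svmCost,
                minPerChild = 1L)),
        error = function(e) NULL)
      if (!is.null(nm)) {
        acc[m, f] <- .argmaxAccuracy(predictNodeProba(nm, Xte), yte)
      }
    }
  }
  plsMean <- rowMeans(plsAcc)
  bestK <- if (all(is.na(plsMean))) NA_integer_ else
    kGrid[which.max(plsMean)]  # ties: smaller component count
  if (!is.na(bestK)) acc["PLS", ] <- plsAcc[which.max(plsMean), ]
  means <- rowMeans(acc)
  means[is.na(means)] <- -Inf
  winner <- HC_METHODS[which.max(means)]  # which.max keeps priority on ties
  list(method = winner, k = as.integer(bestK), table = acc,
       meanAccuracy = unname(means[winner]))
}

# Samples and class labels for a single-offspring problem at `node`:
# the single child versus the offspring of the node's sibling parents.
.singleOffspringData <- function(tree, node, labels, singleChild) {
  parent <- treeParent(tree, node)
  if (is.na(parent)) stop("cannot calibrate single-offspring node: no parent")
  sibs <- setdiff(treeChildren(tree, parent), node)
  ids <- vapply(labels, function(x) .pathId(.parseLineage(x)), "",
                USE.NAMES = FALSE)
  classes <- character(0)
  idx <- integer(0)
  lab <- character(0)
  addClass <- function(cl) {
    i <- which(startsWith(ids, paste0(cl, ";")) | ids == cl)
    if (length(i)) {
      classes <<- c(classes, cl)
      idx <<- c(idx, i)
      lab <<- c(lab, rep(cl, length(i)))
    }
  }
  addClass(singleChild)
  for (s in sibs) {
    kids <- treeChildren(tree, s)
    if (length(kids) == 0) addClass(s) else for (k in kids) addClass(k)
  }
  if (length(setdiff(classes, singleChild)) == 0) {
    stop(sprintf("cannot calibrate single-offspring node '%s': %s",
                 node, "no related classes with samples"))
  }
  list(idx = idx, labels = lab, classes = classes)
}

#' Derive the per-node method map by nested cross-validation
#'
#' Runs [selectNodeMethod()] at every internal node of the tree on that node's
#' stratified samples. Nodes with a single downstream child are included with
#' a `singleOffspring` flag: their method is selected on the extended problem
#' of the single child versus the offspring of the node's sibling parents.
#' Run this on a training portion only; inner folds never see outer test
#' samples.
#'
#' @param tree a [HierarchyTree-class].
#' @param X samples x features matrix.
#' @param labels lineage strings, one per row of `X`.
#' @param cfg a [CVConfig-class].
#' @param seed base fold seed (default `cfg@seed`).
#' @param svmCost SVM cost parameter.
#' @return a [MethodMap-class].
#' @export
deriveMethodMap <- function(tree, X, labels, cfg = cvConfig(),
                            seed = cfg@seed, svmCost = 1) {
  X <- .assertMatrix(X)
  nodes <- internalNodes(tree)
  rows <- list()
  tables <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    groups <- stratifyAtNode(tree, nd, labels)
    if (length(groups) == 0) next
    nodeSeed <- .childSeed(seed, i)
    if (length(groups) >= 2) {
      idx <- unlist(groups, use.names = FALSE)
      lab <- rep(names(groups), lengths(groups))
      sel <- selectNodeMethod(X[idx, , drop = FALSE], lab, cfg,
                          children = names(groups), seed = nodeSeed,
                          svmCost = svmCost)
      so <- FALSE
    } else {
      sd <- .singleOffspringData(tree, nd, labels, names(groups)[1])
      sel <- selectNodeMethod(X[sd$idx, , drop = FALSE], sd$labels, cfg,
                          children = sd$classes, seed = nodeSeed,
                          svmCost = svmCost)
      so <- TRUE
    }
    rows[[nd]] <- data.frame(node = nd, method = sel$method,
                             k = ifelse(is.na(sel$k), NA_integer_, sel$k),
                             singleOffspring = so,
                             meanAccuracy = sel$meanAccuracy,
                             stringsAsFactors = FALSE)
    tables[[nd]] <- sel$table
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  new("MethodMap", map = map, tables = tables)
}

setMethod("show", "MethodMap", function(object) {
  cat(sprintf("MethodMap over %d nodes:\n", nrow(object@map)))
  tab <- table(object@map$method)
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})

#' Train the full hierarchical classification model
#'
#' Fits one [NodeModel-class] per internal node carrying data, using the
#' method (and PLS component count) recorded in the method map. Nodes
#' flagged single-offspring get the extended single-child-versus-relatives
#' model.
#'
#' @param tree a [HierarchyTree-class].
#' @param X samples x features matrix.
#' @param labels lineage strings per sample.
#' @param methodMap a [MethodMap-class]; derived on the fly with `cfg` when
#'   `NULL`.
#' @param cfg a [CVConfig-class] (used when `methodMap` is `NULL`).
#' @param svmCost SVM cost parameter.
#' @return an [HCModel-class].
#' @export
trainHCModel <- function(tree, X, labels, methodMap = NULL,
                         cfg = cvConfig(), svmCost = 1) {
  X <- .assertMatrix(X)
  if (is.null(methodMap)) methodMap <- deriveMethodMap(tree, X, labels, cfg,
                                                       svmCost = svmCost)
  models <- list()
  for (r in seq_len(nrow(methodMap@map))) {
    nd <- methodMap@map$node[r]
    method <- methodMap@map$method[r]
    k <- methodMap@map$k[r]
    if (is.na(k)) k <- NULL
    if (methodMap@map$singleOffspring[r]) {
      groups <- stratifyAtNode(tree, nd, labels)
      sd <- .singleOffspringData(tree, nd, labels, names(groups)[1])
      models[[nd]] <- fitSingleOffspring(X[sd$idx, , drop = FALSE],
                                         sd$labels, names(groups)[1],
                                         method, k = k, svmCost = svmCost,
                                         node = nd)
    } else {
      groups <- stratifyAtNode(tree, nd, labels)
      idx <- unlist(groups, use.names = FALSE)
      lab <- rep(names(groups), lengths(groups))
      models[[nd]] <- fitNode(X[idx, , drop = FALSE], lab, method,
                              children = names(groups), k = k,
                              svmCost = svmCost, node = nd,
                              minPerChild = 1L)
    }
  }
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(X)))
  new("HCModel", tree = tree, methodMap = methodMap, nodeModels = models,
      featureNames = fn, config = cfg)
}

setMethod("show", "HCModel", function(object) {
  cat(sprintf("HCModel: %d node models over a depth-%d tree (%d leaves), %d features\n",
              length(object@nodeModels), object@tree@depth,
              length(treeLeaves(object@tree)), length(object@featureNames)))
  show(object@methodMap)
})

# Group-wise top-down assignment. Returns per-sample class id at each level
# (NA once the descent stops), terminal status and stop level.
.assignTopdown <- function(model, X, delta = 0, maxDepth = Inf) {
  X <- .assertMatrix(X)
  n <- nrow(X)
  depth <- model@tree@depth
  assign <- matrix(NA_character_, n, depth)
  status <- rep("leaf", n)
  stopLevel <- rep(NA_integer_, n)
  tree <- model@tree
  descend <- function(node, idx) {
    lv <- nodeLevel(tree, node)
    if (lv >= maxDepth || length(treeChildren(tree, node)) == 0) return()
    nm <- model@nodeModels[[node]]
    if (is.null(nm)) stop(sprintf("untrained node '%s' encountered", node))
    P <- predictNodeProba(nm, X[idx, , drop = FALSE])
    if (nm@singleOffspring) {
      amax <- nm@classes[max.col(P, ties.method = "first")]
      ok <- amax == nm@children[1]
      bad <- idx[!ok]
      if (length(bad)) {
        status[bad] <<- "non_classified"
        stopLevel[bad] <<- lv + 1L
      }
      good <- idx[ok]
      if (length(good)) {
        assign[good, lv + 1L] <<- nm@children[1]
        descend(nm@children[1], good)
      }
    } else {
      o1 <- max.col(P, ties.method = "first")
      p1 <- P[cbind(seq_along(idx), o1)]
      P2 <- P
      P2[cbind(seq_along(idx), o1)] <- -Inf
      p2 <- apply(P2, 1, max)
      halt <- (p1 - p2) < delta
      bad <- idx[halt]
      if (length(bad)) {
        status[bad] <<- "non_classified"
        stopLevel[bad] <<- lv + 1L
      }
      kid <- nm@children[o1]
      for (ch in unique(kid[!halt])) {
        sub <- idx[!halt & kid == ch]
        assign[sub, lv + 1L] <<- ch
        descend(ch, sub)
      }
    }
  }
  if (n > 0) descend(ROOT_ID, seq_len(n))
  list(assign = assign, status = status, stopLevel = stopLevel)
}

#' Repeated outer cross-validation with per-level confusion matrices
#'
#' For every repetition and outer fold: the method map is derived by nested
#' cross-validation on the training portion only, the full hierarchical
#' model is trained on it, and the outer test portion is classified top-down
#' (threshold 0, so every sample descends to a leaf unless halted by a
#' single-offspring rule). Per-level confusion matrices (with a
#' `non_classified` column) are accumulated, and percent accuracies are
#' averaged over repetitions.
#'
#' @param tree a [HierarchyTree-class].
#' @param X samples x features matrix.
#' @param labels lineage strings per sample.
#' @param cfg a [CVConfig-class].
#' @param svmCost SVM cost parameter.
#' @param verbose print per-repetition progress.
#' @return a [ConfusionReport-class].
#' @export
crossValidate <- function(tree, X, labels, cfg = cvConfig(), svmCost = 1,
                          verbose = FALSE) {
  X <- .assertMatrix(X)
  depth <- tree@depth
  ids <- vapply(labels, function(x) .pathId(.parseLineage(x)), "",
                USE.NAMES = FALSE)
  trueAt <- sapply(seq_len(depth), function(l) {
    vapply(ids, .ancestorAtLevel, "", level = l, USE.NAMES = FALSE)
  })
  if (is.null(dim(trueAt))) trueAt <- matrix(trueAt, nrow = length(ids))
  levClasses <- lapply(seq_len(depth), function(l) {
    tree@nodes$id[tree@nodes$level == l]
  })
  confusion <- lapply(seq_len(depth), function(l) {
    cls <- levClasses[[l]]
    matrix(0L, length(cls), length(cls) + 1L,
           dimnames = list(cls, c(cls, "non_classified")))
  })
  accuracy <- matrix(NA_real_, cfg@reps, depth,
                     dimnames = list(paste0("rep", seq_len(cfg@reps)),
                                     paste0("level", seq_len(depth))))
  accuracyCO <- accuracy
  nodeHit <- nodeTot <- structure(numeric(length(internalNodes(tree))),
                                  names = internalNodes(tree))
  for (rep in seq_len(cfg@reps)) {
    folds <- .stratifiedFolds(ids, cfg@kOuter, .childSeed(cfg@seed, rep),
                              warnShrink = FALSE)
    pred <- matrix(NA_character_, length(ids), depth)
    status <- rep(NA_character_, length(ids))
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      mapSeed <- .childSeed(cfg@seed, rep, f)
      mm <- deriveMethodMap(tree, X[tr, , drop = FALSE], labels[tr], cfg,
                            seed = mapSeed, svmCost = svmCost)
      model <- trainHCModel(tree, X[tr, , drop = FALSE], labels[tr], mm,
                            cfg, svmCost = svmCost)
      res <- .assignTopdown(model, X[!tr, , drop = FALSE], delta = 0)
      pred[!tr, ] <- res$assign
      status[!tr] <- res$status
    }
    for (l in seq_len(depth)) {
      p <- pred[, l]
      p[is.na(p)] <- "non_classified"
      valid <- trueAt[, l] %in% rownames(confusion[[l]])
      tt <- table(factor(trueAt[valid, l], levels = rownames(confusion[[l]])),
                  factor(p[valid], levels = colnames(confusion[[l]])))
      confusion[[l]] <- confusion[[l]] + as.matrix(unclass(tt))
      accuracy[rep, l] <- 100 * mean(p[valid] == trueAt[valid, l])
      cls <- p[valid] != "non_classified"
      accuracyCO[rep, l] <- if (any(cls)) {
        100 * mean(p[valid][cls] == trueAt[valid, l][cls])
      } else NA_real_
    }
    for (nd in names(nodeHit)) {
      lv <- nodeLevel(tree, nd)
      under <- if (nd == ROOT_ID) rep(TRUE, length(ids)) else {
        trueAt[, lv] == nd
      }
      reached <- if (lv == 0) under else under & !is.na(pred[, lv]) &
        pred[, lv] == nd
      if (any(reached)) {
        nodeTot[nd] <- nodeTot[nd] + sum(reached)
        nodeHit[nd] <- nodeHit[nd] +
          sum(!is.na(pred[reached, lv + 1L]) &
              pred[reached, lv + 1L] == trueAt[reached, lv + 1L])
      }
    }
    if (verbose) {
      message(sprintf("rep %d/%d: %s", rep, cfg@reps,
                      paste(sprintf("L%d=%.1f%%", seq_len(depth),
                                    accuracy[rep, ]), collapse = " ")))
    }
  }
  nodeAcc <- ifelse(nodeTot > 0, 100 * nodeHit / nodeTot, NA_real_)
  new("ConfusionReport", levels = seq_len(depth), confusion = confusion,
      accuracy = accuracy, accuracyClassifiedOnly = accuracyCO,
      nodeAccuracy = nodeAcc, config = cfg)
}

#' Summarize a confusion report
#'
#' @param report a [ConfusionReport-class].
#' @return data.frame with per-level mean and sd percent accuracy over
#'   repetitions (non-classified counted as incorrect), plus the
#'   classified-only variant.
#' @export
accuracySummary <- function(report) {
  data.frame(
    level = report@levels,
    meanAccuracy = colMeans(report@accuracy),
    sdAccuracy = apply(report@accuracy, 2, stats::sd),
    meanAccuracyClassifiedOnly = colMeans(report@accuracyClassifiedOnly,
                                          na.rm = TRUE),
    row.names = NULL
  )
}

setMethod("show", "ConfusionReport", function(object) {
  cat(sprintf("ConfusionReport: %d levels, %d repetitions\n",
              length(object@levels), nrow(object@accuracy)))
  s <- accuracySummary(object)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  level %d: %.1f +/- %.1f %%\n", s$level[i],
                s$meanAccuracy[i], s$sdAccuracy[i]))
  }
})

#' Export a confusion report to disk
#'
#' Writes one CSV per level (true classes x predicted classes plus a
#' `non_classified` column) and a JSON accuracy summary.
#'
#' @param report a [ConfusionReport-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeConfusionReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in report@levels) {
    utils::write.csv(report@confusion[[l]],
                     file.path(dir, sprintf("confusion_level%d.csv", l)))
  }
  s <- accuracySummary(report)
  jsonlite::write_json(
    lapply(seq_len(nrow(s)), function(i) {
      list(level = s$level[i], mean = s$meanAccuracy[i],
           sd = s$sdAccuracy[i],
           mean_classified_only = s$meanAccuracyClassifiedOnly[i])
    }),
    file.path(dir, "accuracy_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
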