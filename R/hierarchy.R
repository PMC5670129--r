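#' @include AllClasses.R AllGenerics.R utils.R
NULL

ROOT_ID <- "<root>"

.parseLineage <- function(x) {
  parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  if (length(parts) == 0 || any(!nzchar(parts))) {
    stop(sprintf("lineage '%s' has empty components", x), call. = FALSE)
  }
  parts
}

.pathId <- function(parts) paste(parts, collapse = ";")

#' Build a class taxonomy tree from lineage labels
#'
#' Constructs the unique minimal rooted tree containing every lineage as a
#' root-to-leaf path. Children are stored in first-seen order. Identical
#' display names under different parents are distinct nodes (node identity is
#' the full path), so e.g. repeated species epithets across genera never
#' collide.
#'
#' @param labels character vector of semicolon-delimited lineage strings
#'   (top level first), e.g. `"Gram-negative;Gammaproteobacteria;...;E. coli"`.
#'   Leading/trailing whitespace around components is stripped.
#' @param ragged if `FALSE` (default) all lineages must have equal depth;
#'   `TRUE` permits leaves at different depths.
#' @return a [HierarchyTree-class].
#' @examples
#' tr <- buildTree(c("A;B", "A;C", "D;E"))
#' treeLeaves(tr)
#' @export
buildTree <- function(labels, ragged = FALSE) {
  if (length(labels) < 1) stop("at least one lineage label is required")
  parsed <- lapply(unique(labels), .parseLineage)
  depths <- lengths(parsed)
  if (!ragged && length(unique(depths)) > 1) {
    stop("lineages have unequal depth; pass ragged = TRUE to allow this")
  }
  ids <- ROOT_ID
  nms <- ROOT_ID
  parents <- NA_character_
  levels <- 0L
  seen <- new.env(hash = TRUE)
  assign(ROOT_ID, TRUE, envir = seen)
  for (parts in parsed) {
    for (l in seq_along(parts)) {
      id <- .pathId(parts[seq_len(l)])
      if (!exists(id, envir = seen, inherits = FALSE)) {
        assign(id, TRUE, envir = seen)
        ids <- c(ids, id)
        nms <- c(nms, parts[l])
        parents <- c(parents, if (l == 1) ROOT_ID else .pathId(parts[seq_len(l - 1)]))
        levels <- c(levels, l)
      }
    }
  }
  nodes <- data.frame(id = ids, name = nms, parent = parents,
                      level = as.integer(levels), stringsAsFactors = FALSE)
  new("HierarchyTree", nodes = nodes, depth = max(nodes$level))
}

#' @describeIn buildTree Children ids of a node, in first-seen order.
#' @param tree a [HierarchyTree-class].
#' @param node a node id (full path; `"<root>"` for the root).
#' @export
treeChildren <- function(tree, node) {
  tree@nodes$id[!is.na(tree@nodes$parent) & tree@nodes$parent == node]
}

#' @describeIn buildTree Parent id of a node (`NA` for the root).
#' @export
treeParent <- function(tree, node) {
  tree@nodes$parent[match(node, tree@nodes$id)]
}

#' @describeIn buildTree Ids of all leaves.
#' @export
treeLeaves <- function(tree) {
  setdiff(tree@nodes$id, tree@nodes$parent[!is.na(tree@nodes$parent)])
}

#' @describeIn buildTree Level of a node (root = 0).
#' @export
nodeLevel <- function(tree, node) {
  tree@nodes$level[match(node, tree@nodes$id)]
}

#' @describeIn buildTree Internal (non-leaf) node ids, shallowest first.
#' @export
internalNodes <- function(tree) {
  int <- setdiff(unique(tree@nodes$parent[!is.na(tree@nodes$parent)]), NA)
  int[order(tree@nodes$level[match(int, tree@nodes$id)])]
}

.ancestorAtLevel <- function(id, level) {
  if (level == 0L) return(ROOT_ID)
  parts <- strsplit(id, ";", fixed = TRUE)[[1]]
  if (level > length(parts)) return(NA_character_)
  .pathId(parts[seq_len(level)])
}

#' @rdname lineages
#' @export
setMethod("lineages", "HierarchyTree", function(object, ...) {
  treeLeaves(object)
})

setMethod("show", "HierarchyTree", function(object) {
  cat(sprintf("HierarchyTree: %d nodes, %d leaves, depth %d\n",
              nrow(object@nodes) - 1L, length(treeLeaves(object)),
              object@depth))
  lv <- table(object@nodes$level[object@nodes$level > 0])
  cat("  nodes per level:", paste(sprintf("L%s=%d", names(lv), lv),
                                  collapse = ", "), "\n")
})

#' Stratify samples at a node into its immediate children
#'
#' Each sample whose lineage passes through `node` is assigned to exactly one
#' immediate child; samples not descending through `node` are excluded. The
#' returned groups partition the samples under the node.
#'
#' @param tree a [HierarchyTree-class].
#' @param node an internal node id.
#' @param labels character vector of lineage strings, one per sample.
#' @return named list mapping child id to integer sample indices.
#' @export
stratifyAtNode <- function(tree, node, labels) {
  kids <- treeChildren(tree, node)
  if (length(kids) == 0) {
    stop(sprintf("node '%s' is a leaf: no children to stratify", node))
  }
  lv <- nodeLevel(tree, node)
  ids <- vapply(labels, function(x) .pathId(.parseLineage(x)), "",
                USE.NAMES = FALSE)
  under <- if (node == ROOT_ID) rep(TRUE, length(ids)) else {
    startsWith(ids, paste0(node, ";")) | ids == node
  }
  groups <- lapply(kids, function(k) {
    which(under & (startsWith(ids, paste0(k, ";")) | ids == k))
  })
  names(groups) <- kids
  groups[lengths(groups) > 0]
}

#' Deepest taxonomy level at which a held-out leaf remains predictable
#'
#' When a terminal class is removed from training, its identity can only be
#' predicted down to the deepest ancestor that still exists in the pruned
#' tree, i.e. an ancestor whose presence is not conditional on the held-out
#' leaf because other leaves share it. Ancestors left childless by the
#' removal are pruned away.
#'
#' @param tree a [HierarchyTree-class].
#' @param leaf a leaf id.
#' @return the id of the deepest surviving proper ancestor (possibly the
#'   root).
#' @export
highestPredictionLevel <- function(tree, leaf) {
  lvs <- treeLeaves(tree)
  if (!leaf %in% lvs) stop(sprintf("'%s' is not a leaf of the tree", leaf))
  if (length(lvs) < 2) {
    stop("tree has a single leaf: nothing is predictable without it")
  }
  other <- setdiff(lvs, leaf)
  anc <- treeParent(tree, leaf)
  while (anc != ROOT_ID) {
    hasOther <- any(startsWith(other, paste0(anc, ";")))
    if (hasOther) return(anc)
    anc <- treeParent(tree, anc)
  }
  ROOT_ID
}

#' Read a two-column lineage label file
#'
#' Expects a UTF-8 TSV with columns `sample_id<TAB>lineage` where lineages
#' use `;` separators; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id` and `lineage`.
#' @export
readLineageFile <- function(path) {
  ln <- readLines(path, encoding = "UTF-8")
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop(sprintf("malformed label line %d in '%s'", bad[1], path))
  }
  data.frame(sample_id = trimws(vapply(parts, `[`, "", 1)),
             lineage = trimws(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' @describeIn readLineageFile Write lineage labels in the same format.
#' @param ids sample ids.
#' @param lineageStrings lineage strings, parallel to `ids`.
#' @export
writeLineageFile <- function(ids, lineageStrings, path) {
  writeLines(paste(ids, lineageStrings, sep = "\t"), path, useBytes = TRUE)
}

.treeToNested <- function(tree, node = ROOT_ID) {
  kids <- treeChildren(tree, node)
  out <- list(name = tree@nodes$name[match(node, tree@nodes$id)],
              level = nodeLevel(tree, node))
  if (length(kids)) out$children <- lapply(kids, .treeToNested, tree = tree)
  out
}

#' Export a taxonomy tree
#'
#' `writeTreeJSON()` writes a nested-children JSON representation;
#' `treeEdges()` returns (and `writeTreeTSV()` writes) a flat parent-child
#' table.
#'
#' @param tree a [HierarchyTree-class].
#' @param path output file path.
#' @export
writeTreeJSON <- function(tree, path) {
  jsonlite::write_json(.treeToNested(tree), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTreeJSON
#' @export
treeEdges <- function(tree) {
  nd <- tree@nodes[!is.na(tree@nodes$parent), c("parent", "id", "name", "level")]
  rownames(nd) <- NULL
  names(nd) <- c("parent", "child", "child_name", "level")
  nd
}

#' @rdname writeTreeJSON
#' @export
writeTreeTSV <- function(tree, path) {
  utils::write.table(treeEdges(tree), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
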