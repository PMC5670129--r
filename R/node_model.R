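#' @include AllClasses.R AllGenerics.R utils.R reducers.R
NULL

.defaultPlsK <- function(n, d) max(1L, min(15L, n - 1L, d))

.fitReducer <- function(X, y, method, k = NULL, svmCost = 1) {
  switch(method,
    "PLS" = fitSimpls(X, y, if (is.null(k)) .defaultPlsK(nrow(X), ncol(X))
                            else min(k, .defaultPlsK(nrow(X), ncol(X)))),
    "MMC-LDA" = fitMmcLda(X, y),
    "PCA-LDA" = fitPcaLda(X, y),
    "SVM" = fitLinearSvm(X, y, C = svmCost),
    stop(sprintf("unknown method '%s'", method))
  )
}

# One-vs-all logistic layer over reducer scores; one column per class, or a
# single column applied symmetrically when there are exactly two classes.
.fitLogisticLayer <- function(S, y, classes) {
  if (length(classes) == 2) {
    beta <- .fitLogistic(S, as.numeric(y == classes[1]))
    matrix(beta, ncol = 1, dimnames = list(NULL, classes[1]))
  } else {
    vapply(classes, function(cl) .fitLogistic(S, as.numeric(y == cl)),
           numeric(ncol(S) + 1))
  }
}

.layerProba <- function(coef, S, classes) {
  if (length(classes) == 2) {
    p1 <- .predictLogistic(coef[, 1], S)
    P <- cbind(p1, 1 - p1)
  } else {
    P <- apply(coef, 2, .predictLogistic, S = S)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    rs <- rowSums(P)
    rs[rs == 0] <- 1
    P <- P / rs
  }
  colnames(P) <- classes
  P
}

#' Fit the probabilistic classifier of one tree node
#'
#' Fits the chosen discriminant method on the node's stratified data and a
#' one-vs-all logistic layer on its scores, yielding a probability
#' distribution over the node's children. Probabilities are obtained by
#' normalizing the per-child one-vs-all logistic outputs; with exactly two
#' children a single symmetric model is used so the two probabilities sum to
#' one exactly.
#'
#' @param X samples x features matrix for the samples under this node.
#' @param childLabels child class id per sample.
#' @param method method tag: `"PLS"`, `"MMC-LDA"`, `"PCA-LDA"` or `"SVM"`.
#' @param children ordered child ids (defaults to order of appearance); fixes
#'   the probability column order and argmax tie-breaking.
#' @param k PLS component count (`NULL` = `min(15, n - 1, d)`).
#' @param svmCost SVM cost parameter.
#' @param node node id stored in the model (bookkeeping only).
#' @param minPerChild minimum samples per child (default 2); a child below
#'   the minimum raises an error naming it.
#' @return a [NodeModel-class].
#' @export
fitNode <- function(X, childLabels, method, children = NULL, k = NULL,
                    svmCost = 1, node = "", minPerChild = 2L) {
  X <- .assertMatrix(X)
  y <- as.character(childLabels)
  if (is.null(children)) children <- unique(y)
  if (length(children) < 2) {
    stop("fewer than 2 distinct children; use fitSingleOffspring")
  }
  sizes <- table(factor(y, levels = children))
  small <- names(sizes)[sizes < minPerChild]
  if (length(small)) {
    stop(sprintf("child '%s' has fewer than %d samples", small[1],
                 minPerChild))
  }
  red <- .fitReducer(X, y, method, k = k, svmCost = svmCost)
  S <- scoreSamples(red, X)
  coef <- .fitLogisticLayer(S, y, children)
  new("NodeModel", node = node, method = method, reducer = red, coef = coef,
      children = children, classes = children, singleOffspring = FALSE)
}

#' Fit a single-offspring node model
#'
#' When a parent node has exactly one downstream node, a trivial classifier
#' would accept everything. Instead the single child is discriminated against
#' the offspring of its parent's sibling nodes (e.g. a genus with one species
#' is modeled against the species of the other genera in the family). At
#' prediction time a sample whose highest-probability class is not the single
#' child is flagged non-classified at this node.
#'
#' @param X samples x features for the single child plus all related classes.
#' @param classLabels class id per sample (the single child id or a related
#'   class id).
#' @param singleChild id of the single downstream node.
#' @param method method tag, as in [fitNode()].
#' @param k,svmCost,node as in [fitNode()].
#' @return a [NodeModel-class] with `singleOffspring = TRUE`.
#' @export
fitSingleOffspring <- function(X, classLabels, singleChild, method,
                               k = NULL, svmCost = 1, node = "") {
  X <- .assertMatrix(X)
  y <- as.character(classLabels)
  classes <- unique(c(singleChild, setdiff(unique(y), singleChild)))
  if (length(classes) < 2) {
    stop("cannot calibrate single-offspring node: no related classes")
  }
  red <- .fitReducer(X, y, method, k = k, svmCost = svmCost)
  S <- scoreSamples(red, X)
  coef <- .fitLogisticLayer(S, y, classes)
  new("NodeModel", node = node, method = method, reducer = red, coef = coef,
      children = singleChild, classes = classes, singleOffspring = TRUE)
}

#' Child probabilities of a node model
#'
#' Applies the node's reducer and logistic layer to new samples. Rows sum to
#' one after normalization; the argmax defines the node-level assignment.
#' For a single-offspring node the columns cover the extended class set
#' (single child first).
#'
#' @param model a [NodeModel-class].
#' @param X samples x features matrix.
#' @return probability matrix, samples x classes.
#' @export
predictNodeProba <- function(model, X) {
  S <- scoreSamples(model@reducer, X)
  .layerProba(model@coef, S, model@classes)
}

setMethod("show", "NodeModel", function(object) {
  cat(sprintf("NodeModel[%s]: %s over %d class(es)%s\n",
              if (nzchar(object@node)) object@node else "?", object@method,
              length(object@classes),
              if (object@singleOffspring) " (single-offspring)" else ""))
})
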