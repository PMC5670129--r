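#' @import methods
NULL

#' Class taxonomy tree
#'
#' A rooted, labeled tree of classes. Leaves are terminal classes (species,
#' cancer subtypes, ...); internal nodes are higher taxa. Node identity is the
#' full path from the root, so identical display names under different parents
#' are distinct nodes. The root has level 0 and the reserved id `"<root>"`.
#'
#' @slot nodes data.frame with columns `id` (full semicolon-joined path),
#'   `name` (display name), `parent` (parent id, `NA` for the root) and
#'   `level` (integer depth, root = 0). Rows are in first-seen order, which
#'   fixes the child order used throughout.
#' @slot depth integer; the maximum leaf level.
#' @seealso [buildTree()], [stratifyAtNode()], [highestPredictionLevel()]
#' @export
setClass("HierarchyTree",
  representation(nodes = "data.frame", depth = "integer"),
  validity = function(object) {
    nd <- object@nodes
    req <- c("id", "name", "level", "parent")
    if (!all(req %in% names(nd))) {
      return(sprintf("nodes must have columns %s", paste(req, collapse = ", ")))
    }
    if (sum(is.na(nd$parent)) != 1L) return("exactly one root is required")
    if (anyDuplicated(nd$id)) return("node ids must be unique")
    root <- nd$id[is.na(nd$parent)]
    if (nd$level[nd$id == root] != 0L) return("root must be at level 0")
    nonroot <- nd[!is.na(nd$parent), , drop = FALSE]
    if (nrow(nonroot)) {
      if (!all(nonroot$parent %in% nd$id)) return("dangling parent pointer")
      plev <- nd$level[match(nonroot$parent, nd$id)]
      if (!all(nonroot$level == plev + 1L)) {
        return("level(child) must equal level(parent) + 1")
      }
      key <- paste(nonroot$parent, nonroot$name, sep = "\r")
      if (anyDuplicated(key)) {
        return("node display names must be unique within a parent's children")
      }
    }
    TRUE
  }
)

#' Fitted dimensionality-reduction / discriminant model
#'
#' Common container for the four per-node discriminant methods. For the
#' projection methods (`"PLS"`, `"MMC-LDA"`, `"PCA-LDA"`) `W` holds projection
#' weights (features x components); for `"SVM"` it holds one-vs-all linear
#' hyperplane normals (features x classes) with `intercepts` the matching
#' offsets. Scores of new data are always `sweep(X, 2, center) %*% W`
#' (plus intercepts for SVM).
#'
#' @slot method one of `"PLS"`, `"MMC-LDA"`, `"PCA-LDA"`, `"SVM"`.
#' @slot W numeric matrix of projection weights or hyperplane normals.
#' @slot center numeric; training column means subtracted before projection.
#' @slot k integer; number of components / columns of `W`.
#' @slot classes character; class labels seen at fit time, in training order.
#' @slot intercepts numeric; per-class offsets (SVM only, else length 0).
#' @slot extra list; method-specific diagnostics (eigenvalues, x-loadings ...).
#' @export
setClass("ReducedModel",
  representation(method = "character", W = "matrix", center = "numeric",
                 k = "integer", classes = "character",
                 intercepts = "numeric", extra = "list"),
  validity = function(object) {
    if (!object@method %in% c("PLS", "MMC-LDA", "PCA-LDA", "SVM")) {
      return("unknown method tag")
    }
    if (nrow(object@W) != length(object@center)) {
      return("W rows must match centering vector length")
    }
    TRUE
  }
)

#' Per-node probabilistic classifier
#'
#' A [ReducedModel-class] plus a one-vs-all logistic layer over its scores.
#' At a regular node `classes` equals `children`; at a single-offspring node
#' `children` is the single downstream node while `classes` additionally holds
#' the related classes (offspring of sibling parents) it is calibrated
#' against.
#'
#' @slot node node id this model belongs to.
#' @slot method the selected method tag.
#' @slot reducer the fitted [ReducedModel-class].
#' @slot coef logistic coefficients, (k + 1) x n_models; one column per class
#'   (one single column when there are exactly two classes).
#' @slot children ids of the child classes this node assigns among.
#' @slot classes class ids of the logistic layer, in column order.
#' @slot singleOffspring logical flag for the single-offspring rule.
#' @export
setClass("NodeModel",
  representation(node = "character", method = "character",
                 reducer = "ReducedModel", coef = "matrix",
                 children = "character", classes = "character",
                 singleOffspring = "logical"))

#' Cross-validation configuration
#'
#' @slot kOuter outer stratified folds (default 5).
#' @slot kInner inner (nested) stratified folds (default 5).
#' @slot reps number of repetitions with re-randomized folds (default 5).
#' @slot seed integer random seed; all fold assignment derives from it.
#' @export
setClass("CVConfig",
  representation(kOuter = "integer", kInner = "integer",
                 reps = "integer", seed = "integer"),
  validity = function(object) {
    if (object@kOuter < 2L || object@kInner < 2L) return("folds must be >= 2")
    if (object@reps < 1L) return("reps must be >= 1")
    TRUE
  }
)

#' Per-node method map
#'
#' Records, for every internal node carrying data, which discriminant method
#' won the nested cross-validation, the selected PLS component count where
#' relevant, and the per-method inner-CV accuracy table.
#'
#' @slot map data.frame with columns `node`, `method`, `k`,
#'   `singleOffspring` and `meanAccuracy`.
#' @slot tables named list (by node id) of methods x folds inner accuracy
#'   matrices.
#' @export
setClass("MethodMap",
  representation(map = "data.frame", tables = "list"))

#' Trained hierarchical classification model
#'
#' @slot tree the [HierarchyTree-class] trained over.
#' @slot methodMap the [MethodMap-class] used.
#' @slot nodeModels named list of [NodeModel-class], one per trained node.
#' @slot featureNames feature names the model expects, in order.
#' @slot config the [CVConfig-class] used for method selection.
#' @export
setClass("HCModel",
  representation(tree = "HierarchyTree", methodMap = "MethodMap",
                 nodeModels = "list", featureNames = "character",
                 config = "CVConfig"))

#' Prediction configuration
#'
#' @slot delta probability-difference threshold in `[0, 1]`: at each node,
#'   a sample whose top-two child probabilities differ by less than `delta`
#'   halts as non-classified (default 0.05).
#' @slot maxDepth deepest level to descend to (default `Inf` = full depth).
#' @export
setClass("PredictionConfig",
  representation(delta = "numeric", maxDepth = "numeric"),
  validity = function(object) {
    if (object@delta < 0 || object@delta > 1) return("delta must be in [0, 1]")
    TRUE
  }
)

#' Per-sample top-down prediction trajectory
#'
#' @slot sample sample identifier.
#' @slot steps data.frame with one row per visited node: `node`, `assigned`
#'   (child id or `NA` when non-classified), `p1`, `p2` (top-two child
#'   probabilities).
#' @slot probs list of named per-node probability vectors (same order).
#' @slot status `"leaf"` or `"non_classified"`.
#' @slot level terminal level reached (level of the deepest confident class).
#' @slot finalClass id of the deepest confidently assigned class.
#' @export
setClass("PredictionPath",
  representation(sample = "character", steps = "data.frame", probs = "list",
                 status = "character", level = "integer",
                 finalClass = "character"))

#' Repeated cross-validation confusion report
#'
#' @slot levels integer vector of hierarchy levels reported (1..depth).
#' @slot confusion named list (by level) of square confusion matrices over
#'   that level's classes plus a final `non_classified` column, summed over
#'   repetitions and outer folds.
#' @slot accuracy repetitions x levels matrix of percent accuracy
#'   (non-classified counted as incorrect).
#' @slot accuracyClassifiedOnly same, with non-classified samples excluded
#'   from the denominator.
#' @slot nodeAccuracy named numeric; mean per-node assignment accuracy.
#' @slot config the [CVConfig-class] used.
#' @export
setClass("ConfusionReport",
  representation(levels = "integer", confusion = "list", accuracy = "matrix",
                 accuracyClassifiedOnly = "matrix",
                 nodeAccuracy = "numeric", config = "CVConfig"))

#' Raw profile mass spectrum
#'
#' @slot mz m/z values in Da, strictly increasing.
#' @slot intensity non-negative intensities, same length as `mz`.
#' @slot sample sample identifier.
#' @slot replicate replicate index within the sample.
#' @export
setClass("Spectrum",
  representation(mz = "numeric", intensity = "numeric",
                 sample = "character", replicate = "integer"),
  validity = function(object) {
    if (length(object@mz) != length(object@intensity)) {
      return("mz and intensity must have equal length")
    }
    if (length(object@mz) > 1 && any(diff(object@mz) <= 0)) {
      return("mz must be strictly increasing")
    }
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    TRUE
  }
)

#' Spectral binning configuration
#'
#' @slot resolution bin width in Da (default 0.001).
#' @slot range two-element m/z range in Da (default `c(150, 2000)`).
#' @export
setClass("BinningConfig",
  representation(resolution = "numeric", range = "numeric"),
  validity = function(object) {
    if (object@resolution <= 0) return("resolution must be > 0")
    if (length(object@range) != 2 || object@range[1] >= object@range[2]) {
      return("range must be c(min, max) with min < max")
    }
    TRUE
  }
)

#' Detected peak list for one spectrum
#'
#' @slot mz apex m/z values (bin centers).
#' @slot intensity apex intensities.
#' @slot sample source sample id.
#' @slot replicate source replicate index.
#' @export
setClass("PeakList",
  representation(mz = "numeric", intensity = "numeric",
                 sample = "character", replicate = "integer"))

#' Annotated expression table
#'
#' @slot counts samples x genes non-negative matrix (rownames = sample ids).
#' @slot meta data.frame with columns `sample_id`, `patient_id`,
#'   `tissue_status`, `type`, `subtype`; one row per sample, aligned with
#'   `counts`.
#' @export
setClass("AnnotatedTable",
  representation(counts = "matrix", meta = "data.frame"),
  validity = function(object) {
    req <- c("sample_id", "patient_id", "tissue_status", "type", "subtype")
    if (!all(req %in% names(object@meta))) {
      return(sprintf("meta must have columns %s", paste(req, collapse = ", ")))
    }
    if (nrow(object@counts) != nrow(object@meta)) {
      return("counts rows and meta rows must align")
    }
    if (!identical(rownames(object@counts), object@meta$sample_id)) {
      return("rownames(counts) must equal meta$sample_id")
    }
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(is.na(object@meta$patient_id))) {
      return("every sample needs a patient id")
    }
    TRUE
  }
)
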