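#' Project new samples into a fitted model's score space
#'
#' Applies the stored training centering and then the projection (or, for the
#' SVM, the one-vs-all linear decision functions) of a fitted model to new
#' data. Scoring the training matrix reproduces the stored training scores.
#'
#' @param object a fitted [ReducedModel-class].
#' @param X numeric matrix (samples x features) with the training feature
#'   count.
#' @return numeric score matrix, samples x k (or samples x classes for SVM).
#' @export
setGeneric("scoreSamples", function(object, X) standardGeneric("scoreSamples"))

#' Lineage strings of a taxonomy object
#'
#' @param object an object carrying class lineages.
#' @param ... further arguments for methods.
#' @return character vector of semicolon-delimited lineages.
#' @export
setGeneric("lineages", function(object, ...) standardGeneric("lineages"))
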