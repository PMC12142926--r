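#' Extract the underlying data.frame of a surveillance object
#' @param x An object holding surveillance rows.
#' @return A `data.frame`.
#' @export
setGeneric("strataData", function(x) standardGeneric("strataData"))

#' Declared category level sets
#' @param x An object carrying declared level sets.
#' @return Named list of character vectors.
#' @export
setGeneric("levelSets", function(x) standardGeneric("levelSets"))

#' Number of strata (rows)
#' @param x A surveillance object.
#' @return Integer row count.
#' @export
setGeneric("nStrata", function(x) standardGeneric("nStrata"))

#' Posterior draws as a flat matrix
#'
#' Flattens the (iteration, chain, parameter) array chain-major into a
#' `draws x parameters` matrix.
#' @param x A [PosteriorDraws] object.
#' @return Numeric matrix.
#' @export
setGeneric("drawsMatrix", function(x) standardGeneric("drawsMatrix"))

#' Posterior draws as a 3-d array
#' @param x A [PosteriorDraws] object.
#' @return Array `iterations x chains x parameters`.
#' @export
setGeneric("drawsArray", function(x) standardGeneric("drawsArray"))

#' Parameter names of a fitted object
#' @param x A fitted object.
#' @return Character vector in the shared naming convention.
#' @export
setGeneric("parameterNames", function(x) standardGeneric("parameterNames"))

#' Model specification of a fitted object
#' @param x A fitted object.
#' @return A [ModelSpec].
#' @export
setGeneric("fittedSpec", function(x) standardGeneric("fittedSpec"))
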