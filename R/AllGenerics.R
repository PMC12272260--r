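#' @rdname renderField
#' @export
setGeneric("renderField", function(field, t = 1L, domain = c("A", "B"), ...)
  standardGeneric("renderField"))

#' @rdname groundTruthMask
#' @export
setGeneric("groundTruthMask", function(field, domain = c("A", "B"), ...)
  standardGeneric("groundTruthMask"))

#' @rdname simulateTraces
#' @export
setGeneric("simulateTraces", function(field, T, ...)
  standardGeneric("simulateTraces"))

#' @rdname encode
#' @export
setGeneric("encode", function(object, x, domain = c("A", "B"), ...)
  standardGeneric("encode"))

#' @rdname decode
#' @export
setGeneric("decode", function(object, z, domain = c("A", "B"), ...)
  standardGeneric("decode"))

#' @rdname translate
#' @export
setGeneric("translate", function(object, x, direction = c("AtoB", "BtoA"), ...)
  standardGeneric("translate"))

#' @rdname discriminate
#' @export
setGeneric("discriminate", function(object, x, domain = c("A", "B"), ...)
  standardGeneric("discriminate"))

#' Accessors for synthetic fields and models
#'
#' \code{cells} returns the cell table of a \linkS4class{CellField};
#' \code{traces} its activity-trace matrix; \code{imageSize} its c(H, W);
#' \code{nCells} the number of cells. \code{modelSpec} returns the
#' \linkS4class{TranslationSpec} of a model or config, and
#' \code{parameterCount} the number of learnable parameters per network.
#'
#' @param object a CellField, TranslationModel or TaskConfig.
#' @return See the individual descriptions.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))

#' @rdname accessors
#' @export
setGeneric("imageSize", function(object) standardGeneric("imageSize"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))

#' @rdname accessors
#' @export
setGeneric("parameterCount", function(object) standardGeneric("parameterCount"))
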