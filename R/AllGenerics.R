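# Accessor generics for the fitted model. Slots are never accessed directly
# by user code.

#' @rdname LemurFit-class
#' @param object,fit a [LemurFit-class]
#' @export
setGeneric("latentEmbedding", function(object) standardGeneric("latentEmbedding"))

#' @describeIn LemurFit-class the P x C matrix of (aligned) latent coordinates.
#' @export
setMethod("latentEmbedding", "LemurFit", function(object) object@embedding)

#' @rdname LemurFit-class
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @describeIn LemurFit-class the C x K design matrix.
#' @export
setMethod("designMatrix", "LemurFit", function(object) object@design)

#' @rdname LemurFit-class
#' @export
setGeneric("basePoint", function(object) standardGeneric("basePoint"))

#' @describeIn LemurFit-class the base subspace as a [GrassmannPoint-class].
#' @export
setMethod("basePoint", "LemurFit", function(object) object@basePoint)

#' @rdname LemurFit-class
#' @export
setGeneric("tangentCoefficients", function(object) standardGeneric("tangentCoefficients"))

#' @describeIn LemurFit-class the G x P x K tangent coefficient tensor B.
#' @export
setMethod("tangentCoefficients", "LemurFit", function(object) object@coefB)

#' @rdname LemurFit-class
#' @export
setGeneric("offsetCoefficients", function(object) standardGeneric("offsetCoefficients"))

#' @describeIn LemurFit-class the G x K offset coefficient matrix Gamma.
#' @export
setMethod("offsetCoefficients", "LemurFit", function(object) object@gamma)

#' @rdname LemurFit-class
#' @export
setGeneric("alignmentParams", function(object) standardGeneric("alignmentParams"))

#' @describeIn LemurFit-class list with the alignment tensors \code{W}
#'   (P x P x K) and \code{W0} (P x K).
#' @export
setMethod("alignmentParams", "LemurFit",
          function(object) list(W = object@alignW, W0 = object@alignW0))

#' @rdname LemurFit-class
#' @export
setGeneric("testMask", function(object) standardGeneric("testMask"))

#' @describeIn LemurFit-class logical length-C vector; TRUE marks held-out cells.
#' @export
setMethod("testMask", "LemurFit", function(object) object@testMask)

#' @rdname LemurFit-class
#' @export
setGeneric("latentDim", function(object) standardGeneric("latentDim"))

#' @describeIn LemurFit-class the latent dimension P.
#' @export
setMethod("latentDim", "LemurFit", function(object) object@latentDim)

#' @rdname LemurFit-class
#' @export
setGeneric("basis", function(object) standardGeneric("basis"))

#' @describeIn GrassmannPoint-class the orthonormal basis matrix.
#' @export
setMethod("basis", "GrassmannPoint", function(object) object@basis)

#' @rdname LemurDEResult-class
#' @param object a [LemurDEResult-class]
#' @export
setGeneric("deTable", function(object) standardGeneric("deTable"))

#' @describeIn LemurDEResult-class the per-gene statistics table.
#' @export
setMethod("deTable", "LemurDEResult", function(object) object@table)

#' @rdname LemurDEResult-class
#' @export
setGeneric("neighborhoods", function(object) standardGeneric("neighborhoods"))

#' @describeIn LemurDEResult-class the per-gene neighborhood list.
#' @export
setMethod("neighborhoods", "LemurDEResult", function(object) object@neighborhoods)

#' @rdname LemurDEResult-class
#' @export
setGeneric("deltaMatrix", function(object) standardGeneric("deltaMatrix"))

#' @describeIn LemurDEResult-class the G x C predicted-difference matrix.
#' @export
setMethod("deltaMatrix", "LemurDEResult", function(object) object@delta)
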