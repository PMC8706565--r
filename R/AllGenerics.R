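#' Accessors for package classes
#'
#' Accessor generics for [ReferenceSet-class], [ScreenResult-class],
#' [RelQuant-class] and [ERSModel-class] objects. Slot access via `@` is
#' considered internal.
#'
#' @param x an object of the appropriate class.
#' @return The slot value (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("matureSeqs", function(x) standardGeneric("matureSeqs"))
#' @rdname accessors
#' @export
setGeneric("precursorSeqs", function(x) standardGeneric("precursorSeqs"))
#' @rdname accessors
#' @export
setGeneric("mirnaSeqs", function(x) standardGeneric("mirnaSeqs"))
#' @rdname accessors
#' @export
setGeneric("loopAnnotation", function(x) standardGeneric("loopAnnotation"))
#' @rdname accessors
#' @export
setGeneric("precursorMap", function(x) standardGeneric("precursorMap"))
#' @rdname accessors
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))
#' @rdname accessors
#' @export
setGeneric("intersectionSpecies", function(x) standardGeneric("intersectionSpecies"))
#' @rdname accessors
#' @export
setGeneric("perDoseSets", function(x) standardGeneric("perDoseSets"))
#' @rdname accessors
#' @export
setGeneric("sampleRQ", function(x) standardGeneric("sampleRQ"))
#' @rdname accessors
#' @export
setGeneric("groupSummary", function(x) standardGeneric("groupSummary"))
#' @rdname accessors
#' @export
setGeneric("controlGroup", function(x) standardGeneric("controlGroup"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))
#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))
#' @rdname accessors
#' @export
setGeneric("radiationType", function(x) standardGeneric("radiationType"))
#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' Score samples with an exposure-risk model
#'
#' @param model an [ERSModel-class].
#' @param x marker values (see method documentation).
#' @param ... further arguments.
#' @export
setGeneric("scoreERS", function(model, x, ...) standardGeneric("scoreERS"))
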