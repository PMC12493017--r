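#' @rdname EffectMatrix-class
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("contributions", function(x, ...) standardGeneric("contributions"))

#' @rdname EffectMatrix-class
#' @export
setGeneric("intercept", function(x, ...) standardGeneric("intercept"))

#' @rdname EffectMatrix-class
#' @export
setGeneric("peptideLength", function(x, ...) standardGeneric("peptideLength"))

#' @rdname MutationPath-class
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("pathNodes", function(x, ...) standardGeneric("pathNodes"))

#' @rdname MutationPath-class
#' @export
setGeneric("pathLength", function(x, ...) standardGeneric("pathLength"))

#' @rdname Pattern-class
#' @param x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("patternSlots", function(x, ...) standardGeneric("patternSlots"))

#' @rdname Pattern-class
#' @export
setGeneric("patternCardinality",
           function(x, ...) standardGeneric("patternCardinality"))
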