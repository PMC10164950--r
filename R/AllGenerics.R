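#' Accessors for AnnotatedImage
#'
#' `imageArray()` returns the `H x W x 3` intensity array, `maskArray()` the
#' binary `H x W` mask, and `metadata()` (the S4Vectors generic) the metadata
#' list.
#'
#' @param x an [AnnotatedImage-class].
#' @param ... ignored.
#' @return The requested component.
#' @aliases imageArray maskArray metadata,AnnotatedImage-method
#' @export
setGeneric("imageArray", function(x, ...) standardGeneric("imageArray"))

#' @rdname imageArray
#' @export
setGeneric("maskArray", function(x, ...) standardGeneric("maskArray"))

#' @rdname imageArray
#' @export
setMethod("imageArray", "AnnotatedImage", function(x, ...) x@image)

#' @rdname imageArray
#' @export
setMethod("maskArray", "AnnotatedImage", function(x, ...) x@mask)

#' @rdname imageArray
#' @export
setMethod("metadata", "AnnotatedImage", function(x, ...) x@meta)
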