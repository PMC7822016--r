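#' @name multiphi-accessors
#' @title Accessors for multiphi classes
#' @description Slot access for the package's S4 containers goes through
#'   these generics; code outside the package should never reach into slots
#'   directly.
#' @param x a multiphi object.
#' @return the corresponding component (see each method).
NULL

#' @rdname multiphi-accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname multiphi-accessors
#' @export
setGeneric("numStatesPerNode",
           function(x) standardGeneric("numStatesPerNode"))

#' @rdname multiphi-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname multiphi-accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname multiphi-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname multiphi-accessors
#' @export
setGeneric("distinctions", function(x) standardGeneric("distinctions"))

#' @rdname multiphi-accessors
#' @export
setGeneric("sumPhi", function(x) standardGeneric("sumPhi"))

#' @rdname multiphi-accessors
#' @export
setGeneric("phi", function(x) standardGeneric("phi"))

#' @rdname multiphi-accessors
#' @export
setGeneric("bigPhi", function(x) standardGeneric("bigPhi"))

#' @rdname multiphi-accessors
#' @export
setGeneric("mipCut", function(x) standardGeneric("mipCut"))

#' @rdname multiphi-accessors
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))
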