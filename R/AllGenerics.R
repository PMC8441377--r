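#' @rdname AmpliconReference
#' @param object,x an object of the documented class.
#' @export
setGeneric("ampliconSeq", function(x) standardGeneric("ampliconSeq"))

#' @rdname AmpliconReference
#' @export
setGeneric("wtProductSize", function(x) standardGeneric("wtProductSize"))

#' @rdname Guide
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))

#' @rdname GuidePair
#' @export
setGeneric("pairId", function(x) standardGeneric("pairId"))

#' @rdname GuidePair
#' @export
setGeneric("expectedDeletionSize",
    function(x) standardGeneric("expectedDeletionSize"))

#' Per-pair efficiency vector of a library
#'
#' @param x a [LibraryQuant-class].
#' @return Named numeric vector of per-pair efficiencies.
#' @export
setGeneric("efficiencies", function(x) standardGeneric("efficiencies"))
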