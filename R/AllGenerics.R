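#' @include AllClasses.R
NULL

#' Accessors for scMirEdit containers
#'
#' @param x A \linkS4class{PrecursorSet}, \linkS4class{SampleProfile} or
#'   \linkS4class{EditingExperiment}.
#' @name scMirEdit-accessors
#' @return \code{precursorNames}: character vector of precursor names.
NULL

#' @rdname scMirEdit-accessors
#' @export
setGeneric("precursorNames", function(x) standardGeneric("precursorNames"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("precursorSequences",
           function(x) standardGeneric("precursorSequences"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("precursorLoci", function(x) standardGeneric("precursorLoci"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("matureAnnotations",
           function(x) standardGeneric("matureAnnotations"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("siteCalls", function(x, ...) standardGeneric("siteCalls"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("editingLevels", function(x) standardGeneric("editingLevels"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname scMirEdit-accessors
#' @export
setGeneric("siteTypes", function(x) standardGeneric("siteTypes"))
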