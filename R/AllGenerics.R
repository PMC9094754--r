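#' @rdname UTRSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname UTRSet-accessors
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @rdname selectLongestUTR
#' @export
setGeneric("selectLongestUTR", function(x) standardGeneric("selectLongestUTR"))

#' @rdname TargetSet-accessors
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname TargetSet-accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates", function(x, ...) standardGeneric("averageReplicates"))

#' @rdname timepoints
#' @export
setGeneric("timepoints", function(x) standardGeneric("timepoints"))
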