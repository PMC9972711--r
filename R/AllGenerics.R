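#' @rdname accessors
#' @export
setGeneric("rootLabel", function(x) standardGeneric("rootLabel"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname treeCost
#' @export
setGeneric("treeCost", function(tree) standardGeneric("treeCost"))

#' @rdname treeDepth
#' @export
setGeneric("treeDepth", function(tree) standardGeneric("treeDepth"))
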