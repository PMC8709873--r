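#' @rdname Pedigree-class
#' @param object,x a famseg S4 object.
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname Pedigree-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Founders of a pedigree
#'
#' Exactly the members with both parents missing.
#'
#' @param x a [Pedigree].
#' @return character vector of ids.
#' @examples
#' ped <- trioPedigree()
#' founders(ped) # the two parents
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname ConnectingSubgraph-class
#' @param x a famseg S4 object.
#' @export
setGeneric("meioses", function(x) standardGeneric("meioses"))

#' @rdname ConnectingSubgraph-class
#' @export
setGeneric("carriers", function(x) standardGeneric("carriers"))

#' @rdname FilterReport-class
#' @param x a [FilterReport].
#' @export
setGeneric("surviving", function(x) standardGeneric("surviving"))

#' @rdname FilterReport-class
#' @export
setGeneric("eliminated", function(x) standardGeneric("eliminated"))
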