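#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("eiN", function(x) standardGeneric("eiN"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("eiC", function(x) standardGeneric("eiC"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("edMatrix", function(x) standardGeneric("edMatrix"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("sgMatrix", function(x) standardGeneric("sgMatrix"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("spMatrix", function(x) standardGeneric("spMatrix"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("mappingRegistry", function(x) standardGeneric("mappingRegistry"))

#' @rdname IHCScoreSet-accessors
#' @export
setGeneric("isScored", function(x) standardGeneric("isScored"))

#' @rdname scoreAntibodies
#' @export
setGeneric("scoreAntibodies", function(x, ...) standardGeneric("scoreAntibodies"))

#' @rdname scoresTable
#' @export
setGeneric("scoresTable", function(x, ...) standardGeneric("scoresTable"))
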