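#' Accessors for [IHCScoreSet-class]
#'
#' Extract the assay matrices (antibody x mapping, \code{NA} for untested
#' pairs) and the mapping registry from an [IHCScoreSet-class].
#' \code{sgMatrix()}, \code{spMatrix()} and \code{scoreMatrix()} require the
#' object to have been scored with [scoreAntibodies()]; \code{isScored()}
#' tells whether it has been.
#'
#' @param x an [IHCScoreSet-class].
#' @return a numeric matrix, except \code{mappingRegistry()} which returns
#'   the registry as a \code{data.frame} and \code{isScored()} which returns
#'   a logical scalar.
#' @name IHCScoreSet-accessors
#' @examples
#' ann <- readAnnotations(exampleAnnotationFile())
#' sset <- buildEDMatrix(ann, loadMappingRegistry())
#' edMatrix(sset)["HPA034966", "Breast"]
NULL

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("eiN", "IHCScoreSet", function(x) assay(x, "EiN"))

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("eiC", "IHCScoreSet", function(x) assay(x, "EiC"))

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("edMatrix", "IHCScoreSet", function(x) assay(x, "ED"))

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("nPatients", "IHCScoreSet", function(x) assay(x, "nPatients"))

.scoredAssay <- function(x, name) {
    if (!name %in% assayNames(x))
        stop("assay '", name, "' not present; run scoreAntibodies() first",
             call. = FALSE)
    assay(x, name)
}

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("sgMatrix", "IHCScoreSet", function(x) .scoredAssay(x, "SG"))

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("spMatrix", "IHCScoreSet", function(x) .scoredAssay(x, "SP"))

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("scoreMatrix", "IHCScoreSet", function(x) .scoredAssay(x, "score"))

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("mappingRegistry", "IHCScoreSet", function(x) {
    cd <- as.data.frame(colData(x))
    rownames(cd) <- NULL
    cd[, c("mapping_id", "cancer_type", "normal_tissue", "normal_cell_type")]
})

#' @rdname IHCScoreSet-accessors
#' @export
setMethod("isScored", "IHCScoreSet", function(x) {
    all(c("SG", "SP", "score") %in% assayNames(x))
})

setMethod("show", "IHCScoreSet", function(object) {
    ed <- assay(object, "ED")
    cat("IHCScoreSet:", nrow(object), "antibodies x", ncol(object),
        "mappings\n")
    cat("  tested pairs:", sum(!is.na(ed)), "of", length(ed), "\n")
    cat("  cancer types:", length(unique(colData(object)$cancer_type)), "\n")
    cat("  scored:", isScored(object), "\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})
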