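## The two query modes of the scoring resource.

#' Query scores by gene
#'
#' Lists score and rank of every antibody of the gene for each mapping it
#' was scored on.
#'
#' @param gene a gene identifier.
#' @param scores a scored [IHCScoreSet-class] or [scoresTable()]
#'   \code{data.frame}.
#' @return a \code{data.frame} (possibly empty, with a warning for an
#'   unknown gene), ordered by mapping then rank.
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 10, seed = 1))
#' sset <- scoreAntibodies(sim$annotations, loadMappingRegistry())
#' head(queryByGene("G0003", sset))
#' @export
queryByGene <- function(gene, scores) {
    tab <- .asScoresTable(scores)
    if (!"gene" %in% colnames(tab))
        stop("score table lacks a gene column", call. = FALSE)
    out <- tab[tab$gene == gene, , drop = FALSE]
    if (nrow(out) == 0L)
        warning("gene not found in score table: ", gene, call. = FALSE)
    out <- out[order(out$mapping_id, out$rank), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Query scores by cancer mapping
#'
#' The ranked antibody/gene list of one mapping, sorted by descending score
#' and truncated to \code{limit} rows.
#'
#' @param mapping_id the mapping to query.
#' @param scores a scored [IHCScoreSet-class] or [scoresTable()]
#'   \code{data.frame}.
#' @param limit maximum number of rows (default 100).
#' @return a \code{data.frame} with non-increasing scores.
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 10, seed = 1))
#' sset <- scoreAntibodies(sim$annotations, loadMappingRegistry())
#' queryByCancer("Melanoma", sset, limit = 3)
#' @export
queryByCancer <- function(mapping_id, scores, limit = 100L) {
    stopifnot(length(limit) == 1L, limit >= 1)
    tab <- .asScoresTable(scores)
    if (nrow(tab) == 0L)
        return(tab)
    known <- unique(tab$mapping_id)
    if (!mapping_id %in% known)
        stop("unknown mapping_id: ", mapping_id, call. = FALSE)
    out <- tab[tab$mapping_id == mapping_id, , drop = FALSE]
    out <- out[order(-out$score, out$antibody_id), , drop = FALSE]
    out <- head(out, limit)
    rownames(out) <- NULL
    out
}
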