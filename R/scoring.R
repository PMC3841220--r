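## Core scoring: ED matrix construction and the SG/SP/score assays.

.popSD <- function(x) sqrt(mean((x - mean(x))^2))

## z-scores of v over its non-missing entries; population SD by default.
## Degenerate dispersion (sd = 0) maps every entry to z = 0, so SG/SP = 0.5:
## an undiscriminating axis neither rewards nor punishes. Fewer than 2
## observations -> NA (unscorable).
.zVector <- function(v, sdType = "population") {
    ok <- !is.na(v)
    n <- sum(ok)
    z <- rep(NA_real_, length(v))
    if (n < 2L)
        return(z)
    mu <- mean(v[ok])
    s <- if (sdType == "sample") sd(v[ok]) else .popSD(v[ok])
    z[ok] <- if (s == 0) 0 else (v[ok] - mu) / s
    z
}

#' Build the antibody-by-mapping expression matrix
#'
#' Computes EiN, EiC, patient counts and ED for every (antibody, mapping)
#' pair. A pair is tested — its cell non-missing — only when both the normal
#' record matching the mapping's tissue and cell type and at least one
#' patient record of the mapping's cancer type exist; absent rows mean "not
#' tested". Mappings sharing a cancer type (e.g. the two colorectal
#' mappings) share patient records and hence EiC, but differ in EiN.
#'
#' @param annotations a validated annotation \code{data.frame} from
#'   [readAnnotations()] or [simulateAnnotations()].
#' @param registry a mapping registry from [loadMappingRegistry()].
#' @return an [IHCScoreSet-class] with assays \code{EiN}, \code{EiC},
#'   \code{nPatients} and \code{ED}.
#' @examples
#' sset <- buildEDMatrix(readAnnotations(exampleAnnotationFile()),
#'                       loadMappingRegistry())
#' edMatrix(sset)["HPA034966", "Breast"]   # 18.75
#' @export
buildEDMatrix <- function(annotations, registry) {
    stopifnot(is.data.frame(annotations), is.data.frame(registry))
    if (nrow(registry) == 0L)
        stop("mapping registry is empty", call. = FALSE)
    if (anyDuplicated(registry$mapping_id))
        stop("duplicate mapping_id in registry", call. = FALSE)
    if (nrow(annotations) == 0L)
        stop("no annotations", call. = FALSE)

    antibodies <- sort(unique(annotations$antibody_id))
    gene <- annotations$gene[match(antibodies, annotations$antibody_id)]
    nAb <- length(antibodies)
    nMap <- nrow(registry)

    isN <- annotations$sample_kind == "normal"
    norm <- annotations[isN, , drop = FALSE]
    canc <- annotations[!isN, , drop = FALSE]

    keyN <- paste(norm$antibody_id, norm$tissue, norm$cell_type, sep = "\r")
    valN <- as.numeric(intensityToNumeric(norm$intensity) *
                       quantityToNumeric(norm$quantity))

    ## per (antibody, cancer type): mean product and patient count
    prodC <- as.numeric(intensityToNumeric(canc$intensity) *
                        quantityToNumeric(canc$quantity))
    keyC <- paste(canc$antibody_id, canc$cancer_type, sep = "\r")
    f <- factor(keyC)
    sums <- rowsum(prodC, f)
    cnts <- rowsum(rep(1L, length(f)), f)
    ukeyC <- rownames(sums)

    EiN <- EiC <- NP <- matrix(NA_real_, nAb, nMap,
                               dimnames = list(antibodies,
                                               registry$mapping_id))
    for (j in seq_len(nMap)) {
        qn <- paste(antibodies, registry$normal_tissue[j],
                    registry$normal_cell_type[j], sep = "\r")
        EiN[, j] <- valN[match(qn, keyN)]
        qc <- paste(antibodies, registry$cancer_type[j], sep = "\r")
        i <- match(qc, ukeyC)
        EiC[, j] <- sums[i, 1L] / cnts[i, 1L]
        NP[, j] <- cnts[i, 1L]
    }
    ## a cell exists only when both sides were tested
    miss <- is.na(EiN) | is.na(EiC)
    EiN[miss] <- EiC[miss] <- NP[miss] <- NA_real_
    ED <- EiC - EiN

    new("IHCScoreSet", SummarizedExperiment(
        assays = list(EiN = EiN, EiC = EiC, nPatients = NP, ED = ED),
        rowData = DataFrame(antibody_id = antibodies, gene = gene,
                            row.names = antibodies),
        colData = DataFrame(registry, row.names = registry$mapping_id)))
}

#' Significance and specificity of one expression difference
#'
#' \code{significance()}: the ED of the (antibody, mapping) cell is z-scored
#' against the EDs of \emph{all antibodies} of that mapping (the matrix
#' column) and passed through the standard-normal CDF; the result SG in
#' (0, 1) can be read as the rank of the antibody among all antibodies of
#' the mapping. \code{specificity()}: the same construction along the
#' antibody's row — the ED z-scored against the antibody's EDs over
#' \emph{all mappings} — giving SP, the rank of the mapping among the
#' antibody's mappings. The cell's own ED is included in the mean and
#' (population) standard deviation; a zero-dispersion column or row gives
#' 0.5; an axis with fewer than two tested cells is unscorable (\code{NA}).
#'
#' @param x an [IHCScoreSet-class].
#' @param antibody_id,mapping_id the cell to evaluate; the cell must be
#'   tested.
#' @param sdType \code{"population"} (divide by N; default) or
#'   \code{"sample"} (N-1).
#' @return a numeric scalar in (0, 1), or \code{NA} if unscorable.
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 5, seed = 1))
#' sset <- buildEDMatrix(sim$annotations, loadMappingRegistry())
#' significance(sset, "AB0001", "Breast")
#' @export
significance <- function(x, antibody_id, mapping_id,
                         sdType = c("population", "sample")) {
    sdType <- match.arg(sdType)
    ed <- edMatrix(x)
    .checkCell(ed, antibody_id, mapping_id)
    z <- .zVector(ed[, mapping_id], sdType)
    unname(pnorm(z[match(antibody_id, rownames(ed))]))
}

#' @rdname significance
#' @export
specificity <- function(x, antibody_id, mapping_id,
                        sdType = c("population", "sample")) {
    sdType <- match.arg(sdType)
    ed <- edMatrix(x)
    .checkCell(ed, antibody_id, mapping_id)
    z <- .zVector(ed[antibody_id, ], sdType)
    unname(pnorm(z[match(mapping_id, colnames(ed))]))
}

.checkCell <- function(ed, antibody_id, mapping_id) {
    if (!antibody_id %in% rownames(ed))
        stop("unknown antibody_id: ", antibody_id, call. = FALSE)
    if (!mapping_id %in% colnames(ed))
        stop("unknown mapping_id: ", mapping_id, call. = FALSE)
    if (is.na(ed[antibody_id, mapping_id]))
        stop("pair (", antibody_id, ", ", mapping_id,
             ") was not tested", call. = FALSE)
    invisible(TRUE)
}

#' Score all antibodies against all mappings
#'
#' Adds the \code{SG}, \code{SP} and \code{score} assays:
#' \code{score = EiC * SG * SP}, in [0, 225]. SG is computed per mapping
#' column and SP per antibody row as in [significance()]. Cells whose
#' column or row has fewer than two tested cells are unscorable and left
#' \code{NA}; their number is reported via \code{message()}.
#'
#' Calling \code{scoreAntibodies()} on an annotation \code{data.frame}
#' builds the ED matrix first ([buildEDMatrix()]) and then scores it.
#'
#' @param x an [IHCScoreSet-class], or an annotation \code{data.frame}.
#' @param registry a mapping registry (only for the \code{data.frame}
#'   method).
#' @param sdType \code{"population"} (default) or \code{"sample"} standard
#'   deviation in the z-score normalizations.
#' @param ... passed between methods.
#' @return the scored [IHCScoreSet-class].
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 20, seed = 1))
#' sset <- scoreAntibodies(sim$annotations, loadMappingRegistry())
#' head(scoresTable(sset))
#' @rdname scoreAntibodies
#' @export
setMethod("scoreAntibodies", "IHCScoreSet",
          function(x, sdType = c("population", "sample"), ...) {
    sdType <- match.arg(sdType)
    ed <- edMatrix(x)
    SG <- apply(ed, 2L, .zVector, sdType = sdType)
    if (is.null(dim(SG))) SG <- matrix(SG, nrow = nrow(ed))  # 1-antibody case
    SG <- pnorm(SG)
    SP <- t(apply(ed, 1L, .zVector, sdType = sdType))
    if (ncol(ed) == 1L) SP <- matrix(SP, ncol = 1L)
    SP <- pnorm(SP)
    dimnames(SG) <- dimnames(SP) <- dimnames(ed)
    score <- eiC(x) * SG * SP
    nUnscorable <- sum(is.na(score) & !is.na(ed))
    if (nUnscorable > 0L)
        message(nUnscorable, " tested cell(s) unscorable ",
                "(column or row with < 2 tested cells); omitted")
    assay(x, "SG") <- SG
    assay(x, "SP") <- SP
    assay(x, "score") <- score
    metadata(x)$sdType <- sdType
    validObject(x)
    x
})

#' @rdname scoreAntibodies
#' @export
setMethod("scoreAntibodies", "data.frame",
          function(x, registry, sdType = c("population", "sample"), ...) {
    scoreAntibodies(buildEDMatrix(x, registry), sdType = match.arg(sdType))
})

#' Tidy score table
#'
#' One row per scorable (antibody, mapping) cell with all the per-cell
#' quantities and the rank of the antibody within its mapping (descending
#' score, rank 1 = best; ties broken by ascending antibody id).
#'
#' @param x a scored [IHCScoreSet-class].
#' @param ... unused.
#' @return a \code{data.frame} with columns \code{antibody_id}, \code{gene},
#'   \code{mapping_id}, \code{EiN}, \code{EiC}, \code{n_patients},
#'   \code{ED}, \code{SG}, \code{SP}, \code{score}, \code{rank}.
#' @rdname scoresTable
#' @export
setMethod("scoresTable", "IHCScoreSet", function(x, ...) {
    if (!isScored(x))
        stop("object not scored; run scoreAntibodies() first", call. = FALSE)
    sc <- scoreMatrix(x)
    idx <- which(!is.na(sc), arr.ind = TRUE)
    tab <- data.frame(
        antibody_id = rownames(sc)[idx[, 1L]],
        gene = rowData(x)$gene[idx[, 1L]],
        mapping_id = colnames(sc)[idx[, 2L]],
        EiN = eiN(x)[idx], EiC = eiC(x)[idx],
        n_patients = as.integer(nPatients(x)[idx]),
        ED = edMatrix(x)[idx],
        SG = sgMatrix(x)[idx], SP = spMatrix(x)[idx],
        score = sc[idx],
        stringsAsFactors = FALSE)
    ord <- order(tab$mapping_id, -tab$score, tab$antibody_id)
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- as.integer(stats::ave(seq_len(nrow(tab)), tab$mapping_id,
                                      FUN = seq_along))
    rownames(tab) <- NULL
    tab
})
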