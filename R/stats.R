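## Top-k validation statistics and the ED heat-map matrix.

#' Top-k antibodies of a mapping
#'
#' The k highest-scoring antibodies of one mapping, best first (ties by
#' ascending antibody id). If fewer than \code{k} scorable antibodies exist
#' the full list is returned with a warning.
#'
#' @param scores a scored [IHCScoreSet-class] or a [scoresTable()]
#'   \code{data.frame}.
#' @param mapping_id the mapping to rank.
#' @param k how many antibodies (default 100, the published choice).
#' @return a character vector of antibody ids, ordered by rank.
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 30, seed = 1))
#' sset <- scoreAntibodies(sim$annotations, loadMappingRegistry())
#' topK(sset, "Breast", k = 5)
#' @export
topK <- function(scores, mapping_id, k = 100L) {
    stopifnot(length(k) == 1L, k >= 1)
    tab <- .asScoresTable(scores)
    if (!mapping_id %in% tab$mapping_id)
        stop("unknown mapping_id: ", mapping_id, call. = FALSE)
    tab <- tab[tab$mapping_id == mapping_id, , drop = FALSE]
    tab <- tab[order(-tab$score, tab$antibody_id), , drop = FALSE]
    if (nrow(tab) < k)
        warning("only ", nrow(tab), " scorable antibodies for ", mapping_id,
                " (k = ", k, "); returning all", call. = FALSE)
    head(tab$antibody_id, k)
}

.asScoresTable <- function(scores) {
    if (is(scores, "IHCScoreSet"))
        return(scoresTable(scores))
    stopifnot(is.data.frame(scores),
              all(c("antibody_id", "mapping_id", "score") %in%
                  colnames(scores)))
    scores
}

#' One-sample t-test against a known population mean
#'
#' Tests whether the mean of \code{sample} differs from the known population
#' mean: \code{t = (mean(sample) - mu) / (sd(sample) / sqrt(n))} with
#' \code{n - 1} degrees of freedom and sample (N-1) standard deviation. The
#' default alternative is one-sided \code{greater} — the directional claim
#' that a top-ranked sample mean is higher than the population mean.
#'
#' @param sample numeric vector, \code{n >= 2}, non-constant.
#' @param population_mean the known population mean.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return a one-row \code{data.frame}: \code{n}, \code{sample_mean},
#'   \code{sample_sd}, \code{population_mean}, \code{t_statistic},
#'   \code{p_value}, \code{alternative}.
#' @examples
#' oneSampleTTest(c(1, 2, 3), 0)   # t = 2*sqrt(3), p ~ 0.0371
#' @export
oneSampleTTest <- function(sample, population_mean,
                           alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    n <- length(sample)
    if (n < 2L)
        stop("need at least 2 observations", call. = FALSE)
    s <- sd(sample)
    if (s == 0)
        stop("sample standard deviation is zero", call. = FALSE)
    m <- mean(sample)
    t <- (m - population_mean) / (s / sqrt(n))
    p <- switch(alternative,
                greater = pt(t, df = n - 1L, lower.tail = FALSE),
                two.sided = 2 * pt(abs(t), df = n - 1L, lower.tail = FALSE))
    data.frame(n = n, sample_mean = m, sample_sd = s,
               population_mean = population_mean, t_statistic = t,
               p_value = p, alternative = alternative,
               stringsAsFactors = FALSE)
}

#' Top-k mean validation per mapping
#'
#' For each mapping, compares the mean EiC and the mean ED of the top-k
#' antibodies (selected by score) against the corresponding population means
#' over \emph{all} tested antibodies of the mapping, by one-sample t-tests.
#' This is the machine twin of the published top-100 validation tables: a
#' scoring that prioritizes abundant, overexpressed proteins should give
#' strongly significant positive differences for every mapping.
#'
#' @param x a scored [IHCScoreSet-class].
#' @param k top-k size (default 100).
#' @param alternative passed to [oneSampleTTest()].
#' @return a \code{data.frame} with one row per (mapping, statistic in
#'   \{EiC, ED\}): \code{mapping_id}, \code{statistic},
#'   \code{population_mean}, \code{n_top}, \code{sample_mean},
#'   \code{sample_sd}, \code{t}, \code{p_value}. Mappings with fewer than
#'   two top-k members are skipped with a warning.
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 50, seed = 1))
#' sset <- scoreAntibodies(sim$annotations, loadMappingRegistry())
#' head(validateTopkMeans(sset, k = 10))
#' @export
validateTopkMeans <- function(x, k = 100L,
                              alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    stopifnot(is(x, "IHCScoreSet"))
    if (!isScored(x))
        stop("object not scored; run scoreAntibodies() first", call. = FALSE)
    tab <- scoresTable(x)
    ed <- edMatrix(x); eic <- eiC(x)
    out <- list()
    for (m in colnames(ed)) {
        sub <- tab[tab$mapping_id == m, , drop = FALSE]
        if (nrow(sub) < 2L) {
            warning("mapping ", m, " has < 2 scorable antibodies; skipped",
                    call. = FALSE)
            next
        }
        top <- suppressWarnings(topK(sub, m, k))
        tested <- !is.na(ed[, m])
        for (stat in c("EiC", "ED")) {
            mat <- if (stat == "EiC") eic else ed
            popmean <- mean(mat[tested, m])
            smp <- mat[top, m]
            tt <- oneSampleTTest(smp, popmean, alternative)
            out[[length(out) + 1L]] <- data.frame(
                mapping_id = m, statistic = stat,
                population_mean = popmean, n_top = tt$n,
                sample_mean = tt$sample_mean, sample_sd = tt$sample_sd,
                t = tt$t_statistic, p_value = tt$p_value,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' ED heat-map matrix of top-k antibody sets
#'
#' Cell (i, j) is the mean ED, evaluated on mapping i, of the top-k
#' antibodies selected for mapping j; only antibodies with a tested ED on
#' mapping i enter the average. The final column \code{All} holds the
#' population ED mean of each mapping (all tested antibodies) and does not
#' depend on k. With the default 27-mapping registry the matrix is 27 x 28.
#' Mapping-specific scoring shows up as diagonal dominance: cell (j, j) is
#' the largest entry of row j outside the \code{All} column, while
#' off-diagonal cells stay near the row's population mean.
#'
#' @param x a scored [IHCScoreSet-class].
#' @param k top-k size (default 100).
#' @return a numeric matrix, rows = mappings (evaluation axis), columns =
#'   mappings (selection axis) plus \code{All}, with attribute \code{k}.
#' @seealso [plotEDHeatmap()]
#' @export
edHeatmap <- function(x, k = 100L) {
    stopifnot(is(x, "IHCScoreSet"))
    if (!isScored(x))
        stop("object not scored; run scoreAntibodies() first", call. = FALSE)
    ed <- edMatrix(x)
    maps <- colnames(ed)
    H <- matrix(NA_real_, length(maps), length(maps) + 1L,
                dimnames = list(maps, c(maps, "All")))
    tab <- scoresTable(x)
    for (j in maps) {
        top <- suppressWarnings(topK(tab, j, k))
        H[, j] <- colMeans(ed[top, , drop = FALSE], na.rm = TRUE)
    }
    H[, "All"] <- colMeans(ed, na.rm = TRUE)
    H[is.nan(H)] <- NA_real_
    attr(H, "k") <- as.integer(k)
    H
}

#' Render an ED heat map
#'
#' Draws the [edHeatmap()] matrix with a light-to-dark blue scale (large ED
#' dark). Requires the \pkg{pheatmap} package.
#'
#' @param H a matrix from [edHeatmap()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the \pkg{pheatmap} object, invisibly.
#' @export
plotEDHeatmap <- function(H, ...) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
        stop("package 'pheatmap' is required for plotting", call. = FALSE)
    pal <- grDevices::colorRampPalette(c("#F7FBFF", "#08306B"))(100)
    p <- pheatmap::pheatmap(H, cluster_rows = FALSE, cluster_cols = FALSE,
                            color = pal, ...)
    invisible(p)
}

#' Write the top-k validation table / heat-map matrix
#'
#' TSV writers for [validateTopkMeans()] and [edHeatmap()] output.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeValidation <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeValidation
#' @export
writeHeatmap <- function(x, path) {
    write.table(data.frame(mapping_id = rownames(x), x, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}
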