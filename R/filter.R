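## Candidate filtering: three rules, eight combinations, candidate table.

#' Candidate filtering rules
#'
#' Gene-level predicates used in marker candidate screening:
#' \describe{
#'   \item{\code{rule1Score()}}{some antibody of the gene reaches
#'     \code{score >= scoreThreshold} (inclusive) in at least one of the
#'     configured target mappings. A gene absent from the score table is not
#'     indexed and fails.}
#'   \item{\code{rule2MeanFC()}}{the arithmetic mean of the gene's available
#'     per-patient fold changes is \code{>= fcThreshold} (inclusive).}
#'   \item{\code{rule3PatientCount()}}{the gene has fold change
#'     \code{>= fcThreshold} in \emph{strictly more than}
#'     \code{patientCountThreshold} patients (default: more than 14, i.e.
#'     at least 15).}
#' }
#'
#' @param gene a gene identifier (vectorized).
#' @param scores a score table (\code{data.frame} with \code{gene},
#'   \code{mapping_id}, \code{score}) or a scored [IHCScoreSet-class].
#' @param cohort a cohort \code{data.frame} from [readCohort()].
#' @param config a [FilterConfig-class].
#' @return a logical vector, one element per gene.
#' @examples
#' scores <- readScores(exampleScoresFile())
#' cohort <- readCohort(exampleCohortFile(), quiet = TRUE)
#' rule1Score("CEACAM5", scores, filterConfig())
#' rule3PatientCount(c("CEACAM5", "ANXA4"), cohort, filterConfig())
#' @export
rule1Score <- function(gene, scores, config = filterConfig()) {
    tab <- .asScoresTable(scores)
    if (length(config@targetMappings) == 0L)
        stop("Rule 1 requires non-empty targetMappings", call. = FALSE)
    tab <- tab[tab$mapping_id %in% config@targetMappings, , drop = FALSE]
    best <- .bestScorePerGene(tab)
    hit <- best[match(gene, names(best))]
    !is.na(hit) & hit >= config@scoreThreshold
}

.bestScorePerGene <- function(tab) {
    if (nrow(tab) == 0L) return(setNames(numeric(0), character(0)))
    v <- vapply(split(tab$score, tab$gene), max, numeric(1))
    v
}

#' @rdname rule1Score
#' @export
rule2MeanFC <- function(gene, cohort, config = filterConfig()) {
    mfc <- vapply(split(cohort$fold_change, cohort$gene), mean, numeric(1))
    v <- mfc[match(gene, names(mfc))]
    !is.na(v) & v >= config@fcThreshold
}

#' @rdname rule1Score
#' @export
rule3PatientCount <- function(gene, cohort, config = filterConfig()) {
    cnt <- vapply(split(cohort$fold_change, cohort$gene),
                  function(fc) sum(fc >= config@fcThreshold), numeric(1))
    v <- cnt[match(gene, names(cnt))]
    !is.na(v) & v > config@patientCountThreshold
}

#' Rule on/off pattern of a filtering combination
#'
#' The eight evaluated combinations: 1 applies no rules (it defines the
#' reference population of cohort genes indexed in the score table);
#' 2, 3, 4 apply Rule 1, 2, 3 alone; 5 = Rules 1+2; 6 = Rules 1+3;
#' 7 = Rules 2+3; 8 = all three.
#'
#' @param combination_id an integer 1-8.
#' @return a named logical vector \code{use_rule1}, \code{use_rule2},
#'   \code{use_rule3}.
#' @export
combinationRules <- function(combination_id) {
    patterns <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                     c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                     c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                     c(FALSE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
    if (length(combination_id) != 1L || !combination_id %in% 1:8)
        stop("combination_id must be an integer in 1..8", call. = FALSE)
    setNames(patterns[[combination_id]],
             c("use_rule1", "use_rule2", "use_rule3"))
}

#' Apply one filtering-rule combination to a cohort
#'
#' Restricts the cohort to genes indexed in the score table (the
#' combination-1 population), applies the conjunction of the combination's
#' active rules, and reports counts and proportions of surviving genes and
#' of their biomarker/disease annotations, both within the filtered set and
#' against the combination-1 population.
#'
#' @param combination_id integer 1-8, see [combinationRules()].
#' @param cohort a cohort \code{data.frame} from [readCohort()].
#' @param scores a score table or scored [IHCScoreSet-class].
#' @param gene_annotations optional \code{data.frame} from
#'   [readGeneAnnotations()]; without it annotation counts are \code{NA}.
#' @param config a [FilterConfig-class].
#' @return a [FilterReport-class].
#' @examples
#' rep8 <- applyCombination(8, readCohort(exampleCohortFile(), quiet = TRUE),
#'                          readScores(exampleScoresFile()),
#'                          readGeneAnnotations(exampleGeneAnnotationFile()))
#' rep8
#' @export
applyCombination <- function(combination_id, cohort, scores,
                             gene_annotations = NULL,
                             config = filterConfig()) {
    rules <- combinationRules(combination_id)
    tab <- .asScoresTable(scores)

    ## combination-1 population: cohort genes indexed in the score table
    genes <- sort(unique(cohort$gene))
    indexed <- genes[genes %in% tab$gene]

    keep <- rep(TRUE, length(indexed))
    if (rules[["use_rule1"]])
        keep <- keep & rule1Score(indexed, tab, config)
    if (rules[["use_rule2"]])
        keep <- keep & rule2MeanFC(indexed, cohort, config)
    if (rules[["use_rule3"]])
        keep <- keep & rule3PatientCount(indexed, cohort, config)
    surv <- indexed[keep]

    flag <- function(g, col) {
        if (is.null(gene_annotations)) return(rep(NA, length(g)))
        v <- gene_annotations[[col]][match(g, gene_annotations$gene)]
        !is.na(v) & v
    }
    popBio <- sum(flag(indexed, "is_biomarker"))
    popDis <- sum(flag(indexed, "is_disease_related"))
    nBio <- sum(flag(surv, "is_biomarker"))
    nDis <- sum(flag(surv, "is_disease_related"))

    pct <- function(a, b) if (is.na(a) || is.na(b) || b == 0) NA_real_
                          else 100 * a / b
    evid <- .geneEvidence(surv, tab, cohort, config)
    evid$is_biomarker <- flag(surv, "is_biomarker")
    evid$is_disease_related <- flag(surv, "is_disease_related")

    new("FilterReport",
        combinationId = as.integer(combination_id),
        rules = rules, config = config,
        nPopulation = length(indexed),
        nPopulationBiomarker = as.integer(popBio),
        nPopulationDisease = as.integer(popDis),
        nFiltered = length(surv),
        nBiomarker = as.integer(nBio),
        nDisease = as.integer(nDis),
        propWithinFiltered = c(biomarker = pct(nBio, length(surv)),
                               disease = pct(nDis, length(surv))),
        propVsPopulation = c(filtered = pct(length(surv), length(indexed)),
                             biomarker = pct(nBio, popBio),
                             disease = pct(nDis, popDis)),
        genes = evid)
}

## per-gene evidence: best score over target mappings, mean fold change,
## qualifying patient count
.geneEvidence <- function(genes, tab, cohort, config) {
    sub <- tab[tab$mapping_id %in% config@targetMappings, , drop = FALSE]
    best <- .bestScorePerGene(sub)
    co <- split(cohort$fold_change, cohort$gene)
    mfc <- vapply(co, mean, numeric(1))
    cnt <- vapply(co, function(fc) sum(fc >= config@fcThreshold), numeric(1))
    data.frame(
        gene = genes,
        best_score = unname(best[match(genes, names(best))]),
        mean_fold_change = unname(mfc[match(genes, names(mfc))]),
        n_qualifying_patients = as.integer(
            unname(cnt[match(genes, names(cnt))])),
        stringsAsFactors = FALSE)
}

#' Surviving genes of a filter report
#'
#' @param report a [FilterReport-class].
#' @return the per-gene evidence \code{data.frame} (gene, best score over
#'   the target mappings, mean fold change, qualifying patient count,
#'   annotation flags), sorted by descending best score — the machine twin
#'   of a published candidate table.
#' @export
candidateTable <- function(report) {
    stopifnot(is(report, "FilterReport"))
    g <- report@genes
    g[order(-ifelse(is.na(g$best_score), -Inf, g$best_score), g$gene), ,
      drop = FALSE]
}

#' Write filter report / candidate table TSVs
#'
#' @param report a [FilterReport-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFilterReport <- function(report, path) {
    summary <- data.frame(
        combination_id = report@combinationId,
        use_rule1 = report@rules[["use_rule1"]],
        use_rule2 = report@rules[["use_rule2"]],
        use_rule3 = report@rules[["use_rule3"]],
        n_population = report@nPopulation,
        n_filtered = report@nFiltered,
        n_biomarker = report@nBiomarker,
        n_disease = report@nDisease,
        pct_biomarker_of_filtered = report@propWithinFiltered[["biomarker"]],
        pct_disease_of_filtered = report@propWithinFiltered[["disease"]],
        pct_filtered_of_population = report@propVsPopulation[["filtered"]],
        pct_biomarker_of_population = report@propVsPopulation[["biomarker"]],
        pct_disease_of_population = report@propVsPopulation[["disease"]])
    write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}
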