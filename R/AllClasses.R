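#' IHCScoreSet: antibody-by-mapping expression container
#'
#' An S4 container extending
#' \linkS4class{SummarizedExperiment}. Rows are antibodies, columns are
#' cancer-to-normal tissue mappings. Core assays (all antibody x mapping,
#' \code{NA} where the pair was not tested):
#' \describe{
#'   \item{EiN}{expression in the mapping's normal cell type, \code{I * Q},
#'     in [0, 225].}
#'   \item{EiC}{mean expression across patients of the mapping's cancer
#'     type, in [0, 225].}
#'   \item{nPatients}{number of patient annotations behind EiC.}
#'   \item{ED}{expression difference \code{EiC - EiN}, in [-225, 225].}
#' }
#' After [scoreAntibodies()] three further assays are present: \code{SG},
#' \code{SP} (both in (0, 1)) and \code{score} (\code{EiC * SG * SP}).
#' \code{rowData} carries \code{antibody_id} and \code{gene};
#' \code{colData} carries the mapping registry (\code{mapping_id},
#' \code{cancer_type}, \code{normal_tissue}, \code{normal_cell_type}).
#'
#' Build one with [buildEDMatrix()]; do not call the constructor on raw
#' matrices unless they already satisfy the validity rules.
#'
#' @aliases IHCScoreSet-class
#' @seealso [buildEDMatrix()], [scoreAntibodies()], [scoresTable()]
#' @export
setClass("IHCScoreSet", contains = "SummarizedExperiment")

.validIHCScoreSet <- function(object) {
    msg <- character()
    need <- c("EiN", "EiC", "nPatients", "ED")
    have <- assayNames(object)
    if (!all(need %in% have))
        msg <- c(msg, paste0("missing assay(s): ",
                             paste(setdiff(need, have), collapse = ", ")))
    else {
        ein <- assay(object, "EiN"); eic <- assay(object, "EiC")
        ed <- assay(object, "ED")
        ok <- !is.na(ein) & !is.na(eic)
        if (any(is.na(ed[ok])) ||
            any(abs(ed[ok] - (eic[ok] - ein[ok])) > 1e-9))
            msg <- c(msg, "ED must equal EiC - EiN wherever both are present")
        if (any(ein < -1e-9 | ein > 225 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "EiN out of [0, 225]")
        if (any(eic < -1e-9 | eic > 225 + 1e-9, na.rm = TRUE))
            msg <- c(msg, "EiC out of [0, 225]")
        np <- assay(object, "nPatients")
        if (any(np[!is.na(np)] < 1))
            msg <- c(msg, "nPatients must be >= 1 where the pair was tested")
    }
    cd <- colData(object)
    regcols <- c("mapping_id", "cancer_type", "normal_tissue", "normal_cell_type")
    if (!all(regcols %in% colnames(cd)))
        msg <- c(msg, "colData must carry the mapping registry columns")
    else if (anyDuplicated(cd$mapping_id))
        msg <- c(msg, "duplicate mapping_id in colData")
    if (!"antibody_id" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must carry antibody_id")
    if (length(msg)) msg else TRUE
}

setValidity("IHCScoreSet", .validIHCScoreSet)

#' Filtering configuration for candidate selection rules
#'
#' Holds the thresholds of the three candidate filtering rules:
#' \describe{
#'   \item{Rule 1}{some antibody of the gene reaches
#'     \code{score >= scoreThreshold} in one of \code{targetMappings}.}
#'   \item{Rule 2}{the gene's mean per-patient fold change is
#'     \code{>= fcThreshold}.}
#'   \item{Rule 3}{the gene has fold change \code{>= fcThreshold} in
#'     strictly more than \code{patientCountThreshold} patients.}
#' }
#' Score and fold-change thresholds are inclusive; the patient count is a
#' strict "more than" bound (the default 14 means at least 15 patients).
#'
#' @aliases FilterConfig-class
#' @seealso [filterConfig()], [applyCombination()]
#' @export
setClass("FilterConfig", representation(
    scoreThreshold = "numeric",
    fcThreshold = "numeric",
    patientCountThreshold = "integer",
    targetMappings = "character"
))

setValidity("FilterConfig", function(object) {
    msg <- character()
    if (length(object@scoreThreshold) != 1L || object@scoreThreshold <= 0)
        msg <- c(msg, "scoreThreshold must be a single positive number")
    if (length(object@fcThreshold) != 1L || object@fcThreshold <= 0)
        msg <- c(msg, "fcThreshold must be a single positive number")
    if (length(object@patientCountThreshold) != 1L ||
        object@patientCountThreshold < 0)
        msg <- c(msg, "patientCountThreshold must be a single non-negative integer")
    if (length(msg)) msg else TRUE
})

#' Construct a [FilterConfig-class]
#'
#' @param scoreThreshold minimum antibody score for Rule 1 (inclusive).
#' @param fcThreshold minimum fold change for Rules 2 and 3 (inclusive).
#' @param patientCountThreshold Rule 3 passes only with strictly more
#'   qualifying patients than this.
#' @param targetMappings mapping ids searched by Rule 1; the default is the
#'   colorectal pair used in the package's colorectal-cancer case study.
#' @return a \code{FilterConfig} object.
#' @examples
#' filterConfig(scoreThreshold = 120)
#' @export
filterConfig <- function(scoreThreshold = 100, fcThreshold = 2,
                         patientCountThreshold = 14L,
                         targetMappings = c("Colorectal-A", "Colorectal-B")) {
    new("FilterConfig",
        scoreThreshold = as.numeric(scoreThreshold),
        fcThreshold = as.numeric(fcThreshold),
        patientCountThreshold = as.integer(patientCountThreshold),
        targetMappings = as.character(targetMappings))
}

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig\n")
    cat("  Rule 1: score >=", object@scoreThreshold, "in {",
        paste(object@targetMappings, collapse = ", "), "}\n")
    cat("  Rule 2: mean fold change >=", object@fcThreshold, "\n")
    cat("  Rule 3: fold change >=", object@fcThreshold, "in >",
        object@patientCountThreshold, "patients\n")
})

#' Result of applying one filtering-rule combination
#'
#' Produced by [applyCombination()]. The reference population is the
#' combination-1 population: cohort genes indexed in the score table with no
#' rule applied. Proportions are percentages.
#'
#' @aliases FilterReport-class
#' @seealso [applyCombination()], [candidateTable()]
#' @export
setClass("FilterReport", representation(
    combinationId = "integer",
    rules = "logical",           # named use_rule1/2/3
    config = "FilterConfig",
    nPopulation = "integer",     # combination-1 population size
    nPopulationBiomarker = "integer",
    nPopulationDisease = "integer",
    nFiltered = "integer",
    nBiomarker = "integer",
    nDisease = "integer",
    propWithinFiltered = "numeric",  # biomarker%, disease% of filtered genes
    propVsPopulation = "numeric",    # filtered%, biomarker%, disease% vs population
    genes = "data.frame"             # per-gene evidence for survivors
))

setMethod("show", "FilterReport", function(object) {
    on <- names(object@rules)[object@rules]
    cat("FilterReport (combination ", object@combinationId, ": ",
        if (length(on)) paste(sub("use_", "", on), collapse = "+") else "no rules",
        ")\n", sep = "")
    cat("  population (combination 1):", object@nPopulation, "genes;",
        object@nPopulationBiomarker, "biomarker-annotated;",
        object@nPopulationDisease, "disease-annotated\n")
    cat("  filtered:", object@nFiltered, "genes;",
        object@nBiomarker, "biomarker-annotated;",
        object@nDisease, "disease-annotated\n")
    cat(sprintf("  within filtered: %.1f%% biomarker, %.1f%% disease\n",
                object@propWithinFiltered[["biomarker"]],
                object@propWithinFiltered[["disease"]]))
    cat(sprintf("  vs population: %.1f%% genes, %.1f%% biomarkers, %.1f%% disease\n",
                object@propVsPopulation[["filtered"]],
                object@propVsPopulation[["biomarker"]],
                object@propVsPopulation[["disease"]]))
    if (nrow(object@genes)) {
        cat("  survivors:\n")
        print(utils::head(object@genes, 10))
    }
})
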