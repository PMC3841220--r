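## Seeded synthetic generator: latent-Gaussian ordinal annotations with
## planted mapping-specific markers, and log-normal cohort fold changes
## with planted up-regulated genes.

#' Simulation configuration
#'
#' The generator emulates the structure of an antibody-based IHC annotation
#' resource. Each antibody has a latent staining level per tissue context:
#' \code{Normal(baselineMean, baselineSD)} for normal cell types and
#' \code{Normal(baselineMean + cancerMeanShift + effect, baselineSD)} per
#' cancer patient, where \code{effect} is non-zero only for planted markers.
#' The latent value is discretized through the intensity and quantity cut
#' points into the ordinal labels, so inverting the ordinal-to-numeric
#' transforms recovers the intended I*Q regime.
#'
#' A planted marker emulates a true tissue-specific cancer marker (the CEA
#' archetype): essentially absent from the target mapping's normal cell type
#' and overexpressed in the cancer. Its normal latent mean on the target
#' mapping is \code{baselineMean - effect} and its patient latent mean is
#' \code{baselineMean + effect}; with \code{effect = 3} the planted ED sits
#' about three population SDs above the null ED distribution. Mappings that
#' share a cancer type (e.g. the two colorectal mappings) share patient
#' records, so EiC is pooled per cancer type; the planting therefore shifts
#' \emph{all} patients of that cancer type and additionally raises the
#' \emph{sibling} mappings' normal latent by the same effect — the protein
#' is normally high in the sibling's cell type — which confines the elevated
#' ED to the target mapping.
#'
#' \code{cancerMeanShift} (default -0.3 latent SD) imposes a mild global
#' down-regulation trend on null antibodies in cancer, reproducing the
#' empirical observation that most mappings have a negative population ED
#' mean while top-ranked antibodies are up-regulated.
#'
#' @param nAntibodies number of antibodies (one gene per antibody).
#' @param registry a mapping registry; default the packaged 27-mapping one.
#' @param nPatientsPerCancer patient annotations per (antibody, mapping);
#'   default 12, the maximum patient count per antibody and cancer type in
#'   the emulated resource.
#' @param plantedMarkers \code{data.frame} with columns \code{antibody_id},
#'   \code{mapping_id}, \code{effect} (latent SD units); or \code{NULL}.
#'   An antibody may be planted for at most one mapping per cancer type.
#' @param baselineMean,baselineSD latent baseline (defaults 0, 1).
#' @param cancerMeanShift latent shift applied to all null cancer patients.
#' @param intensityCutpoints 3 increasing latent thresholds splitting
#'   Negative/Weak/Moderate/Strong; default quartile splits.
#' @param quantityCutpoints 4 increasing latent thresholds splitting
#'   Negative/Rare/<25\%/25-75\%/>75\%; default quintile splits.
#' @param missingRate probability that an (antibody, mapping) pair is
#'   untested (its normal and patient records are absent).
#' @param nCohortGenes,nCohortPatients cohort dimensions (defaults 1482
#'   genes, 28 patients, the published cohort shape).
#' @param plantedGenes character vector of up-regulated cohort genes.
#' @param plantedLog2Mean mean log2 fold change of planted genes (default
#'   2: expected mean FC well above 2 and expected qualifying-patient count
#'   well above 14 of 28).
#' @param log2SD per-patient log2 fold-change SD (default 1).
#' @param seed integer seed governing all draws.
#' @return a validated list of class \code{SimConfig}.
#' @seealso [simulateAnnotations()], [simulateCohort()], [plantMarkers()]
#' @export
simConfig <- function(nAntibodies, registry = NULL,
                      nPatientsPerCancer = 12L, plantedMarkers = NULL,
                      baselineMean = 0, baselineSD = 1,
                      cancerMeanShift = -0.3,
                      intensityCutpoints = qnorm(c(0.25, 0.5, 0.75)),
                      quantityCutpoints = qnorm(c(0.2, 0.4, 0.6, 0.8)),
                      missingRate = 0,
                      nCohortGenes = 1482L, nCohortPatients = 28L,
                      plantedGenes = character(), plantedLog2Mean = 2,
                      log2SD = 1, seed = 1L) {
    if (is.null(registry))
        registry <- loadMappingRegistry()
    stopifnot(nAntibodies >= 1, nPatientsPerCancer >= 1, baselineSD > 0,
              missingRate >= 0, missingRate <= 1,
              all(diff(intensityCutpoints) > 0),
              length(intensityCutpoints) == 3L,
              all(diff(quantityCutpoints) > 0),
              length(quantityCutpoints) == 4L,
              nCohortGenes >= 1, nCohortPatients >= 1, log2SD > 0,
              length(seed) == 1L, is.finite(seed))
    if (!is.null(plantedMarkers)) {
        stopifnot(is.data.frame(plantedMarkers),
                  all(c("antibody_id", "mapping_id", "effect") %in%
                      colnames(plantedMarkers)))
        bad <- !plantedMarkers$mapping_id %in% registry$mapping_id
        if (any(bad))
            stop("planted marker references unknown mapping_id: ",
                 plantedMarkers$mapping_id[which(bad)[1L]], call. = FALSE)
        ct <- registry$cancer_type[match(plantedMarkers$mapping_id,
                                         registry$mapping_id)]
        if (anyDuplicated(paste(plantedMarkers$antibody_id, ct)))
            stop("an antibody may be planted for at most one mapping per ",
                 "cancer type", call. = FALSE)
    }
    structure(list(
        nAntibodies = as.integer(nAntibodies), registry = registry,
        nPatientsPerCancer = as.integer(nPatientsPerCancer),
        plantedMarkers = plantedMarkers,
        baselineMean = baselineMean, baselineSD = baselineSD,
        cancerMeanShift = cancerMeanShift,
        intensityCutpoints = intensityCutpoints,
        quantityCutpoints = quantityCutpoints,
        missingRate = missingRate,
        nCohortGenes = as.integer(nCohortGenes),
        nCohortPatients = as.integer(nCohortPatients),
        plantedGenes = as.character(plantedGenes),
        plantedLog2Mean = plantedLog2Mean, log2SD = log2SD,
        seed = as.integer(seed)), class = "SimConfig")
}

#' Antibody / gene identifiers used by the generator
#'
#' \code{simAntibodyIds(n)} gives \code{AB0001 ...}; \code{simGeneIds(n)}
#' the matching \code{G0001 ...} (one gene per antibody).
#'
#' @param n how many identifiers.
#' @return a character vector.
#' @export
simAntibodyIds <- function(n) sprintf("AB%04d", seq_len(n))

#' @rdname simAntibodyIds
#' @export
simGeneIds <- function(n) sprintf("G%04d", seq_len(n))

#' Deterministic planted-marker design
#'
#' Assigns \code{perMapping} distinct antibodies to each mapping in registry
#' order, all at the same latent effect size. Convenience for building the
#' \code{plantedMarkers} slot of [simConfig()].
#'
#' @param nAntibodies total antibodies available; must be at least
#'   \code{perMapping * nrow(registry)}.
#' @param registry a mapping registry.
#' @param perMapping planted antibodies per mapping.
#' @param effect latent effect size in baseline-SD units (3 = strong).
#' @return a \code{data.frame} suitable for [simConfig()].
#' @export
plantMarkers <- function(nAntibodies, registry = NULL, perMapping = 1L,
                         effect = 3) {
    if (is.null(registry))
        registry <- loadMappingRegistry()
    need <- perMapping * nrow(registry)
    if (nAntibodies < need)
        stop("need at least ", need, " antibodies for ", perMapping,
             " planted per mapping", call. = FALSE)
    ab <- simAntibodyIds(nAntibodies)
    data.frame(
        antibody_id = ab[seq_len(need)],
        mapping_id = rep(registry$mapping_id, each = perMapping),
        effect = effect, stringsAsFactors = FALSE)
}

.cutLabels <- function(latent, cutpoints, labels) {
    labels[findInterval(latent, cutpoints) + 1L]
}

#' Simulate an IHC annotation table with known ground truth
#'
#' Generates, for every tested (antibody, mapping) pair, one normal record
#' and \code{nPatientsPerCancer} patient records under the latent model
#' described in [simConfig()]. Fully reproducible: the same config and seed
#' give byte-identical output. Draw order is fixed — testedness, then all
#' normal latents, then all patient latents.
#'
#' @param config a [simConfig()] object.
#' @return a list with \code{annotations} (a validated annotation
#'   \code{data.frame}) and \code{truth} (one row per (antibody, mapping):
#'   \code{antibody_id}, \code{mapping_id}, \code{tested}, \code{planted},
#'   \code{effect}).
#' @examples
#' sim <- simulateAnnotations(simConfig(nAntibodies = 3, seed = 7))
#' nrow(sim$annotations)   # 3 * 27 * (1 + 12)
#' @export
simulateAnnotations <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    reg <- config$registry
    nAb <- config$nAntibodies
    nMap <- nrow(reg)
    nPat <- config$nPatientsPerCancer
    ab <- simAntibodyIds(nAb)
    gene <- simGeneIds(nAb)

    tested <- matrix(runif(nAb * nMap) >= config$missingRate, nAb, nMap,
                     dimnames = list(ab, reg$mapping_id))

    ## planted effects: cancer shift per (antibody, cancer type) spread to
    ## all mappings of that type; normal boost on the sibling mappings
    cancerShift <- normalBoost <- matrix(0, nAb, nMap,
                                         dimnames = dimnames(tested))
    planted <- matrix(FALSE, nAb, nMap, dimnames = dimnames(tested))
    effects <- matrix(0, nAb, nMap, dimnames = dimnames(tested))
    pm <- config$plantedMarkers
    if (!is.null(pm) && nrow(pm)) {
        if (!all(pm$antibody_id %in% ab))
            stop("planted antibody_id outside the simulated antibody set",
                 call. = FALSE)
        for (i in seq_len(nrow(pm))) {
            a <- match(pm$antibody_id[i], ab)
            m <- match(pm$mapping_id[i], reg$mapping_id)
            sibs <- which(reg$cancer_type == reg$cancer_type[m])
            cancerShift[a, sibs] <- cancerShift[a, sibs] + pm$effect[i]
            normalBoost[a, m] <- normalBoost[a, m] - pm$effect[i]
            off <- setdiff(sibs, m)
            normalBoost[a, off] <- normalBoost[a, off] + pm$effect[i]
            planted[a, m] <- TRUE
            effects[a, m] <- pm$effect[i]
        }
    }

    latN <- matrix(rnorm(nAb * nMap, config$baselineMean, config$baselineSD),
                   nAb, nMap) + normalBoost
    shift <- config$baselineMean + config$cancerMeanShift + cancerShift
    latC <- array(rnorm(nAb * nMap * nPat, 0, config$baselineSD),
                  dim = c(nAb, nMap, nPat)) +
        array(shift, dim = c(nAb, nMap, nPat))

    keep <- which(tested)                     # column-major (ab, mapping)
    ai <- ((keep - 1L) %% nAb) + 1L
    mi <- ((keep - 1L) %/% nAb) + 1L
    normRows <- data.frame(
        antibody_id = ab[ai], gene = gene[ai],
        tissue = reg$normal_tissue[mi], cell_type = reg$normal_cell_type[mi],
        sample_kind = "normal", cancer_type = "", patient_id = "",
        intensity = .cutLabels(latN[keep], config$intensityCutpoints,
                               .INTENSITY_LEVELS),
        quantity = .cutLabels(latN[keep], config$quantityCutpoints,
                              .QUANTITY_LEVELS),
        stringsAsFactors = FALSE)

    aiP <- rep(ai, each = nPat)
    miP <- rep(mi, each = nPat)
    pat <- rep(seq_len(nPat), times = length(keep))
    latKeep <- latC[cbind(rep(ai, each = nPat), rep(mi, each = nPat), pat)]
    cancRows <- data.frame(
        antibody_id = ab[aiP], gene = gene[aiP],
        tissue = "", cell_type = "",
        sample_kind = "cancer", cancer_type = reg$cancer_type[miP],
        patient_id = sprintf("%s-P%02d", reg$mapping_id[miP], pat),
        intensity = .cutLabels(latKeep, config$intensityCutpoints,
                               .INTENSITY_LEVELS),
        quantity = .cutLabels(latKeep, config$quantityCutpoints,
                              .QUANTITY_LEVELS),
        stringsAsFactors = FALSE)

    annotations <- rbind(normRows, cancRows)
    ord <- order(annotations$antibody_id,
                 annotations$sample_kind != "normal",
                 annotations$tissue, annotations$cancer_type,
                 annotations$patient_id)
    annotations <- annotations[ord, , drop = FALSE]
    rownames(annotations) <- NULL

    truth <- data.frame(
        antibody_id = rep(ab, nMap),
        mapping_id = rep(reg$mapping_id, each = nAb),
        tested = as.vector(tested),
        planted = as.vector(planted),
        effect = as.vector(effects),
        stringsAsFactors = FALSE)
    list(annotations = .validateAnnotations(annotations), truth = truth)
}

#' Simulate a paired tumor/normal cohort fold-change table
#'
#' Null genes draw per-patient \code{log2} fold changes from
#' \code{Normal(0, log2SD)}; planted genes from
#' \code{Normal(plantedLog2Mean, log2SD)}. With the defaults a planted gene
#' passes both the mean-fold-change and the patient-count filtering rules
#' with high probability, a null gene almost never does. Cohort genes are
#' named as [simGeneIds()], matching the annotation generator's genes, so
#' simulated cohorts and simulated score tables can be filtered together.
#' Uses \code{seed + 1} so annotations and cohort of one config are
#' independent streams.
#'
#' @param config a [simConfig()] object.
#' @return a list with \code{cohort} (\code{gene}, \code{patient_id},
#'   \code{fold_change}) and \code{truth} (\code{gene}, \code{planted}).
#' @examples
#' sim <- simulateCohort(simConfig(nAntibodies = 1, nCohortGenes = 10,
#'                                 plantedGenes = "G0001", seed = 3))
#' subset(sim$truth, planted)
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    genes <- simGeneIds(config$nCohortGenes)
    bad <- setdiff(config$plantedGenes, genes)
    if (length(bad))
        stop("planted gene outside the simulated gene set: ", bad[1L],
             call. = FALSE)
    nP <- config$nCohortPatients
    isPlanted <- genes %in% config$plantedGenes
    mu <- ifelse(isPlanted, config$plantedLog2Mean, 0)
    lfc <- rnorm(length(genes) * nP,
                 mean = rep(mu, each = nP), sd = config$log2SD)
    cohort <- data.frame(
        gene = rep(genes, each = nP),
        patient_id = rep(sprintf("P%02d", seq_len(nP)), length(genes)),
        fold_change = 2^lfc, stringsAsFactors = FALSE)
    list(cohort = cohort,
         truth = data.frame(gene = genes, planted = isPlanted,
                            stringsAsFactors = FALSE))
}
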