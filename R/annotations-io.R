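## On-disk TSV schemas. All readers are strict: unknown labels, missing
## columns and integrity violations are errors naming the offending row.

.INTENSITY_LEVELS <- c("Negative", "Weak", "Moderate", "Strong")
.QUANTITY_LEVELS <- c("Negative", "Rare", "<25%", "25-75%", ">75%")

.ANNOTATION_COLS <- c("antibody_id", "gene", "tissue", "cell_type",
                      "sample_kind", "cancer_type", "patient_id",
                      "intensity", "quantity")
.MAPPING_COLS <- c("mapping_id", "cancer_type", "normal_tissue",
                   "normal_cell_type")
.COHORT_COLS <- c("gene", "patient_id", "fold_change")

.read_tsv <- function(path, required, what, keep_extra = FALSE) {
    if (!file.exists(path))
        stop(what, " file not found: ", path, call. = FALSE)
    x <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "", encoding = "UTF-8")
    miss <- setdiff(required, colnames(x))
    if (length(miss))
        stop(what, " file ", path, " lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (keep_extra)
        x[c(required, setdiff(colnames(x), required))]
    else x[required]
}

## The published spelling "75%-25%" (and dash variants) normalizes to the
## canonical token "25-75%".
.normalizeQuantity <- function(q) {
    q <- gsub("–|—", "-", q)
    q[q %in% c("75%-25%", "25%-75%", "25-75")] <- "25-75%"
    q
}

.checkEnum <- function(value, levels, field, rows) {
    bad <- which(!value %in% levels)
    if (length(bad))
        stop("unknown ", field, " label \"", value[bad[1L]], "\" in row ",
             rows[bad[1L]], " (allowed: ",
             paste(levels, collapse = ", "), ")", call. = FALSE)
    invisible(TRUE)
}

.validateAnnotations <- function(ann) {
    rows <- seq_len(nrow(ann)) + 1L   # +1: header line
    .checkEnum(ann$sample_kind, c("normal", "cancer"), "sample_kind", rows)
    ann$quantity <- .normalizeQuantity(ann$quantity)
    .checkEnum(ann$intensity, .INTENSITY_LEVELS, "intensity", rows)
    .checkEnum(ann$quantity, .QUANTITY_LEVELS, "quantity", rows)

    isN <- ann$sample_kind == "normal"
    bad <- isN & (ann$patient_id != "" | ann$cancer_type != "")
    if (any(bad))
        stop("normal annotation with non-empty patient_id/cancer_type in row ",
             rows[which(bad)[1L]], call. = FALSE)
    bad <- !isN & (ann$patient_id == "" | ann$cancer_type == "")
    if (any(bad))
        stop("cancer annotation with empty patient_id/cancer_type in row ",
             rows[which(bad)[1L]], call. = FALSE)
    bad <- isN & (ann$tissue == "" | ann$cell_type == "")
    if (any(bad))
        stop("normal annotation with empty tissue/cell_type in row ",
             rows[which(bad)[1L]], call. = FALSE)

    ## one normal record per (antibody, tissue, cell type): the source
    ## resource reports a single Intensity/Quantity pair for a normal cell
    ## type however many stainings were done
    key <- paste(ann$antibody_id, ann$tissue, ann$cell_type, sep = "\r")[isN]
    if (anyDuplicated(key)) {
        d <- key[duplicated(key)][1L]
        stop("duplicate normal record for (antibody, tissue, cell_type) = (",
             gsub("\r", ", ", d), ")", call. = FALSE)
    }

    ## an antibody targets a single gene
    g <- unique(ann[c("antibody_id", "gene")])
    if (anyDuplicated(g$antibody_id))
        stop("antibody ", g$antibody_id[duplicated(g$antibody_id)][1L],
             " linked to more than one gene", call. = FALSE)
    ann
}

#' Read an IHC staining annotation table
#'
#' Reads the canonical tab-separated annotation format: one row per staining
#' result with columns \code{antibody_id}, \code{gene}, \code{tissue},
#' \code{cell_type}, \code{sample_kind} (\code{normal} or \code{cancer}),
#' \code{cancer_type}, \code{patient_id}, \code{intensity}
#' (Negative/Weak/Moderate/Strong) and \code{quantity}
#' (Negative/Rare/<25\%/25-75\%/>75\%). Normal rows describe one normal cell
#' type (empty \code{cancer_type}/\code{patient_id}, at most one row per
#' antibody-tissue-cell type); cancer rows describe one patient sample. The
#' alternative quantity spelling \code{75\%-25\%} is accepted and normalized
#' to \code{25-75\%}.
#'
#' @param path path to a TSV file with the header above.
#' @return a \code{data.frame} of validated annotations (character columns).
#' @examples
#' ann <- readAnnotations(exampleAnnotationFile())
#' table(ann$sample_kind)
#' @seealso [writeAnnotations()], [buildEDMatrix()]
#' @export
readAnnotations <- function(path) {
    ann <- .read_tsv(path, .ANNOTATION_COLS, "annotation")
    .validateAnnotations(ann)
}

#' Write an IHC staining annotation table
#'
#' Inverse of [readAnnotations()]; writing then reading is the identity on
#' validated annotation tables.
#'
#' @param ann a validated annotation \code{data.frame}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(ann, path) {
    stopifnot(all(.ANNOTATION_COLS %in% colnames(ann)))
    write.table(ann[.ANNOTATION_COLS], path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Load a cancer-to-normal tissue mapping registry
#'
#' A mapping pairs one cancer type with the normal tissue and cell type it
#' is compared against; a cancer type may appear in several mappings (e.g.
#' colorectal cancer against colon and against rectum glandular cells).
#' Without \code{path} the packaged default registry is loaded: 27 mappings
#' covering 20 cancer types. Ovarian cancer has no mapping (the source
#' resource lacks normal ovary staining), and hepatocellular carcinoma and
#' cholangiocarcinoma are distinct cancer types.
#'
#' @param path optional path to a TSV with columns \code{mapping_id},
#'   \code{cancer_type}, \code{normal_tissue}, \code{normal_cell_type}.
#' @return a \code{data.frame} registry with unique \code{mapping_id}.
#' @examples
#' reg <- loadMappingRegistry()
#' nrow(reg)                      # 27
#' length(unique(reg$cancer_type))  # 20
#' @export
loadMappingRegistry <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "mappings.tsv", package = "ihcscore",
                            mustWork = TRUE)
    reg <- .read_tsv(path, .MAPPING_COLS, "mapping registry")
    if (anyDuplicated(reg$mapping_id))
        stop("duplicate mapping_id: ",
             reg$mapping_id[duplicated(reg$mapping_id)][1L], call. = FALSE)
    if (any(reg$mapping_id == ""))
        stop("empty mapping_id in registry", call. = FALSE)
    reg
}

#' Read a paired tumor/normal cohort fold-change table
#'
#' One row per (gene, patient): the tumor versus adjacent-normal expression
#' ratio of the gene in that patient. Fold changes must be positive and
#' unique per pair.
#'
#' @param path path to a TSV with columns \code{gene}, \code{patient_id},
#'   \code{fold_change}.
#' @param quiet suppress the summary message.
#' @return a \code{data.frame} with character \code{gene}/\code{patient_id}
#'   and numeric \code{fold_change}.
#' @examples
#' co <- readCohort(exampleCohortFile(), quiet = TRUE)
#' length(unique(co$gene))
#' @export
readCohort <- function(path, quiet = FALSE) {
    x <- .read_tsv(path, .COHORT_COLS, "cohort")
    fc <- suppressWarnings(as.numeric(x$fold_change))
    bad <- which(is.na(fc) | fc <= 0)
    if (length(bad))
        stop("non-positive or non-numeric fold_change \"",
             x$fold_change[bad[1L]], "\" in row ", bad[1L] + 1L,
             call. = FALSE)
    key <- paste(x$gene, x$patient_id, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (gene, patient) pair: ",
             gsub("\r", ", ", key[duplicated(key)][1L]), call. = FALSE)
    x$fold_change <- fc
    if (!quiet)
        message("cohort: ", length(unique(x$gene)), " genes, ",
                length(unique(x$patient_id)), " patients")
    x
}

#' Read a gene annotation table (biomarker / disease flags)
#'
#' A stand-in for external curated gene annotation: per gene, whether it has
#' a biomarker annotation and whether it has a disease annotation. Accepts
#' logical-like values (\code{TRUE/FALSE}, \code{Yes/No}, \code{1/0}).
#'
#' @param path path to a TSV with columns \code{gene}, \code{is_biomarker},
#'   \code{is_disease_related}.
#' @return a \code{data.frame} with logical flag columns, one row per gene.
#' @export
readGeneAnnotations <- function(path) {
    x <- .read_tsv(path, c("gene", "is_biomarker", "is_disease_related"),
                   "gene annotation")
    if (anyDuplicated(x$gene))
        stop("duplicate gene in gene annotation table: ",
             x$gene[duplicated(x$gene)][1L], call. = FALSE)
    tological <- function(v, field) {
        out <- rep(NA, length(v))
        out[tolower(v) %in% c("true", "yes", "1", "t", "y")] <- TRUE
        out[tolower(v) %in% c("false", "no", "0", "f", "n")] <- FALSE
        if (anyNA(out))
            stop("non-logical value \"", v[which(is.na(out))[1L]],
                 "\" in column ", field, call. = FALSE)
        out
    }
    x$is_biomarker <- tological(x$is_biomarker, "is_biomarker")
    x$is_disease_related <- tological(x$is_disease_related,
                                      "is_disease_related")
    x
}

#' Write a score table
#'
#' Writes the output of [scoresTable()] as TSV with floats at 6 significant
#' digits.
#'
#' @param scores a score \code{data.frame}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(scores, path) {
    out <- scores
    for (cl in c("EiN", "EiC", "ED", "SG", "SP", "score"))
        if (cl %in% colnames(out))
            out[[cl]] <- signif(out[[cl]], 6L)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a score table written by [writeScores()]
#'
#' @param path path to a scores TSV; must at least carry \code{antibody_id},
#'   \code{gene}, \code{mapping_id} and \code{score}.
#' @return a \code{data.frame}.
#' @export
readScores <- function(path) {
    x <- .read_tsv(path, c("antibody_id", "gene", "mapping_id", "score"),
                   "score", keep_extra = TRUE)
    for (cl in intersect(c("EiN", "EiC", "ED", "SG", "SP"), colnames(x)))
        x[[cl]] <- as.numeric(x[[cl]])
    for (cl in intersect(c("n_patients", "rank"), colnames(x)))
        x[[cl]] <- as.integer(x[[cl]])
    x$score <- as.numeric(x$score)
    if (anyNA(x$score) || any(x$score < 0))
        stop("scores must be non-negative numbers", call. = FALSE)
    x
}

#' Packaged example files
#'
#' \code{exampleAnnotationFile()}: the worked-example staining records of
#' antibody HPA034966 on breast tissue (one normal glandular-cell record,
#' twelve breast-cancer patient records). The remaining three files are a
#' synthetic reconstruction of the published colorectal-cancer case study
#' candidates (CEACAM5, CEACAM6, ANXA4, CAMP): per-patient fold changes
#' constructed so that each gene's mean fold change and qualifying-patient
#' count equal the published values, one antibody score per gene, and the
#' published biomarker/disease flags. The underlying per-patient cohort is
#' not public, hence the \code{synthetic} label.
#'
#' @return a file path.
#' @examples
#' readAnnotations(exampleAnnotationFile())
#' @export
exampleAnnotationFile <- function() {
    system.file("extdata", "hpa034966_breast.tsv", package = "ihcscore",
                mustWork = TRUE)
}

#' @rdname exampleAnnotationFile
#' @export
exampleCohortFile <- function() {
    system.file("extdata", "crc_example_cohort_synthetic.tsv",
                package = "ihcscore", mustWork = TRUE)
}

#' @rdname exampleAnnotationFile
#' @export
exampleScoresFile <- function() {
    system.file("extdata", "crc_example_scores_synthetic.tsv",
                package = "ihcscore", mustWork = TRUE)
}

#' @rdname exampleAnnotationFile
#' @export
exampleGeneAnnotationFile <- function() {
    system.file("extdata", "crc_example_gene_annotations_synthetic.tsv",
                package = "ihcscore", mustWork = TRUE)
}
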