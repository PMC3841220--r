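#' Ordinal-to-numeric transforms of IHC staining annotations
#'
#' The staining strength \emph{Intensity} maps Strong, Moderate, Weak,
#' Negative to 3, 2, 1, 0; the stained-cell fraction \emph{Quantity} maps
#' >75\%, 25-75\%, <25\%, Rare, Negative to 75, 50, 25, 5, 0. The product
#' \code{I * Q} is the numeric expression level of one staining result, on
#' the 0-225 scale.
#'
#' @param label an intensity or quantity label (vectorized).
#' @return an integer vector.
#' @examples
#' intensityToNumeric("Moderate")   # 2
#' quantityToNumeric(">75%")        # 75
#' @export
intensityToNumeric <- function(label) {
    val <- c(Negative = 0L, Weak = 1L, Moderate = 2L, Strong = 3L)
    bad <- which(!label %in% names(val))
    if (length(bad))
        stop("unknown intensity label \"", label[bad[1L]], "\"",
             call. = FALSE)
    unname(val[label])
}

#' @rdname intensityToNumeric
#' @export
quantityToNumeric <- function(label) {
    label <- .normalizeQuantity(label)
    val <- setNames(c(0L, 5L, 25L, 50L, 75L), .QUANTITY_LEVELS)
    bad <- which(!label %in% names(val))
    if (length(bad))
        stop("unknown quantity label \"", label[bad[1L]], "\"",
             call. = FALSE)
    unname(val[label])
}

#' Expression level in a normal cell type (EiN)
#'
#' The resource reports a single Intensity/Quantity pair per normal cell
#' type, so \code{EiN = I * Q} of that one pair, in [0, 225].
#'
#' @param intensity,quantity ordinal labels of the single normal annotation.
#' @return a numeric scalar.
#' @examples
#' expressionInNormal("Moderate", ">75%")   # 2 * 75 = 150
#' @export
expressionInNormal <- function(intensity, quantity) {
    stopifnot(length(intensity) == 1L, length(quantity) == 1L)
    as.numeric(intensityToNumeric(intensity) * quantityToNumeric(quantity))
}

#' Expression level in a cancer type (EiC)
#'
#' Each patient sample contributes one Intensity/Quantity pair;
#' \code{EiC} is the mean of \code{I * Q} over the patients, in [0, 225].
#'
#' @param intensity,quantity equal-length label vectors, one element per
#'   patient annotation (at least one).
#' @return a list with \code{EiC} (numeric) and \code{n_patients} (integer).
#' @examples
#' expressionInCancer(c("Strong", "Moderate"), c(">75%", ">75%"))
#' @export
expressionInCancer <- function(intensity, quantity) {
    if (length(intensity) == 0L)
        stop("antibody not tested in this cancer: no patient annotations",
             call. = FALSE)
    if (length(intensity) != length(quantity))
        stop("intensity and quantity must have one entry per patient",
             call. = FALSE)
    prod <- intensityToNumeric(intensity) * quantityToNumeric(quantity)
    list(EiC = mean(prod), n_patients = length(prod))
}

#' Expression difference (ED)
#'
#' \code{ED = EiC - EiN}, the overexpression signal of an antibody for a
#' mapping, in [-225, 225]. If either side is \code{NA} (pair untested) the
#' result is \code{NA}: the pair is unscored, not an error.
#'
#' @param EiC,EiN numeric vectors on the 0-225 scale.
#' @return a numeric vector.
#' @examples
#' expressionDifference(168.75, 150)   # 18.75
#' @export
expressionDifference <- function(EiC, EiN) {
    EiC - EiN
}
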