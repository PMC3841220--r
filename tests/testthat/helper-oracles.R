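# Independent oracles, deliberately not sharing code paths with the package.

# Standard normal CDF by Taylor series around 0:
# Phi(z) = 1/2 + phi(z) * sum_{n>=0} z^(2n+1) / (1*3*...*(2n+1)).
# Density written out so no stats:: d/p function is involved.
phiSeries <- function(z) {
    vapply(z, function(zi) {
        if (zi < -8) return(0)
        if (zi > 8) return(1)
        term <- zi
        total <- zi
        n <- 0L
        while (abs(term) > 1e-17 && n < 400L) {
            n <- n + 1L
            term <- term * zi * zi / (2 * n + 1)
            total <- total + term
        }
        0.5 + total * exp(-zi^2 / 2) / sqrt(2 * pi)
    }, numeric(1))
}

# Upper-tail Student-t probability by numerical integration of the density.
tUpperTailOracle <- function(t, df) {
    dens <- function(x)
        gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
            (1 + x^2 / df)^(-(df + 1) / 2)
    stats::integrate(dens, lower = t, upper = Inf, rel.tol = 1e-11)$value
}

# One annotation row in the canonical schema.
annRow <- function(antibody, gene, kind, tissue = "", cell = "",
                   cancer = "", patient = "", intensity, quantity) {
    data.frame(antibody_id = antibody, gene = gene, tissue = tissue,
               cell_type = cell, sample_kind = kind, cancer_type = cancer,
               patient_id = patient, intensity = intensity,
               quantity = quantity, stringsAsFactors = FALSE)
}

# Minimal registry for handcrafted cases: nm distinct cancers and tissues.
tinyRegistry <- function(nm = 2L) {
    data.frame(mapping_id = sprintf("M%02d", seq_len(nm)),
               cancer_type = sprintf("Cancer %02d", seq_len(nm)),
               normal_tissue = sprintf("tissue %02d", seq_len(nm)),
               normal_cell_type = "cells",
               stringsAsFactors = FALSE)
}

# Annotation set realizing prescribed EiN/EiC per antibody x mapping.
# EiN must be an attainable single I*Q product; EiC is realized with one
# patient whose product equals the value (also attainable), or NA to leave
# the pair untested.
craftAnnotations <- function(EiN, EiC, registry) {
    lv <- expand.grid(i = c("Negative", "Weak", "Moderate", "Strong"),
                      q = c("Negative", "Rare", "<25%", "25-75%", ">75%"),
                      stringsAsFactors = FALSE)
    lv$p <- intensityToNumeric(lv$i) * quantityToNumeric(lv$q)
    pick <- function(v) {
        k <- which(lv$p == v)[1L]
        if (is.na(k)) stop("value ", v, " not attainable as a single I*Q")
        lv[k, c("i", "q")]
    }
    rows <- list()
    for (a in rownames(EiN)) for (j in seq_len(ncol(EiN))) {
        if (is.na(EiN[a, j]) || is.na(EiC[a, j])) next
        pn <- pick(EiN[a, j]); pc <- pick(EiC[a, j])
        rows[[length(rows) + 1L]] <- rbind(
            annRow(a, paste0("g", a), "normal",
                   tissue = registry$normal_tissue[j],
                   cell = registry$normal_cell_type[j],
                   intensity = pn$i, quantity = pn$q),
            annRow(a, paste0("g", a), "cancer",
                   cancer = registry$cancer_type[j],
                   patient = paste0("pt-", j),
                   intensity = pc$i, quantity = pc$q))
    }
    do.call(rbind, rows)
}
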