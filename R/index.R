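#' Poly(A) usage index (PUI) of one site in one cell
#'
#' For the counts \code{pc} of all poly(A) sites of one gene in one cell,
#' the PUI of site \code{i} is
#' \deqn{\mathrm{PUI}_i = \log_2\frac{pc_i + 1}{\exp(\mathrm{mean}(\ln(pc + 1)))},}
#' i.e. the log2 ratio of the site's pseudocounted expression to the
#' geometric mean of pseudocounted expression over the gene's sites.
#' \code{PUI > 0} means above-average usage of the site in that cell;
#' for the proximal 3'UTR site this indicates a shorter 3'UTR. If no site
#' of the gene is expressed in the cell, the PUI is undefined (\code{NA}).
#'
#' @param pc non-negative counts of all sites of one gene in one cell
#'   (length >= 2).
#' @param i site index within \code{pc}.
#' @return PUI value, or \code{NA} when all counts are zero.
#' @examples
#' computePUI(c(3, 1), 1)  # 0.5
#' computePUI(c(0, 3), 2)  # 1
#' computePUI(c(0, 0), 1)  # NA
#' @export
computePUI <- function(pc, i) {
    .checkPcI(pc, i)
    if (all(pc == 0)) return(NA_real_)
    log2((pc[i] + 1) / exp(mean(log(pc + 1))))
}

#' Usage ratio of one site in one cell
#'
#' The fraction \code{pc[i] / sum(pc)} of the gene's expression in the cell
#' attributed to site \code{i}; \code{NA} when the gene is unexpressed.
#'
#' @inheritParams computePUI
#' @return Ratio in \code{[0, 1]}, or \code{NA} when all counts are zero.
#' @examples
#' computeRatio(c(3, 1), 1)  # 0.75
#' @export
computeRatio <- function(pc, i) {
    .checkPcI(pc, i)
    s <- sum(pc)
    if (s == 0) return(NA_real_)
    pc[i] / s
}

.checkPcI <- function(pc, i) {
    if (length(pc) < 2)
        stop("gene has fewer than two poly(A) sites; not an APA gene")
    if (any(pc < 0)) stop("counts must be non-negative")
    if (length(i) != 1 || i < 1 || i > length(pc))
        stop("site index ", i, " out of range 1..", length(pc))
    invisible(NULL)
}

#' Select the proximal 3'UTR poly(A) site of a gene
#'
#' The proximal site is the one closest to the stop codon: smallest genomic
#' position on the + strand, largest on the - strand (the stop codon lies 5'
#' of the 3'UTR).
#'
#' @param sites data.frame of site annotations for one gene restricted to
#'   regions \code{3UTR} / \code{3UTR_ext}, with columns \code{site_id},
#'   \code{strand}, \code{position}, \code{gene_id}, \code{region}.
#' @return The \code{site_id} of the proximal site.
#' @export
selectProximalSite <- function(sites) {
    sites <- as.data.frame(sites)
    if (nrow(sites) < 2)
        stop("need at least two 3'UTR poly(A) sites to pick a proximal one")
    if (length(unique(sites$gene_id)) > 1)
        stop("sites belong to more than one gene")
    if (!all(as.character(sites$region) %in% .UTR3_REGIONS))
        stop("sites must be restricted to regions 3UTR / 3UTR_ext")
    strand <- unique(as.character(sites$strand))
    if (length(strand) > 1)
        stop("mixed strands within gene ", sites$gene_id[1],
             ": annotation error")
    idx <- if (strand == "+") which.min(sites$position)
           else which.max(sites$position)
    sites$site_id[idx]
}

#' Select the major and minor poly(A) site of a gene
#'
#' The major site is the gene's most expressed site by counts summed across
#' the analysed cells, the minor the least expressed; ties resolve to the
#' lowest site index (annotation order).
#'
#' @param siteTotals per-site counts summed across cells (length >= 2).
#' @return Named integer vector \code{c(major = ..., minor = ...)}.
#' @examples
#' selectMajorMinor(c(10, 3, 7))  # major 1, minor 2
#' @export
selectMajorMinor <- function(siteTotals) {
    if (length(siteTotals) < 2)
        stop("need at least two poly(A) sites")
    major <- unname(which.max(siteTotals))
    rest <- setdiff(seq_along(siteTotals), major)
    minor <- rest[unname(which.min(siteTotals[rest]))]
    c(major = major, minor = minor)
}

#' Build an APA signal matrix from a filtered count matrix
#'
#' Turns a (filtered) \linkS4class{PACountMatrix} into the features-by-cells
#' signal matrix consumed by the modality caller:
#' \describe{
#'   \item{\code{gene_proximal_PUI}}{one row per APA gene: the PUI of its
#'     proximal 3'UTR site in each cell, representing the gene's relative
#'     3'UTR length.}
#'   \item{\code{site_PUI}}{one row per site: its PUI within the gene.}
#'   \item{\code{major_ratio} / \code{minor_ratio}}{one row per gene:
#'     \code{log2(ratio + 1)} of the gene's major / minor site in each cell.
#'     The log2(x+1) transform keeps the ratio on the same order of
#'     magnitude as the PUI.}
#' }
#' Entries are \code{NA} in cells where the gene is unexpressed.
#'
#' @param sm a \linkS4class{PACountMatrix}, already filtered for the chosen
#'   mode (see \code{\link{filter3UTR}} / \code{\link{filterNon3UTR}}).
#' @param mode one of \code{"gene_proximal_PUI"}, \code{"site_PUI"},
#'   \code{"major_ratio"}, \code{"minor_ratio"}.
#' @return An \linkS4class{APASignalMatrix}.
#' @export
buildSignalMatrix <- function(sm, mode = c("gene_proximal_PUI", "site_PUI",
                                           "major_ratio", "minor_ratio")) {
    mode <- match.arg(mode)
    counts <- as.matrix(assay(sm, "counts"))
    rd <- as.data.frame(rowData(sm))
    genes <- split(seq_len(nrow(rd)), rd$gene_id)
    nC <- ncol(counts)
    rows <- list()
    ids <- character()
    for (g in names(genes)) {
        idx <- genes[[g]]
        if (length(idx) < 2)
            stop("gene ", g, " has a single retained site; mode '", mode,
                 "' needs at least two (filter/mode mismatch)")
        sub <- counts[idx, , drop = FALSE]
        expressed <- colSums(sub) > 0
        logp <- log(sub + 1)
        gmLog <- colMeans(logp)     # log geometric mean of pc + 1
        if (mode == "gene_proximal_PUI") {
            utr <- rd[idx, ][as.character(rd$region[idx]) %in% .UTR3_REGIONS, ]
            proxId <- selectProximalSite(utr)
            i <- which(rd$site_id[idx] == proxId)
            val <- (logp[i, ] - gmLog) / log(2)
            val[!expressed] <- NA_real_
            rows[[length(rows) + 1L]] <- val
            ids <- c(ids, g)
        } else if (mode == "site_PUI") {
            for (i in seq_along(idx)) {
                val <- (logp[i, ] - gmLog) / log(2)
                val[!expressed] <- NA_real_
                rows[[length(rows) + 1L]] <- val
                ids <- c(ids, rd$site_id[idx[i]])
            }
        } else {
            mm <- selectMajorMinor(rowSums(sub))
            i <- if (mode == "major_ratio") mm["major"] else mm["minor"]
            ratio <- sub[i, ] / colSums(sub)
            val <- log2(ratio + 1)
            val[!expressed] <- NA_real_
            rows[[length(rows) + 1L]] <- val
            ids <- c(ids, g)
        }
    }
    sig <- do.call(rbind, rows)
    if (is.null(sig)) sig <- matrix(numeric(), 0, nC)
    colnames(sig) <- colnames(counts)
    kind <- switch(mode, gene_proximal_PUI = "gene_proximal_PUI",
                   site_PUI = "site_PUI",
                   major_ratio = "major_site", minor_ratio = "minor_site")
    out <- APASignalMatrix(sig, featureKind = kind, featureId = ids)
    if (mode == "site_PUI") {
        reg <- rd$region[match(ids, rd$site_id)]
        rowData(out)$region <- as.character(reg)
        rowData(out)$gene_id <- rd$gene_id[match(ids, rd$site_id)]
    }
    out
}
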