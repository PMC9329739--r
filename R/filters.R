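#' Expression filters for the 3'UTR modality pipeline
#'
#' Selects well-expressed 3'UTR poly(A) sites, cells and APA genes before
#' modality analysis. Applied in sequence: (1) drop sites with nonzero
#' counts in less than a quarter of cells; (2) drop cells in which less than
#' one tenth of the retained sites are expressed; (3) keep only genes with
#' at least two retained 3'UTR sites. "Expressed" means count > 0.
#'
#' @param sm a \linkS4class{PACountMatrix} restricted to regions
#'   \code{3UTR} / \code{3UTR_ext}.
#' @return The filtered \linkS4class{PACountMatrix}; the per-rule removal
#'   counts are attached as a filter report retrievable with
#'   \code{\link{filterReport}}. An empty result triggers a warning, not an
#'   error.
#' @export
filter3UTR <- function(sm) {
    rd <- rowData(sm)
    if (!all(as.character(rd$region) %in% .UTR3_REGIONS))
        stop("filter3UTR expects a matrix restricted to 3UTR/3UTR_ext sites")
    counts <- assay(sm, "counts")
    nSites0 <- nrow(sm); nCells0 <- ncol(sm)
    nGenes0 <- length(unique(rd$gene_id))

    expressed <- counts > 0
    keepSite <- Matrix::rowMeans(expressed) >= 0.25
    sm1 <- sm[keepSite, ]

    if (nrow(sm1) > 0) {
        keepCell <- Matrix::colMeans(assay(sm1, "counts") > 0) >= 0.10
    } else keepCell <- rep(TRUE, ncol(sm1))
    sm2 <- sm1[, keepCell]

    geneTab <- table(as.character(rowData(sm2)$gene_id))
    keepGene <- as.character(rowData(sm2)$gene_id) %in%
        names(geneTab)[geneTab >= 2]
    sm3 <- sm2[keepGene, ]

    report <- .filterReport(
        nSites0, nCells0, nGenes0, sm3,
        rules = c(sites_low_expression = sum(!keepSite),
                  cells_low_coverage = sum(!keepCell),
                  sites_in_single_site_genes = sum(!keepGene)))
    if (nrow(sm3) == 0 || ncol(sm3) == 0)
        warning("3'UTR filtering left an empty matrix")
    metadata(sm3)$filter_report <- report
    sm3
}

#' Expression filters for the non-3'UTR modality pipeline
#'
#' Applied in sequence: (1) keep genes with more than three poly(A) sites in
#' total, at least one non-3'UTR site and at least two 3'UTR sites; (2) per
#' gene keep only the single non-3'UTR site with the largest total
#' expression (plus the gene's 3'UTR sites); (3) drop sites expressed in
#' less than half of the cells; (4) drop cells in which at most half of the
#' retained sites are expressed.
#'
#' @param sm a \linkS4class{PACountMatrix} containing all genomic regions.
#' @return As \code{\link{filter3UTR}}.
#' @export
filterNon3UTR <- function(sm) {
    rd <- rowData(sm)
    nSites0 <- nrow(sm); nCells0 <- ncol(sm)
    nGenes0 <- length(unique(rd$gene_id))
    isUtr <- as.character(rd$region) %in% .UTR3_REGIONS
    gene <- as.character(rd$gene_id)

    nTotal <- table(gene)
    nUtr <- table(gene[isUtr])
    nNon <- table(gene[!isUtr])
    ok <- function(tab, g, min) !is.na(tab[g]) & tab[g] >= min
    goodGene <- names(nTotal)[nTotal >= 4 &
                              ok(nUtr, names(nTotal), 2) &
                              ok(nNon, names(nTotal), 1)]
    keepGene <- gene %in% goodGene
    sm1 <- sm[keepGene, ]

    rd1 <- rowData(sm1)
    totals <- Matrix::rowSums(assay(sm1, "counts"))
    isUtr1 <- as.character(rd1$region) %in% .UTR3_REGIONS
    keepSiteA <- isUtr1
    for (g in unique(as.character(rd1$gene_id))) {
        idx <- which(as.character(rd1$gene_id) == g & !isUtr1)
        if (length(idx)) keepSiteA[idx[which.max(totals[idx])]] <- TRUE
    }
    sm2 <- sm1[keepSiteA, ]

    keepSiteB <- Matrix::rowMeans(assay(sm2, "counts") > 0) >= 0.5
    sm3 <- sm2[keepSiteB, ]

    if (nrow(sm3) > 0) {
        keepCell <- Matrix::colMeans(assay(sm3, "counts") > 0) > 0.5
    } else keepCell <- rep(TRUE, ncol(sm3))
    sm4 <- sm3[, keepCell]

    report <- .filterReport(
        nSites0, nCells0, nGenes0, sm4,
        rules = c(sites_in_ineligible_genes = sum(!keepGene),
                  non3utr_sites_not_major = sum(!keepSiteA),
                  sites_low_expression = sum(!keepSiteB),
                  cells_low_coverage = sum(!keepCell)))
    if (nrow(sm4) == 0 || ncol(sm4) == 0)
        warning("non-3'UTR filtering left an empty matrix")
    metadata(sm4)$filter_report <- report
    sm4
}

.filterReport <- function(nSites0, nCells0, nGenes0, out, rules) {
    list(n_sites_in = nSites0, n_sites_out = nrow(out),
         n_cells_in = nCells0, n_cells_out = ncol(out),
         n_genes_in = nGenes0,
         n_genes_out = length(unique(as.character(
             rowData(out)$gene_id))),
         removed = as.list(rules))
}
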