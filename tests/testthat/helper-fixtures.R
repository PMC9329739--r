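# Fixture builders shared across tests; everything is generated in code.

# A small annotated count matrix. Two genes on + strand, one on -, with a
# mix of 3'UTR and non-3'UTR sites.
toySites <- function() {
    data.frame(
        site_id = paste0("s", 1:7),
        chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
        strand = c("+", "+", "+", "+", "-", "-", "-"),
        position = c(100L, 600L, 900L, 50L, 5000L, 4400L, 4700L),
        gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gB"),
        region = c("3UTR", "3UTR", "3UTR_ext", "intron",
                   "3UTR", "3UTR", "CDS"),
        stringsAsFactors = FALSE)
}

toyCounts <- function(nCells = 6, seed = 42) {
    set.seed(seed)
    m <- matrix(rpois(7 * nCells, lambda = 3), nrow = 7,
                dimnames = list(paste0("s", 1:7),
                                paste0("c", seq_len(nCells))))
    m
}

toyMatrix <- function(nCells = 6, seed = 42, cellType = NULL) {
    PACountMatrix(toyCounts(nCells, seed), toySites(), cellType = cellType)
}

# random PACountMatrix restricted to 3'UTR regions, for filter properties
randomUtrMatrix <- function(nSites = 20, nCells = 30, nGenes = 6,
                            seed = 1) {
    set.seed(seed)
    sites <- data.frame(
        site_id = paste0("s", seq_len(nSites)),
        chrom = "chr1", strand = "+",
        position = seq_len(nSites) * 100L,
        gene_id = paste0("g", sample.int(nGenes, nSites, replace = TRUE)),
        region = sample(c("3UTR", "3UTR_ext"), nSites, replace = TRUE),
        stringsAsFactors = FALSE)
    counts <- matrix(rbinom(nSites * nCells, 1, 0.5) *
                     rpois(nSites * nCells, 4),
                     nrow = nSites,
                     dimnames = list(sites$site_id,
                                     paste0("c", seq_len(nCells))))
    PACountMatrix(counts, sites)
}

# minimal modality-call table
toyCallsDF <- function(ids, modalities, cellType = "all") {
    data.frame(feature_id = ids, feature_kind = "gene_proximal_PUI",
               cell_type = cellType, modality = modalities,
               M = vapply(modalities, function(m)
                   switch(m, unimodal = 1L, bimodal = 2L,
                          multimodal = 3L, undetected = -1L), 0L),
               n_cells = 50L,
               component_means = ifelse(modalities == "undetected", "",
                                        "0.123457,1.23457"),
               component_sizes = ifelse(modalities == "undetected", "",
                                        "25,25"),
               stringsAsFactors = FALSE)
}

# enumerate all set partitions of n items as label vectors (canonical form)
allPartitions <- function(n) {
    out <- list()
    recur <- function(labels, nextLab) {
        i <- length(labels) + 1L
        if (i > n) {
            out[[length(out) + 1L]] <<- labels
            return(invisible(NULL))
        }
        for (lab in seq_len(nextLab))
            recur(c(labels, lab), max(nextLab, lab + 1L))
    }
    recur(integer(0), 1L)
    out
}

# independent pair-counting ARI oracle, O(n^2), no contingency table
ariPairOracle <- function(a, b) {
    n <- length(a)
    n11 <- n00 <- n10 <- n01 <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        sa <- a[i] == a[j]; sb <- b[i] == b[j]
        if (sa && sb) n11 <- n11 + 1
        else if (!sa && !sb) n00 <- n00 + 1
        else if (sa) n10 <- n10 + 1
        else n01 <- n01 + 1
    }
    num <- 2 * (n11 * n00 - n10 * n01)
    den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
    if (den == 0) return(1)
    num / den
}
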