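#' Configuration for an end-to-end modality run
#'
#' @param matrixPath,sitesPath,cellsPath input file paths (see
#'   \code{\link{readSiteMatrix}}).
#' @param cellTypePath optional cell-type TSV; when given, filters and
#'   modality calls run independently within each cell type's cell subset
#'   and transition summaries are produced for consecutive type pairs.
#' @param mode analysis mode: \code{"gene-pui"} (proximal-site PUI per APA
#'   gene), \code{"major"} / \code{"minor"} (log2(ratio + 1) of the gene's
#'   major / minor 3'UTR site), or \code{"non3utr"} (PUI of the gene's
#'   strongest non-3'UTR site).
#' @param perCellType run per cell type (default when a cell-type table is
#'   given).
#' @param outDir output directory.
#' @param seed top-level seed; stage seeds are derived as
#'   \code{seed + stage index}.
#' @param control a \code{\link{modalityControl}} list (EM settings and
#'   component-correction constants).
#' @return A named list of class \code{apaRunConfig}.
#' @export
apaRunConfig <- function(matrixPath, sitesPath, cellsPath,
                         cellTypePath = NULL,
                         mode = c("gene-pui", "major", "minor", "non3utr"),
                         perCellType = !is.null(cellTypePath),
                         outDir = "apamodes_out", seed = 1L,
                         control = modalityControl()) {
    mode <- match.arg(mode)
    structure(list(matrixPath = matrixPath, sitesPath = sitesPath,
                   cellsPath = cellsPath, cellTypePath = cellTypePath,
                   mode = mode, perCellType = perCellType,
                   outDir = outDir, seed = as.integer(seed),
                   control = control),
              class = "apaRunConfig")
}

#' Run the end-to-end modality pipeline
#'
#' Reads the poly(A)-site matrix, applies the expression filters for the
#' configured mode, builds the APA signal matrix, calls modalities per cell
#' type (or on all cells), writes one modality TSV per cell type plus
#' transition records and summaries for consecutive cell-type pairs, and
#' writes a JSON manifest with the resolved configuration, seed and filter
#' reports. Identical configuration and seed give identical outputs.
#'
#' @param config an \code{\link{apaRunConfig}}.
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "apaRunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    sm <- readSiteMatrix(config$matrixPath, config$sitesPath,
                         config$cellsPath, config$cellTypePath)
    types <- if (config$perCellType && !is.null(cellType(sm)))
        unique(cellType(sm)) else NA_character_
    manifest <- list(mode = config$mode, seed = config$seed,
                     control = unclass(config$control),
                     inputs = list(matrix = config$matrixPath,
                                   sites = config$sitesPath,
                                   cells = config$cellsPath,
                                   cell_types = config$cellTypePath),
                     cell_types = as.list(types),
                     filter_reports = list())
    callsByType <- list()
    for (i in seq_along(types)) {
        ty <- types[i]
        sub <- if (is.na(ty)) sm else sm[, cellType(sm) == ty]
        res <- .runOneType(sub, config$mode, config$seed + i,
                           config$control,
                           if (is.na(ty)) "all" else ty)
        callsByType[[i]] <- res$calls
        manifest$filter_reports[[if (is.na(ty)) "all" else ty]] <-
            res$report
        writeModalityTable(res$calls, file.path(
            config$outDir,
            paste0("modality_", if (is.na(ty)) "all" else ty, ".tsv")))
    }
    if (length(types) >= 2 && !anyNA(types)) {
        for (i in seq_len(length(types) - 1)) {
            rec <- compareModalities(callsByType[[i]], callsByType[[i + 1]])
            pair <- paste0(types[i], "_to_", types[i + 1])
            utils::write.table(rec, file.path(
                config$outDir, paste0("transitions_", pair, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
            summ <- transitionSummary(rec)
            utils::write.table(summ$categories, file.path(
                config$outDir, paste0("transition_summary_", pair, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    invisible(config$outDir)
}

.runOneType <- function(sm, mode, seed, control, label) {
    if (mode %in% c("gene-pui", "major", "minor")) {
        utr <- sm[as.character(rowData(sm)$region) %in% .UTR3_REGIONS, ]
        filt <- filter3UTR(utr)
        sigMode <- switch(mode, "gene-pui" = "gene_proximal_PUI",
                          major = "major_ratio", minor = "minor_ratio")
        sig <- buildSignalMatrix(filt, sigMode)
    } else {
        filt <- filterNon3UTR(sm)
        filt <- .dropUnusableGenes(filt)
        sig <- buildSignalMatrix(filt, "site_PUI")
        keep <- !(as.character(rowData(sig)$region) %in% .UTR3_REGIONS)
        sig <- sig[keep, ]
        rowData(sig)$feature_kind <- rep("non3utr_site", nrow(sig))
    }
    calls <- identifyModalities(sig, seed = seed, cellType = label,
                                control = control)
    list(calls = calls, report = filterReport(filt))
}

# after the non-3'UTR expression filters a gene may have lost its non-3'UTR
# site or be down to a single site; PUI needs >= 2 sites and the pipeline
# reports the non-3'UTR site, so such genes are dropped
.dropUnusableGenes <- function(sm) {
    rd <- rowData(sm)
    gene <- as.character(rd$gene_id)
    isUtr <- as.character(rd$region) %in% .UTR3_REGIONS
    nTotal <- table(gene)
    hasNon <- unique(gene[!isUtr])
    good <- names(nTotal)[nTotal >= 2]
    good <- intersect(good, hasNon)
    out <- sm[gene %in% good, ]
    metadata(out)$filter_report <- metadata(sm)$filter_report
    out
}
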