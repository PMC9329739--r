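#' Read a poly(A)-site expression matrix with annotations
#'
#' Reads a sites-by-cells count matrix together with its site annotation and
#' cell label files and returns a validated \linkS4class{PACountMatrix}.
#' The matrix may be Matrix Market sparse (\code{.mtx}) or dense delimited
#' text (TSV/CSV, no header, no row names). The sites file is a TSV with
#' header columns \code{site_id, chrom, strand, position, gene_id, region};
#' the cells file holds one cell id per line. An optional cell-type TSV
#' (\code{cell_id, type}) attaches per-cell labels.
#'
#' @param matrixPath path to the count matrix (.mtx, .tsv or .csv).
#' @param sitesPath path to the site annotation TSV.
#' @param cellsPath path to the one-column cell id file.
#' @param cellTypePath optional path to a cell-type TSV.
#' @return A \linkS4class{PACountMatrix} with a sparse \code{counts} assay.
#' @seealso \code{\link{PACountMatrix}}
#' @export
readSiteMatrix <- function(matrixPath, sitesPath, cellsPath,
                           cellTypePath = NULL) {
    counts <- .readCounts(matrixPath)
    sites <- utils::read.delim(sitesPath, stringsAsFactors = FALSE)
    need <- c("site_id", "chrom", "strand", "position", "gene_id", "region")
    miss <- setdiff(need, colnames(sites))
    if (length(miss))
        stop("sites file ", sitesPath, " lacks column(s): ",
             paste(miss, collapse = ", "))
    cells <- readLines(cellsPath)
    cells <- cells[nzchar(cells)]
    if (nrow(counts) != nrow(sites))
        stop("matrix ", matrixPath, " has ", nrow(counts),
             " rows but sites file ", sitesPath, " has ", nrow(sites))
    if (ncol(counts) != length(cells))
        stop("matrix ", matrixPath, " has ", ncol(counts),
             " columns but cells file ", cellsPath, " has ", length(cells))
    if (any(counts < 0))
        stop("matrix ", matrixPath, " contains negative counts")
    colnames(counts) <- cells
    cellType <- NULL
    if (!is.null(cellTypePath)) {
        ct <- utils::read.delim(cellTypePath, stringsAsFactors = FALSE)
        if (!all(c("cell_id", "type") %in% colnames(ct)))
            stop("cell-type file must have columns cell_id, type")
        cellType <- ct$type[match(cells, ct$cell_id)]
        if (anyNA(cellType))
            stop("cell-type file ", cellTypePath,
                 " misses ", sum(is.na(cellType)), " cell id(s)")
    }
    sm <- PACountMatrix(counts, sites, cellType = cellType)
    validObject(sm)
    sm
}

.readCounts <- function(path) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "mtx") {
        m <- Matrix::readMM(path)
        methods::as(m, "CsparseMatrix")
    } else {
        sep <- if (ext == "csv") "," else "\t"
        m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
        dimnames(m) <- NULL
        methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    }
}

.MODALITY_TABLE_COLS <- c("feature_id", "feature_kind", "cell_type",
                          "modality", "M", "n_cells", "component_means",
                          "component_sizes")

#' Write and read modality-call tables
#'
#' \code{writeModalityTable} writes the call table of a
#' \linkS4class{ModalityCalls} object (or a bare data.frame with the same
#' columns) as a TSV with a fixed header; floats are formatted at 6
#' significant digits. \code{readModalityTable} reads such a file back; a
#' write-read round trip reproduces the table exactly up to that float
#' formatting.
#'
#' @param table a \linkS4class{ModalityCalls} or its call data.frame.
#' @param path output (input) file path.
#' @return \code{writeModalityTable} returns \code{path} invisibly;
#'   \code{readModalityTable} returns the call data.frame.
#' @export
writeModalityTable <- function(table, path) {
    if (is(table, "ModalityCalls")) table <- modalityCalls(table)
    miss <- setdiff(.MODALITY_TABLE_COLS, colnames(table))
    if (length(miss))
        stop("modality table lacks column(s): ", paste(miss, collapse = ", "))
    out <- table[, .MODALITY_TABLE_COLS, drop = FALSE]
    out$component_means <- vapply(out$component_means, .formatNumList, "")
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write ", path, ": ",
                                             conditionMessage(e)))
    on.exit(close(con))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

.formatNumList <- function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    x <- as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    paste(sprintf("%.6g", x), collapse = ",")
}

#' @rdname writeModalityTable
#' @export
readModalityTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(component_means = "character",
                                            component_sizes = "character"))
    miss <- setdiff(.MODALITY_TABLE_COLS, colnames(tab))
    if (length(miss))
        stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
    if (!all(tab$modality %in% .MODALITY_LEVELS))
        stop("file ", path, " has invalid modality labels")
    tab
}

#' Write and read APA signal matrices as TSV
#'
#' Dense TSV with feature ids in the first column and cell ids in the
#' header; \code{NA} marks missing signals. Mainly used by the simulation
#' subcommand and for exchanging simulated benchmarks.
#'
#' @param signal an \linkS4class{APASignalMatrix}.
#' @param path file path.
#' @return \code{writeSignalMatrix} returns \code{path} invisibly;
#'   \code{readSignalMatrix} returns an \linkS4class{APASignalMatrix}.
#' @export
writeSignalMatrix <- function(signal, path) {
    m <- assay(signal, "signal")
    df <- data.frame(feature_id = rownames(m),
                     feature_kind = as.character(
                         rowData(signal)$feature_kind),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' @rdname writeSignalMatrix
#' @export
readSignalMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(m) <- df$feature_id
    APASignalMatrix(m, featureKind = df$feature_kind,
                    featureId = df$feature_id)
}
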