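#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

.REGION_LEVELS <- c("3UTR", "3UTR_ext", "intron", "CDS", "5UTR", "exon")
.UTR3_REGIONS <- c("3UTR", "3UTR_ext")
.MODALITY_LEVELS <- c("unimodal", "bimodal", "multimodal", "undetected")
.FEATURE_KINDS <- c("gene_proximal_PUI", "major_site", "minor_site",
                    "non3utr_site", "site_PUI", "simulated")

#' Poly(A)-site count matrix
#'
#' A \linkS4class{SummarizedExperiment} holding a sites-by-cells matrix of
#' non-negative UMI counts in the \code{"counts"} assay. Row metadata carries
#' the site annotation (\code{site_id}, \code{chrom}, \code{strand},
#' \code{position}, \code{gene_id}, \code{region}); column metadata may carry
#' a \code{cell_type} label per cell. A zero count means "not expressed", not
#' missing: missingness only arises downstream at the signal-matrix level.
#'
#' @section Validity:
#' Counts must be non-negative; \code{region} must be one of
#' \code{3UTR, 3UTR_ext, intron, CDS, 5UTR, exon}; \code{strand} one of
#' \code{+, -}; \code{position >= 1}; the pair (\code{gene_id},
#' \code{site_id}) must be unique.
#'
#' @aliases PACountMatrix-class
#' @exportClass PACountMatrix
setClass("PACountMatrix", contains = "SummarizedExperiment")

setValidity("PACountMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
        if (anyNA(as.vector(cnt)))
            msg <- c(msg, "counts must not contain NA")
    }
    rd <- rowData(object)
    need <- c("site_id", "chrom", "strand", "position", "gene_id", "region")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("missing site annotation column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        bad <- setdiff(unique(as.character(rd$region)), .REGION_LEVELS)
        if (length(bad))
            msg <- c(msg, paste0("unknown region value(s): ",
                                 paste(bad, collapse = ", "),
                                 "; allowed: ",
                                 paste(.REGION_LEVELS, collapse = ", ")))
        if (!all(as.character(rd$strand) %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        if (any(rd$position < 1))
            msg <- c(msg, "position must be >= 1")
        if (anyDuplicated(paste(rd$gene_id, rd$site_id)))
            msg <- c(msg, "(gene_id, site_id) pairs must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PACountMatrix
#'
#' @param counts sites-by-cells matrix (dense or \pkg{Matrix} sparse) of
#'   non-negative counts.
#' @param sites data.frame of site annotations with columns \code{site_id},
#'   \code{chrom}, \code{strand}, \code{position}, \code{gene_id},
#'   \code{region}, one row per row of \code{counts}.
#' @param cellType optional character vector of cell-type labels, one per
#'   column of \code{counts}.
#' @return A \linkS4class{PACountMatrix}.
#' @examples
#' sites <- data.frame(site_id = c("s1", "s2"), chrom = "chr1",
#'                     strand = "+", position = c(100L, 600L),
#'                     gene_id = "g1", region = "3UTR")
#' cnt <- matrix(c(3, 1, 0, 2), nrow = 2,
#'               dimnames = list(c("s1", "s2"), c("c1", "c2")))
#' PACountMatrix(cnt, sites)
#' @export
PACountMatrix <- function(counts, sites, cellType = NULL) {
    if (nrow(counts) != nrow(sites))
        stop("counts has ", nrow(counts), " rows but sites has ",
             nrow(sites), " rows")
    sites <- as.data.frame(sites, stringsAsFactors = FALSE)
    rownames(counts) <- sites$site_id
    cd <- DataFrame(row.names = colnames(counts))
    if (!is.null(cellType)) {
        if (length(cellType) != ncol(counts))
            stop("cellType must have one entry per cell")
        cd$cell_type <- as.character(cellType)
    }
    new("PACountMatrix",
        SummarizedExperiment(assays = list(counts = counts),
                             rowData = DataFrame(sites), colData = cd))
}

#' APA signal matrix
#'
#' A \linkS4class{SummarizedExperiment} holding a features-by-cells matrix of
#' real-valued APA usage signals (PUI or transformed usage ratios) in the
#' \code{"signal"} assay. \code{NA} entries mark cells in which the feature's
#' gene is unexpressed (the signal is undefined there) or cells masked by the
#' simulator. Row metadata carries \code{feature_id} and \code{feature_kind}.
#'
#' @aliases APASignalMatrix-class
#' @exportClass APASignalMatrix
setClass("APASignalMatrix", contains = "SummarizedExperiment")

setValidity("APASignalMatrix", function(object) {
    msg <- character()
    if (!"signal" %in% assayNames(object))
        msg <- c(msg, "assay 'signal' is required")
    rd <- rowData(object)
    if (!all(c("feature_id", "feature_kind") %in% colnames(rd)))
        msg <- c(msg, "rowData must have feature_id and feature_kind")
    else if (!all(as.character(rd$feature_kind) %in% .FEATURE_KINDS))
        msg <- c(msg, paste0("feature_kind must be one of: ",
                             paste(.FEATURE_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an APASignalMatrix
#'
#' @param signal features-by-cells numeric matrix; \code{NA} marks missing.
#' @param featureKind single kind or one per feature; one of
#'   \code{gene_proximal_PUI, major_site, minor_site, non3utr_site,
#'   site_PUI, simulated}.
#' @param featureId optional feature ids (defaults to rownames).
#' @return An \linkS4class{APASignalMatrix}.
#' @export
APASignalMatrix <- function(signal, featureKind, featureId = rownames(signal)) {
    if (is.null(featureId))
        featureId <- paste0("feature_", seq_len(nrow(signal)))
    rownames(signal) <- featureId
    if (length(featureKind) == 1L)
        featureKind <- rep(featureKind, nrow(signal))
    new("APASignalMatrix",
        SummarizedExperiment(
            assays = list(signal = signal),
            rowData = DataFrame(feature_id = featureId,
                                feature_kind = featureKind,
                                row.names = featureId)))
}

#' Fitted univariate Gaussian mixture
#'
#' Result of fitting a k-component univariate Gaussian mixture to one APA
#' usage vector. Components are ordered by increasing mean.
#'
#' @slot k component count.
#' @slot weights mixing proportions (sum to 1).
#' @slot means component means.
#' @slot variances component variances (floored at the variance floor).
#' @slot loglik final log-likelihood.
#' @slot bic Bayesian information criterion, \code{(3k - 1) * log(n) -
#'   2 * loglik}; smaller is better.
#' @slot n number of observations.
#' @slot posterior n-by-k matrix of posterior component probabilities.
#' @slot loglikTrace per-iteration log-likelihood of the converged EM run.
#'
#' @aliases GMMFit-class
#' @exportClass GMMFit
setClass("GMMFit", representation(
    k = "integer", weights = "numeric", means = "numeric",
    variances = "numeric", loglik = "numeric", bic = "numeric",
    n = "integer", posterior = "matrix", loglikTrace = "numeric"))

setValidity("GMMFit", function(object) {
    msg <- character()
    if (abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1")
    if (length(object@means) != object@k ||
        length(object@variances) != object@k)
        msg <- c(msg, "means/variances length must equal k")
    if (any(object@variances <= 0))
        msg <- c(msg, "variances must be positive")
    if (length(msg)) msg else TRUE
})

#' Modality calls with per-cell memberships
#'
#' @slot calls data.frame with one row per feature: \code{feature_id},
#'   \code{feature_kind}, \code{cell_type}, \code{modality}, \code{M},
#'   \code{n_cells}, \code{component_means}, \code{component_sizes}
#'   (the last two comma-separated).
#' @slot membership features-by-cells integer matrix of posterior-argmax
#'   component memberships; \code{NA} for missing cells and for features
#'   called undetected.
#'
#' @aliases ModalityCalls-class
#' @exportClass ModalityCalls
setClass("ModalityCalls", representation(
    calls = "data.frame", membership = "matrix"))

#' Ground truth for simulated APA signal matrices
#'
#' @slot rowInfo data.frame with one row per simulated feature:
#'   \code{feature_id}, \code{group_id}, \code{modality},
#'   \code{component_means} (comma-separated).
#' @slot componentLabels features-by-cells integer matrix of generating
#'   component labels (component indices follow the group spec's order).
#' @slot missingMask logical matrix flagging injected missing entries.
#' @slot noiseMask logical matrix flagging noise-perturbed entries.
#'
#' @aliases APASimTruth-class
#' @exportClass APASimTruth
setClass("APASimTruth", representation(
    rowInfo = "data.frame", componentLabels = "matrix",
    missingMask = "matrix", noiseMask = "matrix"))

setValidity("APASimTruth", function(object) {
    d <- dim(object@componentLabels)
    if (nrow(object@rowInfo) != d[1])
        return("rowInfo rows must match componentLabels rows")
    if (!identical(dim(object@missingMask), d) ||
        !identical(dim(object@noiseMask), d))
        return("mask dimensions must match componentLabels")
    TRUE
})
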