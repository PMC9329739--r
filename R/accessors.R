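#' Accessors for APAmodes objects
#'
#' \code{siteData} returns the site annotation of a
#' \linkS4class{PACountMatrix} as a data.frame; \code{cellType} the per-cell
#' type labels (or \code{NULL}); \code{filterReport} the filtering report
#' attached by \code{\link{filter3UTR}} / \code{\link{filterNon3UTR}};
#' \code{modalityCalls} and \code{membershipMatrix} the call table and the
#' per-cell component memberships of a \linkS4class{ModalityCalls} object;
#' \code{trueModality}, \code{componentLabels}, \code{missingMask} and
#' \code{noiseMask} the ground-truth slots of an
#' \linkS4class{APASimTruth}.
#'
#' @param x the object.
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("siteData", "PACountMatrix", function(x)
    as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("cellType", "PACountMatrix", function(x) {
    cd <- colData(x)
    if ("cell_type" %in% colnames(cd)) as.character(cd$cell_type) else NULL
})

#' @rdname accessors
#' @export
setMethod("filterReport", "PACountMatrix", function(x)
    metadata(x)$filter_report)

#' @rdname accessors
#' @export
setMethod("modalityCalls", "ModalityCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("membershipMatrix", "ModalityCalls", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("trueModality", "APASimTruth", function(x)
    structure(x@rowInfo$modality, names = x@rowInfo$feature_id))

#' @rdname accessors
#' @export
setMethod("componentLabels", "APASimTruth", function(x) x@componentLabels)

#' @rdname accessors
#' @export
setMethod("missingMask", "APASimTruth", function(x) x@missingMask)

#' @rdname accessors
#' @export
setMethod("noiseMask", "APASimTruth", function(x) x@noiseMask)

setMethod("show", "PACountMatrix", function(object) {
    cat("PACountMatrix:", nrow(object), "poly(A) sites x",
        ncol(object), "cells\n")
    rd <- rowData(object)
    cat("  genes:", length(unique(rd$gene_id)),
        "| regions:", paste(names(table(as.character(rd$region))),
                            collapse = ", "), "\n")
    ct <- cellType(object)
    if (!is.null(ct))
        cat("  cell types:", paste(names(table(ct)), table(ct),
                                   sep = ":", collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "APASignalMatrix", function(object) {
    sig <- assay(object, "signal")
    cat("APASignalMatrix:", nrow(object), "features x", ncol(object),
        "cells (", sprintf("%.1f%%", 100 * mean(is.na(sig))),
        "missing )\n")
    cat("  kinds:", paste(unique(as.character(
        rowData(object)$feature_kind)), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "GMMFit", function(object) {
    cat("GMMFit:", object@k, "component(s), n =", object@n, "\n")
    cat("  weights:  ", paste(sprintf("%.3f", object@weights),
                              collapse = " "), "\n")
    cat("  means:    ", paste(sprintf("%.3f", object@means),
                              collapse = " "), "\n")
    cat("  variances:", paste(sprintf("%.4g", object@variances),
                              collapse = " "), "\n")
    cat("  loglik:", sprintf("%.3f", object@loglik),
        " BIC:", sprintf("%.3f", object@bic), "\n")
    invisible(NULL)
})

setMethod("show", "ModalityCalls", function(object) {
    tab <- table(factor(object@calls$modality, levels = .MODALITY_LEVELS))
    cat("ModalityCalls:", nrow(object@calls), "feature(s)\n  ")
    cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "APASimTruth", function(object) {
    tab <- table(object@rowInfo$modality)
    cat("APASimTruth:", nrow(object@rowInfo), "rows x",
        ncol(object@componentLabels), "cells\n  ")
    cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
    cat("  missing:", sum(object@missingMask),
        "| noise:", sum(object@noiseMask), "entries\n")
    invisible(NULL)
})
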