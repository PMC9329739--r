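#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table: 1 for identical partitions (up to
#' label renaming), expectation 0 under independent random partitions;
#' negative values indicate worse-than-chance agreement.
#'
#' @param labelsA,labelsB equal-length vectors of categorical labels
#'   (length >= 2).
#' @return The ARI, a real number <= 1.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1
#' adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
    if (length(labelsA) != length(labelsB))
        stop("label vectors must have equal length")
    n <- length(labelsA)
    if (n < 2) stop("need at least 2 items")
    tab <- table(labelsA, labelsB)
    sumIJ <- sum(choose(tab, 2))
    sumA <- sum(choose(rowSums(tab), 2))
    sumB <- sum(choose(colSums(tab), 2))
    expIdx <- sumA * sumB / choose(n, 2)
    maxIdx <- (sumA + sumB) / 2
    if (maxIdx == expIdx) return(1)   # both partitions trivial
    (sumIJ - expIdx) / (maxIdx - expIdx)
}

#' Score modality calls against simulation ground truth
#'
#' Compares, row by row, the called modality to the generating modality:
#' counts recognition errors (any row whose call differs from the truth,
#' including detected truths called undetected), builds the confusion
#' matrix over \code{unimodal / bimodal / multimodal / undetected}, and
#' computes the per-row adjusted Rand index between the true generating
#' component labels and the called per-cell memberships over the cells that
#' are non-missing in the evaluated matrix, averaged within each true
#' modality (rows without memberships are skipped in the ARI averages).
#' Error counts are reported per row and, aggregated, per generating group.
#'
#' @param truth an \linkS4class{APASimTruth}.
#' @param calls the matching \linkS4class{ModalityCalls}.
#' @return A list: \code{n_rows}, \code{n_errors}, \code{confusion}
#'   (true-by-called matrix), \code{ari_by_modality},
#'   \code{errors_by_group}, and the per-row data.frame \code{rows}
#'   (feature id, true and called modality, error flag, row ARI).
#' @export
countModalityErrors <- function(truth, calls) {
    info <- truth@rowInfo
    tab <- modalityCalls(calls)
    if (!identical(sort(info$feature_id), sort(tab$feature_id)))
        stop("truth and calls cover different row universes")
    tab <- tab[match(info$feature_id, tab$feature_id), ]
    membership <- membershipMatrix(calls)[info$feature_id, , drop = FALSE]
    labels <- componentLabels(truth)
    miss <- missingMask(truth)

    lev <- .MODALITY_LEVELS
    trueMod <- factor(info$modality, levels = lev)
    calledMod <- factor(tab$modality, levels = lev)
    confusion <- table(true = trueMod, called = calledMod)
    err <- as.character(trueMod) != as.character(calledMod)

    rowARI <- rep(NA_real_, nrow(info))
    for (r in seq_len(nrow(info))) {
        if (all(is.na(membership[r, ]))) next
        obs <- which(!miss[r, ] & !is.na(membership[r, ]))
        if (length(obs) < 2) next
        rowARI[r] <- adjustedRandIndex(labels[r, obs], membership[r, obs])
    }
    ariBy <- tapply(rowARI, trueMod, function(x)
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    errBy <- tapply(err, info$group_id, sum)
    rows <- data.frame(feature_id = info$feature_id,
                       group_id = info$group_id,
                       true_modality = as.character(trueMod),
                       called_modality = as.character(calledMod),
                       error = err, ari = rowARI,
                       stringsAsFactors = FALSE)
    list(n_rows = nrow(info), n_errors = sum(err), confusion = confusion,
         ari_by_modality = ariBy,
         errors_by_group = errBy, rows = rows)
}
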