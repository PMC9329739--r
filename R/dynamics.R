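#' Compare modality calls between two cell types or stages
#'
#' Classifies, per feature, the transition of its modality from stage A to
#' stage B into four categories: \code{same} (detected in both with equal
#' modality), \code{change} (detected in both with different modality),
#' \code{appear} (undetected in A, detected in B) and \code{disappear}
#' (detected in A, undetected in B). The two tables are outer-joined on
#' \code{feature_id}; a feature absent from a table (e.g. removed by
#' filtering in that cell type) counts as undetected there. Features
#' undetected in both stages are omitted.
#'
#' @param callsA,callsB \linkS4class{ModalityCalls} objects or call
#'   data.frames for the two stages.
#' @return A data.frame of transition records with columns
#'   \code{feature_id}, \code{modality_A}, \code{modality_B},
#'   \code{category}.
#' @export
compareModalities <- function(callsA, callsB) {
    a <- .callsDF(callsA)
    b <- .callsDF(callsB)
    if (anyDuplicated(a$feature_id))
        stop("duplicate feature ids in stage-A calls")
    if (anyDuplicated(b$feature_id))
        stop("duplicate feature ids in stage-B calls")
    ids <- union(a$feature_id, b$feature_id)
    modA <- a$modality[match(ids, a$feature_id)]
    modB <- b$modality[match(ids, b$feature_id)]
    modA[is.na(modA)] <- "undetected"
    modB[is.na(modB)] <- "undetected"
    detA <- modA != "undetected"
    detB <- modB != "undetected"
    keep <- detA | detB
    category <- ifelse(detA & detB & modA == modB, "same",
                ifelse(detA & detB, "change",
                ifelse(!detA, "appear", "disappear")))
    data.frame(feature_id = ids[keep], modality_A = modA[keep],
               modality_B = modB[keep], category = category[keep],
               stringsAsFactors = FALSE)
}

.callsDF <- function(x) {
    if (is(x, "ModalityCalls")) x <- modalityCalls(x)
    as.data.frame(x)
}

#' Summarise modality transitions
#'
#' Counts and percentages per transition category, plus counts per
#' (modality A, modality B) pair.
#'
#' @param records transition records from \code{\link{compareModalities}}.
#' @return A list with \code{categories} (category, count, percent) and
#'   \code{pairs} (modality_A, modality_B, count, percent); both empty for
#'   empty input.
#' @export
transitionSummary <- function(records) {
    cats <- c("same", "change", "appear", "disappear")
    if (nrow(records) == 0)
        return(list(categories = data.frame(category = cats,
                                            count = 0L, percent = NA_real_),
                    pairs = data.frame(modality_A = character(),
                                       modality_B = character(),
                                       count = integer(),
                                       percent = numeric())))
    n <- nrow(records)
    cnt <- table(factor(records$category, levels = cats))
    categories <- data.frame(category = cats, count = as.integer(cnt),
                             percent = 100 * as.integer(cnt) / n)
    pt <- as.data.frame(table(modality_A = records$modality_A,
                              modality_B = records$modality_B),
                        stringsAsFactors = FALSE)
    pt <- pt[pt$Freq > 0, ]
    pairs <- data.frame(modality_A = pt$modality_A,
                        modality_B = pt$modality_B,
                        count = as.integer(pt$Freq),
                        percent = 100 * pt$Freq / n,
                        stringsAsFactors = FALSE)
    pairs <- pairs[order(-pairs$count), ]
    rownames(pairs) <- NULL
    list(categories = categories, pairs = pairs)
}
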