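#' Define one simulated modality group
#'
#' @param id group identifier.
#' @param modality \code{"unimodal"}, \code{"bimodal"} or
#'   \code{"multimodal"}.
#' @param means component means (1, 2 or 3 values to match the modality).
#' @param sd common component standard deviation.
#' @param proportions component proportions (default equal); must sum to 1.
#' @return A list of class \code{simGroupSpec}.
#' @seealso \code{\link{defaultGroupSpecs}}
#' @export
simGroupSpec <- function(id, modality, means, sd = 0.1,
                         proportions = NULL) {
    nComp <- switch(modality, unimodal = 1L, bimodal = 2L,
                    multimodal = 3L,
                    stop("unknown modality: ", modality))
    if (length(means) != nComp)
        stop("modality ", modality, " needs ", nComp, " mean(s)")
    if (is.null(proportions))
        proportions <- rep(1 / nComp, nComp)
    if (length(proportions) != nComp ||
        abs(sum(proportions) - 1) > 1e-9)
        stop("proportions must have one entry per component and sum to 1")
    structure(list(id = id, modality = modality, means = as.numeric(means),
                   sd = sd, proportions = proportions),
              class = "simGroupSpec")
}

#' The fifteen default simulation groups
#'
#' The benchmark design: 3 unimodal groups (means 2, -2, 0), 5 bimodal
#' groups (component means (2, -2), (2, 0.5), (-2, -0.5), (2, 0), (-2, 0))
#' and 7 multimodal groups (component means (2, -2, 0), (2, 1, 0.5),
#' (-2, -1, -0.5), (2, 1, 0), (-2, -1, 0), (2, 1, -2), (-2, -1, 2)), with
#' equal component proportions. The dispersion parameter of the design is
#' 0.1; by default it is taken as the component standard deviation, which
#' separates even the closest component pair (0.5 apart) by 5 sd. Setting
#' \code{dispersionIs = "variance"} instead uses sd = sqrt(0.1), under
#' which adjacent components overlap substantially.
#'
#' @param dispersion the dispersion parameter (default 0.1).
#' @param dispersionIs whether \code{dispersion} is the standard deviation
#'   (default) or the variance.
#' @return A list of 15 \code{\link{simGroupSpec}} objects.
#' @export
defaultGroupSpecs <- function(dispersion = 0.1,
                              dispersionIs = c("sd", "variance")) {
    dispersionIs <- match.arg(dispersionIs)
    sd <- if (dispersionIs == "sd") dispersion else sqrt(dispersion)
    uni <- list(2, -2, 0)
    bi <- list(c(2, -2), c(2, 0.5), c(-2, -0.5), c(2, 0), c(-2, 0))
    multi <- list(c(2, -2, 0), c(2, 1, 0.5), c(-2, -1, -0.5), c(2, 1, 0),
                  c(-2, -1, 0), c(2, 1, -2), c(-2, -1, 2))
    specs <- c(
        lapply(seq_along(uni), function(i)
            simGroupSpec(paste0("uni_", i), "unimodal", uni[[i]], sd)),
        lapply(seq_along(bi), function(i)
            simGroupSpec(paste0("bi_", i), "bimodal", bi[[i]], sd)),
        lapply(seq_along(multi), function(i)
            simGroupSpec(paste0("multi_", i), "multimodal", multi[[i]], sd)))
    specs
}

# deterministic component allocation: floor shares, remainder to earlier
# components, in the order the components are specified
.allocateComponents <- function(nCells, proportions) {
    nComp <- length(proportions)
    sizes <- floor(nCells * proportions)
    rem <- nCells - sum(sizes)
    if (rem > 0) {
        idx <- rep_len(seq_len(nComp), rem)
        for (j in idx) sizes[j] <- sizes[j] + 1L
    }
    rep(seq_len(nComp), sizes)
}

#' Simulate a ground-truthed APA signal matrix
#'
#' Draws, for each group spec and replicate, one row of per-cell signals
#' from the group's Gaussian mixture. Cells are allocated to components
#' deterministically by the spec's proportions (floor shares, remainder to
#' earlier components), so component sizes are exact; the generating
#' component of every cell is recorded as ground truth. Fully seeded.
#'
#' @param specs list of \code{\link{simGroupSpec}} objects.
#' @param nCells cells per row (must fit at least 10 cells per component).
#' @param replicates rows generated per group.
#' @param seed integer seed.
#' @return A list with \code{signal} (an \linkS4class{APASignalMatrix} of
#'   \code{length(specs) * replicates} rows by \code{nCells} columns) and
#'   \code{truth} (an \linkS4class{APASimTruth}).
#' @examples
#' sim <- simulateSignalMatrix(defaultGroupSpecs(), nCells = 100,
#'                             replicates = 2, seed = 1)
#' dim(assay(sim$signal))
#' @export
simulateSignalMatrix <- function(specs, nCells = 100L, replicates = 100L,
                                 seed = 1L) {
    maxComp <- max(vapply(specs, function(s) length(s$means), 0L))
    if (nCells < 10L * maxComp)
        stop("nCells must be at least 10 cells per component (",
             10L * maxComp, ")")
    if (replicates < 1L) stop("replicates must be >= 1")
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(seed)
    nR <- length(specs) * replicates
    sig <- matrix(NA_real_, nR, nCells)
    labels <- matrix(NA_integer_, nR, nCells)
    info <- vector("list", nR)
    r <- 0L
    for (s in specs) {
        comp <- .allocateComponents(nCells, s$proportions)
        for (rep in seq_len(replicates)) {
            r <- r + 1L
            sig[r, ] <- stats::rnorm(nCells, mean = s$means[comp],
                                     sd = s$sd)
            labels[r, ] <- comp
            info[[r]] <- data.frame(
                feature_id = sprintf("row_%04d", r),
                group_id = s$id, modality = s$modality,
                component_means = paste(sprintf("%.6g", s$means),
                                        collapse = ","),
                stringsAsFactors = FALSE)
        }
    }
    info <- do.call(rbind, info)
    dimnames(sig) <- list(info$feature_id,
                          sprintf("cell_%04d", seq_len(nCells)))
    dimnames(labels) <- dimnames(sig)
    falseMask <- matrix(FALSE, nR, nCells, dimnames = dimnames(sig))
    truth <- new("APASimTruth", rowInfo = info, componentLabels = labels,
                 missingMask = falseMask, noiseMask = falseMask)
    list(signal = APASignalMatrix(sig, featureKind = "simulated"),
         truth = truth)
}

#' Inject missing values into a simulated signal matrix
#'
#' Sets \code{round(fraction * nCells)} entries per row to \code{NA},
#' chosen uniformly at random but resampled (bounded retries) until every
#' true component of the row retains more than 10 non-missing cells, which
#' keeps every component decidable under the component-size rule.
#'
#' @param m the \linkS4class{APASignalMatrix} to degrade.
#' @param truth the matching \linkS4class{APASimTruth}.
#' @param fraction fraction of cells per row to mask (0 < fraction < 1).
#' @param seed integer seed.
#' @return A list with the degraded \code{signal} and updated \code{truth}
#'   (missing flags set).
#' @export
injectMissing <- function(m, truth, fraction, seed = 1L) {
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must be strictly between 0 and 1")
    sig <- assay(m, "signal")
    labels <- componentLabels(truth)
    nC <- ncol(sig)
    nMiss <- round(fraction * nC)
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(seed)
    mask <- missingMask(truth)
    for (r in seq_len(nrow(sig))) {
        sizes <- table(labels[r, ])
        if (sum(pmax(sizes - 11L, 0L)) < nMiss)
            stop("fraction ", fraction, " cannot leave more than 10 ",
                 "observed cells in every component of row ", r)
        ok <- FALSE
        for (try in seq_len(1000L)) {
            miss <- sample.int(nC, nMiss)
            kept <- table(factor(labels[r, -miss],
                                 levels = names(sizes)))
            if (all(kept > 10L)) { ok <- TRUE; break }
        }
        if (!ok)
            stop("could not satisfy the component-size guarantee for row ",
                 r, " at fraction ", fraction)
        sig[r, miss] <- NA_real_
        mask[r, miss] <- TRUE
    }
    truth@missingMask <- mask
    list(signal = APASignalMatrix(sig,
                                  featureKind = as.character(
                                      rowData(m)$feature_kind),
                                  featureId = rownames(sig)),
         truth = truth)
}

#' Inject noise into a simulated signal matrix
#'
#' Perturbs \code{round(fraction * nCells)} randomly chosen non-missing
#' entries per row by adding a uniform draw from
#' \code{[-amplitude, amplitude]}. The perturbation is label-preserving by
#' design: a noised cell still originates from its generating component,
#' and the default amplitude (0.5, i.e. 5 component standard deviations of
#' the default design) is below half the smallest component separation of
#' the bimodal groups but above half that of adjacent multimodal
#' components, so noise corrupts multimodal memberships before bimodal
#' ones.
#'
#' @inheritParams injectMissing
#' @param fraction fraction of cells per row to perturb.
#' @param amplitude half-width of the uniform perturbation.
#' @return A list with the noised \code{signal} and updated \code{truth}
#'   (noise flags set).
#' @export
injectNoise <- function(m, truth, fraction, seed = 1L, amplitude = 0.5) {
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must be strictly between 0 and 1")
    sig <- assay(m, "signal")
    nC <- ncol(sig)
    nNoise <- round(fraction * nC)
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(seed)
    mask <- noiseMask(truth)
    for (r in seq_len(nrow(sig))) {
        obs <- which(!is.na(sig[r, ]))
        pick <- sample(obs, min(nNoise, length(obs)))
        sig[r, pick] <- sig[r, pick] +
            stats::runif(length(pick), -amplitude, amplitude)
        mask[r, pick] <- TRUE
    }
    truth@noiseMask <- mask
    list(signal = APASignalMatrix(sig,
                                  featureKind = as.character(
                                      rowData(m)$feature_kind),
                                  featureId = rownames(sig)),
         truth = truth)
}

#' Simulate unbalanced bimodal groups
#'
#' Five bimodal designs with component cell ratios 5:5, 6:4, 7:3, 8:2 and
#' 9:1, component means 10 and -10, and sd 0.1. Component sizes are exact
#' (deterministic allocation).
#'
#' @param ratios list of integer pairs summing to 10.
#' @param nCells cells per row; must be divisible by 10.
#' @param replicates rows per ratio group.
#' @param seed integer seed.
#' @param sd component standard deviation.
#' @return As \code{\link{simulateSignalMatrix}}.
#' @export
simulateUnbalancedBimodal <- function(ratios = list(c(5, 5), c(6, 4),
                                                    c(7, 3), c(8, 2),
                                                    c(9, 1)),
                                      nCells = 100L, replicates = 100L,
                                      seed = 1L, sd = 0.1) {
    if (nCells %% 10L != 0L) stop("nCells must be divisible by 10")
    specs <- lapply(ratios, function(rt) {
        if (length(rt) != 2 || sum(rt) != 10)
            stop("each ratio pair must have two entries summing to 10")
        simGroupSpec(paste0("ratio_", rt[1], "_", rt[2]), "bimodal",
                     means = c(10, -10), sd = sd,
                     proportions = rt / 10)
    })
    simulateSignalMatrix(specs, nCells = nCells, replicates = replicates,
                         seed = seed)
}
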