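test_that("the default design has the fifteen published groups", {
    specs <- defaultGroupSpecs()
    expect_length(specs, 15L)
    mods <- vapply(specs, function(s) s$modality, "")
    expect_equal(unname(table(factor(mods, c("unimodal", "bimodal",
                                             "multimodal")))),
                 c(3L, 5L, 7L), ignore_attr = TRUE)
    expect_equal(specs[[4]]$means, c(2, -2))        # first bimodal group
    expect_equal(specs[[15]]$means, c(-2, -1, 2))   # last multimodal group
    expect_true(all(vapply(specs, function(s) s$sd, 0) == 0.1))
    # the variance reading of the dispersion parameter is available
    expect_equal(defaultGroupSpecs(dispersionIs = "variance")[[1]]$sd,
                 sqrt(0.1))
})

test_that("simulated matrices have exact shape, labels and determinism", {
    specs <- defaultGroupSpecs()
    sim <- simulateSignalMatrix(specs, nCells = 100, replicates = 2,
                                seed = 5)
    expect_equal(dim(SummarizedExperiment::assay(sim$signal)), c(30L, 100L))
    expect_equal(sum(trueModality(sim$truth) == "unimodal"), 6L)
    expect_equal(dim(componentLabels(sim$truth)), c(30L, 100L))

    sim2 <- simulateSignalMatrix(specs, nCells = 100, replicates = 2,
                                 seed = 5)
    expect_identical(SummarizedExperiment::assay(sim$signal),
                     SummarizedExperiment::assay(sim2$signal))

    expect_error(simulateSignalMatrix(specs, nCells = 20, replicates = 1),
                 "at least 10")
})

test_that("component allocation is deterministic with exact sizes", {
    spec <- simGroupSpec("g", "multimodal", c(0, 1, 2), 0.1)
    sim <- simulateSignalMatrix(list(spec), nCells = 100, replicates = 1,
                                seed = 1)
    sizes <- table(componentLabels(sim$truth)[1, ])
    expect_equal(as.integer(sizes), c(34L, 33L, 33L))

    # empirical component means converge to the design means
    spec2 <- simGroupSpec("h", "bimodal", c(-3, 3), 0.1)
    sim2 <- simulateSignalMatrix(list(spec2), nCells = 1000,
                                 replicates = 1, seed = 2)
    x <- SummarizedExperiment::assay(sim2$signal)[1, ]
    lab <- componentLabels(sim2$truth)[1, ]
    for (j in 1:2)
        expect_lt(abs(mean(x[lab == j]) - c(-3, 3)[j]),
                  4 * 0.1 / sqrt(500))
})

test_that("missing injection is exact, guarded and seeded", {
    spec <- simGroupSpec("g", "multimodal", c(0, 1, 2), 0.1)
    sim <- simulateSignalMatrix(list(spec), nCells = 100, replicates = 20,
                                seed = 3)
    mi <- injectMissing(sim$signal, sim$truth, 0.1, seed = 4)
    sig <- SummarizedExperiment::assay(mi$signal)
    expect_true(all(rowSums(is.na(sig)) == 10L))
    expect_equal(which(is.na(sig[1, ])),
                 which(missingMask(mi$truth)[1, ]), ignore_attr = TRUE)

    # at 60% missing every component keeps more than 10 observed cells
    mi60 <- injectMissing(sim$signal, sim$truth, 0.6, seed = 5)
    sig60 <- SummarizedExperiment::assay(mi60$signal)
    lab <- componentLabels(mi60$truth)
    for (r in seq_len(nrow(sig60))) {
        kept <- table(lab[r, !is.na(sig60[r, ])])
        expect_true(all(kept > 10L))
    }

    # an unsatisfiable guarantee is an error
    expect_error(injectMissing(sim$signal, sim$truth, 0.95, seed = 6),
                 "component")
    mi2 <- injectMissing(sim$signal, sim$truth, 0.1, seed = 4)
    expect_identical(sig, SummarizedExperiment::assay(mi2$signal))
})

test_that("noise injection perturbs the right number of entries boundedly", {
    spec <- simGroupSpec("g", "bimodal", c(-2, 2), 0.1)
    sim <- simulateSignalMatrix(list(spec), nCells = 100, replicates = 10,
                                seed = 7)
    no <- injectNoise(sim$signal, sim$truth, 0.05, seed = 8)
    before <- SummarizedExperiment::assay(sim$signal)
    after <- SummarizedExperiment::assay(no$signal)
    mask <- noiseMask(no$truth)
    expect_true(all(rowSums(mask) == 5L))
    expect_true(all(after[!mask] == before[!mask]))
    expect_true(all(abs(after[mask] - before[mask]) <= 0.5))
    no2 <- injectNoise(sim$signal, sim$truth, 0.05, seed = 8)
    expect_identical(after, SummarizedExperiment::assay(no2$signal))
})

test_that("unbalanced bimodal designs allocate cells by the stated ratios", {
    ub <- simulateUnbalancedBimodal(nCells = 100, replicates = 1, seed = 9)
    expect_equal(nrow(SummarizedExperiment::assay(ub$signal)), 5L)
    lab <- componentLabels(ub$truth)
    expect_equal(as.integer(table(lab[5, ])), c(90L, 10L))  # 9:1 group
    expect_equal(as.integer(table(lab[1, ])), c(50L, 50L))
    x <- SummarizedExperiment::assay(ub$signal)[5, ]
    expect_equal(mean(x[lab[5, ] == 1]), 10, tolerance = 0.1)
    expect_equal(mean(x[lab[5, ] == 2]), -10, tolerance = 0.2)
    expect_error(simulateUnbalancedBimodal(nCells = 55), "divisible")
    expect_error(simulateUnbalancedBimodal(ratios = list(c(7, 4))),
                 "summing to 10")
})
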