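test_that("single-Gaussian fits match the closed-form MLE and BIC", {
    set.seed(4)
    for (rep in 1:20) {
        n <- sample(10:200, 1)
        x <- rnorm(n, rnorm(1, 0, 3), runif(1, 0.05, 2))
        f <- fitGMM(x, 1)
        s2 <- max(mean((x - mean(x))^2), modalityControl()$varFloor)
        expect_equal(f@means, mean(x))
        expect_equal(f@variances, s2)
        # brute-force closed form: n ln(2 pi sigma^2) + n + 2 ln(n)
        expect_equal(f@bic, n * log(2 * pi * s2) + n + 2 * log(n),
                     tolerance = 1e-10)
    }
    # constant vector: mean recovered, variance at the floor
    f <- fitGMM(rep(1.5, 30), 1)
    expect_equal(f@means, 1.5)
    expect_equal(f@variances, modalityControl()$varFloor)
})

test_that("well-separated two-component structure is recovered", {
    set.seed(5)
    eta <- c(rnorm(50, -10, 0.1), rnorm(50, 10, 0.1))
    f <- fitGMM(eta, 2, seed = 9)
    expect_equal(f@means, c(-10, 10), tolerance = 0.1)
    expect_equal(f@weights, c(0.5, 0.5), tolerance = 0.05)
    expect_equal(sum(f@weights), 1, tolerance = 1e-9)
    # posterior memberships split the sample in half
    expect_equal(as.integer(table(max.col(f@posterior))), c(50L, 50L))

    # single-component recovery with law-of-large-numbers tolerance
    set.seed(6)
    f1 <- fitGMM(rnorm(100, 0, 0.1), 1)
    expect_lt(abs(f1@means), 0.05)

    expect_error(fitGMM(c(1, 2), 3), "at least")
    expect_error(fitGMM(c(1, NA, 2), 1), "missing")
})

test_that("EM log-likelihood is monotonically non-decreasing", {
    set.seed(7)
    for (rep in 1:20) {
        eta <- c(rnorm(40, 0, 0.5), rnorm(30, rnorm(1, 3, 1), 0.5))
        f <- fitGMM(eta, sample(2:3, 1), seed = rep)
        expect_true(all(diff(f@loglikTrace) >= -1e-8))
    }
})

test_that("parameter recovery holds across 100 seeded runs", {
    # two components 100 sd apart, 50 cells each: recovered means must lie
    # within 3 sd / sqrt(n/2) of the truth
    tolMu <- 3 * 0.1 / sqrt(50)
    set.seed(123)
    worst <- 0
    for (s in 1:100) {
        eta <- c(rnorm(50, -10, 0.1), rnorm(50, 10, 0.1))
        f <- fitGMM(eta, 2, seed = s)
        worst <- max(worst, abs(f@means - c(-10, 10)))
    }
    expect_lt(worst, tolMu)
})

test_that("the BIC correction rule follows the remove-then-compare logic", {
    # positive BICs, ratio below threshold: smaller BIC wins outright
    expect_equal(chooseComponentCount(c(200, 100, 80)), 3L)
    # positive BICs within 5%: reduce to the smaller component count
    expect_equal(chooseComponentCount(c(200, 100, 96)), 2L)
    expect_equal(chooseComponentCount(c(200, 96, 100)), 2L)
    # worst of the three is discarded first, whichever k holds it
    expect_equal(chooseComponentCount(c(100, 300, 200)), 1L)
    expect_equal(chooseComponentCount(c(100, 300, 120)), 1L)
    # the closeness branch triggers exactly above the threshold
    expect_equal(chooseComponentCount(c(1000, 95, 100)), 2L)          # 0.95 is not > 0.95
    expect_equal(chooseComponentCount(c(1000, 95.00001, 100)), 2L)
    expect_equal(chooseComponentCount(c(1000, 94.99, 100)), 2L)
    expect_equal(chooseComponentCount(c(1000, 100, 94.99)), 3L)
    # negative BICs: the ratio of two negatives exceeds 1, so the smaller
    # component count always wins
    expect_equal(chooseComponentCount(c(100, -50, -60)), 2L)
    expect_equal(chooseComponentCount(c(-170, -155, -140)), 1L)
    # infeasible fits never count as close
    expect_equal(chooseComponentCount(c(-10, Inf, Inf)), 1L)
})

test_that("component selection matches the design groups end to end", {
    set.seed(8)
    expect_equal(selectComponents(rnorm(100, 0, 0.1), seed = 1), 1L)
    eta2 <- c(rnorm(50, 2, 0.1), rnorm(50, -2, 0.1))
    expect_equal(selectComponents(eta2, seed = 1), 2L)
    eta3 <- c(rnorm(34, 2, 0.1), rnorm(33, -2, 0.1), rnorm(33, 0, 0.1))
    expect_equal(selectComponents(eta3, seed = 1), 3L)
    # a 5-cell component forces the undetected verdict
    etaSmall <- c(rnorm(95, 0, 0.1), rnorm(5, 5, 0.1))
    expect_equal(selectComponents(etaSmall, seed = 1), -1L)
    # fewer than 10 observations are undecidable
    expect_equal(selectComponents(rnorm(9), seed = 1), -1L)
    # invariant under permutation of the input order
    perm <- sample(length(eta2))
    expect_equal(selectComponents(eta2[perm], seed = 1), 2L)
})

test_that("modality labels map fixedly from component counts", {
    expect_equal(classifyModality(1L), "unimodal")
    expect_equal(classifyModality(2L), "bimodal")
    expect_equal(classifyModality(3L), "multimodal")
    expect_equal(classifyModality(-1L), "undetected")
    expect_error(classifyModality(0L), "must be one of")
})

test_that("identifyModalities handles missing cells and small rows", {
    set.seed(12)
    m <- rbind(uni = rnorm(100, 1, 0.1),
               bi = c(rnorm(50, 2, 0.1), rnorm(50, -2, 0.1)),
               sparse = c(rnorm(4, 0, 0.1), rep(NA, 96)))
    colnames(m) <- paste0("c", 1:100)
    sig <- APASignalMatrix(m, featureKind = "simulated")
    calls <- identifyModalities(sig, seed = 3)
    tab <- modalityCalls(calls)
    expect_equal(tab$modality, c("unimodal", "bimodal", "undetected"))
    expect_equal(tab$n_cells, c(100L, 100L, 4L))
    # memberships exist exactly for detected rows, sizes sum to n_cells
    mem <- membershipMatrix(calls)
    expect_equal(sum(!is.na(mem["bi", ])), 100L)
    expect_true(all(is.na(mem["sparse", ])))
    sizes <- as.integer(strsplit(tab$component_sizes[2], ",")[[1]])
    expect_equal(sum(sizes), 100L)
    # determinism: same input and seed reproduce the same calls
    calls2 <- identifyModalities(sig, seed = 3)
    expect_identical(modalityCalls(calls2), tab)

    empty <- APASignalMatrix(matrix(numeric(), 0, 5,
                                    dimnames = list(NULL, paste0("c", 1:5))),
                             featureKind = "simulated",
                             featureId = character(0))
    expect_equal(nrow(modalityCalls(identifyModalities(empty, seed = 1))),
                 0L)
})

test_that("mixture fits agree with an independent implementation", {
    skip_if_not_installed("mclust")
    withr::local_package("mclust")
    set.seed(21)
    eta <- c(rnorm(60, -1, 0.2), rnorm(40, 1.5, 0.2))
    f <- fitGMM(eta, 2, seed = 2)
    mc <- mclust::Mclust(eta, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(f@means), sort(as.numeric(mc$parameters$mean)),
                 tolerance = 1e-3)
    expect_equal(f@loglik, mc$loglik, tolerance = 1e-4)
})
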