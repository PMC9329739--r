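test_that("PUI matches its closed form on hand-computed vectors", {
    # pc = (3,1): geometric mean of (4,2) is sqrt(8); log2(4/sqrt(8)) = 1/2
    expect_equal(computePUI(c(3, 1), 1), 0.5)
    expect_equal(computePUI(c(3, 1), 2), -0.5)
    # pc = (0,3): denominator exp((ln 1 + ln 4)/2) = 2
    expect_equal(computePUI(c(0, 3), 1), -1)
    expect_equal(computePUI(c(0, 3), 2), 1)
    # symmetric counts give average usage
    expect_equal(computePUI(c(1, 1), 1), 0)
    # unexpressed gene has undefined usage
    expect_true(is.na(computePUI(c(0, 0), 1)))
    expect_true(is.na(computePUI(c(0, 0), 2)))

    expect_error(computePUI(c(3, 1), 3), "out of range")
    expect_error(computePUI(c(3), 1), "fewer than two")
})

test_that("usage ratio is the site's share of gene expression", {
    expect_equal(computeRatio(c(3, 1), 1), 0.75)
    expect_equal(computeRatio(c(5, 0, 5), 2), 0)
    expect_true(is.na(computeRatio(c(0, 0), 1)))
    expect_error(computeRatio(c(2), 1), "fewer than two")
})

test_that("PUI identities hold on random count vectors", {
    set.seed(11)
    for (rep in 1:50) {
        nSites <- sample(2:6, 1)
        pc <- rpois(nSites, lambda = sample(1:5, 1))
        if (all(pc == 0)) pc[1] <- 1
        pui <- vapply(seq_along(pc), function(i) computePUI(pc, i), 0)
        # the PUI values of a gene's sites in one cell average to zero
        expect_equal(mean(pui), 0, tolerance = 1e-12)
        # ratios of an expressed gene sum to one
        ratio <- vapply(seq_along(pc), function(i) computeRatio(pc, i), 0)
        expect_equal(sum(ratio), 1, tolerance = 1e-12)
        # PUI depends only on pc[i] and the multiset of counts
        i <- sample(nSites, 1)
        others <- setdiff(seq_len(nSites), i)
        perm <- c(i, others[sample.int(length(others))])
        expect_equal(computePUI(pc[perm], 1), computePUI(pc, i))
        # sign semantics: above-geometric-mean usage gives positive PUI
        gm <- exp(mean(log(pc + 1)))
        if (pc[i] + 1 > gm) expect_gt(computePUI(pc, i), 0)
        if (pc[i] + 1 < gm) expect_lt(computePUI(pc, i), 0)
    }
})

test_that("proximal site selection respects strand orientation", {
    plus <- data.frame(site_id = c("a", "b"), strand = "+",
                       position = c(1000L, 1500L), gene_id = "g",
                       region = "3UTR")
    expect_equal(selectProximalSite(plus), "a")
    minus <- plus; minus$strand <- "-"
    expect_equal(selectProximalSite(minus), "b")
    expect_error(selectProximalSite(plus[1, ]), "at least two")
    mixed <- plus; mixed$strand <- c("+", "-")
    expect_error(selectProximalSite(mixed), "annotation error")
})

test_that("major/minor selection uses totals with annotation-order ties", {
    expect_equal(selectMajorMinor(c(10, 3, 7)),
                 c(major = 1L, minor = 2L))
    expect_equal(selectMajorMinor(c(4, 4)), c(major = 1L, minor = 2L))
    expect_equal(selectMajorMinor(c(0, 0, 5)), c(major = 3L, minor = 1L))
    expect_error(selectMajorMinor(5), "at least two")
})

test_that("signal matrices carry per-cell PUI and transformed ratios", {
    sites <- data.frame(site_id = c("s1", "s2"), chrom = "chr1",
                        strand = "+", position = c(100L, 500L),
                        gene_id = "g1", region = "3UTR",
                        stringsAsFactors = FALSE)
    counts <- matrix(c(3, 1, 1, 1, 0, 0), nrow = 2,
                     dimnames = list(c("s1", "s2"), c("c1", "c2", "c3")))
    sm <- PACountMatrix(counts, sites)

    pui <- SummarizedExperiment::assay(
        buildSignalMatrix(sm, "gene_proximal_PUI"), "signal")
    expect_equal(unname(pui["g1", ]), c(0.5, 0, NA))

    # major site is s1 (total 4 vs 2); log2(0.75 + 1) in cell 1
    maj <- SummarizedExperiment::assay(
        buildSignalMatrix(sm, "major_ratio"), "signal")
    expect_equal(unname(maj["g1", ]),
                 c(log2(1.75), log2(1.5), NA), tolerance = 1e-12)
    expect_equal(log2(1.75), 0.807355, tolerance = 1e-6)

    # ratio transform endpoints: ratio 0 -> 0, ratio 1 -> 1
    counts2 <- matrix(c(4, 0, 0, 3), nrow = 2,
                      dimnames = list(c("s1", "s2"), c("c1", "c2")))
    sm2 <- PACountMatrix(counts2, sites)
    maj2 <- SummarizedExperiment::assay(
        buildSignalMatrix(sm2, "major_ratio"), "signal")
    expect_equal(unname(maj2["g1", ]), c(1, 0))

    # site-level PUI has one row per site and region metadata
    sp <- buildSignalMatrix(sm, "site_PUI")
    expect_equal(nrow(sp), 2L)
    expect_equal(unname(SummarizedExperiment::assay(sp)[1, ]),
                 c(0.5, 0, NA))

    single <- PACountMatrix(counts[1, , drop = FALSE], sites[1, ])
    expect_error(buildSignalMatrix(single, "major_ratio"),
                 "at least two")
})
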