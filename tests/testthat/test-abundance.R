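test_that("low-count filter removes exactly the singletons and doubletons", {
    x <- toyOtuTable()
    expect_message(f <- filterLowCountOtus(x), "2 low-count OTUs removed")
    expect_identical(otuStage(f), "filtered")
    expect_setdiff <- setdiff(rownames(otuCounts(x)), rownames(otuCounts(f)))
    expect_identical(sort(expect_setdiff), c("OTU_D", "OTU_E"))
    expect_true("OTU_F" %in% rownames(otuCounts(f)))   # total 3: retained
    expect_identical(S4Vectors::metadata(f)$n_low_count_removed, 2L)
    # no-op when nothing is low-count
    f2 <- suppressMessages(filterLowCountOtus(x[1:3, ]))
    expect_identical(otuCounts(f2), otuCounts(x)[1:3, ])
})

test_that("rarefaction equalizes column sums exactly, drops shallow samples
           and is seed-deterministic", {
    x <- suppressMessages(filterLowCountOtus(toyOtuTable()))
    r <- rarefyCounts(x, depth = 9000, seed = 3)
    expect_identical(otuStage(r), "rarefied")
    expect_true(all(colSums(otuCounts(r)) == 9000))
    r2 <- rarefyCounts(x, depth = 9000, seed = 3)
    expect_identical(otuCounts(r), otuCounts(r2))
    r3 <- rarefyCounts(x, depth = 9000, seed = 4)
    expect_false(identical(otuCounts(r), otuCounts(r3)))
    # a sample under the depth is dropped with a warning, not an error
    shallow <- toyOtuTable()
    cnt <- otuCounts(shallow); cnt[, "S2"] <- c(10L, 5L, 3L, 0L, 0L, 1L)
    y <- OtuExperiment(cnt, doseDesign(shallow))
    y <- suppressMessages(filterLowCountOtus(y))
    expect_warning(ry <- rarefyCounts(y, 9000, seed = 1), "S2")
    expect_false("S2" %in% colnames(otuCounts(ry)))
    expect_error(rarefyCounts(x, depth = 0), "positive")
})

test_that("copy-number correction reproduces the hand example and conserves
           16S copies", {
    counts <- rbind(OTU_X = c(90L), OTU_Y = c(10L))
    colnames(counts) <- "S1"
    x <- OtuExperiment(counts,
        data.frame(sample_id = "S1", treatment = "Ag+", dose = 1),
        stage = "rarefied")
    ab <- toAbsoluteAbundance(x,
        copyNumbers = c(OTU_X = 3, OTU_Y = 1),
        qpcrTotals = c(S1 = 1000))
    expect_identical(otuStage(ab), "absolute")
    expect_identical(unname(otuCounts(ab)[, 1]), c(300, 100))
    # conservation: sum_i A * CN = T
    tr <- generateTruth(nOtus = 40, seed = 9)
    obs <- simulateObserved(tr, depth = 12000)
    p <- rarefyCounts(suppressMessages(filterLowCountOtus(obs)), 9000,
                      seed = 9)
    ab2 <- toAbsoluteAbundance(p)
    m <- otuCounts(ab2)
    cn <- SummarizedExperiment::rowData(ab2)$copy_number
    tot <- SummarizedExperiment::colData(ab2)$qpcr_total
    expect_equal(unname(colSums(m * cn)), unname(tot), tolerance = 1e-9)
    # all-ones copy numbers degenerate to plain scaling
    ab3 <- toAbsoluteAbundance(x, copyNumbers = c(OTU_X = 1, OTU_Y = 1),
                               qpcrTotals = c(S1 = 1000))
    expect_identical(unname(otuCounts(ab3)[, 1]), c(900, 100))
    expect_error(toAbsoluteAbundance(x, copyNumbers = c(OTU_X = 3,
        OTU_Y = 1), qpcrTotals = c(S9 = 10)), "S1")
})

test_that("the preprocessing stage order is enforced", {
    x <- toyOtuTable()
    expect_error(rarefyCounts(x), "'raw'")
    expect_error(toAbsoluteAbundance(x), "'raw'")
    expect_error(eligibleOtus(x), "'raw'")
    f <- suppressMessages(filterLowCountOtus(x))
    expect_error(filterLowCountOtus(f), "'filtered'")
})

test_that("eligibility requires nonzero abundance in >= 6 samples per arm,
           counting shared controls", {
    set.seed(2)
    n <- 20
    counts <- matrix(rpois(3 * n, 500), 3, n,
        dimnames = list(c("OTU_a", "OTU_b", "OTU_c"),
                        sprintf("S%02d", 1:n)))
    # OTU_b present in control + 5 arm-A samples only (6 total for A);
    # OTU_c in 5 samples total
    counts["OTU_b", ] <- 0L; counts["OTU_b", 1:6] <- 100L
    counts["OTU_c", ] <- 0L; counts["OTU_c", 2:6] <- 100L
    design <- data.frame(sample_id = colnames(counts),
        treatment = c("control", rep("A", 9), rep("B", 10)),
        dose = c(0.1, geomSeq(1, 100, 9), geomSeq(1, 100, 10)))
    x <- OtuExperiment(counts, design, stage = "raw")
    ab <- toAbsoluteAbundance(
        rarefyCounts(suppressMessages(filterLowCountOtus(x)), depth = 100,
                     seed = 1),
        copyNumbers = stats::setNames(rep(1, 3), rownames(counts)),
        qpcrTotals = stats::setNames(rep(1e6, n), colnames(counts)))
    el <- eligibleOtus(ab, minSamples = 6)
    expect_named(el, c("A", "B"))
    expect_true("OTU_a" %in% el$A && "OTU_a" %in% el$B)
    expect_true("OTU_b" %in% el$A)      # control counts toward arm A
    expect_false("OTU_b" %in% el$B)
    expect_false("OTU_c" %in% el$A)     # only 5 nonzero samples
})
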