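test_that("Burr III cdf and quantile are mutual inverses with the right
           special values", {
    p <- BurrIII(scaleB = 10, shapeC = 2, shapeK = 0.5)
    expect_equal(burr3Cdf(p, 10), 2^-0.5)             # direct substitution
    expect_equal(burr3Quantile(p, 2^-0.5), 10)
    k1 <- BurrIII(7, 3, 1)
    expect_equal(burr3Cdf(k1, 7), 0.5)                # median = scale at k=1
    expect_equal(burr3Quantile(k1, 0.5), 7)
    expect_lt(burr3Cdf(p, 1e-12), 1e-10)
    expect_gt(burr3Cdf(p, 1e12), 1 - 1e-10)
    expect_error(burr3Cdf(p, 0), "x > 0")
    expect_error(burr3Quantile(p, 1), "0, 1")
    set.seed(1)
    for (i in 1:20) {
        pp <- BurrIII(exp(runif(1, -2, 5)), runif(1, 0.3, 6),
                      runif(1, 0.1, 5))
        q <- (1:99) / 100
        expect_equal(burr3Cdf(pp, burr3Quantile(pp, q)), q,
                     tolerance = 1e-10)
        xs <- burr3Quantile(pp, sort(runif(30)))
        expect_true(all(diff(burr3Cdf(pp, sort(xs))) >= 0))
    }
})

test_that("Burr III MLE recovers a known distribution and beats its own
           starting values", {
    set.seed(3)
    x <- rBurr3(400, b = 12, c = 1.8, k = 0.9)
    fit <- fitBurr3(x)
    gen5 <- burr3Quantile(BurrIII(12, 1.8, 0.9), 0.05)
    expect_lt(abs(hazardousConcentration(fit, 5) - gen5) / gen5, 0.2)
    # KS distance between fitted and generating CDFs
    grid <- geomSeq(0.01, 1e4, 400)
    ks <- max(abs(burr3Cdf(fit, grid) - burr3Cdf(BurrIII(12, 1.8, 0.9),
                                                 grid)))
    expect_lt(ks, 0.08)
    expect_error(fitBurr3(rep(5, 20)), "degenerate")
    expect_error(fitBurr3(x[1:7]), "at least 8")
    expect_error(fitBurr3(c(x[1:10], -1)), "positive")
})

test_that("hazardous concentrations are distribution quantiles, monotone in
           the protection level", {
    p <- BurrIII(10, 2, 0.5)
    hcs <- hazardousConcentration(p, c(5, 10, 20, 80))
    expect_true(all(diff(hcs) > 0))
    expect_equal(hazardousConcentration(BurrIII(4, 1.4, 1), 50), 4)
    # quantile formula equals numeric CDF inversion
    oracle <- bisectRoot(function(x) 1 - burr3Cdf(p, x), 1 - 0.05,
                         1e-10, 1e10)
    expect_equal(hazardousConcentration(p, 5), oracle, tolerance = 1e-8)
})

test_that("bootstrap HC intervals are deterministic, bracket the point
           estimate and shrink with sample size", {
    set.seed(8)
    x <- rBurr3(60, b = 8, c = 2, k = 1)
    hc <- bootstrapHc(x, protection = c(5, 20), nBoot = 100, seed = 42)
    hc2 <- bootstrapHc(x, protection = c(5, 20), nBoot = 100, seed = 42)
    expect_identical(hc, hc2)
    expect_true(all(hc$ci_low <= hc$value & hc$value <= hc$ci_high))
    xBig <- rBurr3(400, b = 8, c = 2, k = 1)
    hcBig <- bootstrapHc(xBig, protection = 5, nBoot = 100, seed = 42)
    expect_lt(hcBig$ci_high[1] - hcBig$ci_low[1],
              hc$ci_high[1] - hc$ci_low[1])
    expect_warning(bootstrapHc(x, protection = 5, nBoot = 1, seed = 1),
                   "degenerate")
})

test_that("treatment comparison follows the CI-overlap rule, symmetrically", {
    hcA <- list(protection_percent = 20, value = 5.9, ci_low = 4.4,
                ci_high = 8.1)
    hcB <- list(protection_percent = 20, value = 1.4, ci_low = 1.2,
                ci_high = 1.7)
    expect_identical(compareTreatments(hcA, hcB), "significant")
    expect_identical(compareTreatments(hcB, hcA), "significant")
    hcC <- list(protection_percent = 5, value = 0.49, ci_low = 0.32,
                ci_high = 0.73)
    hcD <- list(protection_percent = 5, value = 0.25, ci_low = 0.13,
                ci_high = 0.47)
    expect_identical(compareTreatments(hcC, hcD), "not_significant")
    expect_identical(compareTreatments(hcC, hcC), "not_significant")
    expect_error(compareTreatments(hcA, hcC), "protection")
    expect_error(compareTreatments(list(value = 1), hcA), "confidence")
})

test_that("OSD plot data carries empirical ranks and a fitted curve", {
    set.seed(4)
    x <- rBurr3(50, 5, 2, 1)
    pd <- osdPlotData(x)
    pts <- pd[pd$kind == "point", ]
    expect_equal(pts$fraction_affected, ((1:50) - 0.5) / 50)
    expect_equal(pts$concentration, sort(x))
    crv <- pd[pd$kind == "curve", ]
    expect_true(all(diff(crv$fraction_affected) >= 0))
})
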