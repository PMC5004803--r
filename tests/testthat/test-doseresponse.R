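test_that("log-logistic evaluator matches hand arithmetic and limits", {
    p <- c(b = 2, c = 0, d = 100, e = 10)
    expect_equal(evalLogLogistic(p, 0), 100)     # zero dose -> upper asymptote
    expect_equal(evalLogLogistic(p, 10), 50)     # inflection -> midpoint
    expect_equal(evalLogLogistic(c(b = 1, c = 20, d = 100, e = 5), 15),
                 40)                              # 20 + 80/(1+3)
    expect_lt(evalLogLogistic(p, 1e9), 1e-10)    # limit at +Inf is c
    expect_error(evalLogLogistic(c(b = 1, c = 0, d = 1, e = -1), 1),
                 "e must be")
    expect_error(evalLogLogistic(c(b = NaN, c = 0, d = 1, e = 1), 1),
                 "non-finite")
})

test_that("hormesis evaluator reduces to log-logistic at f = 0 and adds
           stimulation otherwise", {
    expect_equal(evalHormesis(c(b = 2, c = 0, d = 100, e = 10, f = 0), 10),
                 50)
    expect_equal(evalHormesis(c(b = 2, c = 0, d = 100, e = 10, f = 5), 10),
                 75)                              # (100 + 50)/2
    expect_equal(evalHormesis(c(b = 3, c = 7, d = 42, e = 2, f = 9), 0), 42)
    # pointwise identity over a random grid
    set.seed(42)
    for (i in 1:50) {
        p <- c(b = runif(1, 0.3, 5), c = runif(1, -5, 20),
               d = runif(1, 30, 200), e = exp(runif(1, -2, 6)))
        x <- exp(runif(20, -3, 9))
        expect_equal(evalHormesis(c(p, f = 0), x), evalLogLogistic(p, x),
                     tolerance = 1e-12)
    }
})

test_that("least-squares fitting recovers noise-free truth and reports
           sensible diagnostics", {
    s <- llSeries()
    fit <- fitDoseResponse(s$doses, s$responses)
    expect_s4_class(fit, "DoseResponseFit")
    expect_true(fit@converged)
    truth <- c(b = 1.5, c = 5, d = 120, e = 8)
    expect_lt(max(abs(fitParams(fit) - truth) / truth), 1e-4)
    expect_equal(rSquared(fit), 1, tolerance = 1e-8)
    expect_equal(fit@residualDf, 10)
    expect_true(!is.null(fitCovariance(fit)))
    # hormesis refit of a loglogistic truth lands at f ~ 0
    fitH <- fitDoseResponse(s$doses, s$responses, "hormesis5")
    expect_lt(abs(fitParams(fitH)[["f"]]), 1e-4)
})

test_that("flat responses yield a failed, never-crashing fit", {
    x <- geomSeq(0.1, 100, 10)
    fit <- fitDoseResponse(x, rep(7, 10))
    expect_false(fit@converged)
    expect_false(isAccepted(applyAcceptanceCriteria(fit, maxDose = 100)))
    expect_identical(rejectionReasons(applyAcceptanceCriteria(fit, 100)),
                     "fit_failed")
})

test_that("fit preconditions are enforced", {
    expect_error(fitDoseResponse(1:4, 1:4), "at least 5")
    expect_error(fitDoseResponse(1:5, 1:5, "hormesis5"), "at least 6")
    expect_error(fitDoseResponse(c(-1, 1:9), rnorm(10)), "finite")
})

test_that("acceptance criteria reject with the correct single reason", {
    mk <- function(b = 2, e = 10, r2 = 0.9)
        DoseResponseFit("loglogistic4", c(b = b, c = 0, d = 100, e = e),
                        rSquared = r2)
    expect_identical(
        rejectionReasons(applyAcceptanceCriteria(mk(b = -2), maxDose = 404)),
        "slope_nonpositive")
    expect_identical(
        rejectionReasons(applyAcceptanceCriteria(mk(e = 700), maxDose = 404)),
        "e_exceeds_max_dose")
    expect_identical(
        rejectionReasons(applyAcceptanceCriteria(mk(r2 = 0.5), maxDose = 404)),
        "r2_below_threshold")
    acc <- applyAcceptanceCriteria(mk(), maxDose = 404)
    expect_true(isAccepted(acc))
    expect_length(rejectionReasons(acc), 0)
    # boundary: R2 must strictly exceed the threshold
    expect_false(isAccepted(applyAcceptanceCriteria(mk(r2 = 0.65), 404)))
})

test_that("hormesis significance is a t-based interval on f", {
    cov5 <- diag(c(1, 1, 1, 1, 4))
    dimnames(cov5) <- rep(list(c("b", "c", "d", "e", "f")), 2)
    mk <- function(f) DoseResponseFit("hormesis5",
        c(b = 2, c = 0, d = 100, e = 10, f = f), covariance = cov5,
        residualDf = 9)
    expect_true(testHormesisSignificance(mk(10)))   # CI (5.48, 14.52)
    expect_false(testHormesisSignificance(mk(1)))   # straddles zero
    expect_false(testHormesisSignificance(mk(0)))
    noCov <- DoseResponseFit("hormesis5",
        c(b = 2, c = 0, d = 100, e = 10, f = 10), residualDf = 9)
    expect_warning(res <- testHormesisSignificance(noCov), "covariance")
    expect_false(res)
})

test_that("model selection is conservative", {
    ll <- DoseResponseFit("loglogistic4", c(b = 2, c = 0, d = 100, e = 10),
                          accepted = TRUE)
    h <- DoseResponseFit("hormesis5",
                         c(b = 2, c = 0, d = 100, e = 10, f = 1),
                         accepted = TRUE)
    llBad <- DoseResponseFit("loglogistic4", c(b = -1, c = 0, d = 1, e = 1),
                             rejectionReasons = "slope_nonpositive")
    hBad <- DoseResponseFit("hormesis5",
                            c(b = -1, c = 0, d = 1, e = 1, f = 0),
                            rejectionReasons = "slope_nonpositive")
    expect_identical(fitModel(selectModel(ll, h)), "hormesis5")
    expect_identical(fitModel(selectModel(ll, hBad)), "loglogistic4")
    expect_identical(fitModel(selectModel(llBad, h)), "hormesis5")
    expect_null(selectModel(llBad, hBad))
})

test_that("ECx closed forms agree with hand values and a bisection oracle", {
    fit <- DoseResponseFit("loglogistic4", c(b = 1, c = 0, d = 100, e = 10))
    expect_equal(computeEcx(fit, 50, "span")$value, 10)
    expect_equal(computeEcx(fit, 50, "upper_asymptote")$value, 10)
    expect_equal(computeEcx(fit, 20, "span")$value, 2.5)
    set.seed(7)
    for (i in 1:40) {
        p <- c(b = runif(1, 0.5, 4), c = runif(1, 0, 10),
               d = runif(1, 50, 200), e = exp(runif(1, -1, 5)))
        f <- DoseResponseFit("loglogistic4", p)
        for (lev in c(20, 50)) {
            spanV <- computeEcx(f, lev, "span")$value
            oracle <- bisectRoot(function(x) evalLogLogistic(p, x),
                                 p[["c"]] + (1 - lev / 100) *
                                     (p[["d"]] - p[["c"]]),
                                 1e-12, p[["e"]] * 1e8)
            expect_equal(spanV, oracle, tolerance = 1e-8)
        }
    }
})

test_that("hormesis ECx matches a brute-force grid scan on the descending
           limb", {
    pars <- c(b = 2, c = 0, d = 100, e = 10, f = 5)
    fit <- DoseResponseFit("hormesis5", pars, doses = c(0.1, 100))
    v <- computeEcx(fit, 20, "upper_asymptote")$value
    grid <- seq(1e-4, 1000, length.out = 1e6)
    y <- evalHormesis(pars, grid)
    peak <- which.max(y)
    target <- 0.8 * pars[["d"]]
    gscan <- grid[peak - 1 + which.min(abs(y[peak:length(y)] - target))]
    expect_equal(v, gscan, tolerance = 1e-4)
    # monotone non-decreasing in p
    vals <- vapply(c(5, 10, 20, 40, 60, 80),
                   function(p) computeEcx(fit, p)$value, numeric(1))
    expect_true(all(diff(vals) >= 0))
})

test_that("ECx errors clearly when the reduction is never attained", {
    fit <- DoseResponseFit("loglogistic4", c(b = 1, c = 80, d = 100, e = 10))
    expect_error(computeEcx(fit, 50, "upper_asymptote"), "no crossing")
    stim <- DoseResponseFit("hormesis5",
        c(b = 0.4, c = 95, d = 100, e = 5, f = 2), doses = c(0.1, 50))
    expect_error(computeEcx(stim, 50, "upper_asymptote"), "no crossing")
})

test_that("delta-method CI has the analytic width under e-only uncertainty
           and degenerates with zero covariance", {
    pars <- c(b = 2, c = 0, d = 100, e = 10)
    sig2 <- 4
    cov0 <- matrix(0, 4, 4, dimnames = rep(list(names(pars)), 2))
    covE <- cov0; covE["e", "e"] <- sig2
    f0 <- DoseResponseFit("loglogistic4", pars, covariance = cov0)
    est0 <- ecxConfidenceInterval(f0, 20, "span")
    expect_equal(est0$ci_low, est0$value)
    expect_equal(est0$ci_high, est0$value)
    fE <- DoseResponseFit("loglogistic4", pars, covariance = covE)
    est <- ecxConfidenceInterval(fE, 20, "span")
    expect_equal(est$ci_high - est$ci_low,
                 2 * qnorm(0.975) * sqrt(sig2) * (20 / 80)^(1 / 2),
                 tolerance = 1e-10)
    # numeric gradient path (upper_asymptote) agrees with analytic span path
    # where the two modes coincide (c = 0 scales both the same way for p=50)
    est2 <- ecxConfidenceInterval(fE, 50, "upper_asymptote")
    est3 <- ecxConfidenceInterval(fE, 50, "span")
    expect_equal(est2$ci_high, est3$ci_high, tolerance = 1e-5)
})

test_that("delta-method CI covers a known EC20 at near-nominal rate", {
    truth <- c(b = 1.5, c = 5, d = 120, e = 8)
    trueEc <- computeEcx(DoseResponseFit("loglogistic4", truth), 20,
                         "upper_asymptote")$value
    x <- geomSeq(0.1, 500, 14)
    mu <- evalLogLogistic(truth, x)
    set.seed(11)
    cover <- vapply(1:200, function(i) {
        y <- mu + rnorm(length(x), 0, 2.4)   # 2% of the control level
        fit <- fitDoseResponse(x, y)
        est <- tryCatch(ecxConfidenceInterval(fit, 20, "upper_asymptote"),
                        error = function(e) NULL)
        if (is.null(est)) return(NA)
        est$ci_low <= trueEc && trueEc <= est$ci_high
    }, logical(1))
    expect_gt(mean(cover, na.rm = TRUE), 0.88)
    expect_lt(mean(cover, na.rm = TRUE), 1)
})
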