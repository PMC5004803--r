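#' @importFrom stats nlminb sd quantile plogis rlnorm runif rnorm
NULL

.burrCheck <- function(params) {
    if (is(params, "BurrIII"))
        c(b = params@scaleB, c = params@shapeC, k = params@shapeK)
    else {
        stopifnot(all(c("scaleB", "shapeC", "shapeK") %in% names(params)))
        c(b = params[["scaleB"]], c = params[["shapeC"]],
          k = params[["shapeK"]])
    }
}

#' Burr Type III cumulative distribution function
#'
#' \deqn{F(x) = (1 + (b/x)^c)^{-k}} on `x > 0`, strictly increasing with
#' limits 0 and 1. In a sensitivity distribution, `F(x)` is the fraction of
#' taxa affected at concentration `x`.
#'
#' @param params a [BurrIII-class] object (or named vector with `scaleB`,
#'   `shapeC`, `shapeK`).
#' @param x concentrations, mg kg^-1 (> 0).
#' @return CDF values in (0, 1).
#' @examples
#' burr3Cdf(BurrIII(10, 2, 0.5), 10)   # 2^-0.5
#' @export
burr3Cdf <- function(params, x) {
    p <- .burrCheck(params)
    if (any(x <= 0)) stop("Burr III is defined on x > 0")
    # (1 + exp(w))^(-k) with w = c*log(b/x), computed on the log scale
    w <- p[["c"]] * (log(p[["b"]]) - log(x))
    exp(-p[["k"]] * ifelse(w > 35, w, log1p(exp(w))))
}

#' Burr Type III quantile function
#'
#' Inverse of [burr3Cdf()]:
#' \deqn{Q(p) = b \, (p^{-1/k} - 1)^{-1/c}.}
#'
#' @inheritParams burr3Cdf
#' @param p probabilities in (0, 1).
#' @return Concentrations, mg kg^-1.
#' @export
burr3Quantile <- function(params, p) {
    pr <- .burrCheck(params)
    if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
    pr[["b"]] / (p^(-1 / pr[["k"]]) - 1)^(1 / pr[["c"]])
}

# Negative log-likelihood and gradient in theta = (log b, log c, log k).
# density: f(x) = k c u / (x (1+u)^(k+1)), u = (b/x)^c.
.burrNll <- function(theta, lx) {
    b <- theta[1]; cc <- exp(theta[2]); k <- exp(theta[3]) # b = log b here
    w <- cc * (b - lx)
    l1p <- ifelse(w > 35, w, log1p(exp(w)))
    -(length(lx) * (log(k) + log(cc)) + sum(w) - sum(lx) -
      (k + 1) * sum(l1p))
}

.burrNllGrad <- function(theta, lx) {
    b <- theta[1]; cc <- exp(theta[2]); k <- exp(theta[3])
    n <- length(lx)
    w <- cc * (b - lx)
    sig <- plogis(w)                     # u/(1+u)
    l1p <- ifelse(w > 35, w, log1p(exp(w)))
    dlb <- cc * (n - (k + 1) * sum(sig))            # d ll / d log b
    dlc <- n + sum(w) - (k + 1) * sum(sig * w)      # d ll / d log c
    dlk <- n - k * sum(l1p)                         # d ll / d log k
    -c(dlb, dlc, dlk)
}

#' Fit a Burr Type III sensitivity distribution by maximum likelihood
#'
#' Fits the three-parameter Burr III distribution to a set of positive EC20
#' values, the backbone of the OTU sensitivity distribution. Parameters are
#' optimized on the log scale (positivity structural) from moment-style
#' starting values, with perturbed restarts; the best converged optimum is
#' returned. At least 8 EC20 values are required: below that the heavy-tailed
#' three-parameter family is not identifiable and small-sample fallback
#' distributions (not implemented here) should be used instead.
#'
#' @param ec20 numeric vector of positive EC20 values (mg kg^-1), or a
#'   data.frame with an `ec20` column.
#' @return A [BurrIII-class] object carrying the log-likelihood and `n`.
#' @export
fitBurr3 <- function(ec20) {
    if (is.data.frame(ec20)) ec20 <- ec20$ec20
    x <- as.numeric(ec20)
    if (any(!is.finite(x)) || any(x <= 0))
        stop("EC20 values must be positive and finite")
    if (length(x) < 8)
        stop("at least 8 EC20 values are required to fit a Burr III ",
             "distribution; with fewer points use a small-sample method")
    lx <- log(x)
    if (sd(lx) == 0)
        stop("degenerate input: all EC20 values identical")
    # moment-style inits: with k = 1, the median is b and sd(log X) ~ pi/(c sqrt(3))
    c0 <- pi / (sd(lx) * sqrt(3))
    starts <- list(c(median(lx), log(c0), 0),
                   c(median(lx), log(c0 * 2), log(0.5)),
                   c(mean(lx), log(c0 / 2), log(2)))
    best <- NULL
    for (th0 in starts) {
        o <- tryCatch(nlminb(th0, .burrNll, gradient = .burrNllGrad, lx = lx,
                             control = list(iter.max = 500, eval.max = 1000)),
                      error = function(e) NULL)
        if (is.null(o) || !is.finite(o$objective)) next
        if (is.null(best) || o$objective < best$objective) best <- o
    }
    if (is.null(best))
        stop("Burr III fit failed to converge from all starting values")
    th <- best$par
    BurrIII(scaleB = exp(th[1]), shapeC = exp(th[2]), shapeK = exp(th[3]),
            logLik = -best$objective, n = length(x))
}

#' Hazardous concentration HCp
#'
#' The concentration affecting `p`% of taxa (protecting `100 - p`%): the
#' `p/100` quantile of the fitted sensitivity distribution.
#'
#' @inheritParams burr3Cdf
#' @param p protection percentage in (0, 100); conventionally 5, 10, 20
#'   and, to delimit the insensitive tail, 80.
#' @return Concentration, mg kg^-1.
#' @export
hazardousConcentration <- function(params, p) {
    stopifnot(all(p > 0 & p < 100))
    burr3Quantile(params, p / 100)
}

#' Bootstrap confidence intervals for hazardous concentrations
#'
#' Nonparametric bootstrap: EC20 values are resampled with replacement,
#' the Burr III distribution refitted, and each HCp recomputed; the 2.5th
#' and 97.5th percentiles of the bootstrap HCp distribution form the 95%
#' interval. Resamples whose fit fails are dropped and counted — a warning
#' escalates when more than 10% fail, an error above 50%.
#'
#' @inheritParams fitBurr3
#' @param protection vector of protection percentages (default 5, 10, 20, 80).
#' @param nBoot number of bootstrap resamples (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame with one row per protection level: `protection_percent`,
#'   `value`, `ci_low`, `ci_high`, `n_ec20`, `n_boot_ok`.
#' @export
bootstrapHc <- function(ec20, protection = c(5, 10, 20, 80), nBoot = 1000,
                        seed = 1L) {
    if (is.data.frame(ec20)) ec20 <- ec20$ec20
    x <- as.numeric(ec20)
    fit <- fitBurr3(x)
    point <- hazardousConcentration(fit, protection)
    if (nBoot < 2)
        warning("nBoot < 2 gives a degenerate bootstrap interval")
    idx <- withSeed(as.integer(seed),
        matrix(sample.int(length(x), length(x) * nBoot, replace = TRUE),
               nrow = nBoot))
    hcs <- matrix(NA_real_, nBoot, length(protection))
    for (i in seq_len(nBoot)) {
        bf <- tryCatch(suppressWarnings(fitBurr3(x[idx[i, ]])),
                       error = function(e) NULL)
        if (!is.null(bf)) hcs[i, ] <- hazardousConcentration(bf, protection)
    }
    ok <- rowSums(is.na(hcs)) == 0
    failRate <- mean(!ok)
    if (failRate > 0.5)
        stop(sprintf("bootstrap failed: %.0f%% of resamples did not converge",
                     100 * failRate))
    if (failRate > 0.1)
        warning(sprintf("%.0f%% of bootstrap resamples failed to converge",
                        100 * failRate))
    ci <- apply(hcs[ok, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.975), names = FALSE)
    data.frame(protection_percent = protection, value = unname(point),
               ci_low = ci[1, ], ci_high = ci[2, ],
               n_ec20 = length(x), n_boot_ok = sum(ok))
}

#' Compare two treatments' hazardous concentrations
#'
#' Two HCp estimates at the same protection level are called significantly
#' different when their 95% confidence intervals do not overlap (the rule
#' behind distinct superscript letters in an HC table). The comparison is
#' symmetric; an estimate is never significantly different from itself.
#'
#' @param a,b one-row data.frames (or lists) with `value`, `ci_low`,
#'   `ci_high` and `protection_percent` at the same protection level, e.g.
#'   rows of [bootstrapHc()] output.
#' @return `"significant"` or `"not_significant"`.
#' @examples
#' compareTreatments(
#'   list(protection_percent = 20, value = 5.9, ci_low = 4.4, ci_high = 8.1),
#'   list(protection_percent = 20, value = 1.4, ci_low = 1.2, ci_high = 1.7))
#' @export
compareTreatments <- function(a, b) {
    need <- c("ci_low", "ci_high")
    if (!all(need %in% names(a)) || !all(need %in% names(b)) ||
        anyNA(c(a$ci_low, a$ci_high, b$ci_low, b$ci_high)))
        stop("both estimates need 95% confidence intervals")
    if (!is.null(a$protection_percent) && !is.null(b$protection_percent) &&
        a$protection_percent != b$protection_percent)
        stop("estimates are at different protection levels")
    if (a$ci_low > b$ci_high || b$ci_low > a$ci_high) "significant"
    else "not_significant"
}

# Compact letter display from pairwise CI overlap: treatments sharing a
# letter are not significantly different. Greedy grouping over estimates
# sorted by value; adequate for the handful of arms in a dose study.
.cldLetters <- function(values, ciLow, ciHigh, labels) {
    ord <- order(values)
    groups <- list()
    for (i in ord) {
        placed <- FALSE
        for (g in seq_along(groups)) {
            overlapAll <- all(vapply(groups[[g]], function(j)
                ciLow[i] <= ciHigh[j] && ciLow[j] <= ciHigh[i], logical(1)))
            if (overlapAll) {
                groups[[g]] <- c(groups[[g]], i)
                placed <- TRUE
                break
            }
        }
        if (!placed) groups[[length(groups) + 1L]] <- i
    }
    lett <- character(length(values))
    for (g in seq_along(groups))
        for (i in groups[[g]])
            lett[i] <- paste0(lett[i], letters[g])
    stats::setNames(lett, labels)
}

#' Plot-ready OSD data
#'
#' Sorted EC20 values with empirical cumulative ranks (Hazen plotting
#' positions, `(i - 0.5)/n`) plus a sampled fitted Burr III curve, for
#' drawing an OTU sensitivity distribution.
#'
#' @inheritParams fitBurr3
#' @param fit a [BurrIII-class] fit of the same values (fitted on the fly
#'   when omitted).
#' @param nCurve number of fitted-curve sample points (default 200).
#' @return data.frame with columns `kind` (`"point"`/`"curve"`),
#'   `concentration`, `fraction_affected`.
#' @export
osdPlotData <- function(ec20, fit = NULL, nCurve = 200) {
    if (is.data.frame(ec20)) ec20 <- ec20$ec20
    x <- sort(as.numeric(ec20))
    if (is.null(fit)) fit <- fitBurr3(x)
    pts <- data.frame(kind = "point", concentration = x,
                      fraction_affected = (seq_along(x) - 0.5) / length(x))
    grid <- geomSeq(min(x) / 10, max(x) * 10, nCurve)
    crv <- data.frame(kind = "curve", concentration = grid,
                      fraction_affected = burr3Cdf(fit, grid))
    rbind(pts, crv)
}
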