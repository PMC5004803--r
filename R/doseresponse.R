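#' @importFrom stats qt qnorm uniroot optimize var coef
#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

# (dose/e)^b with the zero-dose limit taken for b != 0
.drPow <- function(dose, e, b) {
    u <- (dose / e)^b
    z <- dose == 0
    if (any(z)) u[z] <- if (b > 0) 0 else if (b < 0) Inf else 1
    u
}

.checkDrParams <- function(params, need) {
    if (!all(need %in% names(params)))
        stop("params must be named: ", paste(need, collapse = ", "))
    p <- params[need]
    if (any(!is.finite(p))) stop("invalid parameters: non-finite value")
    if (p[["e"]] <= 0) stop("invalid parameters: e must be > 0")
    p
}

#' Four-parameter log-logistic dose-response model
#'
#' Evaluates the sigmoidal model
#' \deqn{y = c + \frac{d - c}{1 + (x/e)^b}}
#' where `d` is the response in the control (upper asymptote), `c` the lower
#' asymptote, `e` the inflection dose (the EC50 of the `d - c` span) and `b`
#' the slope around `e`. A positive `b` describes inhibition with increasing
#' dose.
#'
#' @param params named numeric vector with elements `b`, `c`, `d`, `e`
#'   (`e > 0`).
#' @param dose concentrations, mg kg^-1 (>= 0).
#' @return Predicted responses, same length as `dose`.
#' @examples
#' evalLogLogistic(c(b = 2, c = 0, d = 100, e = 10), c(0, 10, 1e6))
#' @export
evalLogLogistic <- function(params, dose) {
    p <- .checkDrParams(params, c("b", "c", "d", "e"))
    stopifnot(all(dose >= 0))
    u <- .drPow(dose, p[["e"]], p[["b"]])
    unname(p[["c"]] + (p[["d"]] - p[["c"]]) / (1 + u))
}

#' Five-parameter Brain-Cousens hormesis model
#'
#' Evaluates
#' \deqn{y = c + \frac{d - c + f x}{1 + (x/e)^b}}
#' which extends the log-logistic model with a linear low-dose stimulation
#' term `f` (initial rate of increase). With `f = 0` it is pointwise
#' identical to [evalLogLogistic()]; under hormesis `b` and `e` lose their
#' interpretation as slope and inflection point.
#'
#' @param params named numeric vector `b`, `c`, `d`, `e`, `f` (`e > 0`).
#' @inheritParams evalLogLogistic
#' @return Predicted responses.
#' @examples
#' evalHormesis(c(b = 2, c = 0, d = 100, e = 10, f = 5), 10)
#' @export
evalHormesis <- function(params, dose) {
    p <- .checkDrParams(params, c("b", "c", "d", "e", "f"))
    stopifnot(all(dose >= 0))
    u <- .drPow(dose, p[["e"]], p[["b"]])
    num <- p[["d"]] - p[["c"]] + p[["f"]] * dose
    y <- p[["c"]] + num / (1 + u)
    # b < 0 sends u -> Inf at dose 0; the ratio limit is still d - c
    y[dose == 0 & !is.finite(u)] <- p[["d"]]
    unname(y)
}

.drEval <- function(params, model, dose) {
    if (model == "hormesis5") evalHormesis(params, dose)
    else evalLogLogistic(params, dose)
}

# Analytic Jacobian of model predictions wrt natural parameters, rows =
# observations. Used for covariance s^2 (J'J)^-1 and the delta method.
.drJacobian <- function(params, model, dose) {
    b <- params[["b"]]; cc <- params[["c"]]; d <- params[["d"]]
    e <- params[["e"]]
    f <- if (model == "hormesis5") params[["f"]] else 0
    u <- .drPow(dose, e, b)
    D <- 1 + u
    N <- d - cc + f * dose
    lr <- ifelse(dose > 0, log(dose / e), 0)   # u * log term -> 0 at dose 0
    J <- cbind(
        b = -N / D^2 * u * lr,
        c = 1 - 1 / D,
        d = 1 / D,
        e = N * u * b / (e * D^2))
    if (model == "hormesis5") J <- cbind(J, f = dose / D)
    J
}

.drFailedFit <- function(model, doses, responses, n) {
    pnames <- if (model == "hormesis5") c("b", "c", "d", "e", "f")
              else c("b", "c", "d", "e")
    DoseResponseFit(model,
        params = stats::setNames(rep(NA_real_, length(pnames)), pnames),
        covariance = NULL, rSquared = NA_real_,
        residualDf = n - length(pnames), accepted = FALSE,
        rejectionReasons = "fit_failed", hormesisSignificant = NA,
        doses = doses, responses = responses, converged = FALSE)
}

#' Fit a dose-response model by least squares
#'
#' Levenberg-Marquardt least squares with `e` fitted on the log scale so that
#' positivity is structural. Starting values follow a robust recipe suitable
#' for automated fitting of thousands of OTU series: `d` from the mean
#' response at the two lowest doses, `c` from `min(0, min(response))`, `e`
#' from the geometric mean of the positive doses, `b = 1`, `f = 0`. On
#' convergence failure three perturbed restarts are tried; if all fail the
#' returned fit carries rejection reason `fit_failed` rather than an error.
#'
#' The covariance matrix is \eqn{s^2 (J'J)^{-1}} with `J` the analytic
#' Jacobian in natural parameters at the optimum; a singular Jacobian leaves
#' it `NULL`. `rSquared` is \eqn{1 - SS_{res}/SS_{tot}} about the response
#' mean.
#'
#' @param doses,responses numeric vectors of equal length `n >= p + 1`
#'   (p = 4 or 5 parameters); doses in mg kg^-1, >= 0.
#' @param model `"loglogistic4"` or `"hormesis5"`.
#' @param init optional named starting vector overriding the default recipe.
#' @return A [DoseResponseFit-class]; `accepted` is `FALSE` until
#'   [applyAcceptanceCriteria()] is applied.
#' @examples
#' x <- geomSeq(0.1, 500, 14)
#' y <- evalLogLogistic(c(b = 1.5, c = 5, d = 120, e = 8), x)
#' fitParams(fitDoseResponse(x, y))
#' @export
fitDoseResponse <- function(doses, responses,
                            model = c("loglogistic4", "hormesis5"),
                            init = NULL) {
    model <- match.arg(model)
    np <- if (model == "hormesis5") 5L else 4L
    n <- length(doses)
    if (length(responses) != n) stop("doses and responses differ in length")
    if (n < np + 1L)
        stop(sprintf("need at least %d observations for %s", np + 1L, model))
    if (any(!is.finite(doses)) || any(doses < 0) || any(!is.finite(responses)))
        stop("doses must be finite >= 0 and responses finite")
    if (var(responses) == 0)   # flat series: nothing to fit
        return(.drFailedFit(model, doses, responses, n))

    ord <- order(doses)
    d0 <- mean(responses[ord][seq_len(min(2L, n))])
    c0 <- min(0, min(responses))
    e0 <- geomMean(doses)
    start <- c(b = 1, c = c0, d = d0, loge = log(e0))
    if (model == "hormesis5") start <- c(start, f = 0)
    if (!is.null(init)) {
        ini <- init
        if ("e" %in% names(ini)) {
            start[names(ini)[names(ini) != "e"]] <-
                ini[names(ini) != "e"]
            start["loge"] <- log(ini[["e"]])
        } else start[names(ini)] <- ini
    }

    residFn <- function(th) {
        p <- c(b = th[["b"]], c = th[["c"]], d = th[["d"]],
               e = exp(th[["loge"]]))
        if (model == "hormesis5") p <- c(p, f = th[["f"]])
        responses - .drEval(p, model, doses)
    }
    ctrl <- nls.lm.control(ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
                           maxfev = 10000, maxiter = 1024)
    tryFit <- function(th0) {
        tryCatch({
            fit <- nls.lm(par = th0, fn = residFn, control = ctrl)
            if (fit$info %in% c(0L, 5L, 9L)) NULL else fit
        }, error = function(e) NULL, warning = function(w) NULL)
    }
    fit <- tryFit(start)
    if (is.null(fit)) {                      # multi-start on failure
        for (k in 1:3) {
            pert <- start
            pert["b"] <- start[["b"]] * c(0.5, 2, 4)[k]
            pert["loge"] <- start[["loge"]] + c(-1, 1, 0)[k]
            fit <- tryFit(pert)
            if (!is.null(fit)) break
        }
    }
    if (is.null(fit)) return(.drFailedFit(model, doses, responses, n))

    th <- coef(fit)
    pars <- c(b = th[["b"]], c = th[["c"]], d = th[["d"]],
              e = exp(th[["loge"]]))
    if (model == "hormesis5") pars <- c(pars, f = th[["f"]])
    res <- responses - .drEval(pars, model, doses)
    ssres <- sum(res^2)
    sstot <- sum((responses - mean(responses))^2)
    r2 <- 1 - ssres / sstot
    dfres <- n - np
    J <- .drJacobian(pars, model, doses)
    covm <- tryCatch({
        s2 <- ssres / dfres
        jtj <- crossprod(J)
        cm <- s2 * solve(jtj)
        if (any(!is.finite(cm))) NULL else cm
    }, error = function(e) NULL)
    if (!is.null(covm)) dimnames(covm) <- list(names(pars), names(pars))
    DoseResponseFit(model, params = pars, covariance = covm,
                    rSquared = r2, residualDf = dfres, accepted = FALSE,
                    rejectionReasons = character(),
                    hormesisSignificant = NA,
                    doses = doses, responses = responses, converged = TRUE)
}

#' Apply the fit-acceptance criteria
#'
#' A fit is accepted only when all three criteria hold: (1) `b > 0`,
#' denoting a negative slope and hence inhibition; (2) `e` below the maximum
#' spiking concentration; and (3) `R^2 > r2Min` (strict inequality, default
#' 0.65). A failed optimization carries the single reason `fit_failed`.
#' Criterion (2) is applied to hormesis fits as well, even though `e` loses
#' its interpretation as the inflection point there.
#'
#' @param fit a [DoseResponseFit-class].
#' @param maxDose maximum spiking concentration of the design (defaults to
#'   the fitted series' maximum dose).
#' @param r2Min acceptance threshold for `R^2` (default 0.65).
#' @return The fit with `accepted` and `rejectionReasons` filled in.
#' @examples
#' f <- DoseResponseFit("loglogistic4",
#'     c(b = -2, c = 0, d = 100, e = 10), rSquared = 0.9)
#' rejectionReasons(applyAcceptanceCriteria(f, maxDose = 404))
#' @export
applyAcceptanceCriteria <- function(fit, maxDose = max(fit@doses),
                                    r2Min = 0.65) {
    stopifnot(is(fit, "DoseResponseFit"))
    if (!fit@converged) {
        fit@rejectionReasons <- "fit_failed"
        fit@accepted <- FALSE
        return(fit)
    }
    reasons <- character()
    if (!is.finite(fit@params[["b"]]) || fit@params[["b"]] <= 0)
        reasons <- c(reasons, "slope_nonpositive")
    if (!is.finite(fit@params[["e"]]) || fit@params[["e"]] >= maxDose)
        reasons <- c(reasons, "e_exceeds_max_dose")
    if (!is.finite(fit@rSquared) || fit@rSquared <= r2Min)
        reasons <- c(reasons, "r2_below_threshold")
    fit@rejectionReasons <- reasons
    fit@accepted <- length(reasons) == 0L
    fit
}

#' Wald test for significant hormesis
#'
#' Hormesis is deemed statistically significant when the `(1 - alpha)`
#' t-based confidence interval for the stimulation parameter `f`,
#' `f +/- t(df, 1 - alpha/2) SE(f)`, does not intercept zero.
#'
#' @param fit a hormesis-model [DoseResponseFit-class] with covariance.
#' @param alpha significance level (default 0.05).
#' @return `TRUE` iff the interval excludes zero. When the covariance is
#'   unavailable the test returns `FALSE` with a warning.
#' @export
testHormesisSignificance <- function(fit, alpha = 0.05) {
    stopifnot(is(fit, "DoseResponseFit"))
    if (fit@model != "hormesis5")
        stop("hormesis significance is defined for hormesis5 fits only")
    if (is.null(fit@covariance) || !"f" %in% rownames(fit@covariance)) {
        warning("covariance unavailable; hormesis significance set to FALSE")
        return(FALSE)
    }
    f <- fit@params[["f"]]
    # negligible stimulation relative to the curve span is never significant,
    # whatever a near-zero-residual fit says about SE(f)
    span <- abs(fit@params[["d"]] - fit@params[["c"]])
    if (!is.finite(f) ||
        abs(f) * fit@params[["e"]] < 1e-8 * max(span, 1e-12))
        return(FALSE)
    se <- sqrt(fit@covariance["f", "f"])
    if (!is.finite(se) || se == 0) return(f != 0)
    tq <- qt(1 - alpha / 2, df = fit@residualDf)
    (f - tq * se) > 0 || (f + tq * se) < 0
}

#' Conservative model selection between the two fitted models
#'
#' When both the log-logistic and the hormesis fits pass the acceptance
#' criteria the hormesis model is selected, which yields conservative
#' (lower) EC20 estimates. If exactly one passes, that one is used; when
#' neither passes, `NULL` is returned and the OTU is excluded from
#' downstream sensitivity-distribution calculations. Selection does not
#' require `f` to be significant; significance is metadata.
#'
#' @param fitLL accepted-or-not `loglogistic4` fit.
#' @param fitH accepted-or-not `hormesis5` fit.
#' @return The selected [DoseResponseFit-class], or `NULL` (excluded).
#' @export
selectModel <- function(fitLL, fitH) {
    stopifnot(fitLL@model == "loglogistic4", fitH@model == "hormesis5")
    if (fitH@accepted) return(fitH)
    if (fitLL@accepted) return(fitLL)
    NULL
}

# ECx as a pure function of a parameter vector (used by the delta method).
.ecxFromParams <- function(params, model, p, mode, maxDose) {
    b <- params[["b"]]; cc <- params[["c"]]; d <- params[["d"]]
    e <- params[["e"]]
    if (model == "loglogistic4") {
        if (mode == "span") return(e * (p / (100 - p))^(1 / b))
        target <- (1 - p / 100) * d
        if (target <= cc)
            stop(sprintf(
                "no crossing: %g%% reduction of the upper asymptote (%.4g) lies below the lower asymptote (%.4g)",
                p, d, cc))
        u <- (d - cc) / (target - cc) - 1
        if (u <= 0) stop("no crossing: target not attained")
        return(e * u^(1 / b))
    }
    # hormesis: locate the descending-limb crossing numerically
    target <- if (mode == "span") cc + (1 - p / 100) * (d - cc)
              else (1 - p / 100) * d
    hi <- maxDose * 10
    g <- function(x) evalHormesis(params, x) - target
    xmax <- optimize(function(x) evalHormesis(params, x),
                     interval = c(0, hi), maximum = TRUE,
                     tol = hi * 1e-10)$maximum
    lo <- if (g(xmax) > 0) xmax else 0
    if (g(hi) > 0 || g(lo) < 0)
        stop(sprintf("no crossing: %g%% reduction not attained within (0, %g]",
                     p, hi))
    uniroot(g, interval = c(lo, hi),
            tol = max(1e-14, hi * 1e-12))$root
}

#' Effective concentration for a p% response reduction
#'
#' For the log-logistic model the default `upper_asymptote` mode solves
#' \eqn{c + (d-c)/(1+(x/e)^b) = (1 - p/100) d} in closed form: the ECx is
#' referenced to the upper asymptote `d`, so EC20 is the dose reducing the
#' fitted control-level response by 20%. The `span` mode uses the classical
#' \eqn{EC_p = e (p/(100-p))^{1/b}}, referenced to the `d - c` span. For the
#' hormesis model the crossing of the target response on the descending limb
#' is found numerically (bracketed between the curve maximum and ten times
#' the maximum dose).
#'
#' Estimates below the control background concentration are retained but
#' flagged `below_background`: with upper-asymptote referencing, immediately
#' affected OTUs can yield ECx values below any tested dose, a numerical
#' artefact of highly sensitive responders.
#'
#' @param fit an accepted [DoseResponseFit-class].
#' @param p percent reduction, in (0, 100). Default 20.
#' @param mode `"upper_asymptote"` (default) or `"span"`.
#' @param controlDose background concentration used for the
#'   `below_background` flag (default 0.1 mg kg^-1).
#' @param maxDose maximum spiking concentration (hormesis root bracket);
#'   defaults to the fitted series' maximum dose.
#' @return One-row data.frame: `level`, `value` (mg kg^-1), `ci_low`,
#'   `ci_high` (NA here; see [ecxConfidenceInterval()]), `mode`,
#'   `below_background`.
#' @examples
#' f <- DoseResponseFit("loglogistic4", c(b = 1, c = 0, d = 100, e = 10))
#' computeEcx(f, p = 20, mode = "span")$value   # 2.5
#' @export
computeEcx <- function(fit, p = 20, mode = c("upper_asymptote", "span"),
                       controlDose = 0.1, maxDose = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(fit, "DoseResponseFit"), p > 0, p < 100)
    if (!fit@converged) stop("cannot compute ECx from a failed fit")
    if (is.null(maxDose))
        maxDose <- if (length(fit@doses)) max(fit@doses) else
            fit@params[["e"]] * 100
    value <- .ecxFromParams(fit@params, fit@model, p, mode, maxDose)
    data.frame(level = p, value = value, ci_low = NA_real_,
               ci_high = NA_real_, mode = mode,
               below_background = value < controlDose)
}

#' Delta-method 95% confidence interval for an ECx
#'
#' Propagates the parameter covariance through the gradient of the ECx with
#' respect to the parameters: analytic for the log-logistic span mode,
#' central-difference otherwise. The lower bound is floored at 0.
#'
#' @inheritParams computeEcx
#' @return As [computeEcx()] with `ci_low`/`ci_high` filled in; when the
#'   covariance is unavailable the point estimate is returned with a
#'   warning and NA bounds.
#' @export
ecxConfidenceInterval <- function(fit, p = 20,
                                  mode = c("upper_asymptote", "span"),
                                  controlDose = 0.1, maxDose = NULL) {
    mode <- match.arg(mode)
    est <- computeEcx(fit, p, mode, controlDose, maxDose)
    if (is.null(fit@covariance)) {
        warning("covariance unavailable; ECx returned without CI")
        return(est)
    }
    if (is.null(maxDose))
        maxDose <- if (length(fit@doses)) max(fit@doses) else
            fit@params[["e"]] * 100
    pars <- fit@params
    if (fit@model == "loglogistic4" && mode == "span") {
        r <- p / (100 - p)
        b <- pars[["b"]]; e <- pars[["e"]]
        g <- c(b = -e * r^(1 / b) * log(r) / b^2, c = 0, d = 0,
               e = r^(1 / b))
    } else {
        g <- vapply(seq_along(pars), function(i) {
            h <- max(abs(pars[[i]]), 1e-4) * 1e-6
            up <- pars; up[[i]] <- up[[i]] + h
            dn <- pars; dn[[i]] <- dn[[i]] - h
            (.ecxFromParams(up, fit@model, p, mode, maxDose) -
             .ecxFromParams(dn, fit@model, p, mode, maxDose)) / (2 * h)
        }, numeric(1))
        names(g) <- names(pars)
    }
    v <- drop(t(g[colnames(fit@covariance)]) %*% fit@covariance %*%
              g[colnames(fit@covariance)])
    half <- qnorm(0.975) * sqrt(max(v, 0))
    est$ci_low <- max(0, est$value - half)
    est$ci_high <- est$value + half
    est
}
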