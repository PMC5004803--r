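#' Net nitrate production over the incubation
#'
#' Total NO3- production over 28 d, computed per sample as the concentration
#' at t = 28 d minus that at t = 0. The subtraction corrects both for the
#' NO3- already present in the soil and for NO3- added with a soluble salt
#' (e.g. AgNO3). Negative values (net consumption) are retained with a
#' warning.
#'
#' @param no3T0,no3T28 nitrate concentrations, mg NO3- kg^-1, at lucerne
#'   addition and after 28 d (vectorized; both must be present and >= 0).
#' @return Net production, mg NO3- kg^-1.
#' @examples
#' netNitrate(8.2, 153.7)   # 145.5
#' @export
netNitrate <- function(no3T0, no3T28) {
    if (length(no3T0) != length(no3T28))
        stop("t0 and t28 measurements differ in length")
    if (anyNA(no3T0) || anyNA(no3T28))
        stop("missing timepoint in nitrate measurements")
    stopifnot(all(no3T0 >= 0), all(no3T28 >= 0))
    out <- no3T28 - no3T0
    if (any(out < 0))
        warning(sum(out < 0), " sample(s) show net nitrate consumption ",
                "(negative production); values retained")
    out
}

#' Express endpoint values as a percentage of the control
#'
#' @param values per-sample endpoint values (e.g. net nitrate production).
#' @param controlMean mean endpoint in the control samples (> 0).
#' @return `100 * values / controlMean`; control samples average 100 by
#'   construction. Renormalizing an already-normalized series whose control
#'   mean is 100 changes nothing.
#' @export
percentOfControl <- function(values, controlMean) {
    if (!is.finite(controlMean) || controlMean <= 0)
        stop("control mean must be positive")
    100 * values / controlMean
}

.fitEndpointSeries <- function(doses, responses, maxDose, r2Min,
                               requireHormesisSignificance = TRUE) {
    fitLL <- applyAcceptanceCriteria(
        fitDoseResponse(doses, responses, "loglogistic4"),
        maxDose = maxDose, r2Min = r2Min)
    fitH <- applyAcceptanceCriteria(
        fitDoseResponse(doses, responses, "hormesis5"),
        maxDose = maxDose, r2Min = r2Min)
    hSig <- if (fitH@converged)
        tryCatch(suppressWarnings(testHormesisSignificance(fitH)),
                 error = function(e) FALSE) else FALSE
    fitH@hormesisSignificant <- hSig
    if (requireHormesisSignificance) {
        if (fitH@accepted && hSig) fitH
        else if (fitLL@accepted) fitLL
        else if (fitH@accepted) fitH
        else NULL
    } else selectModel(fitLL, fitH)
}

#' Functional-endpoint ECx analysis
#'
#' Builds per-treatment dose-response tables for a functional endpoint such
#' as net nitrate production (or any pre-computed response like amoA gene
#' copies). Per treatment arm: the endpoint is normalized to the shared
#' control mean, both the sigmoidal and the hormesis model are fitted, and
#' the hormesis model is used only when its stimulation parameter is
#' significant (unlike the per-OTU branch, where hormesis is preferred
#' whenever it fits). EC values at the requested levels are interpolated
#' with delta-method 95% confidence intervals, and treatments are assigned
#' compact letters per EC level by CI overlap (shared letter = no
#' significant difference).
#'
#' @param measurements data.frame with columns `sample_id`, `treatment`,
#'   `dose`, and either `no3_t0` + `no3_t28` or a pre-computed `response`.
#'   Control samples carry `treatment == controlLabel` and are shared across
#'   arms.
#' @param ecLevels percent reductions to report (default 10, 20, 50).
#' @param mode ECx referencing, `"upper_asymptote"` (default) or `"span"`.
#' @param r2Min acceptance threshold for R^2 (default 0.65).
#' @param controlLabel label of control samples (default `"control"`).
#' @return data.frame: `treatment`, `model`, `r_squared`,
#'   `hormesis_significant`, then one row per EC level with `ec_level`,
#'   `estimate`, `ci_low`, `ci_high`, `letter`. Treatments without an
#'   accepted fit appear with NA estimates.
#' @export
runNitrificationAnalysis <- function(measurements,
                                     ecLevels = c(10, 20, 50),
                                     mode = c("upper_asymptote", "span"),
                                     r2Min = 0.65,
                                     controlLabel = "control") {
    mode <- match.arg(mode)
    m <- as.data.frame(measurements)
    if (!"response" %in% names(m)) {
        if (!all(c("no3_t0", "no3_t28") %in% names(m)))
            stop("need no3_t0/no3_t28 columns or a response column")
        m$response <- netNitrate(m$no3_t0, m$no3_t28)
    }
    ctrl <- m$treatment == controlLabel
    if (!any(ctrl)) stop("no control samples (treatment == '",
                         controlLabel, "')")
    controlMean <- mean(m$response[ctrl])
    m$pct <- percentOfControl(m$response, controlMean)
    arms <- setdiff(unique(m$treatment), controlLabel)
    rows <- list()
    for (a in arms) {
        sel <- ctrl | m$treatment == a
        doses <- m$dose[sel]
        if (length(unique(doses)) < 6) {
            warning("treatment ", a, " has fewer than 6 dose levels; skipped")
            next
        }
        fit <- .fitEndpointSeries(doses, m$pct[sel], maxDose = max(doses),
                                  r2Min = r2Min)
        if (is.null(fit)) {
            rows[[a]] <- data.frame(treatment = a, model = NA_character_,
                r_squared = NA_real_, hormesis_significant = NA,
                ec_level = ecLevels, estimate = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_)
            next
        }
        ecs <- lapply(ecLevels, function(p)
            tryCatch(ecxConfidenceInterval(fit, p, mode = mode),
                     error = function(e) data.frame(level = p,
                         value = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, mode = mode,
                         below_background = NA)))
        ecs <- do.call(rbind, ecs)
        rows[[a]] <- data.frame(treatment = a, model = fit@model,
            r_squared = fit@rSquared,
            hormesis_significant = isTRUE(fit@hormesisSignificant),
            ec_level = ecs$level, estimate = ecs$value,
            ci_low = ecs$ci_low, ci_high = ecs$ci_high)
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out) || !nrow(out)) return(out)
    out$letter <- NA_character_
    for (lev in unique(out$ec_level)) {
        i <- which(out$ec_level == lev & !is.na(out$estimate) &
                   !is.na(out$ci_low))
        if (length(i) >= 2)
            out$letter[i] <- .cldLetters(out$estimate[i], out$ci_low[i],
                                         out$ci_high[i], out$treatment[i])
        else if (length(i) == 1) out$letter[i] <- "a"
    }
    out
}
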