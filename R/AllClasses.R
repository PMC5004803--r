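#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData rowData<- colData colData<-
NULL

.OTU_STAGES <- c("raw", "filtered", "rarefied", "absolute")

#' Container for an OTU abundance table with dose design
#'
#' `OtuExperiment` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `stage` marker that enforces the preprocessing order
#' raw -> filtered -> rarefied -> absolute. OTUs are rows, samples are
#' columns. `colData` carries the dose design (`treatment`, `dose`, optionally
#' `qpcr_total`); `rowData` may carry `taxonomy` and `copy_number`.
#'
#' Integer read counts are required up to the `rarefied` stage; the
#' `absolute` stage holds continuous genome-equivalent abundances after 16S
#' copy-number correction.
#'
#' @slot stage character scalar, one of `"raw"`, `"filtered"`, `"rarefied"`,
#'   `"absolute"`.
#' @export
setClass("OtuExperiment",
    contains = "SummarizedExperiment",
    slots = c(stage = "character"))

setValidity("OtuExperiment", function(object) {
    msg <- character()
    if (length(object@stage) != 1L || !object@stage %in% .OTU_STAGES)
        msg <- c(msg, sprintf("stage must be one of %s",
                              paste(.OTU_STAGES, collapse = ", ")))
    m <- assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    if (object@stage %in% c("raw", "filtered", "rarefied") &&
        any(abs(m - round(m)) > 1e-8))
        msg <- c(msg, "read-count stages must be integer-valued")
    if (object@stage == "rarefied" && ncol(m) > 1L &&
        length(unique(round(colSums(m)))) != 1L)
        msg <- c(msg, "rarefied stage requires identical column sums")
    cd <- colData(object)
    if (!all(c("treatment", "dose") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'treatment' and 'dose'")
    else if (any(!is.finite(cd$dose)) || any(cd$dose < 0))
        msg <- c(msg, "doses must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts numeric matrix, OTUs x samples, with dimnames.
#' @param design data.frame with columns `sample_id`, `treatment`, `dose`
#'   (mg Ag kg^-1 soil). Row order is matched to `colnames(counts)`.
#' @param taxonomy optional named character vector (OTU -> lineage string).
#' @param copyNumbers optional named numeric vector of 16S rRNA gene copies
#'   per genome (values >= 1).
#' @param qpcrTotals optional named numeric vector of total 16S copies per
#'   sample from qPCR.
#' @param stage preprocessing stage of `counts` (default `"raw"`).
#' @return An [OtuExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(12, 20), 3, 4,
#'     dimnames = list(paste0("OTU", 1:3), paste0("S", 1:4)))
#' des <- data.frame(sample_id = paste0("S", 1:4),
#'     treatment = c("control", "Ag+", "Ag+", "Ag+"),
#'     dose = c(0.1, 1, 10, 100))
#' OtuExperiment(cnt, des)
#' @export
OtuExperiment <- function(counts, design, taxonomy = NULL, copyNumbers = NULL,
                          qpcrTotals = NULL, stage = "raw") {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have OTU rownames and sample colnames")
    if (!all(c("sample_id", "treatment", "dose") %in% colnames(design)))
        stop("design needs columns sample_id, treatment, dose")
    idx <- match(colnames(counts), design$sample_id)
    if (anyNA(idx))
        stop("samples missing from design: ",
             paste(colnames(counts)[is.na(idx)], collapse = ", "))
    cd <- DataFrame(treatment = as.character(design$treatment[idx]),
                    dose = as.numeric(design$dose[idx]),
                    row.names = colnames(counts))
    if (!is.null(qpcrTotals)) {
        if (any(!is.finite(qpcrTotals)) || any(qpcrTotals <= 0))
            stop("qPCR totals must be positive and finite")
        cd$qpcr_total <- unname(qpcrTotals[colnames(counts)])
    }
    rd <- DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy))
        rd$taxonomy <- unname(taxonomy[rownames(counts)])
    if (!is.null(copyNumbers)) {
        if (any(copyNumbers < 1, na.rm = TRUE))
            stop("16S copy numbers must be >= 1")
        rd$copy_number <- unname(copyNumbers[rownames(counts)])
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rd, colData = cd)
    new("OtuExperiment", se, stage = stage)
}

setMethod("show", "OtuExperiment", function(object) {
    callNextMethod()
    cat("stage:", object@stage, "\n")
})

#' Dose-response fit result
#'
#' Holds the least-squares fit of a four-parameter log-logistic
#' (`loglogistic4`) or five-parameter Brain-Cousens hormesis (`hormesis5`)
#' model to one dose series, together with fit diagnostics and the
#' acceptance state set by [applyAcceptanceCriteria()].
#'
#' @slot model `"loglogistic4"` or `"hormesis5"`.
#' @slot params named numeric vector (b, c, d, e and, for hormesis, f).
#' @slot covariance parameter covariance matrix `s^2 (J'J)^-1`, or `NULL`
#'   when the Jacobian was singular.
#' @slot rSquared coefficient of determination, `1 - SSres/SStot`.
#' @slot residualDf residual degrees of freedom `n - p`.
#' @slot accepted logical; `TRUE` iff `rejectionReasons` is empty.
#' @slot rejectionReasons subset of `slope_nonpositive`,
#'   `e_exceeds_max_dose`, `r2_below_threshold`, `fit_failed`.
#' @slot hormesisSignificant logical (`NA` until tested; hormesis only).
#' @slot doses,responses the fitted data.
#' @slot converged logical; `FALSE` when the optimizer failed.
#' @export
setClass("DoseResponseFit", slots = c(
    model = "character",
    params = "numeric",
    covariance = "ANY",
    rSquared = "numeric",
    residualDf = "numeric",
    accepted = "logical",
    rejectionReasons = "character",
    hormesisSignificant = "logical",
    doses = "numeric",
    responses = "numeric",
    converged = "logical"))

setValidity("DoseResponseFit", function(object) {
    msg <- character()
    if (!object@model %in% c("loglogistic4", "hormesis5"))
        msg <- c(msg, "model must be loglogistic4 or hormesis5")
    ok <- c("slope_nonpositive", "e_exceeds_max_dose", "r2_below_threshold",
            "fit_failed")
    if (!all(object@rejectionReasons %in% ok))
        msg <- c(msg, "unknown rejection reason")
    if (object@accepted && length(object@rejectionReasons))
        msg <- c(msg, "accepted fit cannot carry rejection reasons")
    if (length(object@rSquared) && !is.na(object@rSquared) &&
        object@rSquared > 1 + 1e-12)
        msg <- c(msg, "r_squared cannot exceed 1")
    if (length(msg)) msg else TRUE
})

#' Construct a DoseResponseFit by hand
#'
#' Mostly useful for testing acceptance rules and ECx arithmetic on known
#' parameter vectors; fitted objects normally come from [fitDoseResponse()].
#'
#' @param model `"loglogistic4"` or `"hormesis5"`.
#' @param params named numeric vector with elements b, c, d, e (and f for
#'   the hormesis model).
#' @param covariance optional covariance matrix matching `params`.
#' @param rSquared,residualDf fit diagnostics.
#' @param accepted,rejectionReasons acceptance state.
#' @param hormesisSignificant logical flag (NA until tested).
#' @param doses,responses the underlying dose series, if available.
#' @param converged did the optimizer converge.
#' @return A [DoseResponseFit-class] object.
#' @export
DoseResponseFit <- function(model, params, covariance = NULL,
                            rSquared = NA_real_, residualDf = NA_real_,
                            accepted = FALSE,
                            rejectionReasons = character(),
                            hormesisSignificant = NA,
                            doses = numeric(), responses = numeric(),
                            converged = TRUE) {
    need <- if (model == "hormesis5") c("b", "c", "d", "e", "f")
            else c("b", "c", "d", "e")
    if (!all(need %in% names(params)))
        stop("params must be named: ", paste(need, collapse = ", "))
    new("DoseResponseFit", model = model, params = params[need],
        covariance = covariance, rSquared = rSquared,
        residualDf = residualDf, accepted = accepted,
        rejectionReasons = rejectionReasons,
        hormesisSignificant = hormesisSignificant,
        doses = doses, responses = responses, converged = converged)
}

setMethod("show", "DoseResponseFit", function(object) {
    cat("DoseResponseFit:", object@model, "\n")
    print(round(object@params, 5))
    cat(sprintf("R2 = %.4f | residual df = %d | %s\n",
                object@rSquared, as.integer(object@residualDf),
                if (object@accepted) "ACCEPTED"
                else paste("rejected:",
                           paste(object@rejectionReasons, collapse = ","))))
})

#' Burr Type III distribution parameters
#'
#' Parameterization fixed throughout the package (Burrlioz convention):
#' \deqn{F(x) = (1 + (b/x)^c)^{-k}, \quad x > 0}
#' with scale `b` (mg kg^-1) and shapes `c`, `k`, all strictly positive.
#' Parameterizations of the Burr III family vary across the literature;
#' every function in this package uses this one.
#'
#' @slot scaleB,shapeC,shapeK distribution parameters (all > 0).
#' @slot logLik log-likelihood at the fitted optimum (`NA` for hand-built
#'   parameter sets).
#' @slot n number of EC20 observations behind a fit (`NA` otherwise).
#' @export
setClass("BurrIII", slots = c(
    scaleB = "numeric", shapeC = "numeric", shapeK = "numeric",
    logLik = "numeric", n = "numeric"))

setValidity("BurrIII", function(object) {
    p <- c(object@scaleB, object@shapeC, object@shapeK)
    if (length(p) != 3L || any(!is.finite(p)) || any(p <= 0))
        "scaleB, shapeC, shapeK must all be finite and > 0"
    else TRUE
})

#' @param scaleB,shapeC,shapeK distribution parameters (all > 0).
#' @param logLik,n optional fit metadata.
#' @return A [BurrIII-class] object.
#' @rdname BurrIII-class
#' @examples
#' BurrIII(scaleB = 10, shapeC = 2, shapeK = 0.5)
#' @export
BurrIII <- function(scaleB, shapeC, shapeK, logLik = NA_real_, n = NA_real_) {
    new("BurrIII", scaleB = scaleB, shapeC = shapeC, shapeK = shapeK,
        logLik = logLik, n = n)
}

setMethod("show", "BurrIII", function(object) {
    cat(sprintf("Burr III  F(x) = (1 + (b/x)^c)^(-k)\n"))
    cat(sprintf("  b = %.5g, c = %.5g, k = %.5g", object@scaleB,
                object@shapeC, object@shapeK))
    if (!is.na(object@logLik))
        cat(sprintf("  (logLik %.3f, n = %d)", object@logLik,
                    as.integer(object@n)))
    cat("\n")
})
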