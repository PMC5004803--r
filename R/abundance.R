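#' Remove singleton and doubleton OTUs
#'
#' Drops every OTU whose summed read count across all samples is at most
#' `maxTotal` (default 2, i.e. singletons and doubletons), the conventional
#' guard against spurious OTUs from sequencing error.
#'
#' @param x an [OtuExperiment-class] at stage `"raw"`.
#' @param maxTotal largest total count that is still removed (default 2).
#' @return The filtered [OtuExperiment-class] at stage `"filtered"`; the
#'   number of removed OTUs is reported via `message()` and stored in
#'   `metadata(x)$n_low_count_removed`.
#' @export
filterLowCountOtus <- function(x, maxTotal = 2) {
    stopifnot(is(x, "OtuExperiment"))
    if (otuStage(x) != "raw")
        stop("filterLowCountOtus expects a 'raw' table, got '",
             otuStage(x), "'")
    tot <- rowSums(otuCounts(x))
    keep <- tot > maxTotal
    out <- x[keep, ]
    out@stage <- "filtered"
    metadata(out)$n_low_count_removed <- sum(!keep)
    message(sum(!keep), " low-count OTUs removed (total count <= ",
            maxTotal, "); ", sum(keep), " retained")
    if (!any(keep)) warning("all OTUs removed by the low-count filter")
    validObject(out)
    out
}

# Subsample one sample's counts to `depth` reads without replacement
# (multivariate hypergeometric draw).
.rarefyOne <- function(counts, depth) {
    reads <- rep.int(seq_along(counts), counts)
    tabulate(sample(reads, depth, replace = FALSE), nbins = length(counts))
}

#' Rarefy samples to a common sequencing depth
#'
#' Each sample with at least `depth` reads is subsampled without replacement
#' to exactly `depth` reads; samples below `depth` are dropped with a
#' warning (they cannot be equalized without upsampling). Per-sample random
#' streams are derived deterministically from (`seed`, sample id), so the
#' result is reproducible and independent of sample order.
#'
#' @param x an [OtuExperiment-class] at stage `"filtered"`.
#' @param depth target reads per sample (default 9000).
#' @param seed integer seed controlling the subsampling.
#' @return Rarefied [OtuExperiment-class] (stage `"rarefied"`), every column
#'   summing exactly to `depth`.
#' @export
rarefyCounts <- function(x, depth = 9000, seed = 1L) {
    stopifnot(is(x, "OtuExperiment"))
    if (otuStage(x) != "filtered")
        stop("rarefyCounts expects a 'filtered' table, got '",
             otuStage(x), "'")
    if (depth <= 0) stop("depth must be a positive count")
    m <- otuCounts(x)
    tot <- colSums(m)
    keep <- tot >= depth
    if (any(!keep))
        warning("dropping ", sum(!keep), " sample(s) below depth ", depth,
                ": ", paste(colnames(m)[!keep], collapse = ", "))
    if (!any(keep)) stop("no sample reaches the rarefaction depth")
    out <- x[, keep]
    m <- otuCounts(out)
    for (s in colnames(m)) {
        m[, s] <- withSeed(stableSeed(seed, s),
                           .rarefyOne(m[, s], depth))
    }
    assays(out)$counts <- m
    out@stage <- "rarefied"
    metadata(out)$rarefaction <- list(depth = depth, seed = seed,
                                      n_dropped = sum(!keep))
    validObject(out)
    out
}

#' Convert reads to copy-number-corrected absolute abundance
#'
#' Combines each sample's qPCR total 16S load with the rarefied read
#' composition and per-OTU 16S gene copy numbers:
#' \deqn{A_{is} = T_s \, r_{is} / CN_i}
#' where \eqn{r_{is}} is OTU i's read relative abundance in sample s,
#' \eqn{T_s} the sample's total 16S copies from qPCR and \eqn{CN_i} the 16S
#' copies per genome. The result is a genome-equivalent ("single-copy 16S
#' gene") absolute abundance; by construction
#' \eqn{\sum_i A_{is} CN_i = T_s} (conservation of 16S copies).
#'
#' @param x an [OtuExperiment-class] at stage `"rarefied"`.
#' @param copyNumbers named numeric vector, OTU id -> copies per genome
#'   (>= 1); defaults to `rowData(x)$copy_number`.
#' @param qpcrTotals named numeric vector, sample id -> total 16S copies;
#'   defaults to `colData(x)$qpcr_total`. Every sample must be present.
#' @param defaultCopyNumber copy number substituted for OTUs absent from
#'   `copyNumbers`; default is the mean of the supplied values (the
#'   convention of copy-number correction tools for unmapped taxa).
#' @return [OtuExperiment-class] at stage `"absolute"` with continuous
#'   abundances.
#' @export
toAbsoluteAbundance <- function(x, copyNumbers = NULL, qpcrTotals = NULL,
                                defaultCopyNumber = NULL) {
    stopifnot(is(x, "OtuExperiment"))
    if (otuStage(x) != "rarefied")
        stop("toAbsoluteAbundance expects a 'rarefied' table, got '",
             otuStage(x), "'")
    m <- otuCounts(x)
    if (is.null(copyNumbers)) {
        cnv <- rowData(x)$copy_number
        if (is.null(cnv)) stop("no copy numbers supplied or stored")
        copyNumbers <- stats::setNames(cnv, rownames(m))
    }
    if (is.null(qpcrTotals)) {
        qv <- colData(x)$qpcr_total
        if (is.null(qv)) stop("no qPCR totals supplied or stored")
        qpcrTotals <- stats::setNames(qv, colnames(m))
    }
    missingT <- colnames(m)[!colnames(m) %in% names(qpcrTotals) |
                            is.na(qpcrTotals[colnames(m)])]
    if (length(missingT))
        stop("missing qPCR total for sample(s): ",
             paste(missingT, collapse = ", "))
    Tvec <- qpcrTotals[colnames(m)]
    if (any(Tvec <= 0)) stop("qPCR totals must be positive")
    cn <- copyNumbers[rownames(m)]
    nmiss <- sum(is.na(cn))
    if (nmiss) {
        fallback <- defaultCopyNumber %||% mean(copyNumbers, na.rm = TRUE)
        message(nmiss, " OTU(s) missing a copy number; using ",
                signif(fallback, 4))
        cn[is.na(cn)] <- fallback
    }
    if (any(cn < 1)) stop("copy numbers must be >= 1")
    rel <- sweep(m, 2, colSums(m), "/")
    abs_ab <- sweep(rel, 2, Tvec, "*") / as.numeric(cn)
    out <- x
    assays(out)$counts <- abs_ab
    rowData(out)$copy_number <- as.numeric(cn)
    colData(out)$qpcr_total <- as.numeric(Tvec)
    out@stage <- "absolute"
    validObject(out)
    out
}

#' Per-treatment eligibility screen for dose-response fitting
#'
#' An OTU enters curve fitting for a treatment arm only when it has nonzero
#' abundance in at least `minSamples` of that arm's samples, satisfying
#' degrees-of-freedom requirements of the 4- and 5-parameter models. Samples
#' labelled `control` in the design count toward every arm (the control soil
#' is shared across arms).
#'
#' @param x an [OtuExperiment-class] at stage `"absolute"`.
#' @param minSamples minimum number of samples with nonzero abundance
#'   (default 6).
#' @param controlLabel treatment label identifying shared control samples
#'   (default `"control"`).
#' @return Named list (one element per non-control treatment) of eligible
#'   OTU id vectors, with an `"excluded"` attribute tallying per-arm
#'   exclusions.
#' @export
eligibleOtus <- function(x, minSamples = 6, controlLabel = "control") {
    stopifnot(is(x, "OtuExperiment"))
    if (otuStage(x) != "absolute")
        stop("eligibleOtus expects an 'absolute' table, got '",
             otuStage(x), "'")
    m <- otuCounts(x)
    trt <- colData(x)$treatment
    arms <- setdiff(unique(trt), controlLabel)
    ctrl <- trt == controlLabel
    out <- lapply(arms, function(a) {
        cols <- ctrl | trt == a
        n_nonzero <- rowSums(m[, cols, drop = FALSE] > 0)
        rownames(m)[n_nonzero >= minSamples]
    })
    names(out) <- arms
    attr(out, "excluded") <- vapply(arms, function(a)
        nrow(m) - length(out[[a]]), numeric(1))
    out
}
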