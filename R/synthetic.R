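#' @importFrom stats rmultinom rgamma median
NULL

#' Generate a ground-truth synthetic community
#'
#' Draws per-OTU dose-response truths for a synthetic soil community exposed
#' to a toxicant dose series. Each OTU belongs to one of three response
#' classes: `insensitive` (flat), `loglogistic` (declining sigmoid) or
#' `hormetic` (low-dose stimulation then decline). Per-OTU parameters are
#' sampled as: inflection dose `e` lognormal; slope `b` uniform on
#' `bRange`; lower-asymptote fraction `c/d` uniform on (0, 0.2); hormetic
#' `f` sized numerically so peak stimulation lies between 10% and 50% of
#' the control level; base relative (genome) abundances lognormal,
#' renormalized to sum to 1; 16S copy numbers uniform on `copyNumbers`.
#' Everything is a deterministic function of `seed`.
#'
#' Defaults mirror a 14-level geometric dose series from 0.1 (the control
#' soil's background silver concentration) to 5590 mg Ag kg^-1 and a total
#' 16S pool of 1e8 copies in the control.
#'
#' @param nOtus number of OTUs (>= 10; default 500).
#' @param classProportions named proportions for `insensitive`,
#'   `loglogistic`, `hormetic` (must sum to 1).
#' @param doseGrid strictly increasing dose levels, mg kg^-1; the first is
#'   the control background.
#' @param ec50Meanlog,ec50Sdlog lognormal parameters of the true `e`
#'   (defaults: median 20 mg kg^-1, sdlog 1.2 — most declining OTUs have
#'   `e` inside the dose range).
#' @param bRange range of the true slope (default 0.8 to 4).
#' @param abundSdlog lognormal spread of base abundances (default 1.5).
#' @param copyNumbers candidate 16S copies per genome (default 1:10).
#' @param qpcrTotal0 total 16S copies in the control community (default 1e8).
#' @param seed integer seed.
#' @return A list of class `SyntheticTruth`: per-OTU data.frame `otus`
#'   (class, b, c, d, e, f, base_abundance, copy_number), plus `doseGrid`,
#'   `qpcrTotal0`, `seed`.
#' @export
generateTruth <- function(nOtus = 500,
                          classProportions = c(insensitive = 0.5,
                                               loglogistic = 0.4,
                                               hormetic = 0.1),
                          doseGrid = geomSeq(0.1, 5590, 14),
                          ec50Meanlog = log(20), ec50Sdlog = 1.2,
                          bRange = c(0.8, 4), abundSdlog = 1.5,
                          copyNumbers = 1:10, qpcrTotal0 = 1e8,
                          seed = 1L) {
    if (nOtus < 10) stop("nOtus must be >= 10")
    cls <- c("insensitive", "loglogistic", "hormetic")
    if (!all(cls %in% names(classProportions)) ||
        any(classProportions < 0) ||
        abs(sum(classProportions) - 1) > 1e-8)
        stop("classProportions must be named ", paste(cls, collapse = "/"),
             " and sum to 1")
    stopifnot(all(diff(doseGrid) > 0), doseGrid[1] > 0)
    withSeed(as.integer(seed), {
        klass <- sample(cls, nOtus, replace = TRUE,
                        prob = classProportions[cls])
        base <- rlnorm(nOtus, 0, abundSdlog)
        base <- base / sum(base)
        cn <- sample(copyNumbers, nOtus, replace = TRUE)
        # genome abundances scaled so the control 16S pool equals qpcrTotal0
        g0 <- qpcrTotal0 * base / sum(base * cn)
        b <- runif(nOtus, bRange[1], bRange[2])
        e <- rlnorm(nOtus, ec50Meanlog, ec50Sdlog)
        cfrac <- runif(nOtus, 0, 0.2)
        f <- numeric(nOtus)
        stim <- runif(nOtus, 0.1, 0.5)
        for (i in which(klass == "hormetic"))
            f[i] <- .sizeHormesisF(b[i], cfrac[i] * g0[i], g0[i], e[i],
                                   stim[i])
        otus <- data.frame(
            otu_id = sprintf("OTU_%04d", seq_len(nOtus)),
            class = klass, b = b, c = cfrac * g0, d = g0, e = e, f = f,
            base_abundance = base, copy_number = cn,
            stringsAsFactors = FALSE)
        otus$c[klass == "insensitive"] <- 0
        structure(list(otus = otus, doseGrid = doseGrid,
                       qpcrTotal0 = qpcrTotal0, seed = as.integer(seed)),
                  class = "SyntheticTruth")
    })
}

# Find f giving the requested peak stimulation (fraction of d) for a
# hormesis curve; monotone in f, solved by root finding over a log-dose grid.
.sizeHormesisF <- function(b, cc, d, e, targetStim) {
    grid <- geomSeq(e * 1e-4, e * 10, 200)
    peak <- function(f) {
        y <- evalHormesis(c(b = b, c = cc, d = d, e = e, f = f), grid)
        max(y) / d - 1 - targetStim
    }
    hi <- 10 * d / e
    while (peak(hi) < 0) hi <- hi * 4
    uniroot(peak, c(0, hi), tol = 1e-8 * hi)$root
}

# True genome abundance of every OTU at the given doses (doses x otus).
.truthAbundance <- function(truth, doses) {
    o <- truth$otus
    A <- matrix(0, length(doses), nrow(o))
    for (i in seq_len(nrow(o))) {
        A[, i] <- switch(o$class[i],
            insensitive = rep(o$d[i], length(doses)),
            loglogistic = evalLogLogistic(
                c(b = o$b[i], c = o$c[i], d = o$d[i], e = o$e[i]), doses),
            hormetic = evalHormesis(
                c(b = o$b[i], c = o$c[i], d = o$d[i], e = o$e[i],
                  f = o$f[i]), doses))
    }
    colnames(A) <- o$otu_id
    A
}

#' Simulate an observed sequencing + qPCR experiment from a truth
#'
#' Per dose level: the expected genome abundance of each OTU follows its
#' true response model; the expected 16S pool is the copy-number-weighted
#' sum; read counts are drawn multinomially at the sequencing depth from
#' the 16S pool proportions (optionally Dirichlet-multinomial for
#' overdispersion); and the qPCR total is a lognormal draw around the true
#' pool with coefficient of variation `qpcrCv`. One sample per dose by
#' default, mirroring a pooled-DNA dose series; `nReplicates` adds
#' independent samples per dose for power studies.
#'
#' The first grid dose is labelled `control`, remaining samples get the
#' `treatment` label, so the output feeds [eligibleOtus()] and
#' [fitOtuEc20s()] directly.
#'
#' @param truth a `SyntheticTruth` from [generateTruth()].
#' @param depth sequencing depth per sample (default 20000 reads).
#' @param qpcrCv lognormal coefficient of variation of the qPCR totals
#'   (default 0.02).
#' @param treatment treatment label (default `"Ag"`).
#' @param nReplicates samples per dose (default 1).
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives plain multinomial reads, larger values concentrate less.
#' @param seed integer seed (defaults to a stream derived from the truth's
#'   seed).
#' @return An [OtuExperiment-class] at stage `"raw"` with copy numbers,
#'   qPCR totals and design attached.
#' @export
simulateObserved <- function(truth, depth = 20000, qpcrCv = 0.02,
                             treatment = "Ag", nReplicates = 1,
                             overdispersion = 0, seed = NULL) {
    stopifnot(inherits(truth, "SyntheticTruth"))
    seed <- seed %||% stableSeed(truth$seed, "observed")
    doses <- rep(truth$doseGrid, each = nReplicates)
    A <- .truthAbundance(truth, doses)
    pool <- sweep(A, 2, truth$otus$copy_number, "*")
    withSeed(as.integer(seed), {
        counts <- matrix(0L, ncol(A), nrow(A))
        qpcr <- numeric(nrow(A))
        sdlog <- sqrt(log(1 + qpcrCv^2))
        for (s in seq_len(nrow(A))) {
            pr <- pool[s, ] / sum(pool[s, ])
            if (overdispersion > 0) {
                al <- pr / overdispersion
                gam <- rgamma(length(al), shape = al)
                pr <- gam / sum(gam)
            }
            counts[, s] <- as.integer(rmultinom(1, depth, pr))
            qpcr[s] <- rlnorm(1, log(sum(pool[s, ])) - sdlog^2 / 2, sdlog)
        }
        ids <- sprintf("S%02d", seq_len(nrow(A)))
        rownames(counts) <- truth$otus$otu_id
        colnames(counts) <- ids
        design <- data.frame(sample_id = ids,
            treatment = ifelse(doses == truth$doseGrid[1], "control",
                               treatment),
            dose = doses)
        OtuExperiment(counts, design,
            copyNumbers = stats::setNames(as.numeric(truth$otus$copy_number),
                                          truth$otus$otu_id),
            qpcrTotals = stats::setNames(qpcr, ids))
    })
}

#' Simulate a nitrification dose series
#'
#' Generates replicated t0/t28 nitrate measurements from a known sigmoidal
#' or hormetic truth for the net-nitrate endpoint. The control produces
#' `controlProduction` mg NO3- kg^-1 net; at dose `x` the expected
#' production is the truth curve (as % of control, `d = 100`) scaled to
#' that level. Gaussian noise with standard deviation `noiseSd` (percent of
#' control) is added to the production; t0 is held at `no3T0`.
#'
#' @param params named truth vector `b`, `c`, `d`, `e` (and `f` for a
#'   hormetic truth), on the percent-of-control scale (`d = 100`).
#' @param doses dose levels, mg kg^-1; the first is the control background.
#' @param nReplicates replicates per dose (default 3).
#' @param noiseSd Gaussian noise sd in percent-of-control units (default 5).
#' @param controlProduction net control production, mg NO3- kg^-1
#'   (default 145.5, i.e. 8.2 rising to 153.7).
#' @param no3T0 baseline nitrate at t = 0 (default 8.2 mg kg^-1).
#' @param treatment treatment label (default `"Ag"`).
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `treatment`, `dose`, `replicate`,
#'   `no3_t0`, `no3_t28`, ready for [runNitrificationAnalysis()].
#' @export
simulateNitrification <- function(params, doses = geomSeq(0.1, 2285, 8),
                                  nReplicates = 3, noiseSd = 5,
                                  controlProduction = 145.5, no3T0 = 8.2,
                                  treatment = "Ag", seed = 1L) {
    model <- if ("f" %in% names(params)) "hormesis5" else "loglogistic4"
    dd <- rep(doses, each = nReplicates)
    mu <- .drEval(params, model, dd)          # percent of control
    withSeed(as.integer(seed), {
        pct <- mu + rnorm(length(dd), 0, noiseSd)
        prod <- controlProduction * pct / 100
        data.frame(
            sample_id = sprintf("N%02d", seq_along(dd)),
            treatment = ifelse(dd == doses[1], "control", treatment),
            dose = dd,
            replicate = rep(seq_len(nReplicates), times = length(doses)),
            no3_t0 = no3T0,
            no3_t28 = pmax(0, no3T0 + prod))
    })
}
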