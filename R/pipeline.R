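#' @importFrom jsonlite write_json
#' @importFrom utils packageVersion write.table
NULL

#' Per-OTU dual-model fitting and EC20 extraction
#'
#' For every treatment arm and every eligible OTU, fits both the
#' four-parameter log-logistic and the five-parameter hormesis model to the
#' OTU's absolute abundance across the arm's dose series (shared control
#' included), applies the acceptance criteria, selects the model
#' conservatively ([selectModel()]) and interpolates the ECx. OTUs rejected
#' by both models, or whose accepted curve never attains the target
#' reduction, are excluded; exclusions are tallied per rejection reason.
#'
#' @param x an [OtuExperiment-class] at stage `"absolute"`.
#' @param ecLevel percent reduction for the toxicity value (default 20).
#' @param mode ECx referencing (default `"upper_asymptote"`).
#' @param r2Min R^2 acceptance threshold (default 0.65).
#' @param minSamples eligibility threshold (default 6 samples with nonzero
#'   abundance per arm).
#' @param controlDose background concentration for the `below_background`
#'   flag (default 0.1 mg kg^-1).
#' @param controlLabel design label of the shared control samples.
#' @return data.frame of EC20 records: `otu_id`, `treatment`, `ec20`,
#'   `model_used`, `hormesis_significant`, `below_background`, `taxonomy`.
#'   A `"diagnostics"` attribute tallies eligible/fitted counts and
#'   rejection reasons per arm.
#' @export
fitOtuEc20s <- function(x, ecLevel = 20,
                        mode = c("upper_asymptote", "span"),
                        r2Min = 0.65, minSamples = 6, controlDose = 0.1,
                        controlLabel = "control") {
    mode <- match.arg(mode)
    stopifnot(is(x, "OtuExperiment"))
    elig <- eligibleOtus(x, minSamples = minSamples,
                         controlLabel = controlLabel)
    m <- otuCounts(x)
    trt <- colData(x)$treatment
    dose <- colData(x)$dose
    tax <- rowData(x)$taxonomy
    if (is.null(tax)) tax <- stats::setNames(rep(NA_character_, nrow(m)),
                                             rownames(m))
    else tax <- stats::setNames(as.character(tax), rownames(m))
    ctrl <- trt == controlLabel
    records <- list()
    diag <- list()
    for (a in names(elig)) {
        cols <- ctrl | trt == a
        doses <- dose[cols]
        maxDose <- max(doses)
        tally <- c(eligible = length(elig[[a]]), fitted = 0,
                   slope_nonpositive = 0, e_exceeds_max_dose = 0,
                   r2_below_threshold = 0, fit_failed = 0, no_crossing = 0)
        for (otu in elig[[a]]) {
            y <- m[otu, cols]
            fitLL <- applyAcceptanceCriteria(
                fitDoseResponse(doses, y, "loglogistic4"),
                maxDose = maxDose, r2Min = r2Min)
            fitH <- applyAcceptanceCriteria(
                fitDoseResponse(doses, y, "hormesis5"),
                maxDose = maxDose, r2Min = r2Min)
            sel <- selectModel(fitLL, fitH)
            if (is.null(sel)) {
                for (r in unique(c(fitLL@rejectionReasons,
                                   fitH@rejectionReasons)))
                    tally[r] <- tally[r] + 1
                next
            }
            hSig <- NA
            if (sel@model == "hormesis5")
                hSig <- tryCatch(
                    suppressWarnings(testHormesisSignificance(sel)),
                    error = function(e) NA)
            ec <- tryCatch(
                computeEcx(sel, p = ecLevel, mode = mode,
                           controlDose = controlDose, maxDose = maxDose),
                error = function(e) NULL)
            if (is.null(ec) || !is.finite(ec$value) || ec$value <= 0) {
                tally["no_crossing"] <- tally["no_crossing"] + 1
                next
            }
            tally["fitted"] <- tally["fitted"] + 1
            records[[length(records) + 1L]] <- data.frame(
                otu_id = otu, treatment = a, ec20 = ec$value,
                model_used = sel@model,
                hormesis_significant = hSig,
                below_background = ec$below_background,
                taxonomy = unname(tax[otu]),
                stringsAsFactors = FALSE)
        }
        diag[[a]] <- tally
        message(sprintf(
            "[%s] %d eligible OTUs, %d fitted with an EC%g", a,
            tally[["eligible"]], tally[["fitted"]], ecLevel))
    }
    out <- if (length(records)) do.call(rbind, records)
        else data.frame(otu_id = character(), treatment = character(),
                        ec20 = numeric(), model_used = character(),
                        hormesis_significant = logical(),
                        below_background = logical(),
                        taxonomy = character())
    attr(out, "diagnostics") <- diag
    out
}

#' Default pipeline configuration
#'
#' Named list of every pipeline constant: rarefaction depth 9000,
#' eligibility threshold 6 samples, R^2 threshold 0.65, EC level 20 with
#' upper-asymptote referencing, protection percentages 5/10/20/80,
#' 1000 bootstrap resamples. Flags: `exclude_below_background` drops
#' EC20 records flagged below the control background from the OSD (kept by
#' default), `require_hormesis_significance` restricts hormesis selection
#' to significant fits (off by default in the OTU branch).
#'
#' @return Named list of defaults; override entries and pass to
#'   [runOsdPipeline()].
#' @export
defaultPipelineConfig <- function() {
    list(otu_table = NULL, taxonomy = NULL, copy_numbers = NULL,
         qpcr_totals = NULL, design = NULL, output_dir = "otusd_out",
         rarefaction_depth = 9000, min_samples = 6, r2_min = 0.65,
         ec_level = 20, ec_mode = "upper_asymptote",
         protection_percents = c(5, 10, 20, 80), n_boot = 1000,
         seed = 1L, control_dose = 0.1, control_label = "control",
         exclude_below_background = FALSE,
         require_hormesis_significance = FALSE)
}

.loadConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- defaultPipelineConfig()
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
        stop("unknown config entries: ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
    cfg
}

#' Run the full OTU-sensitivity pipeline
#'
#' Executes, in order: low-count filtering, rarefaction, copy-number
#' correction to absolute abundance, per-treatment eligibility, dual-model
#' per-OTU fitting with acceptance rules, EC20 extraction, Burr III OSD
#' fitting per treatment, HCx with bootstrap confidence intervals, and
#' pairwise treatment comparisons. Writes `ec20_table.csv`,
#' `hc_report.json`, `osd_plot_data.csv`, `fit_diagnostics.csv` and
#' `manifest.json` to the configured output directory.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or path
#'   to a YAML file of overrides. Either file paths (`otu_table`, `design`,
#'   `copy_numbers`, `qpcr_totals`, optionally `taxonomy`) or a prebuilt
#'   `x` passed via the `otu_experiment` argument.
#' @param otu_experiment optional [OtuExperiment-class] at stage `"raw"`,
#'   bypassing file input.
#' @return Invisible list: `ec20s`, `hc` (per-treatment HC tables with
#'   letters), `burr_fits`, `diagnostics`, `config`.
#' @export
runOsdPipeline <- function(config = list(), otu_experiment = NULL) {
    cfg <- .loadConfig(config)
    if (is.null(otu_experiment)) {
        if (is.null(cfg$otu_table) || is.null(cfg$design))
            stop("config error: otu_table and design paths are required")
        counts <- readOtuTable(cfg$otu_table)
        design <- readDoseDesign(cfg$design)
        tax <- if (!is.null(cfg$taxonomy)) readTaxonomy(cfg$taxonomy)
        cn <- if (!is.null(cfg$copy_numbers)) readCopyNumbers(cfg$copy_numbers)
        qt <- if (!is.null(cfg$qpcr_totals)) readQpcrTotals(cfg$qpcr_totals)
        x <- OtuExperiment(counts, design, taxonomy = tax,
                           copyNumbers = cn, qpcrTotals = qt)
    } else x <- otu_experiment
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

    x <- filterLowCountOtus(x)
    x <- rarefyCounts(x, depth = cfg$rarefaction_depth, seed = cfg$seed)
    x <- toAbsoluteAbundance(x)
    ec20s <- fitOtuEc20s(x, ecLevel = cfg$ec_level, mode = cfg$ec_mode,
                         r2Min = cfg$r2_min, minSamples = cfg$min_samples,
                         controlDose = cfg$control_dose,
                         controlLabel = cfg$control_label)
    diagnostics <- attr(ec20s, "diagnostics")
    osdInput <- ec20s
    if (cfg$exclude_below_background)
        osdInput <- osdInput[!osdInput$below_background, ]

    hc <- list(); burrFits <- list(); plotData <- list()
    for (a in unique(osdInput$treatment)) {
        vals <- osdInput$ec20[osdInput$treatment == a]
        if (length(vals) < 8) {
            message("OSD skipped for ", a, ": only ", length(vals),
                    " EC20 values (>= 8 required)")
            next
        }
        burrFits[[a]] <- fitBurr3(vals)
        hc[[a]] <- bootstrapHc(vals, protection = cfg$protection_percents,
                               nBoot = cfg$n_boot,
                               seed = stableSeed(cfg$seed, a))
        hc[[a]]$treatment <- a
        pd <- osdPlotData(vals, burrFits[[a]])
        pd$treatment <- a
        plotData[[a]] <- pd
    }
    hcTable <- if (length(hc)) do.call(rbind, c(hc,
        list(make.row.names = FALSE))) else NULL
    if (!is.null(hcTable)) {
        hcTable$letter <- NA_character_
        for (p in unique(hcTable$protection_percent)) {
            i <- which(hcTable$protection_percent == p)
            if (length(i) >= 2)
                hcTable$letter[i] <- .cldLetters(hcTable$value[i],
                    hcTable$ci_low[i], hcTable$ci_high[i],
                    hcTable$treatment[i])
            else hcTable$letter[i] <- "a"
        }
    }

    writeEc20Table(ec20s, file.path(cfg$output_dir, "ec20_table.csv"))
    diagDf <- do.call(rbind, lapply(names(diagnostics), function(a)
        data.frame(treatment = a, t(diagnostics[[a]]))))
    write.csv(diagDf, file.path(cfg$output_dir, "fit_diagnostics.csv"),
              row.names = FALSE)
    if (length(plotData))
        write.csv(do.call(rbind, c(plotData, list(make.row.names = FALSE))),
                  file.path(cfg$output_dir, "osd_plot_data.csv"),
                  row.names = FALSE)
    report <- lapply(names(hc), function(a) list(
        treatment = a,
        burr3 = as.list(fitParams(burrFits[[a]])),
        log_lik = burrFits[[a]]@logLik,
        n_ec20 = hc[[a]]$n_ec20[1],
        hc = hc[[a]][, c("protection_percent", "value", "ci_low",
                         "ci_high", "n_boot_ok")]))
    names(report) <- names(hc)
    write_json(report, file.path(cfg$output_dir, "hc_report.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(config = cfg[!vapply(cfg, is.null, logical(1))],
                     package_version = as.character(packageVersion("otuSD")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
    write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
               auto_unbox = TRUE, pretty = TRUE)
    invisible(list(ec20s = ec20s, hc = hcTable, burr_fits = burrFits,
                   diagnostics = diagnostics, config = cfg))
}
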