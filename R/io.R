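#' @importFrom utils read.delim read.csv write.csv
NULL

#' Read an OTU table from a tab-separated file
#'
#' Accepts the plain TSV convention (first column OTU ids, header row sample
#' ids) including the flat export of BIOM tables, whose leading
#' `# Constructed from biom file` comment line and `#OTU ID` header are
#' handled.
#'
#' @param path file path.
#' @return Integer matrix, OTUs x samples.
#' @export
readOtuTable <- function(path) {
    first <- readLines(path, n = 2L)
    skip <- if (grepl("^#", first[1]) && !grepl("\t", first[1])) 1L else 0L
    df <- read.delim(path, skip = skip, check.names = FALSE,
                     comment.char = "", stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "numeric"
    m
}

#' Write an OTU table as TSV
#' @param counts OTUs x samples matrix.
#' @param path file path.
#' @export
writeOtuTable <- function(counts, path) {
    df <- data.frame(`#OTU ID` = rownames(counts), counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a two-column taxonomy map (OTU id, semicolon-delimited lineage)
#' @param path TSV file path.
#' @return Named character vector.
#' @export
readTaxonomy <- function(path) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read per-OTU 16S copy numbers (two-column TSV)
#' @param path TSV file path.
#' @return Named numeric vector.
#' @export
readCopyNumbers <- function(path) {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read per-sample qPCR 16S totals (two-column CSV)
#' @param path CSV file path.
#' @return Named numeric vector.
#' @export
readQpcrTotals <- function(path) {
    df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
    stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Read a dose design (CSV: sample_id, treatment, dose)
#' @param path CSV file path.
#' @return data.frame.
#' @export
readDoseDesign <- function(path) {
    df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "treatment", "dose") %in% names(df)))
    df
}

#' Read an EC20 record table (CSV)
#' @param path CSV file path.
#' @return data.frame with at least `otu_id`, `treatment`, `ec20`.
#' @export
readEc20Table <- function(path) {
    df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("otu_id", "treatment", "ec20") %in% names(df)))
    df
}

#' Write an EC20 record table (CSV)
#' @param ec20s data.frame from [fitOtuEc20s()].
#' @param path CSV file path.
#' @export
writeEc20Table <- function(ec20s, path) {
    write.csv(ec20s, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
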