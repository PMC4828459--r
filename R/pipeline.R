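.combinePSMSets <- function(sets) {
    frames <- lapply(sets, psmData)
    PSMSet(do.call(rbind, c(frames, list(make.row.names = FALSE))))
}

.resolvePSMInput <- function(psms) {
    if (is(psms, "PSMSet"))
        return(psms)
    if (is.character(psms)) {
        paths <- psms
        if (length(paths) == 1L && dir.exists(paths))
            paths <- sort(list.files(paths, pattern = "\\.tsv$",
                                     full.names = TRUE))
        if (length(paths) == 0L)
            stop("no PSM tables found", call. = FALSE)
        return(.combinePSMSets(lapply(paths, readPSMTable)))
    }
    stop("'psms' must be a PSMSet, file path(s), or a directory",
         call. = FALSE)
}

#' Run the full selection pipeline
#'
#' Executes the stages of the spectral-counting selection procedure in
#' order: confidence filtering, shared-peptide exclusion, per-run spectral
#' counting and normalization, per-replicate evidence (ratios and
#' qualifying flags), tier classification against the exclusion list, and
#' the annotation report when annotations are supplied.  When an output
#' directory is given, the classification table, count matrix and JSON
#' summaries are written there with rows sorted by accession, so repeated
#' runs on identical inputs produce byte-identical files.
#'
#' @param psms a \linkS4class{PSMSet}, a character vector of PSM table
#'   paths, or a directory containing \code{.tsv} PSM tables (one or more
#'   runs per file).
#' @param exclusions \code{NULL}, a \code{data.frame} with
#'   \code{protein_id}/\code{reason}, or the path of an exclusion table.
#' @param annotations \code{NULL}, an annotation \code{data.frame}, or
#'   the path of an annotation table.
#' @param param a \linkS4class{CountingParam}.
#' @param outDir \code{NULL} or a directory (created if needed) receiving
#'   \code{classification.tsv}, \code{counts.tsv}, \code{summary.json}
#'   and, when annotations are given, \code{report.json}.
#' @return a list with elements \code{counts}
#'   (\linkS4class{SpectralCountExperiment}), \code{evidence},
#'   \code{classification}, \code{summary} (the tally, with the
#'   thresholds echoed for provenance), \code{report} (or \code{NULL})
#'   and \code{files} (paths written).
#' @export
#' @examples
#' sim <- simulateExperiment(SimulationParam(
#'     classCounts = c(TRUE_ACYL_EXCLUSIVE = 5, TRUE_ACYL_ENRICHED = 5,
#'                     NONSPECIFIC = 5, CONTAMINANT_RIBOSOMAL = 2,
#'                     LOW_EVIDENCE = 3), seed = 1))
#' res <- runPipeline(sim$psms, exclusions = sim$exclusions)
#' res$summary$byCategory
runPipeline <- function(psms, exclusions = NULL, annotations = NULL,
                        param = CountingParam(), outDir = NULL) {
    psms <- .resolvePSMInput(psms)
    if (is.character(exclusions))
        exclusions <- readExclusions(exclusions)
    if (is.character(annotations))
        annotations <- readAnnotations(annotations)
    counts <- countSpectra(psms, param)
    evidence <- buildEvidence(counts, param)
    classification <- classifyProteins(evidence, exclusions)
    summary <- classificationSummary(classification, param)
    report <- if (!is.null(annotations))
        summarizeReport(classification, annotations) else NULL
    files <- character()
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        f1 <- file.path(outDir, "classification.tsv")
        writeClassification(classification, f1)
        f2 <- file.path(outDir, "counts.tsv")
        writeCountMatrix(counts, f2)
        f3 <- file.path(outDir, "summary.json")
        jsonlite::write_json(summary, f3, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        files <- c(classification = f1, counts = f2, summary = f3)
        if (!is.null(report)) {
            f4 <- file.path(outDir, "report.json")
            jsonlite::write_json(report, f4, auto_unbox = TRUE,
                                 digits = NA, pretty = TRUE)
            files <- c(files, report = f4)
        }
    }
    list(counts = counts, evidence = evidence,
         classification = classification, summary = summary,
         report = report, files = files)
}
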