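## Flat TSV interchange. The only fields downstream stages need are the run
## identity, peptide, accession list and the three probabilities, so a
## bespoke table is used rather than pepXML/protXML. ";" is the reserved
## accession-list separator and may not occur inside an accession.

.PSM_HEADER <- c("replicate", "condition", "spectrum_id", "peptide_sequence",
                 "protein_ids", "psm_probability", "peptide_probability",
                 "protein_probability")

.readTSV <- function(path, expected) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            quote = "", comment.char = "")
    if (!identical(names(df), expected)) {
        bad <- setdiff(expected, names(df))
        extra <- setdiff(names(df), expected)
        stop("malformed header in '", basename(path), "': ",
             if (length(bad)) paste0("missing column(s) ",
                                     paste(bad, collapse = ", ")) else
                 paste0("unexpected column(s) ",
                        paste(extra, collapse = ", ")),
             call. = FALSE)
    }
    df
}

.asNum <- function(x, what, path) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(is.na(x) | x == ""))
    if (length(bad))
        stop(sprintf("row %d of '%s': %s is not numeric", bad[1L],
                     basename(path), what), call. = FALSE)
    v
}

#' Read a PSM interchange table
#'
#' Reads a tab-separated PSM table (UTF-8, header required, columns
#' \code{replicate, condition, spectrum_id, peptide_sequence, protein_ids,
#' psm_probability, peptide_probability, protein_probability}) and returns
#' a validated \linkS4class{PSMSet}.  \code{protein_ids} entries are split
#' on \code{";"}, preserving order and collapsing duplicates.
#'
#' @param path path to a TSV file.
#' @return a \linkS4class{PSMSet}.
#' @seealso [writePSMTable()]
#' @export
#' @examples
#' f <- system.file("extdata", "example_psms.tsv", package = "abeSelect")
#' readPSMTable(f)
readPSMTable <- function(path) {
    df <- .readTSV(path, .PSM_HEADER)
    if (nrow(df) == 0L)
        return(PSMSet())
    df$replicate <- suppressWarnings(as.integer(df$replicate))
    bad <- which(is.na(df$replicate))
    if (length(bad))
        stop(sprintf("row %d of '%s': replicate is not an integer", bad[1L],
                     basename(path)), call. = FALSE)
    for (p in c("psm_probability", "peptide_probability",
                "protein_probability"))
        df[[p]] <- .asNum(df[[p]], p, path)
    out <- tryCatch(PSMSet(df), error = function(e)
        stop("invalid PSM table '", basename(path), "': ",
             conditionMessage(e), call. = FALSE))
    out
}

#' Write a PSM interchange table
#'
#' Writes a \linkS4class{PSMSet} in the tab-separated interchange format
#' read by [readPSMTable()].  Probabilities are printed with enough digits
#' for an exact round trip, so \code{readPSMTable(writePSMTable(x))}
#' reproduces the records identically.
#'
#' @param x a \linkS4class{PSMSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePSMTable <- function(x, path) {
    stopifnot(is(x, "PSMSet"))
    validObject(x)
    df <- x@psm
    out <- data.frame(
        replicate = df$replicate,
        condition = df$condition,
        spectrum_id = df$spectrum_id,
        peptide_sequence = df$peptide_sequence,
        protein_ids = vapply(df$protein_ids, paste, "", collapse = ";"),
        psm_probability = sprintf("%.17g", df$psm_probability),
        peptide_probability = sprintf("%.17g", df$peptide_probability),
        protein_probability = sprintf("%.17g", df$protein_probability),
        stringsAsFactors = FALSE)
    .writeTSV(out, path)
}

.writeTSV <- function(df, path) {
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE, na = "")
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write '", path, "': ", conditionMessage(ok),
             call. = FALSE)
    invisible(path)
}

#' Read an exclusion list
#'
#' Reads the two-column tab-separated exclusion table
#' (\code{protein_id}, \code{reason}) listing proteins removed from the
#' candidate list regardless of evidence: ribosomal proteins and proteins
#' carrying thioester linkages unrelated to S-acylation.
#'
#' @param path path to a TSV file with header
#'   \code{protein_id\\treason}; \code{reason} must be \code{RIBOSOMAL} or
#'   \code{THIOESTER}.
#' @return a \code{data.frame} with columns \code{protein_id} and
#'   \code{reason}, one row per protein.  A protein listed twice with the
#'   same reason is collapsed; conflicting reasons are an error.
#' @seealso [classifyProteins()]
#' @export
readExclusions <- function(path) {
    df <- .readTSV(path, c("protein_id", "reason"))
    if (nrow(df)) {
        bad <- which(!df$reason %in% .EXCLUSION_REASONS)
        if (length(bad))
            stop(sprintf(
                "row %d of '%s': unknown reason '%s' (allowed: %s)",
                bad[1L], basename(path), df$reason[bad[1L]],
                paste(.EXCLUSION_REASONS, collapse = ", ")), call. = FALSE)
        bad <- which(df$protein_id == "")
        if (length(bad))
            stop(sprintf("row %d of '%s': empty protein_id", bad[1L],
                         basename(path)), call. = FALSE)
        df <- unique(df)
        dup <- df$protein_id[duplicated(df$protein_id)]
        if (length(dup))
            stop("conflicting exclusion reasons for: ",
                 paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    rownames(df) <- NULL
    df
}

#' Write an exclusion list
#'
#' @param exclusions a \code{data.frame} with columns \code{protein_id}
#'   and \code{reason} (values \code{RIBOSOMAL} or \code{THIOESTER}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExclusions <- function(exclusions, path) {
    stopifnot(is.data.frame(exclusions),
              all(c("protein_id", "reason") %in% names(exclusions)),
              all(exclusions$reason %in% .EXCLUSION_REASONS))
    .writeTSV(exclusions[, c("protein_id", "reason")], path)
}

.ANNOTATION_HEADER <- c("protein_id", "functional_class", "kinase_family",
                        "kinase_class", "tmd_count", "palm_site_count",
                        "myristoylated", "prenylated", "drm_enriched")

.asLogical <- function(x, what, path) {
    v <- rep(NA, length(x))
    v[x %in% c("TRUE", "true", "1")] <- TRUE
    v[x %in% c("FALSE", "false", "0")] <- FALSE
    bad <- which(is.na(v) & !(is.na(x) | x == ""))
    if (length(bad))
        stop(sprintf("row %d of '%s': %s is not a logical value", bad[1L],
                     basename(path), what), call. = FALSE)
    as.logical(v)
}

#' Read a protein annotation table
#'
#' Reads the tab-separated annotation table of externally predicted
#' properties consumed by the cross-tabulation summaries: functional class
#' labels, kinase family/class, transmembrane domain (TMD) counts, numbers
#' of predicted palmitoylation sites, predicted myristoylation and
#' prenylation flags, and detergent-resistant membrane (DRM) enrichment
#' flags.  Predictions are inputs produced by external programs; this
#' package never computes them.  Empty fields are read as missing.
#'
#' @param path path to a TSV file with header columns
#'   \code{protein_id, functional_class, kinase_family, kinase_class,
#'   tmd_count, palm_site_count, myristoylated, prenylated, drm_enriched}.
#' @return a \code{data.frame}, one row per protein.
#' @seealso [summarizeReport()], [summarizeDRMOverlap()]
#' @export
readAnnotations <- function(path) {
    df <- .readTSV(path, .ANNOTATION_HEADER)
    if (nrow(df)) {
        dup <- df$protein_id[duplicated(df$protein_id)]
        if (length(dup))
            stop("duplicate protein_id in annotation table: ",
                 paste(unique(dup), collapse = ", "), call. = FALSE)
        for (p in c("kinase_class", "tmd_count", "palm_site_count")) {
            v <- suppressWarnings(as.integer(df[[p]]))
            bad <- which(is.na(v) & !(is.na(df[[p]]) | df[[p]] == ""))
            if (length(bad))
                stop(sprintf("row %d of '%s': %s is not an integer",
                             bad[1L], basename(path), p), call. = FALSE)
            if (p != "kinase_class" && any(v < 0, na.rm = TRUE))
                stop("negative ", p, " in annotation table", call. = FALSE)
            df[[p]] <- v
        }
        for (p in c("myristoylated", "prenylated", "drm_enriched"))
            df[[p]] <- .asLogical(df[[p]], p, path)
        df$functional_class[df$functional_class == ""] <- NA_character_
        df$kinase_family[df$kinase_family == ""] <- NA_character_
    } else {
        for (p in c("kinase_class", "tmd_count", "palm_site_count"))
            df[[p]] <- integer()
        for (p in c("myristoylated", "prenylated", "drm_enriched"))
            df[[p]] <- logical()
    }
    rownames(df) <- NULL
    df
}

#' Read a kinase family table
#'
#' Reads a tab-separated table of S-acylated protein kinases with one row
#' per accession (\code{family_label}, \code{kinase_class},
#' \code{accession}) and aggregates it to one row per (family, class) with
#' an accession list, the layout used by [summarizeKinaseClasses()].  The
#' packaged fixture \code{table1_kinases.tsv} transcribes the 52 kinases of
#' the study's high probability group.
#'
#' @param path path to a TSV file.
#' @return a \code{data.frame} with columns \code{family_label},
#'   \code{kinase_class} (integer) and \code{accessions} (list column).
#' @export
#' @examples
#' f <- system.file("extdata", "table1_kinases.tsv", package = "abeSelect")
#' summarizeKinaseClasses(readKinaseTable(f))$total
readKinaseTable <- function(path) {
    df <- .readTSV(path, c("family_label", "kinase_class", "accession"))
    df$kinase_class <- suppressWarnings(as.integer(df$kinase_class))
    bad <- which(is.na(df$kinase_class))
    if (length(bad))
        stop(sprintf("row %d of '%s': kinase_class is not an integer",
                     bad[1L], basename(path)), call. = FALSE)
    if (any(df$accession == ""))
        stop("empty accession in kinase table", call. = FALSE)
    key <- paste(df$family_label, df$kinase_class, sep = "\r")
    keys <- unique(key)
    out <- data.frame(
        family_label = sub("\r.*$", "", keys),
        kinase_class = as.integer(sub("^.*\r", "", keys)),
        stringsAsFactors = FALSE)
    out$accessions <- I(lapply(keys, function(k) df$accession[key == k]))
    rownames(out) <- NULL
    out
}

#' Write a classification table
#'
#' Writes the per-protein classification in the tab-separated layout
#' \code{protein_id, category, subtype, q, t, ever_in_minus,
#' exclusion_reason, rule_trace}, sorted lexicographically by accession for
#' reproducible diffs.
#'
#' @param classification the \code{DataFrame} returned by
#'   [classifyProteins()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeClassification <- function(classification, path) {
    df <- as.data.frame(classification)
    df <- df[order(df$protein_id), c("protein_id", "category", "subtype",
                                     "q", "t", "ever_in_minus",
                                     "exclusion_reason", "rule_trace")]
    .writeTSV(df, path)
}

#' Write a spectral count matrix
#'
#' Writes one row per (protein, run) in the layout \code{protein_id,
#' replicate, condition, raw_count, normalized_count, n_unique_peptides,
#' identified}, sorted by accession then run.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(x, path) {
    stopifnot(is(x, "SpectralCountExperiment"))
    cd <- colData(x)
    n <- nrow(x)
    rows <- lapply(seq_len(ncol(x)), function(j) {
        data.frame(protein_id = rownames(x),
                   replicate = rep(cd$replicate[j], n),
                   condition = rep(cd$condition[j], n),
                   raw_count = assay(x, "raw")[, j],
                   normalized_count = sprintf(
                       "%.17g", assay(x, "normalized")[, j]),
                   n_unique_peptides = assay(x, "nUniquePeptides")[, j],
                   identified = assay(x, "identified")[, j],
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[order(df$protein_id, df$replicate, df$condition), ]
    .writeTSV(df, path)
}
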