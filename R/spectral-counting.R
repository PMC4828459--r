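#' Filter PSMs to the confident subset
#'
#' Keeps the records whose protein probability and peptide probability are
#' at or above the configured cutoffs (inclusive; the default 0.95/0.95
#' mirrors the export filter of a ProteinProphet-style pipeline).  The
#' spectrum-level probability is not consulted here: it governs which
#' spectra are counted, not which peptides identify a protein.
#'
#' @param psms a \linkS4class{PSMSet}.
#' @param param a \linkS4class{CountingParam}.
#' @return a \linkS4class{PSMSet} with the surviving records, in input
#'   order.
#' @seealso [uniquePeptideMap()], [countSpectra()]
#' @export
filterConfident <- function(psms, param = CountingParam()) {
    stopifnot(is(psms, "PSMSet"), is(param, "CountingParam"))
    validObject(param)
    df <- psms@psm
    keep <- df$protein_probability >= param@proteinProbCutoff &
        df$peptide_probability >= param@peptideProbCutoff
    new("PSMSet", psm = .normalizePSMFrame(df[keep, , drop = FALSE]))
}

#' Map proteins to their unique peptides
#'
#' A peptide observed mapping to two or more distinct proteins anywhere in
#' the dataset (a shared peptide) is excluded from the analysis and
#' contributes to no protein.  Uniqueness is assessed dataset-wide, across
#' all runs, so a protein's unique-peptide set is stable between runs.
#' Proteins left with no unique peptide (identified by shared peptides
#' only) are likewise excluded and reported in the dropped set.
#'
#' @param psms a \linkS4class{PSMSet}, normally the confident subset from
#'   [filterConfident()].
#' @return a list with elements \code{map} (named list: protein accession
#'   to sorted character vector of its unique peptides) and \code{dropped}
#'   (accessions observed only through shared peptides).
#' @export
#' @examples
#' df <- data.frame(replicate = 1L, condition = "PLUS",
#'                  spectrum_id = c("s1", "s2"),
#'                  peptide_sequence = c("AAAK", "CCCK"),
#'                  protein_ids = c("P1", "P1;P2"),
#'                  psm_probability = 0.99, peptide_probability = 0.99,
#'                  protein_probability = 0.99)
#' uniquePeptideMap(PSMSet(df))
uniquePeptideMap <- function(psms) {
    stopifnot(is(psms, "PSMSet"))
    df <- psms@psm
    if (nrow(df) == 0L)
        return(list(map = stats::setNames(list(), character()),
                    dropped = character()))
    n <- lengths(df$protein_ids)
    pep <- rep(df$peptide_sequence, n)
    prot <- unlist(df$protein_ids, use.names = FALSE)
    owners <- lapply(split(prot, pep), unique)
    allProteins <- sort(unique(prot))
    uniq <- owners[lengths(owners) == 1L]
    byProtein <- split(names(uniq), unlist(uniq, use.names = FALSE))
    map <- lapply(byProtein, sort)
    map <- map[order(names(map))]
    list(map = map, dropped = setdiff(allProteins, names(map)))
}

.runKey <- function(replicate, condition)
    sprintf("%sHyd_%d", ifelse(condition == "PLUS", "+", "-"), replicate)

#' Count spectra per protein and run
#'
#' Applies the full spectral-counting procedure to a PSM dataset: records
#' are filtered to the confident subset, shared peptides are excluded
#' dataset-wide, and within each run every spectrum whose PSM probability
#' is strictly above the spectrum cutoff and whose peptide is unique to a
#' protein is indexed to that protein's raw count.  Raw counts are
#' normalized to the total number of spectra counted in the run.  A
#' protein is considered identified in a run when it has at least one
#' confident unique-peptide record there, regardless of the spectrum-level
#' cutoff.
#'
#' @param psms a \linkS4class{PSMSet} covering one or more runs.
#' @param param a \linkS4class{CountingParam}.
#' @return a \linkS4class{SpectralCountExperiment} with one column per run
#'   present in \code{psms} and one row per protein identified in at least
#'   one run.
#' @seealso [computeRatio()], [buildEvidence()]
#' @export
countSpectra <- function(psms, param = CountingParam()) {
    stopifnot(is(psms, "PSMSet"), is(param, "CountingParam"))
    validObject(psms)
    validObject(param)
    runs <- runTable(psms)
    conf <- filterConfident(psms, param)
    upm <- uniquePeptideMap(conf)
    proteins <- names(upm$map)
    nr <- length(proteins)
    nc <- nrow(runs)
    dimn <- list(proteins, .runKey(runs$replicate, runs$condition))
    raw <- matrix(0L, nr, nc, dimnames = dimn)
    identified <- matrix(FALSE, nr, nc, dimnames = dimn)
    nUniq <- matrix(0L, nr, nc, dimnames = dimn)
    peptidesPlus <- stats::setNames(
        rep(list(character()), nr), proteins)

    df <- conf@psm
    if (nrow(df)) {
        # peptide -> owning protein, for unique peptides only
        owner <- stats::setNames(
            rep(names(upm$map), lengths(upm$map)),
            unlist(upm$map, use.names = FALSE))
        df$owner <- owner[df$peptide_sequence]
        df <- df[!is.na(df$owner), , drop = FALSE]
        if (nrow(df)) {
            runIdx <- match(paste(df$replicate, df$condition),
                            paste(runs$replicate, runs$condition))
            pi <- match(df$owner, proteins)
            identified[cbind(pi, runIdx)] <- TRUE
            counted <- df$psm_probability > param@spectrumProbCutoff
            tab <- table(factor(pi[counted], levels = seq_len(nr)),
                         factor(runIdx[counted], levels = seq_len(nc)))
            raw[] <- as.integer(tab)
            key <- paste(pi, runIdx)
            npep <- vapply(split(df$peptide_sequence, key),
                           function(p) length(unique(p)), 0L)
            kk <- strsplit(names(npep), " ", fixed = TRUE)
            for (k in seq_along(npep))
                nUniq[as.integer(kk[[k]][1L]),
                      as.integer(kk[[k]][2L])] <- npep[[k]]
            isPlus <- df$condition == "PLUS"
            pp <- lapply(split(df$peptide_sequence[isPlus],
                               df$owner[isPlus]),
                         function(p) sort(unique(p)))
            peptidesPlus[names(pp)] <- pp
        }
    }
    total <- colSums(raw)
    normalized <- raw
    storage.mode(normalized) <- "double"
    nz <- total > 0
    normalized[, nz] <- sweep(raw[, nz, drop = FALSE], 2L, total[nz], "/")
    normalized[, !nz] <- 0

    se <- SummarizedExperiment(
        assays = SimpleList(raw = raw, normalized = normalized,
                            identified = identified,
                            nUniquePeptides = nUniq),
        rowData = DataFrame(
            uniquePeptides = CharacterList(upm$map),
            peptidesPlus = CharacterList(peptidesPlus),
            row.names = proteins),
        colData = DataFrame(replicate = runs$replicate,
                            condition = runs$condition,
                            total = as.integer(total),
                            row.names = dimn[[2L]]))
    metadata(se) <- list(param = param, dropped = upm$dropped)
    new("SpectralCountExperiment", se)
}

#' +Hyd/-Hyd enrichment ratio for one protein in one replicate
#'
#' The normalized spectral count ratio is computed only when the protein
#' is identified in both the +Hyd and -Hyd runs of the replicate.
#' Otherwise the outcome is categorical: \code{ONLY_PLUS} when the protein
#' is absent from the control, \code{ONLY_MINUS} when absent from the
#' treated sample, and \code{PLUS_OVER_ZERO} when identified in both but
#' with a zero normalized count in the control (treated downstream as
#' exceeding any threshold).
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param proteinId a single accession present in \code{rownames(x)}.
#' @param replicate the replicate index whose (+Hyd, -Hyd) run pair to
#'   compare.
#' @return a list with elements \code{kind} (one of \code{FINITE},
#'   \code{ONLY_PLUS}, \code{ONLY_MINUS}, \code{PLUS_OVER_ZERO}) and
#'   \code{value} (the ratio, only for \code{FINITE}).
#' @export
computeRatio <- function(x, proteinId, replicate) {
    stopifnot(is(x, "SpectralCountExperiment"), length(proteinId) == 1L,
              length(replicate) == 1L)
    if (!proteinId %in% rownames(x))
        stop("unknown protein: ", proteinId, call. = FALSE)
    cd <- colData(x)
    jp <- which(cd$replicate == replicate & cd$condition == "PLUS")
    jm <- which(cd$replicate == replicate & cd$condition == "MINUS")
    if (length(jp) == 0L && length(jm) == 0L)
        stop("no runs for replicate ", replicate, call. = FALSE)
    idP <- length(jp) == 1L && assay(x, "identified")[proteinId, jp]
    idM <- length(jm) == 1L && assay(x, "identified")[proteinId, jm]
    if (!idP && !idM)
        stop("protein ", proteinId, " is identified in neither run of ",
             "replicate ", replicate, call. = FALSE)
    if (idP && !idM)
        return(list(kind = "ONLY_PLUS", value = NA_real_))
    if (!idP && idM)
        return(list(kind = "ONLY_MINUS", value = NA_real_))
    np <- assay(x, "normalized")[proteinId, jp]
    nm <- assay(x, "normalized")[proteinId, jm]
    if (nm == 0)
        return(list(kind = "PLUS_OVER_ZERO", value = NA_real_))
    list(kind = "FINITE", value = np / nm)
}
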