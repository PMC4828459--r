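#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

.CONDITIONS <- c("PLUS", "MINUS")
.EXCLUSION_REASONS <- c("RIBOSOMAL", "THIOESTER")
.CATEGORIES <- c("HIGH", "MEDIUM", "REMOVED_SINGLETON", "EXCLUDED",
                 "NOT_CANDIDATE")
.SUBTYPES <- c("PLUS_ONLY", "RATIO", "NONE")
.RATIO_KINDS <- c("FINITE", "ONLY_PLUS", "ONLY_MINUS", "PLUS_OVER_ZERO")
.TRUTH_CLASSES <- c("TRUE_ACYL_EXCLUSIVE", "TRUE_ACYL_ENRICHED",
                    "NONSPECIFIC", "CONTAMINANT_RIBOSOMAL", "LOW_EVIDENCE")

#' Parameters for spectral counting and candidate selection
#'
#' Holds the four thresholds of the selection procedure: the protein- and
#' peptide-level probability cutoffs applied when deciding which
#' peptide-spectrum matches (PSMs) are confident, the spectrum-level
#' probability cutoff applied when indexing spectra for counting, and the
#' +Hyd/-Hyd normalized spectral count ratio above which a protein detected
#' in both conditions still qualifies as enriched.
#'
#' Probability cutoffs are inclusive (a record at exactly the cutoff is
#' kept); the spectrum cutoff and the ratio threshold are strict (a spectrum
#' at exactly 0.5, or a ratio of exactly 4, does not qualify).
#'
#' @slot proteinProbCutoff numeric(1) in [0,1]; minimum protein probability.
#' @slot peptideProbCutoff numeric(1) in [0,1]; minimum peptide probability.
#' @slot spectrumProbCutoff numeric(1) in [0,1]; spectra are counted only
#'   when their PSM probability is strictly above this value.
#' @slot ratioThreshold numeric(1) > 0; strict lower bound on the
#'   +Hyd/-Hyd normalized count ratio for ratio-based qualification.
#'
#' @aliases CountingParam-class
#' @seealso [filterConfident()], [countSpectra()], [buildEvidence()]
#' @export CountingParam
#' @exportClass CountingParam
#' @examples
#' CountingParam()
#' CountingParam(ratioThreshold = 10)
CountingParam <- setClass("CountingParam",
    slots = c(proteinProbCutoff = "numeric",
              peptideProbCutoff = "numeric",
              spectrumProbCutoff = "numeric",
              ratioThreshold = "numeric"),
    prototype = prototype(proteinProbCutoff = 0.95,
                          peptideProbCutoff = 0.95,
                          spectrumProbCutoff = 0.5,
                          ratioThreshold = 4))

setValidity("CountingParam", function(object) {
    msg <- character()
    for (s in c("proteinProbCutoff", "peptideProbCutoff",
                "spectrumProbCutoff")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("'%s' must be a single value in [0, 1]", s))
    }
    v <- object@ratioThreshold
    if (length(v) != 1L || is.na(v) || v <= 0)
        msg <- c(msg, "'ratioThreshold' must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' Set of validated peptide-spectrum matches
#'
#' A \code{PSMSet} stores one row per peptide-spectrum match (PSM) across
#' all runs of an acyl-biotin exchange experiment.  Each run is identified
#' by its biological replicate index and condition (\code{PLUS} for
#' hydroxylamine-treated, \code{MINUS} for the untreated control).  A PSM
#' carries the peptide sequence, the accession(s) of the protein(s) the
#' peptide maps to, and three probabilities in [0,1]: the spectrum-level
#' (PSM) probability, the peptide probability and the protein probability,
#' as produced upstream by a PeptideProphet/ProteinProphet-style
#' validation chain.
#'
#' Validity enforces: probabilities in [0,1]; peptide sequences matching
#' \code{^[A-Z]+$}; non-empty, duplicate-free accession lists with no
#' \code{";"} inside an accession (it is the reserved list separator);
#' spectrum identifiers unique within each run; at most one run per
#' (replicate, condition) pair.
#'
#' @slot psm a \code{data.frame} with columns \code{replicate} (integer),
#'   \code{condition} (\code{"PLUS"}/\code{"MINUS"}), \code{spectrum_id},
#'   \code{peptide_sequence}, \code{protein_ids} (list of character
#'   vectors), \code{psm_probability}, \code{peptide_probability},
#'   \code{protein_probability}.
#'
#' @param psm a \code{data.frame} as above; \code{protein_ids} may be given
#'   either as a list column or as \code{";"}-separated strings.
#' @aliases PSMSet-class
#' @seealso [readPSMTable()], [writePSMTable()], [filterConfident()]
#' @export PSMSet
#' @exportClass PSMSet
#' @examples
#' df <- data.frame(replicate = 1L, condition = "PLUS", spectrum_id = "s1",
#'                  peptide_sequence = "AAAK", protein_ids = "P1",
#'                  psm_probability = 0.99, peptide_probability = 0.99,
#'                  protein_probability = 0.99)
#' PSMSet(df)
setClass("PSMSet", slots = c(psm = "data.frame"))

PSMSet <- function(psm = .emptyPSMFrame()) {
    psm <- .normalizePSMFrame(psm)
    new("PSMSet", psm = psm)
}

.PSM_COLUMNS <- c("replicate", "condition", "spectrum_id",
                  "peptide_sequence", "protein_ids", "psm_probability",
                  "peptide_probability", "protein_probability")

.emptyPSMFrame <- function() {
    data.frame(replicate = integer(), condition = character(),
               spectrum_id = character(), peptide_sequence = character(),
               protein_ids = I(list()), psm_probability = numeric(),
               peptide_probability = numeric(),
               protein_probability = numeric())
}

.normalizePSMFrame <- function(psm) {
    stopifnot(is.data.frame(psm))
    missing <- setdiff(.PSM_COLUMNS, names(psm))
    if (length(missing))
        stop("PSM table is missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    psm <- psm[, .PSM_COLUMNS]
    psm$replicate <- as.integer(psm$replicate)
    psm$condition <- as.character(psm$condition)
    psm$spectrum_id <- as.character(psm$spectrum_id)
    psm$peptide_sequence <- as.character(psm$peptide_sequence)
    if (!is.list(psm$protein_ids)) {
        ids <- strsplit(as.character(psm$protein_ids), ";", fixed = TRUE)
        psm$protein_ids <- I(lapply(ids, unique))
    } else {
        psm$protein_ids <- I(lapply(psm$protein_ids,
                                    function(x) unique(as.character(x))))
    }
    rownames(psm) <- NULL
    psm
}

setValidity("PSMSet", function(object) {
    df <- object@psm
    msg <- character()
    missing <- setdiff(.PSM_COLUMNS, names(df))
    if (length(missing))
        return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
    if (nrow(df) == 0L)
        return(TRUE)
    bad <- which(!df$condition %in% .CONDITIONS)
    if (length(bad))
        msg <- c(msg, sprintf("row %d: condition must be PLUS or MINUS",
                              bad[1L]))
    bad <- which(is.na(df$replicate) | df$replicate < 1L)
    if (length(bad))
        msg <- c(msg, sprintf("row %d: replicate must be a positive integer",
                              bad[1L]))
    for (p in c("psm_probability", "peptide_probability",
                "protein_probability")) {
        v <- df[[p]]
        bad <- which(is.na(v) | v < 0 | v > 1)
        if (length(bad))
            msg <- c(msg, sprintf("row %d: %s outside [0, 1]", bad[1L], p))
    }
    bad <- which(!grepl("^[A-Z]+$", df$peptide_sequence))
    if (length(bad))
        msg <- c(msg, sprintf(
            "row %d: peptide_sequence must be a non-empty uppercase string",
            bad[1L]))
    nid <- lengths(df$protein_ids)
    bad <- which(nid == 0L)
    if (length(bad))
        msg <- c(msg, sprintf("row %d: protein_ids must be non-empty",
                              bad[1L]))
    dup <- which(vapply(df$protein_ids, anyDuplicated, 0L) > 0L)
    if (length(dup))
        msg <- c(msg, sprintf("row %d: duplicate accession in protein_ids",
                              dup[1L]))
    semi <- which(vapply(df$protein_ids,
                         function(x) any(grepl(";", x, fixed = TRUE)),
                         logical(1)))
    if (length(semi))
        msg <- c(msg, sprintf(
            "row %d: accession contains the reserved separator ';'",
            semi[1L]))
    run <- paste(df$replicate, df$condition)
    dup <- which(duplicated(paste(run, df$spectrum_id)))
    if (length(dup))
        msg <- c(msg, sprintf("row %d: duplicate spectrum_id within run %s",
                              dup[1L], run[dup[1L]]))
    if (length(msg)) msg else TRUE
})

#' Spectral count matrix over runs
#'
#' A \code{SpectralCountExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are proteins (those identified
#' by at least one unique peptide in at least one run), columns are runs
#' (one per replicate x condition).  Assays:
#' \describe{
#'   \item{\code{raw}}{integer spectral counts: spectra matching the
#'     protein's unique peptides with PSM probability strictly above the
#'     spectrum cutoff.}
#'   \item{\code{normalized}}{\code{raw} divided by the run total (the
#'     normalized spectral count, NSC); all zero when a run counted no
#'     spectra.}
#'   \item{\code{identified}}{logical: the protein had at least one
#'     confident unique-peptide PSM in the run, regardless of whether any
#'     spectrum passed the counting cutoff.}
#'   \item{\code{nUniquePeptides}}{number of distinct unique peptides of
#'     the protein observed confidently in the run.}
#' }
#' \code{rowData} carries \code{uniquePeptides} (the dataset-wide unique
#' peptide set per protein) and \code{peptidesPlus} (distinct unique
#' peptides observed in +Hyd runs, whose length is the peptide tally used
#' by the selection rules).  \code{colData} carries \code{replicate},
#' \code{condition} and \code{total}.  \code{metadata} records the
#' \linkS4class{CountingParam} used and the proteins dropped for lacking
#' unique peptides.
#'
#' @aliases SpectralCountExperiment-class
#' @seealso [countSpectra()], [computeRatio()], [buildEvidence()]
#' @exportClass SpectralCountExperiment
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
    need <- c("raw", "normalized", "identified", "nUniquePeptides")
    if (!all(need %in% names(assays(object))))
        return(paste0("assays must include: ", paste(need, collapse = ", ")))
    cd <- colData(object)
    if (!all(c("replicate", "condition", "total") %in% names(cd)))
        return("colData must have replicate, condition, total")
    raw <- assay(object, "raw")
    if (ncol(object) && any(colSums(raw) != cd$total))
        return("colData total must equal the raw assay column sums")
    TRUE
})

#' Parameters of the synthetic PSM generator
#'
#' Describes a simulated acyl-biotin exchange experiment:
#' \code{nReplicates} biological replicates, each with a +Hyd and a -Hyd
#' run, over proteins planted in five classes.  Per-run spectral counts are
#' Poisson with class- and condition-specific means (\code{lambdaPlus},
#' \code{lambdaMinus}), multiplied by a per-protein, per-replicate
#' log-normal jitter shared between the two conditions of a replicate (the
#' +Hyd and -Hyd aliquots derive from the same biological preparation).
#' Spectra are spread uniformly over each protein's tryptic peptides, a
#' fraction of which is shared with a second protein and therefore
#' discarded downstream.  Probability scores of genuine matches are drawn
#' from a Beta distribution concentrated near 1, decoy (noise) records from
#' one concentrated near 0, so the 0.95/0.5 cutoffs are exercised.
#'
#' Planted classes:
#' \describe{
#'   \item{\code{TRUE_ACYL_EXCLUSIVE}}{S-acylated, absent from controls
#'     (\code{lambdaMinus} fixed at 0).}
#'   \item{\code{TRUE_ACYL_ENRICHED}}{S-acylated but leaking into the
#'     control at a mean fold enrichment above the ratio threshold.}
#'   \item{\code{NONSPECIFIC}}{binds the affinity resin equally in both
#'     conditions.}
#'   \item{\code{CONTAMINANT_RIBOSOMAL}}{abundant ribosomal background;
#'     always written to the generated exclusion list.}
#'   \item{\code{LOW_EVIDENCE}}{exactly one unique peptide in exactly one
#'     +Hyd run; the singleton-removal rule should discard it.}
#' }
#'
#' @slot nReplicates integer(1) >= 1.
#' @slot classCounts named integer(5), proteins per planted class.
#' @slot lambdaPlus,lambdaMinus named numeric(4), mean spectra per protein
#'   and run for the four Poisson classes (LOW_EVIDENCE is handled
#'   separately).
#' @slot peptidesPerProtein integer(1) >= 1.
#' @slot sharedPeptideFraction numeric(1) in [0,1).
#' @slot trueScoreShape,decoyScoreShape numeric(2), Beta shape parameters
#'   for genuine and decoy peptide/spectrum scores.
#' @slot proteinScoreShape numeric(2), Beta shapes for per-run protein
#'   probabilities (multi-peptide proteins score near 1).
#' @slot decoyFraction numeric(1) >= 0, noise records added per run as a
#'   fraction of its genuine records.
#' @slot replicateJitterSD numeric(1) >= 0, sdlog of the per-replicate
#'   abundance jitter.
#' @slot seed integer(1), default RNG seed for [simulateExperiment()].
#'
#' @aliases SimulationParam-class
#' @seealso [simulateExperiment()], [evaluateRecovery()]
#' @export SimulationParam
#' @exportClass SimulationParam
#' @examples
#' SimulationParam(seed = 1)
.SimulationParam <- setClass("SimulationParam",
    slots = c(nReplicates = "integer",
              classCounts = "integer",
              lambdaPlus = "numeric",
              lambdaMinus = "numeric",
              peptidesPerProtein = "integer",
              sharedPeptideFraction = "numeric",
              trueScoreShape = "numeric",
              decoyScoreShape = "numeric",
              proteinScoreShape = "numeric",
              decoyFraction = "numeric",
              replicateJitterSD = "numeric",
              seed = "integer"),
    prototype = prototype(
        nReplicates = 3L,
        classCounts = c(TRUE_ACYL_EXCLUSIVE = 50L, TRUE_ACYL_ENRICHED = 50L,
                        NONSPECIFIC = 50L, CONTAMINANT_RIBOSOMAL = 50L,
                        LOW_EVIDENCE = 50L),
        lambdaPlus = c(TRUE_ACYL_EXCLUSIVE = 20, TRUE_ACYL_ENRICHED = 20,
                       NONSPECIFIC = 10, CONTAMINANT_RIBOSOMAL = 15),
        lambdaMinus = c(TRUE_ACYL_EXCLUSIVE = 0, TRUE_ACYL_ENRICHED = 2.5,
                        NONSPECIFIC = 10, CONTAMINANT_RIBOSOMAL = 15),
        peptidesPerProtein = 8L,
        sharedPeptideFraction = 0.05,
        trueScoreShape = c(50, 1),
        decoyScoreShape = c(1, 20),
        proteinScoreShape = c(200, 1),
        decoyFraction = 0.1,
        replicateJitterSD = 0.3,
        seed = 17L))

SimulationParam <- function(...) {
    args <- list(...)
    for (s in c("nReplicates", "peptidesPerProtein", "seed"))
        if (!is.null(args[[s]]))
            args[[s]] <- as.integer(args[[s]])
    if (!is.null(args$classCounts)) {
        cc <- args$classCounts
        args$classCounts <- stats::setNames(as.integer(cc), names(cc))
    }
    do.call(.SimulationParam, args)
}

setValidity("SimulationParam", function(object) {
    msg <- character()
    if (object@nReplicates < 1L)
        msg <- c(msg, "'nReplicates' must be >= 1")
    cc <- object@classCounts
    if (!setequal(names(cc), .TRUTH_CLASSES) || any(cc < 0L))
        msg <- c(msg, paste0("'classCounts' must be a non-negative vector ",
                             "named by the five planted classes"))
    pois <- setdiff(.TRUTH_CLASSES, "LOW_EVIDENCE")
    for (s in c("lambdaPlus", "lambdaMinus")) {
        v <- slot(object, s)
        if (!all(pois %in% names(v)) || any(v < 0))
            msg <- c(msg, sprintf(
                "'%s' must be non-negative and named for the Poisson classes",
                s))
    }
    if (object@peptidesPerProtein < 1L)
        msg <- c(msg, "'peptidesPerProtein' must be >= 1")
    sf <- object@sharedPeptideFraction
    if (length(sf) != 1L || sf < 0 || sf >= 1)
        msg <- c(msg, "'sharedPeptideFraction' must lie in [0, 1)")
    for (s in c("trueScoreShape", "decoyScoreShape", "proteinScoreShape"))
        if (length(slot(object, s)) != 2L || any(slot(object, s) <= 0))
            msg <- c(msg, sprintf("'%s' must be two positive Beta shapes", s))
    if (object@decoyFraction < 0)
        msg <- c(msg, "'decoyFraction' must be >= 0")
    if (object@replicateJitterSD < 0)
        msg <- c(msg, "'replicateJitterSD' must be >= 0")
    if (length(msg)) msg else TRUE
})
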