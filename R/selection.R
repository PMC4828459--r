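#' Per-protein, per-replicate evidence for the selection rules
#'
#' Digests a \linkS4class{SpectralCountExperiment} into one evidence record
#' per identified protein.  Within each biological replicate, a protein
#' \emph{qualifies} when it is identified only in the +Hyd run of the pair,
#' or when its +Hyd/-Hyd normalized spectral count ratio exceeds the
#' threshold (a zero control count with identification in both runs counts
#' as exceeding any threshold).  The record carries \code{q}, the number of
#' qualifying replicates, and \code{t}, the number of distinct unique
#' peptides observed for the protein across all +Hyd runs — the two
#' quantities the tier rules consume — together with \code{ever_in_minus}
#' and the per-replicate identification, ratio and qualifying detail.
#'
#' @param x a \linkS4class{SpectralCountExperiment}.
#' @param param a \linkS4class{CountingParam}; its \code{ratioThreshold} is
#'   the strict lower bound for ratio-based qualification.
#' @return a \code{DataFrame} with one row per protein: scalar columns
#'   \code{protein_id}, \code{q}, \code{t}, \code{ever_in_minus}, and
#'   matrix columns (one column per replicate) \code{identified_plus},
#'   \code{identified_minus}, \code{qualifying}, \code{ratio_kind},
#'   \code{ratio_value}.
#' @seealso [classifyProteins()]
#' @export
buildEvidence <- function(x, param = CountingParam()) {
    stopifnot(is(x, "SpectralCountExperiment"), is(param, "CountingParam"))
    validObject(param)
    cd <- colData(x)
    reps <- sort(unique(cd$replicate))
    bad <- vapply(reps, function(r)
        any(cd$replicate == r & cd$condition == "MINUS") &&
        !any(cd$replicate == r & cd$condition == "PLUS"), logical(1))
    if (any(bad))
        stop("replicate(s) ", paste(reps[bad], collapse = ", "),
             " have a -Hyd run but no +Hyd run", call. = FALSE)

    proteins <- rownames(x)
    nr <- length(proteins)
    nrep <- length(reps)
    dimn <- list(proteins, paste0("BR", reps))
    idP <- idM <- matrix(FALSE, nr, nrep, dimnames = dimn)
    kind <- matrix(NA_character_, nr, nrep, dimnames = dimn)
    value <- matrix(NA_real_, nr, nrep, dimnames = dimn)
    idMat <- assay(x, "identified")
    normMat <- assay(x, "normalized")
    for (k in seq_along(reps)) {
        jp <- which(cd$replicate == reps[k] & cd$condition == "PLUS")
        jm <- which(cd$replicate == reps[k] & cd$condition == "MINUS")
        p <- if (length(jp)) idMat[, jp] else rep(FALSE, nr)
        m <- if (length(jm)) idMat[, jm] else rep(FALSE, nr)
        idP[, k] <- p
        idM[, k] <- m
        kind[p & !m, k] <- "ONLY_PLUS"
        kind[!p & m, k] <- "ONLY_MINUS"
        both <- p & m
        if (length(jm)) {
            zero <- both & normMat[, jm] == 0
            kind[zero, k] <- "PLUS_OVER_ZERO"
            fin <- both & !zero
            kind[fin, k] <- "FINITE"
            value[fin, k] <- normMat[fin, jp] / normMat[fin, jm]
        }
    }
    qualifying <- (idP & !idM) |
        (!is.na(kind) & kind == "PLUS_OVER_ZERO") |
        (!is.na(kind) & kind == "FINITE" &
             !is.na(value) & value > param@ratioThreshold)
    ev <- DataFrame(protein_id = proteins,
                    q = as.integer(rowSums(qualifying)),
                    t = unname(lengths(rowData(x)$peptidesPlus)),
                    ever_in_minus = rowSums(idM) > 0L,
                    row.names = proteins)
    ev$identified_plus <- idP
    ev$identified_minus <- idM
    ev$qualifying <- qualifying
    ev$ratio_kind <- kind
    ev$ratio_value <- value
    metadata(ev) <- list(param = param, replicates = reps)
    ev
}

.classifyOne <- function(q, t, everInMinus, exclusionReason = NA_character_) {
    trace <- "R1"
    if (!is.na(exclusionReason) && nzchar(exclusionReason) &&
        exclusionReason != "NONE")
        return(list(category = "EXCLUDED", subtype = "NONE",
                    exclusion_reason = exclusionReason, trace = trace))
    trace <- c(trace, "R2")
    if (q == 0L)
        return(list(category = "NOT_CANDIDATE", subtype = "NONE",
                    exclusion_reason = "NONE", trace = trace))
    trace <- c(trace, "R3")
    if (q == 1L && t == 1L)
        return(list(category = "REMOVED_SINGLETON", subtype = "NONE",
                    exclusion_reason = "NONE", trace = trace))
    trace <- c(trace, "R4")
    if (q == 1L && t >= 2L)
        return(list(category = "MEDIUM", subtype = "NONE",
                    exclusion_reason = "NONE", trace = trace))
    trace <- c(trace, "R5")
    if (q >= 2L && t == 1L)
        return(list(category = "MEDIUM", subtype = "NONE",
                    exclusion_reason = "NONE", trace = trace))
    trace <- c(trace, "R6")
    list(category = "HIGH",
         subtype = if (everInMinus) "RATIO" else "PLUS_ONLY",
         exclusion_reason = "NONE", trace = trace)
}

#' Classify a single evidence record
#'
#' Applies the ordered selection decision table to one protein.  Rules are
#' evaluated in order, first match wins, and the trace records the path:
#' \describe{
#'   \item{R1}{on the exclusion list (ribosomal / non-acyl thioester):
#'     \code{EXCLUDED}.}
#'   \item{R2}{no qualifying replicate: \code{NOT_CANDIDATE}.}
#'   \item{R3}{one qualifying replicate, one unique peptide overall:
#'     \code{REMOVED_SINGLETON}.}
#'   \item{R4}{one qualifying replicate, two or more unique peptides:
#'     \code{MEDIUM}.}
#'   \item{R5}{two or more qualifying replicates on a single unique
#'     peptide: \code{MEDIUM}.}
#'   \item{R6}{two or more qualifying replicates and two or more unique
#'     peptides: \code{HIGH}, with subtype \code{PLUS_ONLY} when the
#'     protein was never identified in a control run and \code{RATIO}
#'     otherwise.}
#' }
#'
#' @param q number of qualifying replicates.
#' @param t number of distinct unique peptides across +Hyd runs.
#' @param everInMinus was the protein identified in any -Hyd run?
#' @param exclusionReason \code{NA}/\code{"NONE"} or an exclusion reason
#'   (\code{RIBOSOMAL}, \code{THIOESTER}).
#' @return a list with \code{category}, \code{subtype},
#'   \code{exclusion_reason} and \code{trace} (rule identifiers evaluated,
#'   the last being the rule that fired).
#' @seealso [classifyProteins()]
#' @export
classifyProtein <- function(q, t, everInMinus,
                            exclusionReason = NA_character_) {
    stopifnot(length(q) == 1L, length(t) == 1L, length(everInMinus) == 1L)
    .classifyOne(as.integer(q), as.integer(t), isTRUE(everInMinus),
                 exclusionReason)
}

#' Classify all proteins and tally the tiers
#'
#' Runs the selection decision table (see [classifyProtein()]) over every
#' evidence record and returns the per-protein results together with a
#' summary tally.  Exclusion-list membership dominates: a listed protein is
#' \code{EXCLUDED} regardless of its evidence.
#'
#' @param evidence the \code{DataFrame} from [buildEvidence()].
#' @param exclusions \code{NULL}, or a \code{data.frame} with columns
#'   \code{protein_id} and \code{reason} as returned by
#'   [readExclusions()].
#' @return a \code{DataFrame} sorted by accession with columns
#'   \code{protein_id}, \code{category}, \code{subtype}, \code{q},
#'   \code{t}, \code{ever_in_minus}, \code{exclusion_reason},
#'   \code{rule_trace}; its \code{metadata()$tally} holds the
#'   [classificationSummary()].
#' @export
classifyProteins <- function(evidence, exclusions = NULL) {
    stopifnot(is(evidence, "DataFrame"))
    reason <- rep(NA_character_, nrow(evidence))
    if (!is.null(exclusions) && nrow(exclusions)) {
        stopifnot(all(c("protein_id", "reason") %in% names(exclusions)))
        m <- match(evidence$protein_id, exclusions$protein_id)
        reason[!is.na(m)] <- exclusions$reason[m[!is.na(m)]]
    }
    n <- nrow(evidence)
    res <- vector("list", n)
    for (i in seq_len(n))
        res[[i]] <- .classifyOne(evidence$q[i], evidence$t[i],
                                 evidence$ever_in_minus[i], reason[i])
    out <- DataFrame(
        protein_id = evidence$protein_id,
        category = factor(vapply(res, `[[`, "", "category"),
                          levels = .CATEGORIES),
        subtype = factor(vapply(res, `[[`, "", "subtype"),
                         levels = .SUBTYPES),
        q = evidence$q,
        t = evidence$t,
        ever_in_minus = evidence$ever_in_minus,
        exclusion_reason = vapply(res, `[[`, "", "exclusion_reason"),
        rule_trace = vapply(res, function(r) paste(r$trace, collapse = ">"),
                            ""),
        row.names = evidence$protein_id)
    out <- out[order(out$protein_id), ]
    metadata(out) <- list(
        param = metadata(evidence)$param,
        tally = classificationSummary(out, metadata(evidence)$param))
    out
}

#' Tally a classification
#'
#' Counts proteins per category and per \code{HIGH} subtype, and reports
#' the share of the high probability group detectable only in the +Hyd
#' samples, rounded to a whole percent.
#'
#' @param classification the \code{DataFrame} from [classifyProteins()],
#'   or any data frame with \code{category} and \code{subtype} columns.
#' @param param optional \linkS4class{CountingParam}; when supplied its
#'   thresholds are echoed into the summary for provenance.
#' @return a list: \code{n} (proteins classified), \code{byCategory}
#'   (named counts over the five categories), \code{highSubtype} (counts
#'   of \code{PLUS_ONLY} and \code{RATIO}), \code{pctPlusOnly}
#'   (\code{round(100 * PLUS_ONLY / HIGH)}, \code{NA} when no protein is
#'   \code{HIGH}) and \code{thresholds}.
#' @export
#' @examples
#' ## the study's printed group sizes: 274 of 292 high-probability
#' ## proteins were seen only in +Hyd samples
#' cls <- data.frame(
#'     category = rep("HIGH", 292),
#'     subtype = rep(c("PLUS_ONLY", "RATIO"), c(274, 18)))
#' classificationSummary(cls)$pctPlusOnly
classificationSummary <- function(classification, param = NULL) {
    df <- as.data.frame(classification)
    byCategory <- table(factor(df$category, levels = .CATEGORIES))
    high <- df$subtype[df$category == "HIGH"]
    highSubtype <- table(factor(high, levels = c("PLUS_ONLY", "RATIO")))
    nHigh <- sum(byCategory["HIGH"])
    list(n = nrow(df),
         byCategory = stats::setNames(as.integer(byCategory),
                                      names(byCategory)),
         highSubtype = stats::setNames(as.integer(highSubtype),
                                       names(highSubtype)),
         pctPlusOnly = if (nHigh > 0)
             as.integer(round(100 * highSubtype[["PLUS_ONLY"]] / nHigh))
         else NA_integer_,
         thresholds = if (!is.null(param))
             list(protein_prob = param@proteinProbCutoff,
                  peptide_prob = param@peptideProbCutoff,
                  spectrum_prob = param@spectrumProbCutoff,
                  ratio_threshold = param@ratioThreshold)
         else NULL)
}
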