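#' Tabulate kinases by class
#'
#' Counts kinase accessions per kinase class (the iTAK-style class labels
#' consumed from the kinase table) and per family label.  Applied to the
#' packaged high-probability kinase fixture this reproduces the study's
#' kinase tabulation: 52 kinases in total, 37 of class 1 (transmembrane
#' receptor kinases and relatives), 5 of class 2, 8 of class 4 (mainly
#' calcium-dependent kinases) and 2 of class 5.
#'
#' @param rows a \code{data.frame} as returned by [readKinaseTable()]:
#'   columns \code{family_label}, \code{kinase_class} and
#'   \code{accessions} (list column, non-empty per row).
#' @return a list: \code{total} (all accessions), \code{byClass} (named
#'   integer counts per class) and \code{byFamily} (named counts per
#'   family label).
#' @export
summarizeKinaseClasses <- function(rows) {
    stopifnot(is.data.frame(rows),
              all(c("family_label", "kinase_class", "accessions") %in%
                      names(rows)))
    if (any(lengths(rows$accessions) == 0L))
        stop("every kinase table row must list at least one accession",
             call. = FALSE)
    acc <- unlist(rows$accessions, use.names = FALSE)
    dup <- unique(acc[duplicated(acc)])
    if (length(dup))
        stop("accession(s) repeated across kinase table rows: ",
             paste(dup, collapse = ", "), call. = FALSE)
    nper <- lengths(rows$accessions)
    byClass <- tapply(nper, rows$kinase_class, sum)
    byFamily <- tapply(nper, rows$family_label, sum)
    list(total = length(acc),
         byClass = stats::setNames(as.integer(byClass), names(byClass)),
         byFamily = stats::setNames(as.integer(byFamily), names(byFamily)))
}

.highIds <- function(classification) {
    df <- as.data.frame(classification)
    stopifnot(all(c("protein_id", "category") %in% names(df)))
    df$protein_id[df$category == "HIGH"]
}

#' Overlap between the high probability group and DRM-enriched proteins
#'
#' Cross-tabulates experimentally selected S-acylated proteins (category
#' \code{HIGH}) against proteins flagged as enriched in detergent-resistant
#' membrane microdomains (DRMs) in the annotation table.  Missing flags are
#' treated as not enriched.
#'
#' @param classification the \code{DataFrame} from [classifyProteins()]
#'   (or any data frame with \code{protein_id} and \code{category}).
#' @param annotations annotation \code{data.frame} from
#'   [readAnnotations()].
#' @return a list: \code{n_drm_enriched} (proteins flagged DRM-enriched),
#'   \code{n_overlap} (of those, classified \code{HIGH}),
#'   \code{n_overlap_with_sites} (overlap proteins that also carry at
#'   least one predicted palmitoylation site) and \code{overlap_percent}
#'   (\code{100 * n_overlap / n_drm_enriched}).
#' @export
summarizeDRMOverlap <- function(classification, annotations) {
    stopifnot(is.data.frame(annotations))
    drm <- annotations$drm_enriched
    drm[is.na(drm)] <- FALSE
    drmIds <- annotations$protein_id[drm]
    high <- .highIds(classification)
    overlap <- intersect(drmIds, high)
    sites <- annotations$palm_site_count[
        match(overlap, annotations$protein_id)]
    list(n_drm_enriched = length(drmIds),
         n_overlap = length(overlap),
         n_overlap_with_sites = sum(!is.na(sites) & sites >= 1L),
         overlap_percent = if (length(drmIds))
             100 * length(overlap) / length(drmIds) else NA_real_)
}

#' Descriptive report on the high probability group
#'
#' Restricted to proteins classified \code{HIGH}, cross-tabulates the
#' external annotations: functional class composition (percentages to the
#' whole percent), the transmembrane domain distribution in buckets
#' 0 / 1 / 2-or-more, tallies of proteins with at least one predicted
#' palmitoylation, myristoylation or prenylation site, and the DRM
#' overlap.  Proteins without an annotation row contribute to no tally;
#' annotated proteins with no functional label are reported under
#' \code{"unknown"}.
#'
#' @inheritParams summarizeDRMOverlap
#' @return a list: \code{n_total}, \code{by_functional_class} (list with
#'   \code{counts} and integer \code{percent}), \code{tmd_distribution}
#'   (named counts for \code{"0"}, \code{"1"}, \code{">=2"}),
#'   \code{site_tallies} (\code{palmitoylation}, \code{myristoylation},
#'   \code{prenylation}) and \code{drm_overlap} (see
#'   [summarizeDRMOverlap()]).
#' @export
summarizeReport <- function(classification, annotations) {
    stopifnot(is.data.frame(annotations))
    high <- .highIds(classification)
    nTotal <- length(high)
    ann <- annotations[annotations$protein_id %in% high, , drop = FALSE]

    fc <- ann$functional_class
    fc[is.na(fc)] <- "unknown"
    counts <- if (nrow(ann)) table(fc) else table(character())
    counts <- stats::setNames(as.integer(counts), names(counts))
    percent <- if (nTotal > 0)
        stats::setNames(as.integer(round(100 * counts / nTotal)),
                        names(counts))
    else counts

    tmd <- ann$tmd_count[!is.na(ann$tmd_count)]
    tmdDist <- c("0" = sum(tmd == 0L), "1" = sum(tmd == 1L),
                 ">=2" = sum(tmd >= 2L))

    list(n_total = nTotal,
         by_functional_class = list(counts = counts, percent = percent),
         tmd_distribution = stats::setNames(as.integer(tmdDist),
                                            names(tmdDist)),
         site_tallies = list(
             palmitoylation = sum(ann$palm_site_count >= 1L, na.rm = TRUE),
             myristoylation = sum(ann$myristoylated, na.rm = TRUE),
             prenylation = sum(ann$prenylated, na.rm = TRUE)),
         drm_overlap = summarizeDRMOverlap(classification, annotations))
}
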