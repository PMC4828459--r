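#' @rdname PSMSet
#' @param object,x an object.
#' @export
setGeneric("psmData", function(x) standardGeneric("psmData"))

#' @describeIn PSMSet the underlying PSM \code{data.frame}
#'   (\code{protein_ids} is a list column).
#' @export
setMethod("psmData", "PSMSet", function(x) x@psm)

#' @describeIn PSMSet number of PSM records.
#' @export
setMethod("length", "PSMSet", function(x) nrow(x@psm))

#' @describeIn PSMSet one row per run present in the set, with columns
#'   \code{replicate}, \code{condition} and \code{n} (records in the run).
#' @export
setGeneric("runTable", function(x) standardGeneric("runTable"))

#' @rdname PSMSet
#' @export
setMethod("runTable", "PSMSet", function(x) {
    df <- x@psm
    if (nrow(df) == 0L)
        return(data.frame(replicate = integer(), condition = character(),
                          n = integer()))
    tab <- as.data.frame(table(replicate = df$replicate,
                               condition = df$condition),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, ]
    out <- data.frame(replicate = as.integer(tab$replicate),
                      condition = tab$condition, n = as.integer(tab$Freq))
    out[order(out$replicate, out$condition, method = "radix",
              decreasing = c(FALSE, TRUE)), , drop = FALSE]
})

setMethod("show", "PSMSet", function(object) {
    rt <- runTable(object)
    cat(sprintf("PSMSet with %d records across %d run(s)\n",
                length(object), nrow(rt)))
    if (nrow(rt)) {
        lab <- sprintf("%sHyd_%d", ifelse(rt$condition == "PLUS", "+", "-"),
                       rt$replicate)
        cat("  runs:", paste(sprintf("%s (%d)", lab, rt$n), collapse = ", "),
            "\n")
    }
})

setMethod("show", "CountingParam", function(object) {
    cat("CountingParam\n")
    cat(sprintf("  protein probability cutoff:  >= %g\n",
                object@proteinProbCutoff))
    cat(sprintf("  peptide probability cutoff:  >= %g\n",
                object@peptideProbCutoff))
    cat(sprintf("  spectrum probability cutoff: >  %g\n",
                object@spectrumProbCutoff))
    cat(sprintf("  +Hyd/-Hyd ratio threshold:   >  %g\n",
                object@ratioThreshold))
})

#' @rdname CountingParam
#' @param x a \code{CountingParam}.
#' @return \code{ratioThreshold}, \code{proteinProbCutoff},
#'   \code{peptideProbCutoff} and \code{spectrumProbCutoff} return the
#'   corresponding threshold.
#' @export
setGeneric("ratioThreshold", function(x) standardGeneric("ratioThreshold"))

#' @rdname CountingParam
#' @export
setMethod("ratioThreshold", "CountingParam", function(x) x@ratioThreshold)

#' @rdname CountingParam
#' @export
setGeneric("proteinProbCutoff",
           function(x) standardGeneric("proteinProbCutoff"))

#' @rdname CountingParam
#' @export
setMethod("proteinProbCutoff", "CountingParam",
          function(x) x@proteinProbCutoff)

#' @rdname CountingParam
#' @export
setGeneric("peptideProbCutoff",
           function(x) standardGeneric("peptideProbCutoff"))

#' @rdname CountingParam
#' @export
setMethod("peptideProbCutoff", "CountingParam",
          function(x) x@peptideProbCutoff)

#' @rdname CountingParam
#' @export
setGeneric("spectrumProbCutoff",
           function(x) standardGeneric("spectrumProbCutoff"))

#' @rdname CountingParam
#' @export
setMethod("spectrumProbCutoff", "CountingParam",
          function(x) x@spectrumProbCutoff)

#' @rdname SpectralCountExperiment
#' @param x a \code{SpectralCountExperiment}.
#' @return \code{rawCounts} and \code{normCounts} return the integer and
#'   normalized count matrices; \code{identifiedMatrix} the logical
#'   identification matrix.
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname SpectralCountExperiment
#' @export
setMethod("rawCounts", "SpectralCountExperiment",
          function(x) assay(x, "raw"))

#' @rdname SpectralCountExperiment
#' @export
setGeneric("normCounts", function(x) standardGeneric("normCounts"))

#' @rdname SpectralCountExperiment
#' @export
setMethod("normCounts", "SpectralCountExperiment",
          function(x) assay(x, "normalized"))

#' @rdname SpectralCountExperiment
#' @export
setGeneric("identifiedMatrix",
           function(x) standardGeneric("identifiedMatrix"))

#' @rdname SpectralCountExperiment
#' @export
setMethod("identifiedMatrix", "SpectralCountExperiment",
          function(x) assay(x, "identified"))
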