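# Independent brute-force re-implementation of counting, evidence and
# classification, written as literal nested loops over the rule text.  It
# shares no code with the package and is deliberately naive; it is only
# ever run on small datasets.

oracleEvaluate <- function(df, proteinProb = 0.95, peptideProb = 0.95,
                           spectrumProb = 0.5, ratioThr = 4,
                           excluded = character()) {
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df)))
        keep[i] <- df$protein_probability[i] >= proteinProb &&
            df$peptide_probability[i] >= peptideProb
    conf <- df[keep, , drop = FALSE]

    # dataset-wide peptide ownership
    peps <- unique(conf$peptide_sequence)
    ownersOf <- function(pep) {
        os <- character()
        for (i in seq_len(nrow(conf)))
            if (conf$peptide_sequence[i] == pep)
                os <- union(os, conf$protein_ids[[i]])
        sort(os)
    }
    owners <- lapply(peps, ownersOf)
    names(owners) <- peps
    allProt <- sort(unique(unlist(conf$protein_ids)))
    uniquePeps <- function(p) {
        out <- character()
        for (pep in peps)
            if (length(owners[[pep]]) == 1L && owners[[pep]] == p)
                out <- c(out, pep)
        sort(out)
    }
    umap <- lapply(allProt, uniquePeps)
    names(umap) <- allProt
    inMap <- allProt[vapply(umap, length, 0L) > 0L]
    dropped <- setdiff(allProt, inMap)

    reps <- sort(unique(df$replicate))
    rawOf <- function(p, r, cond) {
        n <- 0L
        for (i in seq_len(nrow(conf)))
            if (conf$replicate[i] == r && conf$condition[i] == cond &&
                conf$peptide_sequence[i] %in% umap[[p]] &&
                conf$psm_probability[i] > spectrumProb)
                n <- n + 1L
        n
    }
    identifiedIn <- function(p, r, cond) {
        for (i in seq_len(nrow(conf)))
            if (conf$replicate[i] == r && conf$condition[i] == cond &&
                conf$peptide_sequence[i] %in% umap[[p]])
                return(TRUE)
        FALSE
    }
    runTotal <- function(r, cond) {
        tot <- 0L
        for (p in inMap) tot <- tot + rawOf(p, r, cond)
        tot
    }

    evidence <- list()
    for (p in inMap) {
        q <- 0L
        everMinus <- FALSE
        identifiedAnywhere <- FALSE
        plusPeps <- character()
        perRep <- list()
        for (r in reps) {
            idP <- identifiedIn(p, r, "PLUS")
            idM <- identifiedIn(p, r, "MINUS")
            identifiedAnywhere <- identifiedAnywhere || idP || idM
            if (idM) everMinus <- TRUE
            if (idP)
                for (i in seq_len(nrow(conf)))
                    if (conf$replicate[i] == r &&
                        conf$condition[i] == "PLUS" &&
                        conf$peptide_sequence[i] %in% umap[[p]])
                        plusPeps <- union(plusPeps,
                                          conf$peptide_sequence[i])
            qual <- FALSE
            kind <- NA_character_
            val <- NA_real_
            if (idP && !idM) {
                kind <- "ONLY_PLUS"
                qual <- TRUE
            } else if (!idP && idM) {
                kind <- "ONLY_MINUS"
            } else if (idP && idM) {
                totP <- runTotal(r, "PLUS")
                totM <- runTotal(r, "MINUS")
                nP <- if (totP > 0) rawOf(p, r, "PLUS") / totP else 0
                nM <- if (totM > 0) rawOf(p, r, "MINUS") / totM else 0
                if (nM == 0) {
                    kind <- "PLUS_OVER_ZERO"
                    qual <- TRUE
                } else {
                    kind <- "FINITE"
                    val <- nP / nM
                    if (val > ratioThr) qual <- TRUE
                }
            }
            if (qual) q <- q + 1L
            perRep[[as.character(r)]] <- list(idP = idP, idM = idM,
                                              kind = kind, value = val,
                                              qual = qual)
        }
        if (!identifiedAnywhere) next
        evidence[[p]] <- list(q = q, t = length(plusPeps),
                              everMinus = everMinus, perRep = perRep)
    }

    classify <- function(p, e) {
        if (p %in% excluded) return("EXCLUDED")
        if (e$q == 0L) return("NOT_CANDIDATE")
        if (e$q == 1L && e$t == 1L) return("REMOVED_SINGLETON")
        if (e$q == 1L && e$t >= 2L) return("MEDIUM")
        if (e$q >= 2L && e$t == 1L) return("MEDIUM")
        "HIGH"
    }
    categories <- vapply(names(evidence), function(p)
        classify(p, evidence[[p]]), "")
    subtype <- vapply(names(evidence), function(p) {
        if (categories[[p]] != "HIGH") "NONE"
        else if (evidence[[p]]$everMinus) "RATIO" else "PLUS_ONLY"
    }, "")
    list(dropped = dropped, evidence = evidence,
         categories = categories, subtype = subtype,
         rawOf = rawOf, identifiedIn = identifiedIn)
}
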