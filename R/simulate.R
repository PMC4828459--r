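## Deterministic distinct tryptic-like peptide sequences: the peptide body
## encodes an integer over an 18-letter alphabet (K and R reserved for the
## C-terminal residue), so no two peptide indices ever collide.
.PEPTIDE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                       "N", "P", "Q", "S", "T", "V", "W", "Y")

.peptideSeq <- function(k) {
    n <- length(.PEPTIDE_ALPHABET)
    k <- k - 1L
    body <- character(length(k))
    for (pos in 1:6) {
        body <- paste0(.PEPTIDE_ALPHABET[(k %% n) + 1L], body)
        k <- k %/% n
    }
    paste0(body, "K")
}

.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    force(expr)
}

#' Simulate a seeded ABE spectral-counting experiment
#'
#' Generates PSM tables for \code{nReplicates} biological replicates, each
#' with a +Hyd and a -Hyd run, over proteins planted in the five classes
#' described in \linkS4class{SimulationParam}, together with the planted
#' truth and the exclusion list (all ribosomal contaminants).  Spectrum
#' counts per protein and run are Poisson with class/condition means,
#' modulated by a per-protein, per-replicate log-normal jitter shared by
#' the two conditions of a replicate; spectra are spread uniformly over
#' the protein's peptides; a configured fraction of peptides is shared
#' with a second protein.  Genuine records draw their peptide and spectrum
#' probabilities from the true-score Beta distribution and per-run protein
#' probabilities from the protein-score distribution; injected decoy
#' records draw all three from the decoy distribution.  LOW_EVIDENCE
#' proteins emit spectra of exactly one unique peptide in exactly one
#' +Hyd run.  The same parameters and seed always reproduce the output
#' byte for byte.
#'
#' @param param a \linkS4class{SimulationParam}.
#' @param seed integer RNG seed; defaults to the seed stored in
#'   \code{param}.  The caller's RNG state is restored on exit.
#' @return a list with elements \code{psms} (a \linkS4class{PSMSet} over
#'   all runs), \code{truth} (\code{data.frame} with \code{protein_id},
#'   \code{class}) and \code{exclusions} (\code{data.frame} with
#'   \code{protein_id}, \code{reason}).
#' @seealso [evaluateRecovery()], [runPipeline()]
#' @export
#' @examples
#' sim <- simulateExperiment(SimulationParam(
#'     classCounts = c(TRUE_ACYL_EXCLUSIVE = 5, TRUE_ACYL_ENRICHED = 5,
#'                     NONSPECIFIC = 5, CONTAMINANT_RIBOSOMAL = 2,
#'                     LOW_EVIDENCE = 3), seed = 1))
#' sim$psms
simulateExperiment <- function(param = SimulationParam(),
                               seed = param@seed) {
    stopifnot(is(param, "SimulationParam"))
    validObject(param)
    cc <- param@classCounts[.TRUTH_CLASSES]
    if (sum(cc) == 0L)
        stop("empty experiment: all class counts are zero", call. = FALSE)
    .withSeed(seed, .simulate(param, cc))
}

.simulate <- function(param, cc) {
    nProt <- sum(cc)
    cls <- rep(names(cc), cc)
    ids <- sprintf("SIM%04d", seq_len(nProt))
    nPep <- param@peptidesPerProtein
    pepStart <- (seq_len(nProt) - 1L) * nPep  # peptide k of protein i is
                                              # pepStart[i] + k
    isLow <- cls == "LOW_EVIDENCE"

    # peptide ownership; shared peptides restricted to multi-peptide
    # (non-LOW_EVIDENCE) proteins so LOW_EVIDENCE keeps its single unique
    # peptide by construction
    totalPep <- nProt * nPep
    owner2 <- integer(totalPep)          # 0 = not shared
    poolProt <- which(!isLow)
    poolPep <- as.vector(outer(seq_len(nPep), pepStart[poolProt], "+"))
    # decoy (noise) matches are drawn against proteins expected in the
    # sample of that condition, so a protein absent from the control never
    # acquires -Hyd records
    minusProt <- which(!isLow & param@lambdaMinus[cls] > 0)
    poolPepMinus <- as.vector(outer(seq_len(nPep), pepStart[minusProt],
                                    "+"))
    if (length(poolProt) >= 2L && param@sharedPeptideFraction > 0) {
        nShared <- floor(param@sharedPeptideFraction * length(poolPep))
        if (nShared > 0L) {
            sharedPep <- sort(sample(poolPep, nShared))
            firstOwner <- ((sharedPep - 1L) %/% nPep) + 1L
            for (k in seq_len(nShared)) {
                cand <- setdiff(poolProt, firstOwner[k])
                owner2[sharedPep[k]] <- cand[sample.int(length(cand), 1L)]
            }
        }
    }

    nrep <- param@nReplicates
    jitter <- matrix(stats::rlnorm(nProt * nrep, 0,
                                   param@replicateJitterSD),
                     nProt, nrep)
    lamP <- param@lambdaPlus[cls]
    lamM <- param@lambdaMinus[cls]
    lamP[isLow] <- 0
    lamM[isLow] <- 0

    lowRun <- integer(nProt)
    lowCount <- integer(nProt)
    if (any(isLow)) {
        lowRun[isLow] <- sample.int(nrep, sum(isLow), replace = TRUE)
        lowCount[isLow] <- 1L + stats::rpois(sum(isLow), 1)
    }

    ts <- param@trueScoreShape
    ds <- param@decoyScoreShape
    ps <- param@proteinScoreShape

    runFrames <- list()
    for (r in seq_len(nrep)) {
        for (cond in c("PLUS", "MINUS")) {
            lam <- if (cond == "PLUS") lamP else lamM
            n <- stats::rpois(nProt, lam * jitter[, r])
            if (cond == "PLUS" && any(isLow))
                n[isLow & lowRun == r] <- lowCount[isLow & lowRun == r]
            protProb <- stats::rbeta(nProt, ps[1L], ps[2L])
            tot <- sum(n)
            pidx <- rep.int(seq_len(nProt), n)
            if (tot > 0L) {
                off <- sample.int(nPep, tot, replace = TRUE)
                off[isLow[pidx]] <- 1L  # the designated singleton peptide
                pepIdx <- pepStart[pidx] + off
            } else {
                pepIdx <- integer()
            }
            nDecoy <- as.integer(round(param@decoyFraction * tot))
            pool <- if (cond == "PLUS") poolPep else poolPepMinus
            dPep <- if (nDecoy > 0L && length(pool))
                sample(pool, nDecoy, replace = TRUE) else integer()
            allPep <- c(pepIdx, dPep)
            if (length(allPep) == 0L)
                next
            ownA <- ((allPep - 1L) %/% nPep) + 1L
            ownB <- owner2[allPep]
            proteinIds <- ifelse(ownB > 0L,
                                 paste(ids[ownA], ids[ownB], sep = ";"),
                                 ids[ownA])
            isTrue <- c(rep(TRUE, tot), rep(FALSE, nDecoy))
            pepProb <- ifelse(isTrue,
                              stats::rbeta(length(allPep), ts[1L], ts[2L]),
                              stats::rbeta(length(allPep), ds[1L], ds[2L]))
            psmProb <- ifelse(isTrue,
                              stats::rbeta(length(allPep), ts[1L], ts[2L]),
                              stats::rbeta(length(allPep), ds[1L], ds[2L]))
            prProb <- ifelse(isTrue, protProb[ownA],
                             stats::rbeta(length(allPep), ds[1L], ds[2L]))
            runFrames[[length(runFrames) + 1L]] <- data.frame(
                replicate = r,
                condition = cond,
                spectrum_id = sprintf("%sHyd_%d.%05d",
                                      if (cond == "PLUS") "p" else "m",
                                      r, seq_along(allPep)),
                peptide_sequence = .peptideSeq(allPep),
                protein_ids = proteinIds,
                psm_probability = psmProb,
                peptide_probability = pepProb,
                protein_probability = prProb,
                stringsAsFactors = FALSE)
        }
    }
    psm <- if (length(runFrames)) do.call(rbind, runFrames) else
        .emptyPSMFrame()
    list(psms = PSMSet(psm),
         truth = data.frame(protein_id = ids, class = cls,
                            stringsAsFactors = FALSE),
         exclusions = data.frame(
             protein_id = ids[cls == "CONTAMINANT_RIBOSOMAL"],
             reason = rep("RIBOSOMAL",
                          sum(cls == "CONTAMINANT_RIBOSOMAL")),
             stringsAsFactors = FALSE))
}

#' Score a classification against the planted truth
#'
#' Compares pipeline output with the generator's planted classes.
#' Sensitivity is the fraction of planted S-acylated proteins
#' (\code{TRUE_ACYL_EXCLUSIVE} and \code{TRUE_ACYL_ENRICHED}) recovered in
#' the \code{HIGH} or \code{MEDIUM} tier; the false-discovery proportion
#' is the fraction of the \code{HIGH}/\code{MEDIUM} set planted as
#' \code{NONSPECIFIC} or \code{CONTAMINANT_RIBOSOMAL}.  A planted protein
#' that was never identified (for example because all its matches fell
#' below the probability cutoffs) counts against sensitivity and appears
#' in the confusion table under \code{UNDETECTED}.
#'
#' @param classification the \code{DataFrame} from [classifyProteins()]
#'   (or a data frame with \code{protein_id} and \code{category}).
#' @param truth the \code{truth} data frame from [simulateExperiment()].
#' @return a list: \code{sensitivity},
#'   \code{false_discovery_proportion} and \code{confusion} (a planted
#'   class x category contingency table).
#' @export
evaluateRecovery <- function(classification, truth) {
    df <- as.data.frame(classification)
    stopifnot(all(c("protein_id", "category") %in% names(df)),
              all(c("protein_id", "class") %in% names(truth)))
    unknown <- setdiff(df$protein_id, truth$protein_id)
    if (length(unknown))
        stop("classified accession(s) absent from the truth table: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    cat4 <- as.character(df$category)[match(truth$protein_id,
                                            df$protein_id)]
    cat4[is.na(cat4)] <- "UNDETECTED"
    selected <- cat4 %in% c("HIGH", "MEDIUM")
    isTrueAcyl <- truth$class %in% c("TRUE_ACYL_EXCLUSIVE",
                                     "TRUE_ACYL_ENRICHED")
    isFalse <- truth$class %in% c("NONSPECIFIC", "CONTAMINANT_RIBOSOMAL")
    list(
        sensitivity = if (any(isTrueAcyl))
            mean(selected[isTrueAcyl]) else NA_real_,
        false_discovery_proportion = if (any(selected))
            mean(isFalse[selected]) else 0,
        confusion = table(
            planted = factor(truth$class, levels = .TRUTH_CLASSES),
            category = factor(cat4,
                              levels = c(.CATEGORIES, "UNDETECTED"))))
}
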