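# In-code fixtures: a terse PSM row builder and a random small-dataset
# generator kept independent of the package's own simulator.

psmRow <- function(rep, cond, spec, pep, prots, psm = 0.99, pept = 0.99,
                   prot = 0.99) {
    data.frame(replicate = as.integer(rep), condition = cond,
               spectrum_id = spec, peptide_sequence = pep,
               protein_ids = I(list(prots)), psm_probability = psm,
               peptide_probability = pept, protein_probability = prot,
               stringsAsFactors = FALSE)
}

psmFrame <- function(...) do.call(rbind, list(...))

kinaseFixture <- function()
    readKinaseTable(system.file("extdata", "table1_kinases.tsv",
                                package = "abeSelect"))

drmFixture <- function()
    utils::read.delim(system.file("extdata", "table2_drm.tsv",
                                  package = "abeSelect"),
                      stringsAsFactors = FALSE)

# annotation frame with every column present and given defaults
annFrame <- function(protein_id, functional_class = NA, tmd_count = NA,
                     palm_site_count = NA, myristoylated = NA,
                     prenylated = NA, drm_enriched = NA) {
    n <- length(protein_id)
    data.frame(protein_id = protein_id,
               functional_class = rep(as.character(functional_class),
                                      length.out = n),
               kinase_family = rep(NA_character_, n),
               kinase_class = rep(NA_integer_, n),
               tmd_count = rep(as.integer(tmd_count), length.out = n),
               palm_site_count = rep(as.integer(palm_site_count),
                                     length.out = n),
               myristoylated = rep(as.logical(myristoylated),
                                   length.out = n),
               prenylated = rep(as.logical(prenylated), length.out = n),
               drm_enriched = rep(as.logical(drm_enriched),
                                  length.out = n),
               stringsAsFactors = FALSE)
}

classFrame <- function(protein_id, category)
    data.frame(protein_id = protein_id, category = category,
               subtype = "NONE", stringsAsFactors = FALSE)

# Random dataset over <= nProteins proteins and <= nSpectra spectra; run
# labels span up to 3 replicates x 2 conditions.  Probabilities are drawn
# from a mix that includes the exact cutoff values so boundary behaviour
# is exercised.  Every replicate with a -Hyd run is guaranteed a +Hyd run
# (the pairing the evidence builder requires).
randomPSMFrame <- function(seed, nProteins = 10, nSpectra = 50) {
    set.seed(seed)
    np <- sample(2:nProteins, 1)
    prots <- paste0("P", seq_len(np))
    npep <- sample(3:15, 1)
    peps <- unique(vapply(seq_len(npep), function(i)
        paste0(paste(sample(LETTERS[1:20], 5, replace = TRUE),
                     collapse = ""), "K"), ""))
    owners <- lapply(seq_along(peps), function(i) {
        k <- sample(1:2, 1, prob = c(0.75, 0.25))
        sample(prots, min(k, np))
    })
    ns <- sample(5:nSpectra, 1)
    rows <- vector("list", ns)
    counter <- integer()
    rprob <- function(n) {
        pool <- c(stats::runif(n), rep(c(0.95, 0.949, 0.5, 0.51, 0.99), 2))
        sample(pool, n)
    }
    pr <- rprob(ns); pe <- rprob(ns); ps <- rprob(ns)
    for (i in seq_len(ns)) {
        r <- sample(1:3, 1)
        cond <- sample(c("PLUS", "MINUS"), 1)
        run <- paste(r, cond)
        counter[run] <- if (is.na(counter[run])) 1L else counter[run] + 1L
        j <- sample(seq_along(peps), 1)
        rows[[i]] <- psmRow(r, cond, sprintf("s%03d", counter[[run]]),
                            peps[j], owners[[j]], psm = ps[i], pept = pe[i],
                            prot = pr[i])
    }
    df <- do.call(rbind, rows)
    for (r in unique(df$replicate)) {
        hasMinus <- any(df$replicate == r & df$condition == "MINUS")
        hasPlus <- any(df$replicate == r & df$condition == "PLUS")
        if (hasMinus && !hasPlus) {
            i <- which(df$replicate == r & df$condition == "MINUS")[1L]
            df$condition[i] <- "PLUS"
            df$spectrum_id[i] <- paste0(df$spectrum_id[i], "f")
        }
    }
    df
}
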