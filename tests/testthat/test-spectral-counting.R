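test_that("confidence filtering keeps inclusive 0.95 boundaries", {
    df <- psmFrame(
        psmRow(1, "PLUS", "s1", "AAAK", "P1", pept = 0.95, prot = 0.95),
        psmRow(1, "PLUS", "s2", "AAAK", "P1", pept = 0.949, prot = 0.99),
        psmRow(1, "PLUS", "s3", "AAAK", "P1", pept = 0.99, prot = 0.949),
        psmRow(1, "PLUS", "s4", "AAAK", "P1", pept = 1, prot = 1),
        psmRow(1, "PLUS", "s5", "AAAK", "P1", pept = 0.96, prot = 0.95),
        psmRow(1, "PLUS", "s6", "AAAK", "P1", pept = 0.2, prot = 0.2))
    kept <- filterConfident(PSMSet(df))
    # survivors enumerated by hand: s1, s4, s5 pass both cutoffs
    expect_identical(psmData(kept)$spectrum_id, c("s1", "s4", "s5"))

    # order preserved, empty output allowed
    none <- filterConfident(PSMSet(df),
                            CountingParam(peptideProbCutoff = 1,
                                          proteinProbCutoff = 1))
    expect_identical(length(none), 1L)  # only the (1, 1) record
})

test_that("shared peptides contribute to no protein", {
    df <- psmFrame(
        psmRow(1, "PLUS", "s1", "AAAK", "P1"),
        psmRow(1, "PLUS", "s2", "CCCK", c("P1", "P2")))
    upm <- uniquePeptideMap(PSMSet(df))
    expect_identical(upm$map, list(P1 = "AAAK"))
    expect_identical(upm$dropped, "P2")

    # all peptides shared: empty map, everything dropped
    df2 <- psmFrame(
        psmRow(1, "PLUS", "s1", "AAAK", c("P1", "P2")),
        psmRow(1, "PLUS", "s2", "CCCK", c("P2", "P3")))
    upm2 <- uniquePeptideMap(PSMSet(df2))
    expect_length(upm2$map, 0)
    expect_setequal(upm2$dropped, c("P1", "P2", "P3"))

    # sharing is dataset-wide: the same peptide seen for P1 alone in one
    # run and for P2 in another is still shared
    df3 <- psmFrame(
        psmRow(1, "PLUS", "s1", "AAAK", "P1"),
        psmRow(2, "PLUS", "s1", "AAAK", "P2"),
        psmRow(2, "PLUS", "s2", "CCCK", "P2"))
    upm3 <- uniquePeptideMap(PSMSet(df3))
    expect_identical(names(upm3$map), "P2")
    expect_identical(upm3$map$P2, "CCCK")
})

test_that("unique-peptide maps equal brute-force recomputation", {
    for (seed in 1:25) {
        df <- randomPSMFrame(seed, nProteins = 5)
        conf <- filterConfident(PSMSet(df))
        upm <- uniquePeptideMap(conf)
        oracle <- oracleEvaluate(df)
        expect_setequal(as.character(upm$dropped),
                        as.character(oracle$dropped))
        expect_setequal(as.character(names(upm$map)),
                        as.character(names(oracle$evidence)))
    }
})

test_that("spectra at exactly the 0.5 cutoff are not counted but still identify", {
    df <- psmFrame(
        psmRow(1, "PLUS", "s1", "AAAK", "P1", psm = 0.5),
        psmRow(1, "PLUS", "s2", "CCCK", "P2", psm = 0.51))
    x <- countSpectra(PSMSet(df))
    expect_identical(rawCounts(x)["P1", "+Hyd_1"], 0L)
    expect_identical(rawCounts(x)["P2", "+Hyd_1"], 1L)
    expect_true(all(identifiedMatrix(x)[, "+Hyd_1"]))
})

test_that("normalized counts are fractions of the run total", {
    rows <- c(lapply(1:8, function(i)
        psmRow(1, "PLUS", paste0("a", i), "AAAK", "P1")),
        lapply(1:2, function(i)
            psmRow(1, "PLUS", paste0("b", i), "CCCK", "P2")))
    x <- countSpectra(PSMSet(do.call(rbind, rows)))
    expect_identical(SummarizedExperiment::colData(x)$total, 10L)
    expect_equal(normCounts(x)[, "+Hyd_1"], c(P1 = 0.8, P2 = 0.2))
    expect_equal(sum(normCounts(x)), 1, tolerance = 1e-12)
})

test_that("normalization sums to one on every non-empty run", {
    for (seed in 26:45) {
        x <- countSpectra(PSMSet(randomPSMFrame(seed)))
        tot <- SummarizedExperiment::colData(x)$total
        s <- colSums(normCounts(x))
        expect_equal(unname(s[tot > 0]), rep(1, sum(tot > 0)),
                     tolerance = 1e-12)
        expect_equal(unname(s[tot == 0]), rep(0, sum(tot == 0)))
    }
})

test_that("duplicating every spectrum leaves normalized counts and ratios unchanged", {
    df <- randomPSMFrame(99)
    k <- 3
    dup <- do.call(rbind, lapply(seq_len(k), function(i) {
        d <- df
        d$spectrum_id <- paste0(d$spectrum_id, ".", i)
        d
    }))
    x1 <- countSpectra(PSMSet(df))
    xk <- countSpectra(PSMSet(dup))
    expect_equal(normCounts(xk)[rownames(x1), colnames(x1)],
                 normCounts(x1))
    ev1 <- buildEvidence(x1)
    evk <- buildEvidence(xk)
    fin <- !is.na(ev1$ratio_value)
    expect_equal(evk[rownames(ev1), ]$ratio_value[fin],
                 ev1$ratio_value[fin])
})

test_that("raising the spectrum cutoff never raises any raw count", {
    df <- randomPSMFrame(7)
    cuts <- c(0, 0.3, 0.5, 0.7, 0.95)
    prev <- NULL
    for (cut in cuts) {
        x <- countSpectra(PSMSet(df),
                          CountingParam(spectrumProbCutoff = cut))
        if (!is.null(prev))
            expect_true(all(rawCounts(x) <= prev[rownames(x),
                                                 colnames(x)]))
        prev <- rawCounts(x)
    }
})

test_that("ratio kinds follow identification in the replicate pair", {
    # +Hyd: P1 2/25 = 0.08; -Hyd: P1 1/50 = 0.02 -> FINITE 4.0
    rows <- c(lapply(1:2, function(i)
        psmRow(1, "PLUS", paste0("p", i), "AAAK", "P1")),
        lapply(1:23, function(i)
            psmRow(1, "PLUS", paste0("q", i), "CCCK", "P2")),
        lapply(1:1, function(i)
            psmRow(1, "MINUS", paste0("m", i), "AAAK", "P1")),
        lapply(1:49, function(i)
            psmRow(1, "MINUS", paste0("n", i), "CCCK", "P2")))
    x <- countSpectra(PSMSet(do.call(rbind, rows)))
    r <- computeRatio(x, "P1", 1)
    expect_identical(r$kind, "FINITE")
    expect_equal(r$value, 4.0)

    # identified only in +Hyd
    df <- psmFrame(psmRow(1, "PLUS", "s1", "AAAK", "P1"),
                   psmRow(1, "PLUS", "s2", "AAAK", "P1"),
                   psmRow(1, "MINUS", "s1", "CCCK", "P2"))
    x2 <- countSpectra(PSMSet(df))
    expect_identical(computeRatio(x2, "P1", 1)$kind, "ONLY_PLUS")
    expect_identical(computeRatio(x2, "P2", 1)$kind, "ONLY_MINUS")

    # identified in both but zero counted -Hyd spectra (0.5 exactly)
    df3 <- psmFrame(psmRow(1, "PLUS", "s1", "AAAK", "P1"),
                    psmRow(1, "MINUS", "s1", "AAAK", "P1", psm = 0.5),
                    psmRow(1, "MINUS", "s2", "CCCK", "P2"))
    x3 <- countSpectra(PSMSet(df3))
    expect_identical(computeRatio(x3, "P1", 1)$kind, "PLUS_OVER_ZERO")

    # identified in neither run of the replicate: caller must not ask
    expect_error(computeRatio(x2, "P2", 2), "neither|no runs")
})

test_that("raw counts and identification equal a brute-force tally", {
    for (seed in 46:60) {
        df <- randomPSMFrame(seed, nProteins = 8, nSpectra = 30)
        x <- countSpectra(PSMSet(df))
        oracle <- oracleEvaluate(df)
        cd <- SummarizedExperiment::colData(x)
        for (p in rownames(x)) {
            for (j in seq_len(ncol(x))) {
                expect_identical(rawCounts(x)[p, j],
                                 oracle$rawOf(p, cd$replicate[j],
                                              cd$condition[j]))
                expect_identical(identifiedMatrix(x)[p, j],
                                 oracle$identifiedIn(p, cd$replicate[j],
                                                     cd$condition[j]))
            }
        }
    }
})
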