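evidenceFor <- function(df, param = CountingParam())
    buildEvidence(countSpectra(PSMSet(df), param), param)

test_that("evidence digests qualification per replicate pair", {
    # seen in +Hyd of BR1 only
    df <- psmFrame(psmRow(1, "PLUS", "s1", "AAAK", "P1"),
                   psmRow(1, "MINUS", "s1", "CCCK", "P2"))
    ev <- evidenceFor(df)
    expect_identical(ev["P1", ]$q, 1L)
    expect_false(ev["P1", ]$ever_in_minus)
    expect_identical(ev["P2", ]$q, 0L)
    expect_true(ev["P2", ]$ever_in_minus)

    # a FINITE ratio of exactly 4.0 does not qualify (strict > 4)
    rows <- c(lapply(1:2, function(i)
        psmRow(2, "PLUS", paste0("p", i), "AAAK", "P1")),
        lapply(1:23, function(i)
            psmRow(2, "PLUS", paste0("q", i), "CCCK", "P2")),
        list(psmRow(2, "MINUS", "m1", "AAAK", "P1")),
        lapply(1:49, function(i)
            psmRow(2, "MINUS", paste0("n", i), "CCCK", "P2")))
    ev2 <- evidenceFor(do.call(rbind, rows))
    expect_equal(ev2["P1", ]$ratio_value[, "BR2"], 4.0)
    expect_false(ev2["P1", ]$qualifying[, "BR2"])
    # ... but it does once the threshold is lowered below it
    ev3 <- evidenceFor(do.call(rbind, rows),
                       CountingParam(ratioThreshold = 3.9))
    expect_true(ev3["P1", ]$qualifying[, "BR2"])
})

test_that("a -Hyd run without its +Hyd partner is a configuration error", {
    df <- psmFrame(psmRow(1, "PLUS", "s1", "AAAK", "P1"),
                   psmRow(2, "MINUS", "s1", "AAAK", "P1"))
    x <- countSpectra(PSMSet(df))
    expect_error(buildEvidence(x), "-Hyd run but no \\+Hyd")
})

test_that("the decision table is total and ordered", {
    cases <- list(
        # q, t, everInMinus, exclusionReason -> category, subtype
        list(1, 1, FALSE, NA, "REMOVED_SINGLETON", "NONE"),
        list(1, 1, TRUE, NA, "REMOVED_SINGLETON", "NONE"),
        list(1, 2, FALSE, NA, "MEDIUM", "NONE"),
        list(1, 5, TRUE, NA, "MEDIUM", "NONE"),
        list(2, 1, FALSE, NA, "MEDIUM", "NONE"),
        list(3, 1, TRUE, NA, "MEDIUM", "NONE"),
        list(2, 2, FALSE, NA, "HIGH", "PLUS_ONLY"),
        list(3, 5, FALSE, NA, "HIGH", "PLUS_ONLY"),
        list(2, 2, TRUE, NA, "HIGH", "RATIO"),
        list(0, 0, FALSE, NA, "NOT_CANDIDATE", "NONE"),
        list(0, 3, TRUE, NA, "NOT_CANDIDATE", "NONE"),
        list(3, 5, FALSE, "RIBOSOMAL", "EXCLUDED", "NONE"),
        list(0, 0, FALSE, "THIOESTER", "EXCLUDED", "NONE"))
    for (cs in cases) {
        r <- classifyProtein(cs[[1]], cs[[2]], cs[[3]],
                             exclusionReason = cs[[4]])
        expect_identical(r$category, cs[[5]])
        expect_identical(r$subtype, cs[[6]])
        # trace ends at the rule that fired and walks the order
        expect_identical(r$trace, paste0("R", seq_along(r$trace)))
    }
    expect_identical(classifyProtein(3, 5, FALSE, "RIBOSOMAL")$trace, "R1")
    expect_identical(
        classifyProtein(3, 5, FALSE, "RIBOSOMAL")$exclusion_reason,
        "RIBOSOMAL")
})

test_that("classifyProteins tallies one category per protein", {
    expect_identical(
        classifyProteins(S4Vectors::DataFrame(
            protein_id = character(), q = integer(), t = integer(),
            ever_in_minus = logical()))$protein_id,
        character())

    # one protein per category
    ev <- S4Vectors::DataFrame(
        protein_id = paste0("P", 1:5),
        q = c(3L, 1L, 1L, 3L, 0L),
        t = c(4L, 3L, 1L, 4L, 2L),
        ever_in_minus = c(FALSE, FALSE, FALSE, TRUE, TRUE),
        row.names = paste0("P", 1:5))
    cls <- classifyProteins(
        ev, data.frame(protein_id = "P4", reason = "RIBOSOMAL"))
    expect_identical(
        as.character(cls[paste0("P", 1:5), ]$category),
        c("HIGH", "MEDIUM", "REMOVED_SINGLETON", "EXCLUDED",
          "NOT_CANDIDATE"))
    tally <- S4Vectors::metadata(cls)$tally
    expect_identical(unname(tally$byCategory), rep(1L, 5))
    expect_identical(sum(tally$byCategory), tally$n)
})

test_that("exclusion dominates any strength of evidence", {
    df <- do.call(rbind, c(
        lapply(1:3, function(r) psmRow(r, "PLUS", "s1", "AAAK", "P1")),
        lapply(1:3, function(r) psmRow(r, "PLUS", "s2", "CCCWK", "P1")),
        list(psmRow(1, "MINUS", "s1", "DDDK", "P2"),
             psmRow(1, "PLUS", "s9", "DDDK", "P2"))))
    ev <- evidenceFor(df)
    cls <- classifyProteins(ev, data.frame(protein_id = "P1",
                                           reason = "THIOESTER"))
    expect_identical(as.character(cls["P1", ]$category), "EXCLUDED")
    expect_identical(cls["P1", ]$exclusion_reason, "THIOESTER")
})

test_that("every HIGH/PLUS_ONLY protein has zero -Hyd identifications", {
    nHigh <- 0L
    violations <- 0L
    for (seed in 61:75) {
        df <- randomPSMFrame(seed)
        ev <- evidenceFor(df)
        cls <- classifyProteins(ev)
        high <- cls$protein_id[cls$category == "HIGH"]
        nHigh <- nHigh + length(high)
        for (p in high) {
            inMinus <- any(ev[p, ]$identified_minus)
            sub <- as.character(cls[p, ]$subtype)
            if ((sub == "PLUS_ONLY") == inMinus)
                violations <- violations + 1L
        }
    }
    # a deterministic HIGH/RATIO case so the property is always exercised
    rows <- list()
    for (r in 1:2) rows <- c(rows, list(
        psmRow(r, "PLUS", "a", "AAAGLK", "P1"),
        psmRow(r, "PLUS", "b", "CCWNDK", "P1"),
        psmRow(r, "PLUS", "c", "DDDPLK", "P2"),
        psmRow(r, "MINUS", "a", "AAAGLK", "P1", psm = 0.5),
        psmRow(r, "MINUS", "b", "DDDPLK", "P2")))
    cls <- classifyProteins(evidenceFor(do.call(rbind, rows)))
    expect_identical(as.character(cls["P1", ]$category), "HIGH")
    expect_identical(as.character(cls["P1", ]$subtype), "RATIO")
    expect_identical(violations, 0L)
})

test_that("raising the ratio threshold never adds candidates", {
    for (seed in 76:85) {
        df <- randomPSMFrame(seed)
        sel <- lapply(c(4, 10, 1000), function(thr) {
            ev <- evidenceFor(df, CountingParam(ratioThreshold = thr))
            cls <- classifyProteins(ev)
            cls$protein_id[cls$category %in% c("HIGH", "MEDIUM")]
        })
        expect_true(all(sel[[2]] %in% sel[[1]]))
        expect_true(all(sel[[3]] %in% sel[[2]]))
    }
})

test_that("evidence and categories equal rule-by-rule brute force", {
    for (seed in 86:105) {
        df <- randomPSMFrame(seed, nProteins = 8, nSpectra = 40)
        ev <- evidenceFor(df)
        cls <- classifyProteins(ev)
        oracle <- oracleEvaluate(df)
        expect_setequal(as.character(cls$protein_id),
                        as.character(names(oracle$categories)))
        for (p in cls$protein_id) {
            expect_identical(ev[p, ]$q, oracle$evidence[[p]]$q)
            expect_identical(ev[p, ]$t, oracle$evidence[[p]]$t)
            expect_identical(as.character(cls[p, ]$category),
                             unname(oracle$categories[[p]]))
            expect_identical(as.character(cls[p, ]$subtype),
                             unname(oracle$subtype[[p]]))
        }
    }
})
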