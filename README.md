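# abeSelect

Selection of S-acylated proteins from acyl-biotin exchange (ABE)
proteomics by label-free spectral counting.

## The problem

S-acylation (most commonly palmitoylation) attaches a fatty acid to a
cysteine through a thioester bond and controls membrane targeting and
trafficking of many plant and animal proteins. The ABE assay purifies
formerly S-acylated proteins by blocking free cysteines, cleaving
thioesters with hydroxylamine, and biotinylating the exposed cysteines.
Because the affinity resin also binds proteins nonspecifically, every
biological replicate (BR) is run twice: a hydroxylamine-treated sample
(+Hyd) that captures S-acylated proteins plus background, and an
untreated control (−Hyd) that captures background only. Deciding which
identified proteins are genuinely S-acylated is therefore a statistical
selection problem over paired enrichment/control runs.

`abeSelect` implements that selection for tab-separated tables of
peptide-spectrum matches (PSMs), the export of a
PeptideProphet/ProteinProphet-style validation chain. It is aimed at
proteomics analysts who have spectral-count-level data from an ABE (or
comparable enrichment/control) design and want a reproducible,
rule-traceable classification.

## The method

For each run, PSMs are filtered at protein and peptide probability
≥ 0.95; peptides matching two or more proteins are excluded dataset-wide;
spectra with PSM probability > 0.5 matching a protein's unique peptides
are counted, and counts are normalized to the run total (normalized
spectral count, NSC). Within each replicate the enrichment ratio

    R_br(p) = NSC_+Hyd(p) / NSC_−Hyd(p)

is computed only when protein *p* is identified in both runs of the pair.
A replicate *qualifies* when *p* is found only in +Hyd, or when
R_br(p) > 4. With *q* the number of qualifying replicates and *t* the
number of distinct unique peptides across +Hyd runs, an ordered decision
table assigns each protein one tier:

| rule | condition | outcome |
|------|-----------|---------|
| R1 | on the exclusion list (ribosomal / non-acyl thioester) | EXCLUDED |
| R2 | q = 0 | NOT_CANDIDATE |
| R3 | q = 1, t = 1 | REMOVED_SINGLETON |
| R4 | q = 1, t ≥ 2 | MEDIUM |
| R5 | q ≥ 2, t = 1 | MEDIUM |
| R6 | q ≥ 2, t ≥ 2 | HIGH (subtype PLUS_ONLY or RATIO) |

The package also ships a seeded synthetic PSM generator with five planted
protein classes (exclusively enriched, enriched-but-leaky, nonspecific,
ribosomal contaminant, low-evidence singleton) for validating the
procedure, recovery scoring against the planted truth, and descriptive
cross-tabulations of external annotations (kinase families, TMD counts,
predicted acylation sites, detergent-resistant membrane overlap).

## Worked example

```r
library(abeSelect)

sim <- simulateExperiment(SimulationParam(seed = 17))
sim$psms
#> PSMSet with 15751 records across 6 run(s)
#>   runs: +Hyd_1 (3684), -Hyd_1 (1609), +Hyd_2 (3532), -Hyd_2 (1444),
#>         +Hyd_3 (3883), -Hyd_3 (1599)

res <- runPipeline(sim$psms, exclusions = sim$exclusions)
res$summary$byCategory
#>              HIGH            MEDIUM REMOVED_SINGLETON          EXCLUDED
#>                74                18                47                50
#>     NOT_CANDIDATE
#>                58

rec <- evaluateRecovery(res$classification, sim$truth)
round(c(rec$sensitivity, rec$false_discovery_proportion), 3)
#> [1] 0.92 0.00
```

The simulated experiment plants 50 proteins per class over 3 replicates.
74 + 18 proteins reach the HIGH/MEDIUM tiers (92% of the 100 planted
S-acylated proteins — a handful of leaky enriched proteins drop below the
ratio threshold), all 50 ribosomal contaminants are EXCLUDED via the
exclusion list, all low-evidence singletons that were detected are
REMOVED_SINGLETON, and no nonspecific binder is selected (false-discovery
proportion 0). Each row of `res$classification` carries the rule trace
that produced it, e.g. `R1>R2>R3>R4>R5>R6` for a protein that fell
through to the HIGH rule.

The packaged kinase-family table tabulates the same way as the study it
transcribes:

```r
s <- summarizeKinaseClasses(readKinaseTable(
    system.file("extdata", "table1_kinases.tsv", package = "abeSelect")))
s$total       #> 52
s$byClass     #> 1: 37, 2: 5, 4: 8, 5: 2
```

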