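# checOrigins

Genome-wide mapping of candidate DNA replication origins in budding
yeast from MCM-ChEC fragment data.

## The problem

Only ~350-830 yeast replication origins are annotated, largely because
classical assays see only origins active enough to sustain a plasmid.
Origins are *licensed* by loading of the Mcm2-7 helicase in G1 — a
head-to-head double hexamer covering ~61 bp next to an oriented ARS
consensus sequence (ACS) — so "a site where Mcm is bound in G1" is an
operational origin definition that extends far below the sensitivity of
activity assays.  Chromatin endogenous cleavage (ChEC) tags Mcm with
micrococcal nuclease; activated cleavage releases short fragments exactly
at binding footprints, and paired-end insert sizes peak at the 61 bp
footprint length.

`checOrigins` turns such aligned fragments into a ranked list of
**candidate Mcm binding sites (CMBSs)** and characterizes them, cohort by
cohort down the abundance ranking, with the hallmarks of replication
origins: external replication-activity composites (ssDNA S/G1, BrdU),
nucleosome-free-region architecture, genic/intergenic context and
flanking-gene orientation, flanking ACS motifs and downstream-loading
directionality, GC-skew footprints, and licensing-fraction estimates.
A seeded synthetic-data module emulates every input, so the complete
pipeline is exercisable and testable with no downloads.

## The core algorithm

From 51-100 bp size-selected inserts, two per-base tracks are built —
full-extent coverage `F` (wide, robust) and fragment midpoints `M`
(sharp) — and both are smoothed with a centered 10 bp sliding mean.
Sites are then called iteratively:

1. `c = argmax F` (genome-wide);
2. `m = argmax M` over `[c - 60, c + 60]` — the reported midpoint;
3. record height `F(c)` and abundance = unsmoothed midpoint counts in
   `m ± 30` (the 61 bp double-hexamer footprint);
4. zero `F` and `M` on `[m - 500, m + 500]`;
5. repeat until the global maximum is exhausted; then keep only the
   best-ranked site in the rDNA, drop sites within 100 bp of Ty
   elements, and re-rank consecutively.

Ties break deterministically (chromosome order, then lowest coordinate);
step 4 enforces a minimum inter-site spacing of 441 bp.  ACS scanning
uses the packaged 17-position EACS probability matrix with log2-odds
scores `S = Σ log2((f[i,b]+ε)/(q[b]+ε))`; GC skew is `(G−C)/(G+C)` on
the Watson strand in a 51 bp window; cohort licensing is propagated as
`100 × fraction₁ × relative abundance`.

## Worked example

```r
library(checOrigins)

cfg  <- sim_config(chrom_lengths = c(chrS = 200000L), n_origins = 40)
sim  <- simulate_genome(cfg, seed = 1)
frags <- simulate_fragments(sim$truth, "mcm_chec", 80000, seed = 2)

res <- identify_cmbs(frags, annotation = sim$annotation, cohort_size = 10)
res$cmbs
#> <cmbs_list> 54 candidate Mcm binding site(s)
#>    rank chrom midpoint peak_height abundance cohort
#> 1     1  chrS    87839       10444     10444      1
#> 2     2  chrS    33163        8689      8689      1
#> 3     3  chrS    14111        7176      7176      1
#> ...

head(cohort_table(res$cmbs), 4)
#>   cohort  n median_abundance normalized_median partial
#> 1      1 10           4702.5       100.0000000   FALSE
#> 2      2 10            834.5        17.7458799   FALSE
#> 3      3 10            143.0         3.0409357   FALSE
#> 4      4 10             19.0         0.4040404   FALSE

evaluate_recovery(res$cmbs, sim$truth, tol = 20)[c("n_recovered",
                                                   "spearman_rank_abundance")]
#> recovered 40/40 planted origins; Spearman(rank, abundance) = -0.999

downstream_bias(res$cmbs, sim$annotation$acs)$fraction
#> downstream of ACS: 35/40 = 88%

licensed_percent(0.69, 0.015)
#> [1] 1
```

The ranked list recovers every planted origin within 20 bp, with rank
almost perfectly anti-correlated with planted abundance; cohort medians
(normalized so cohort 1 = 100) fall across the planted three orders of
magnitude; most sites sit downstream of their oriented ACS, as expected
from directional loading by Orc; and a cohort at 1.5 % of cohort-1
abundance with 69 % cohort-1 licensing is licensed in 1.0 % of cells.

Downstream characterization uses the same ranked list:
`cohort_composite()` / `acs_composite()` / `skew_composite()` for
anchor-aligned profiles, `nfr_occupancy_score()` for nucleosome
architecture, `classify_genic()` and `flanking_orientation()` for genic
context, and `fit_licensing_model()` for the abundance-licensing
regression.  See the vignette in `vignettes/mapping-mcm-origins.Rmd` for
the model, parameter meanings, and design notes.

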