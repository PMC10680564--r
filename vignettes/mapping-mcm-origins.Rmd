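---
title: "Mapping candidate replication origins from MCM-ChEC fragment data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping candidate replication origins from MCM-ChEC fragment data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checOrigins)
```

## The measurement and the model

In budding yeast, a DNA replication origin is made competent ("licensed")
by loading of the Mcm2-7 replicative helicase during G1, as a head-to-head
double hexamer that covers about 61 bp of DNA adjacent to an oriented,
AT-rich ARS consensus sequence (ACS) bound by the origin recognition
complex (Orc).  Chromatin endogenous cleavage (ChEC) fuses a Mcm subunit
to micrococcal nuclease; calcium-activated cleavage releases short
(~50-100 bp) fragments precisely at Mcm binding footprints, against a
background of much longer nucleosomal and inter-origin fragments.  After
paired-end sequencing, the insert-size distribution is sharply peaked at
61 bp — the double-hexamer footprint — with a secondary nucleosomal mode
near 165 bp.

`checOrigins` converts aligned paired-end inserts into a ranked,
genome-wide list of **candidate Mcm binding sites (CMBSs)** and then asks,
cohort by cohort down the abundance ranking, whether the sites carry the
hallmarks of replication origins:

* replication activity in external ssDNA (S/G1) or BrdU tracks,
* residence in an intergenic, ~150 bp nucleosome-free region (NFR)
  flanked by positioned nucleosomes,
* flanking ACS motifs in the orientation expected from directional Mcm
  loading by Orc (downstream of the motif),
* an evolutionary GC-skew footprint — skew rising 5'→3' across the
  midpoint on either strand, crossing zero at the initiation point,
* licensing fractions consistent with a linear relation between ChEC
  abundance and the fraction of cells carrying a loaded double hexamer.

## The peak caller

Two depth tracks are built from the 51-100 bp size-selected inserts: a
*full-extent* track (each fragment adds 1 to every covered base; wide and
robust) and a *midpoint* track (each fragment adds 1 at
`start + floor(length/2)`; sharp but noisy).  Both are smoothed with a
centered sliding mean (default width 10 bp, i.e. the centered 11-point
window; at chromosome ends the mean is over the available positions only,
so no signal is invented).  Calling then iterates:

1. find the genome-wide argmax of the smoothed full-extent track;
2. refine: take the argmax of the smoothed midpoint track within 60 bp;
3. record the site there, with the full-track height at selection and an
   *abundance* equal to the unsmoothed midpoint counts in ±30 bp (the
   61 bp double-hexamer footprint);
4. zero both smoothed tracks within 500 bp of the refined coordinate;
5. repeat until the global maximum reaches the stop level.

Argmax ties are broken deterministically (declared chromosome order, then
lowest coordinate), so identical inputs give bitwise-identical output.
Step 4 guarantees that no two sites are closer than
`500 - 60 + 1 = 441` bp.  After calling, all but the best-ranked site in
the rDNA repeat locus are removed, sites within 100 bp of Ty elements are
removed, and survivors are re-ranked consecutively.

The caller maintains per-block maxima (block size 4096) so each exclusion
only invalidates a handful of blocks; the test suite verifies bitwise
equality against a naive implementation that re-scans the genome on every
iteration.

**Stop rule.** The published analysis stopped "when a sharp drop-off
indicated the genome was covered" — a visual criterion.  We expose two
explicit knobs, `min_signal` (default 0: stop when the zeroed track's
global maximum reaches zero) and `max_peaks`, both recorded in the
result's provenance; reproducing a particular published site count on
real data requires tuning one of them.

**Smoothing width.** 10 bp is the calling default; a 200 bp window is
appropriate for display-scale signal profiles and is available through
the same `smooth_track()` parameter.

## Coordinates and file formats

Internally everything is 1-based and closed-interval, the native
convention of the `GenomicRanges`/`Biostrings` stack used for all I/O and
interval arithmetic; BED/bedGraph/BEDPE input and output are converted
from/to their 0-based half-open convention at the boundary.  The fragment
midpoint convention `start + floor(length/2)` is deterministic for
even-length fragments.  bedGraph is written with 17 significant digits so
a write/read round trip reproduces doubles bitwise; zero and no-data runs
are omitted.

## The ACS position-weight matrix

The 17-position EACS probability matrix ships as plain text package data.
Scores are log-odds
$S = \sum_{i=1}^{17} \log_2\frac{f_{i,b_i} + \varepsilon}{q_{b_i} + \varepsilon}$
with uniform background $q$ and pseudocount $\varepsilon = 0.001$ by
default; base, background and pseudocount are configurable.  Published
figures based on this matrix quote a "maximum possible score" of 12.742
and a strong-site threshold of 10.8.  We brute-forced the obvious
conventions (log base 2, e, 10; uniform and AT-rich genomic backgrounds;
pseudocounts 0-0.01) and none reproduces 12.742 — the per-position-max
consensus `TTTTTTTATGTTTAGTT` scores 26.229 bits under log2/uniform/no
pseudocount.  The source convention is evidently different (and not
recoverable from the available description), so the package documents its
own convention explicitly and treats 10.8 as a configurable threshold
rather than a derived quantity.

Both strands are scanned; the Crick score of a window is assigned to the
window's *leftmost* coordinate, the same indexing as Watson, so the two
tracks are directly comparable per offset.  Windows containing non-ACGT
bases, and the trailing 16 positions of each chromosome, are missing.

## Composites

`extract_matrix()` aligns any per-base track to a set of anchors
(CMBS midpoints, ACS positions, ...), reversing rows on "-"-strand
anchors so the offset axis runs 5'→3'; anchors whose window would cross a
chromosome end are dropped and counted.  Column summaries come in three
flavors: plain means (missing data excluded, so sparse microarray-style
tracks are averaged only over covered probes rather than diluted with
zeros), per-row scaling to 100 followed by summation (the cumulative
convention used for ACS-anchored loading-direction profiles), and
per-cohort means with cohort median abundances normalized so cohort 1
is 100.

`nfr_occupancy_score()` summarizes nucleosome architecture at a site as
the ratio of mean dyad signal at the midpoint (±50 bp) to the flanks
(±51-150 bp): ~0 for an NFR with positioned neighbors, ~1 for
indistinct chromatin, >1 for a nucleosome sitting on the site itself.

## GC skew

Skew is `(G - C)/(G + C)` counted on the Watson strand in a centered
51 bp window and assigned to the window's center.  Windows without G or C
return 0; windows containing N, and positions too close to a chromosome
end, are missing.  Composites are computed on the Watson strand only: the
"either strand, 5'→3'" reading follows from exact antisymmetry (computing
skew on the reverse complement and mirroring the offset axis negates the
profile), which the test suite asserts.  Raw windowed values are
averaged, not re-smoothed.  The short central inversion attributable to
the two hexamers crossing over each other is not modeled; the composite
simply reports it when present in the data.

## Licensing

`fit_licensing_model()` is ordinary least squares of measured licensed
fraction on ChEC abundance — deliberately unweighted, as nothing more is
stated about the published fit.  Predictions are clamped to [0, 1] with a
flag.  Because the "cohort-1 licensing" question could mean either the
regression prediction at the cohort median or the median of per-site
predictions, `predict()` is vectorized so both are one line.
`licensed_percent()` performs the propagation to lower cohorts
(`100 x fraction x relative abundance`) and reports one decimal, matching
the precision convention of the published arithmetic (0.69 x 0.015 →
1.0%).

## The synthetic-data generator

`simulate_genome()` and friends emulate the statistical structure the
analysis assumes, at a scale where the full pipeline runs in seconds:

* 1 chromosome x 500 kb, 100 origins, 200k fragments by default;
* planted abundances follow a geometric series across `c(1, 1000)` —
  three orders of magnitude, realized exactly — assigned in random order;
* each origin sits in a 150 bp NFR flanked by dyad arrays at ±115 bp and
  then every 165 bp;
* a PWM-sampled, oriented ACS 17-mer is planted with its window start
  35 bp from the Mcm midpoint, on the side implied by its strand and
  downstream flag; 77% of origins load downstream, the rate observed at
  annotated origins *in vivo* (set `downstream_fraction = 1` for strictly
  directional loading);
* genes tile the non-NFR sequence with strands that make every origin's
  flanks divergently transcribed;
* MCM-ChEC insert lengths: with probability 0.15 an exact 61 bp footprint
  cut, otherwise a discretized Gaussian (mean 61, sd 8) truncated to
  51-100 bp.  The point-mass component reflects the sharply peaked
  observed distribution and makes the *empirical* mode of even a 10^4
  draw reliably 61 — a pure sd-8 Gaussian puts nearly equal mass on
  60/61/62 and its sample mode is a coin flip;
* 20% of MCM-ChEC fragments are nucleosome-length background centered at
  dyads (mostly removed by the 51-100 bp size selection, as in the real
  assay);
* `simulate_ssdna()` produces the *processed* S/G1-ratio style track
  (Gaussian bumps proportional to activity over baseline 1.0, optional
  probe-like sparsity) — it emulates the consumed data product, not fork
  progression or checkpoint biology;
* `plant_gc_skew()` deaminates C→T on the lagging-strand template within
  ±200 bp of each midpoint at rate `q = 2s/(1+s)`, which yields expected
  Watson skew ∓`s` across the midpoint on a base-balanced genome; planted
  ACS motifs are never mutated.

All generators are bitwise-reproducible for a fixed seed.

**What passing synthetic tests does and does not show.**  The generator
plants clean, isolated footprints in uniform-composition background; real
data have multi-scale coverage heterogeneity, repeat families, copy-number
structure, and correlated noise between samples.  Recovery and geometry
results on synthetic data validate the *implementation* (the algorithms
find what was planted, where it was planted, in the right order), not the
biological error rates on real libraries.

**A deliberate artifact worth knowing about.**  Fragment centers are
jittered uniformly within ±3 bp of the planted midpoint, which is
narrower than the 11-point smoothing window.  Every window position whose
span covers the whole ±3 bp cloud therefore ties exactly on the smoothed
midpoint track, and the lowest-coordinate tie-break resolves the tie to
the left edge of the plateau: called midpoints sit systematically ~2 bp
left of the planted ones, and the ACS composite peaks at -33 rather than
-35.  Real data break these ties through dispersed cut positions.  We
keep the documented tie-break (determinism is worth more than 2 bp) and
the narrow jitter (it is the stated planting geometry).

## Problem sizes used by the tests

Module tests run on a 120 kb genome with 24 origins and 60k fragments;
the acceptance-level checks use the full default conditions above (500 kb,
100 origins, 200k fragments) plus 100 random 50-kb tracks for the
caller-vs-oracle equality.  These sizes were chosen so the entire suite
exercises every code path, at full planted dynamic range, in well under a
minute of compute.

## Known limitations

* No statistical significance or FDR is attached to called sites; the
  ranking is exhaustive by design and interpretation is retrospective,
  cohort by cohort.
* Multi-mapping reads are consumed as the aligner emitted them; the rDNA
  filter is the only repeat handling.
* BigWig output is not provided; bedGraph covers the round-trip needs.
* The exact stop condition that produced a particular published site
  count is not recoverable from the method description; on real data the
  count depends on the chosen `min_signal`/`max_peaks`.
* Whether the step-4 refinement shift should also re-center the step-5
  exclusion zone admits two readings; we zero around the refined
  coordinate, as the procedure is written.
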