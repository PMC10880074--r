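---
title: "Predicting off-target promoters of heterologous ECF sigma factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting off-target promoters of heterologous ECF sigma factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecfscan)
```

## The problem

Extracytoplasmic-function (ECF) sigma factors are minimal alternative sigma
factors whose sigma4 and sigma2 domains read a bipartite promoter: a -35
box, a spacer of 15-17 nt, and a -10 box lying 3-6 bases upstream of the
transcription start site (TSS). Because ECF promoter preferences are
group-specific and compact, a heterologous ECF imported into a new host as
part of a genetic switch may recognise *off-target* sites in the host
genome and drive unintended transcription. `ecfscan` implements a
computational pipeline to quantify that risk:

1. **TSS detection** from Cappable-seq-style per-base 5'-end read counts in
   an ECF-overexpression sample versus a control;
2. **bipartite PSSM scanning** of TSS-anchored upstream windows and of
   windows around all annotated features, with empirical E-values from
   composition-matched shuffles;
3. **cutoff calibration**: Pareto-optimal promoter hits upstream of
   operons/monocistrons up-regulated in a differential-expression (DE)
   experiment supply "worst value" score cutoffs, relaxed by an
   uncertainty factor;
4. **genome-wide prediction** of off-target promoters passing all cutoffs.

Because the pipeline's inputs are large sequencing data sets, the package
ships a fully specified synthetic-data generator with known ground truth,
so every stage is testable end to end by parameter recovery.

## Scores and matrices

A promoter box is modelled as a position-specific scoring matrix (PSSM) of
per-column base log-probabilities. We fix **base 2** throughout: any base
is monotone-equivalent for ranking, Pareto fronts and E-values, but fixing
one makes printed scores comparable across runs. A box score is the sum of
the log-probabilities of the observed bases, so scores are always
non-positive and a score nearer 0 means greater similarity to the motif
(log-probability semantics, not log-odds). The total promoter score of a
placement is the sum of the -35 and -10 box scores.

Count or frequency matrices are converted with a per-column pseudocount
`eps` (default 0.01): `log2((f + eps) / (1 + 4 * eps))`, which renormalises
each column exactly and avoids infinite penalties in sparse columns. The
consensus of a PSSM (ties broken alphabetically A < C < G < T) attains the
maximal score; this is verified exhaustively in the tests.

## TSS detection

For each genomic base the 5'-end read count `Rns` is normalised to the
relative read score `RRS = (Rns / Rt) * 1e6`, with `Rt` the sample's total
mapped TSS reads (whole sample: all replicons, both strands). Neighbouring
TSS form a cluster when the positional difference between neighbours does
not exceed 3 nt (a difference of exactly 3 joins, 4 splits); the maximal-
`Rns` member is the cluster's dominant TSS, ties going to the 5'-most
member on the strand. Dominant TSS with RRS >= 3.0 (the default of the
thresholds 1.5/3.0/7.5) are retained. A TSS is *strain-specific* to the
overexpression sample when the control has no threshold-passing TSS on the
same contig and strand within +/-3 nt -- the tolerance deliberately mirrors
the cluster gap, since presence/absence matching needs some positional
slack. Strands never cluster together.

## Promoter scanning and empirical E-values

Windows are always handled in transcription orientation (minus-strand
windows are reverse-complemented), so the box order in a window is
-35 -> spacer -> -10 -> TSS. Within a window every placement with spacer in
[15, 17] is enumerated; when the window is anchored on a TSS (40 nt
windows including the TSS base), the placement must additionally leave 3-6
bases *strictly between* the -10 box end and the TSS. We adopt the
strictly-between reading of the "3 to 6 nt between the end of the -10
motif and the TSS" geometry and apply it consistently in the scanner and
the synthetic generator. Offsets in a window are 1-based, the R
convention; all genomic coordinates are 1-based inclusive forward-strand,
except BED/bedGraph files which follow their own standards.

The best placement maximises the total score; exact ties prefer the
smaller spacer, then the placement closest to the TSS/3' end. Both choices
are arbitrary but fixed and documented, and matter only for degenerate
(e.g. uniform) matrices.

The significance of a hit is an **empirical E-value**: the fraction of
`n = 1000` random sequences with the *same mononucleotide composition* as
the window whose best score (under the same scan mode, anchored or free)
is at least the observed total. We use exact shuffles -- uniform random
permutations of the window's own bases -- rather than i.i.d. draws from
the empirical composition, reading "same mononucleotide distribution"
strictly; the null therefore conditions on the realised base counts. The
plain `k/n` estimator is used so that 0 is attainable ("probability of
observing scores at least as extreme"); a `(k+1)/(n+1)` variant is
available via `laplace = TRUE`. Anchored hits with E-value <= 0.05 are
retained. Because the observed window is exchangeable with its own
shuffles under the null, the retention probability of a truly random
window is `51/1001` at `n = 1000`, i.e. calibrated at the nominal 5%; the
acceptance tests verify this on 2,000 null windows. The shuffle loop is
implemented in C++ (driven by R's RNG, so fully seed-reproducible).

## Cutoff calibration

Genome-wide scanning needs score cutoffs. These are derived from units
(operons or monocistrons, supplied as a table -- operon inference is out of
scope) that are up-regulated upon ECF overexpression: `log2fc > 2` and
`padj < 0.05`, both strict. For each regulated unit, the Pareto-optimal
hits in the (-35 score, -10 score) plane are collected from the window of
the unit's 5'-most member gene (no other hit at least as good on both
coordinates with one strict improvement; exact duplicates retained). Over
the union of all fronts, the *worst* values -- the most negative -35, -10
and total scores, and the largest E-value -- become minimal cutoffs. Each
is then relaxed by 5%: negative scores are multiplied by 1.05 (moving away
from 0, i.e. more permissive) and the E-value cutoff by 1.05 (capped
at 1). The four cutoffs act conjunctively with inclusive boundaries. By
construction every calibration hit passes the relaxed cutoffs.

One property worth stating because it is easy to get wrong: adding hits to
a unit can make the calibrated cutoffs *stricter*, not only looser -- a new
hit that dominates existing front points displaces them, raising the
worst-of-front minima. What is invariant is that hits dominated by the
existing front never change the cutoffs; the tests check exactly that.
The default E-value cutoff is front-derived like the score cutoffs; a
fixed cutoff (e.g. 0.05) can be supplied via `fixed_max_evalue` instead.

## Genome-wide prediction

Windows run from 500 nt upstream to 100 nt downstream of every annotated
feature, anchored on the feature's strand-aware start coordinate (the
annotation's transcriptional/translational start; configurable), clipped
and flagged at contig edges. All placements in each window are filtered by
the three score cutoffs first; E-values are then computed for the
survivors from a single null simulation per window (every candidate in a
window shares the same null), and the E-value cutoff is applied last. This
ordering is purely an optimisation -- the retained set equals the full
conjunctive filter -- but it avoids simulating nulls for windows with no
plausible candidate. Adjacent features' windows overlap, so one genomic
promoter can be attributed to two features; both attributions are listed
and duplicates are flagged by genomic coordinates (`duplicate_of`).

A background scan of overlapping genome tiles (601 nt, matching the
feature-window length, step 300 -- the tiling is this package's choice)
summarises the genome-wide distribution of best placement scores.
Promoter predictions can optionally be intersected with an externally
produced list of low-DNA-duplex-stability intervals (`stability_bed`);
computing duplex stability itself is out of scope, the hook only flags
overlap.

## The synthetic-data generator

`generate_genome()` emits an i.i.d. background sequence (default GC 0.62,
matching a GC-rich alphaproteobacterial genome) of 100 kb with 200 evenly
spaced 120-bp gene features on alternating strands, and plants a promoter
site upstream of 10 randomly chosen "regulated" features: consensus boxes
(or column-wise sampled ones) with spacer drawn from 15-17, TSS 3-6
intervening bases downstream of the -10 box, and a 20-40 nt 5' UTR. The
i.i.d. background (no dinucleotide structure) is sufficient because the
E-value null conditions on the realised composition of each window.

`simulate_tss_counts()` emulates the two Cappable-seq samples at 1e6 reads
each. A fraction (default 0.1) of the treatment's reads lands on the
planted TSS with +/-1 nt jitter (80/10/10 mass -- arbitrary but fixed, to
exercise the clustering rule). The rest of the reads in both samples is
background noise: most falls on ~300 shared spurious start positions with
heavy-tailed weights common to both samples (emulating RNA-processing
sites, which real control samples are full of and which the
strain-specificity comparison must cancel), plus a thin uniform scatter of
about 0.1 reads per base. The scatter rate is chosen so that, at the
canonical depth, a scatter position rarely reaches the RRS 3.0 threshold
(P ~ 1.5e-4 per base), giving a small, quantifiable false-positive TSS
stream. A pure per-base uniform model for *all* non-signal reads would
put several reads on every base of a 100-kb genome at this depth, pass
the (relative) RRS threshold everywhere and collapse the clustering --
i.e. it would not emulate the sparse 5'-end landscape the method is built
for.

`simulate_de_table()` gives planted units `log2fc = 4`, `padj = 1e-6` and
all others Gaussian log2fc noise with `padj >= 0.2`, so the DE filter
recovers exactly the planted set whenever the effect exceeds 2.

What passing the recovery tests does **not** show about real data: real
TSS landscapes have processed-RNA contamination structure, sequence-
dependent capture efficiency and non-uniform read depth; real promoter
strengths are far below consensus; and operon structure must come from an
external source. The synthetic conditions establish correctness of the
machinery (coordinates, strands, thresholds, statistics), not performance
on any particular organism.

## Numerical and design choices

* Scores in bits (base-2 logs), pseudocount 0.01 -- the score scale of any
  particular published scan can only be matched if its log base and
  pseudocount are known, so absolute score magnitudes are comparable only
  within one convention.
* E-value estimator `k/n`, shuffle null, `n = 1000`; seeded via R's RNG
  from a single pipeline seed, so identical config + seed gives
  byte-identical reports.
* Degenerate inputs: windows too short for any placement return empty hit
  sets (not errors); clipped windows are flagged; a regulated unit with no
  hits is excluded from calibration with a warning and recorded in the
  cutoff provenance; an empty sample (Rt = 0) is a hard error.
* Problem sizes in the shipped tests and acceptance script -- 100-kb
  genomes, 200 features, 1e6 reads, 1000-shuffle nulls, tens of replicate
  seeds -- were chosen as the smallest scale at which the binomial
  tolerances of the calibration checks are meaningful.
* Stage caching/resume is not implemented; a pipeline run recomputes all
  stages from its config and seed (runs at these scales take seconds).

## Known limitations

* Extended -10 elements, UP elements and discriminator sequences are not
  scored; the model is strictly bipartite.
* Read mapping, multimapper filtering and DE fitting happen upstream; the
  pipeline consumes their outputs.
* The E-value null mirrors the observed scan mode exactly (anchored nulls
  keep the TSS constraint); whether a published scan re-anchors its null
  is generally unknowable from methods text alone, so comparisons across
  implementations should use the same convention.
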