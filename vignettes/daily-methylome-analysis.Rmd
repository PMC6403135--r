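---
title: "Daily methylome dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily methylome dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models behind `methylrhythm`, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the choices we made where the design was genuinely open.
Everything quantitative stated here is computed by the test suite or by
`scripts/acceptance.R`; the vignette adds the reasoning.

## The study design

Nine leaf samples are collected over 48 h: a 16 h light / 8 h dark day
(LD0, LD4, LD8, LD16) followed by a continuous-light free-running day
(CL0, CL4, CL8, CL16, CL24). Samples are paired by clock time into five
groups — G1 (LD0, CL0), G2 (LD4, CL4), G3 (LD8, CL8), G4 (LD16, CL16),
G5 (CL0, CL24) — so that each group represents one time of day observed
on both days, and methylation differences between consecutive groups
(G2 vs G1, …, G5 vs G4) capture daily methylome movement that is not an
artefact of a single day. Note that CL0 legitimately serves in both G1
and G5; the only structural requirement we enforce is that the two groups
inside any one comparison are disjoint, because the Fisher test pools
counts within each side.

Time stamps are hours from the LD0 origin: LD0/4/8/16 = 0/4/8/16 h and
CL0/4/8/16/24 = 24/28/32/40/48 h.

## Methylation levels and non-conversion correction

A site's level is the fraction of reads supporting methylation,
`ML = mC/(mC + umC)`, undefined (never zero) at zero coverage. Pooled
levels — windows, features, gene regions, DMR spans — are always
`sum(mC)/sum(mC + umC)`, i.e. the coverage-weighted mean of member site
levels (an exact identity the tests assert).

Bisulfite conversion is imperfect: a fraction `r` of unmethylated
cytosines reads as methylated. `r` is estimated from the unmethylated
lambda spike-in as the fraction of non-converted reads at lambda cytosine
positions. Since the expected observed level is `true + (1 − true)·r`,
we invert with `ML* = max(0, (ML − r)/(1 − r))`, clipped at zero. The
source protocol cites a correction without printing a formula; this
error-rate deconvolution is the standard choice and is used everywhere a
"corrected" level appears, including the level differences that gate
DMCs and DMRs (the protocol does not say whether its thresholds applied
to raw or corrected levels; we use corrected throughout).

## Methylated positions

Reported fractions of "methylated positions" require a calling rule the
protocol does not state. Ours is explicit and parameterised: a position
with coverage ≥ 5 is methylated when a one-sided binomial test of its
methylated count against `r` rejects at BH q < 0.05. On simulated
truly-unmethylated genomes the called fraction stays below the nominal
level (a Monte-Carlo test asserts this). The minimum coverage of 5 is
also the default site filter in the report reader; both are exposed.

## Differential methylation

For each comparison, member samples' counts are pooled per position —
the protocol compares "two groups" without stating replicate handling,
and pooling is the only way to form the single 2×2 table per position
that a Fisher exact test needs. Positions covered in both groups are
tested (two-sided hypergeometric sum, implemented vectorised and checked
against full enumeration and `stats::fisher.test`); skipped zero-coverage
positions are tallied. BH is applied per comparison over all tested
positions genome-wide, and contexts are tested jointly in one stream with
composition reported afterwards. DMCs require q < 0.05 and a corrected
level difference above 0.2 in absolute value.

DMRs are built from DMCs, not from windows: same-direction DMCs with
adjacent gaps under 300 bp are single-linkage clustered (an
opposite-direction DMC breaks the chain, since each region must carry one
hyper/hypo label for the hypo:hyper accounting); clusters of ≥ 3 DMCs
spanning first-to-last member become candidates, and the region-level
difference — pooled over *all* cytosines in the span, not just the DMCs —
must exceed 0.1. The 3,000/600 bp sliding windows are computed and
reported descriptively, but the DMR definition is the clustering rule;
the source text links the two ambiguously and the clustering sentence is
the operative one. All thresholds (0.05, 0.2, 0.1, 3, 300) are arguments
defaulting to these values.

## Annotation

Gene bodies are the full [TSS, TES] span including introns and UTRs
(matching the differentially-methylated-gene definition, which asks
whether a DMR overlaps the body or the 2 kb promoter); exon/intron/UTR
are sub-classifications. Features overlap, so items carry multiple
labels; the exclusive "primary" label uses the precedence promoter >
UTR > exon > intron > flank > TE > intergenic — reported percentages need
an exclusive rule and none is stated, so ours is documented rather than
reconstructed. TE overlap is any-overlap (≥ 1 bp). Metagene profiles cut
each 2 kb flank into twenty 100 bp bins and the body into twenty
proportional bins, flipping minus-strand genes so bin 1 is always most
5'; genes shorter than the bin count assign items by fractional position.

## Rhythmic genes

The original analysis used an external spectral tool with unstated
defaults, which is not reproducible; with a single 24 h cycle sampled at
nine points, the natural replacement is fixed-period harmonic (cosinor)
regression on `log2(FPKM + 1)`:
`y = mesor + a·cos(2πt/24) + b·sin(2πt/24)`, amplitude `√(a²+b²)`, phase
`atan2(b, a)·24/2π` in [0, 24). The period is an argument.

Significance is the F test of the two harmonic terms against the
intercept-only model. With nine samples there are only six residual
degrees of freedom, so by default the residual variances are moderated
across the transcriptome with limma's empirical-Bayes shrinkage before
the F test — the standard remedy for small-n expression designs; the
unmoderated per-gene test remains available (`moderate = FALSE`) and is
what the closed-form/noiseless tests exercise. Genes with constant
series get p = 1 by convention. BH across genes; rhythmic means
q < 0.05.

Expression "up/down" in the quadrant integration is the sign of the
change in group-mean `log2(FPKM + 1)` across a comparison, with no
significance gate (none is stated for that accounting); genes with zero
expression in both groups, or exactly zero change, are excluded and
tallied. When a gene carries DMRs of both directions in one comparison,
the largest-|difference| DMR decides its methylation direction.
Methylation–expression correlations are Spearman (no coefficient is
named in the source; rank correlation is invariant to the monotone
log transform and is an argument).

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

- **Genome.** Uniform-composition random sequence (default two 200 kb
  chromosomes), non-overlapping genes (1–6 exons, terminal UTRs, both
  strands, spans 0.9–3 kb) and TEs (families including hAT and CMC-EnSpm)
  placed by bounded rejection sampling.
- **Methylome.** Context baselines CG/CHG/CHH = 0.4399/0.2984/0.1157 —
  the leaf methylome means of the motivating study. Feature multipliers
  (TE 1.5, flanks 1.2, exon/intron 0.9, UTR 0.5) impose the observed
  qualitative ordering (TEs high, UTRs low) and a lognormal per-gene body
  factor (SD 0.3 on the log scale) gives genes distinguishable body
  levels; multipliers are renormalised per context so the genome-wide
  mean stays at the baselines, which is what the level-recovery check
  asserts (±0.01 at ≥ 10⁵ sites per context). Coverage is negative
  binomial (mean 30 — the study's sequencing depth — dispersion size 5);
  within-group biological variation is a mean-zero level jitter of 0.02
  absolute per sample, a parameter the source gives no value for.
  Non-conversion acts only on unmethylated molecules
  (`p_obs = level + (1 − level)·r`, default r = 0.005, matching ">99%
  conversion"), which the corrected-level formula inverts exactly; the
  lambda control draws `Binomial(total, r)`.
- **Planted differential regions.** A planted region is an additive
  offset (default Δ = 0.4 on CHH sites, the dominant daily-change
  context) on one group's samples. Because groups are reused across
  comparisons, one offset induces effects in two comparisons (hyper in
  one, hypo in the next); the truth ledger records the full induced set
  and recovery is scored against it. Default planting targets groups
  G2/G3/G4, whose membership is not shared, so the offsets touch exactly
  the intended samples.
- **Expression.** Rhythmic genes (12% by default, the study's reported
  proportion) follow `mesor + A·cos(2π(t − φ)/24)` with lognormal
  multiplicative noise (log2 SD 0.5); amplitudes default to 1–3 log2
  units. Gene-body coupling ties mesors to the simulated body factors
  through a Gaussian copula calibrated to a target Spearman correlation
  (`r_latent = 2·sin(πρ/6)`, default ρ = 0.5, positive — the direction
  reported for gene bodies). Genes near planted regions can additionally
  receive an anti-phase group shift (−3Δ log2 units: methylation up,
  expression down), which is itself a genuine daily signal since each
  group is a fixed clock time.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: spatial autocorrelation of methylation
beyond the planted regions (real methylomes have large unmethylated
deserts and dense TE blocks; ours has levels around nonzero baselines
everywhere, so the "fraction of positions methylated" statistic is near
one rather than the 15–20% of a real leaf methylome), read-level
artefacts (M-bias, duplicates, mapping), strand hemimethylation
asymmetry, and dispersion between true biological replicates beyond the
level jitter. Fisher's pooled test is anti-conservative under strong
biological overdispersion; the null-replicate check (≤ 1 spurious DMR in
at least 9 of 10 seeds under jitter 0.02) bounds this under the simulated
conditions only.

## Numerical choices

- Two-sided Fisher p sums hypergeometric point probabilities ≤ observed
  with the conventional `1 + 1e-7` relative tie tolerance (as
  `stats::fisher.test` uses), computed in bulk over concatenated supports
  in 50,000-table chunks.
- BH is `stats::p.adjust(method = "BH")`; NA p-values stay NA and do not
  count toward the number of tests.
- Windows anchor at position 1 and keep the final truncated window, for
  determinism and full coverage.
- Context is undefined (site dropped) when fewer than two downstream
  bases exist or an N intervenes.
- Degenerate inputs: zero-coverage levels are NA, never 0; empty regions
  give NA density; an empty DMR set writes an empty BED and summarises to
  a zero-filled table; constant expression series get rhythm p = 1.
- All simulation randomness flows from a single integer seed;
  `run_daily_methylome_analysis()` reruns byte-identically.

## Problem sizes

The shipped analyses and checks use a 2 × 200 kb genome (≈ 200,000
cytosines, 9 samples), scaling to ≈ 1.1 Mb (so every context exceeds
10⁵ sites) for the level-recovery check and to 500 genes for the
coupling-recovery check; rhythm recovery uses 2,000 genes at the
calibrated amplitude of three noise SDs. These sizes make every stage's
behaviour measurable while keeping a full run in tens of seconds on one
CPU; all of them are arguments, and nothing in the method depends on the
scale.

## Known limitations

- Pooling within groups discards replicate-level variance; a
  beta-binomial or logistic-dispersion model is out of scope by design.
- One FDR stream per comparison across contexts; per-context streams are
  deliberately not provided.
- The DMR builder is purely DMC-driven; window-seeded region refinement
  is not implemented (the window output is descriptive).
- The rhythm model is a single fixed-period harmonic: no multi-period
  scans, no damping estimation across the 48 h span.
- The source reports identical feature percentages for DMRs and DMCs
  (likely a duplication); we compute both independently and they will
  generally differ.
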