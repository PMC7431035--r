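---
title: "Screening for deeply conserved cis-regulatory elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for deeply conserved cis-regulatory elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cis-regulatory elements (CREs) — enhancers and silencers that direct where
and when developmental control genes are expressed — can remain recognizably
similar between genomes separated by hundreds of millions of years, for
example between an insect CRE and the regulatory region of its mouse or
human homolog. Detecting such elements is harder than detecting conserved
proteins: the sequences are short, non-coding, and embedded in large,
essentially unalignable loci, so a naive genome-against-genome search drowns
in chance matches and repeats.

`crescreen` implements a conservative screening procedure for this setting.
Its core idea is to *restrict the search space before asking for sequence
similarity*: candidate matches are only sought inside genomic windows
around genes that are already known to be homologous, and every match must
then survive four explicit conservation criteria plus a reciprocal
uniqueness check against the entire partner locus set.

## The screen

For a pair of loci anchored by a homologous gene pair the stages are:

1. **Window construction.** Each gene span is extended by a flank (default
   20 kb) and clipped to its locus. One window pair is built per
   (gene A, gene B) combination, so one-to-many homology (e.g. a fly gene
   with two vertebrate homologs) yields several pairs.
2. **Declumped local alignment.** Window sequences are first hard-masked
   for repeats (entropy/tandem detection plus any annotated repeat
   intervals; masked bases become `N` and score as mismatches), the same
   search-time masking genome-search tools apply: without it, repeat
   tracts present in both species anchor spurious matches and — because
   gap extension is cheap — can chain a genuine conserved element to a
   nearby repeat into one low-identity candidate. The masked windows are
   then compared with an exact affine-gap Smith–Waterman aligner; suboptimal matches are enumerated
   Waterman–Eggert style, i.e. after each reported alignment its aligned
   residue pairs are forbidden and the matrix is recomputed, so no residue
   pair is reported twice. Both strands of the B window are searched, and
   E-values are accordingly computed over the doubled search space
   `m x 2n` (likewise in the reciprocal search).
3. **Significance.** Each alignment score S receives a Karlin–Altschul
   E-value `E = K m n exp(-lambda S)`. For gapped scores no closed form
   exists, so lambda and K are calibrated empirically: best local scores of
   random sequence pairs are simulated under the background composition and
   fitted to a Gumbel law by maximum likelihood (location mu, scale beta map
   to `lambda = 1/beta`, `K = exp(mu/beta)/m/n`). The calibration is done
   once per (scheme, background, length) and cached; the simulated length
   is matched to the window scale, capped at 2 kb, so the extrapolation to
   the full window area stays modest. The analytic ungapped
   solution (bisection on `sum p_i p_j exp(lambda s_ij) = 1`, K from the
   classical lattice-case series truncated at 1e-6) is retained as the
   closed-form reference and fallback.
4. **Four criteria.** A candidate passes only if (1) it is linked to the
   homologous gene pair; (2) identity >= 62% over >= 55 alignment columns
   with E <= 0.1; (3) it is not coding (no annotated-exon overlap; where no
   exon annotation exists, an open-reading-frame scan of >= 300 bp vetoes
   instead); and (4) it is not repetitive (at most half of its span flagged
   by the built-in low-complexity/tandem detector or annotated repeats).
5. **Reciprocal uniqueness.** The candidate sequence is searched back
   against *all* partner-species loci in overlapping tiles; if any hit that
   itself passes the criterion-2 thresholds lies outside the homologous
   gene's window, the candidate is rejected. A candidate whose only passing
   hits are the homologous ones is accepted; one with no passing hit at all
   is accepted by vacuity with a warning.
6. **Refinement and motif mapping.** Passing candidates are re-aligned
   globally (Needleman–Wunsch, end gaps penalized); transcription-factor
   binding sites found by PWM scanning are mapped onto the refined
   alignment and counted only where the smoothed column identity (21-column
   running mean) stays at or above the identity cutoff.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `match`, `mismatch` | +5 / -4 | score | EDNAFULL-like DNA scoring |
| `gap_open`, `gap_extend` | 16 / 4 | score | Matcher-like affine costs; first gap column costs 16, later ones 4 |
| `min_identity` | 0.62 | fraction | conservation cutoff; inclusive (>= 62%) |
| `min_length` | 55 | alignment columns | minimum conserved span |
| `max_evalue` | 0.1 | E-value | statistical confidence cutoff |
| `flank` | 20 000 | bp | window half-width; large enough to cover intragenic and near-gene CREs while keeping the homolog restriction meaningful |
| `max_repeat_fraction` | 0.5 | fraction | a candidate must *be* a repeat, not merely touch one, to fail criterion 4 |
| TFBS `pvalue_threshold` | 1e-4 | p-value | exact-distribution threshold; a relative-score mode is deliberately not the default because the exact distribution is available |

Three readings of the criteria were genuinely open and are fixed as
package decisions, all config-overridable:

* the identity cutoff is **inclusive** (62.0% passes);
* the E-value cutoff is read as **E <= 0.1**;
* criterion-2 length counts **gapped alignment columns**, consistent with
  the identity denominator (identical non-N columns / all columns,
  BLAST-style). An ungapped-span mode would count fewer columns for the
  same alignment; the inclusive/gapped combination is the more permissive
  and simpler-to-reason-about pair.

## Numerical choices

* **Tie-breaking** in all tracebacks is fixed: diagonal, then gap-in-b,
  then gap-in-a; the best local cell is the first encountered in row-major
  order. Outputs are therefore bit-reproducible.
* **N bases** score as mismatches against everything and never count as
  identities; windows containing N are disqualified in PWM scanning.
* **No banding or heuristic seeding**: exact dynamic programming only,
  with a hard cap of 2.6e8 matrix cells per comparison. The screen is
  meant for desk-scale locus sets, not whole-genome scans.
* **PWM score grid**: log-odds are rounded to a 1e-3 nat grid
  (round-half-even); the score distribution is then exact by construction
  on that grid, and p-values agree with exhaustive enumeration over all
  4^w words (tested to width 8).
* **Lambda bisection** runs to a residual below 1e-9; the K series is
  truncated once terms fall below 1e-6.
* **Hartley's Fmax critical values** are computed exactly by numerical
  integration, `P(Fmax <= c) = k * Int f(x) [F(cx) - F(x)]^(k-1) dx` over
  the chi-square density, rather than from an embedded table. This
  reproduces published table values (e.g. 5.34 at k = 3, df = 9) and
  covers any (k, df) without table-edge fallbacks.
* **Degenerate inputs**: all-negative local matrices return the empty
  alignment with score 0; zero-variance groups fail the variance gate with
  a warning; a reciprocal search with no passing hits anywhere returns
  TRUE (vacuity) with a warning.

## The synthetic generator

Real cross-phylum inputs are genome builds plus curated CRE sequences;
neither is bundled. Instead `generate_locus_pair()` builds ortholog locus
pairs in which everything is known:

* species A is i.i.d. uniform random DNA with planted features: a central
  gene whose exons carry real open reading frames (start codon, sense
  codons, stop), homopolymer/tandem repeat tracts, one or more conserved
  elements, and optional PWM-sampled motif instances inside the first
  element;
* species B is derived segment-by-segment: conserved elements are evolved
  to a *target identity* (substitution count drawn binomially, uniform
  replacement to one of the three other bases, optional geometric indels);
  the background is independent i.i.d. uniform DNA — the known null
  against which false-pass rates are measured. (Setting
  `background_identity` above 0.25 instead evolves the background,
  producing positionally syntenic flanks for sensitivity analyses; local
  alignments then legitimately extend beyond planted element borders.)
  Exon and repeat tracts are re-planted so both annotation sets are
  informative;
* the truth set records every planted feature once with exact coordinates,
  and each element's *realized* identity is measured post hoc by global
  alignment — the classifier is always judged against realized, not
  nominal, identity.

Defaults (chosen once as the package's study conditions): 4 kb loci, one
150 bp element at target identity 0.85 over unrelated background, indel
rate 0.02 per substituted site, two 300 bp ORF exons, two 60 bp repeat
tracts.
The element size and identity mirror the few-hundred-bp, >62%-identity
conserved cores the screen is designed to find; 10 kb element-free pairs
are used for specificity measurements. Benchmarks in the test suite use
50 seeds per condition (20 for the reciprocal-uniqueness flip check, 200
random instances for the alignment oracle, 1000 simulated datasets for the
behavioral branch frequencies); these sizes are the package's chosen
trade-off between Monte-Carlo error and a test suite that stays pleasant
to run.

What the generator does **not** emulate: rate heterogeneity, CpG effects,
transition/transversion bias, rearrangements, duplications, realistic
repeat families, or chromatin context. Passing the synthetic benchmarks
therefore shows that the implementation is correct and well-calibrated
under a known null and a known signal; it does not show that the default
thresholds are optimal for any particular pair of real genomes.

## Behavioral statistics

The package also implements the statistics used for the climbing
(startle-induced negative geotaxis) assay that accompanies such screens:
groups of 10 flies per tube, 15 trials per tube averaged into one score,
10 tubes per sex per genotype as the experimental units. The decision tree
is: Anderson–Darling normality on every group (alpha 0.05) and Hartley's
Fmax variance gate; if both pass, one-way ANOVA with Tukey–Kramer post hoc
tests; otherwise Kruskal–Wallis with pairwise Mann–Whitney U tests at the
Dunn–Šidák-adjusted level `1 - (1 - alpha)^(1/3)` (the correction is
applied to the pairwise level, not the omnibus). A genotype is called
significant only under the dual-control rule: different from *both* its
driver and responder controls while the controls do not differ from each
other. Sexes are analysed separately and pooled, and both results are
reported, since either convention is defensible for tube-level replicates.

## Known limitations

* **The identity cutoff is soft.** Criterion 2 evaluates identity on the
  local alignment, whose boundaries are chosen to maximize score. This
  selection bias means an element whose *global* identity sits somewhat
  below 62% can still present a shorter internal stretch above 62% that
  clears the E-value bar, so the screen's effective identity threshold is
  a band, not a knife edge — a property of every local-alignment-based
  criterion, amplified by the generous match/cheap-extend DNA scoring.
  The synthetic benchmark quantifies this directly (elements generated at
  target identity 0.55 versus 0.85).

* The empirical Gumbel calibration ignores edge-length corrections; with
  windows much longer than alignments this biases E-values mildly
  conservative.
* Waterman–Eggert declumping forbids aligned pairs rather than re-zeroing
  individual cell contributions; for DNA scoring the two disagree only in
  contrived cases.
* The repeat detector is an entropy/tandem heuristic, not a curated
  repeat library; genuine transposon fragments that are neither
  low-complexity nor tandem will not be flagged (annotation-based repeat
  intervals fill that gap when available). The tandem rule requires >= 4
  unit copies spanning >= 8 bp, so that i.i.d. random sequence is flagged
  at only a ~2% base rate (expected-run arithmetic) while genuine
  microsatellites are still caught.
* Reciprocal uniqueness tiles loci with exact alignment; it is quadratic
  and intended for locus sets, not full genome assemblies.
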