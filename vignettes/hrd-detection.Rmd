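---
title: "Genomic scar scoring from targeted SNP panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar scoring from targeted SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdkit)
```

## The problem

Tumors that cannot repair DNA double-strand breaks by homologous
recombination (HRD tumors) accumulate characteristic structural damage —
"genomic scars" — and respond preferentially to PARP inhibitors and
platinum chemotherapy. Three scar counts, summed into an HRD score, are the
established biomarker:

* **HRD-LOH** — loss-of-heterozygosity segments longer than 15 Mb but
  shorter than a whole chromosome;
* **TAI** (telomeric allelic imbalance) — allelically imbalanced regions
  reaching a sub-telomere without crossing the centromere;
* **LST** (large-scale state transitions) — breakpoints between adjacent
  copy-number regions of at least 11 Mb, after smoothing away variation
  shorter than 3 Mb.

A sample with HRD = LOH + TAI + LST of 42 or more is classified HRD
positive (the comparison is inclusive; the published threshold states the
value but not the boundary convention).

Rather than whole-genome sequencing, the scores can be computed from a
targeted backbone of common SNPs spaced about 50 kb apart across the
genome. `hrdkit` implements that whole workflow: panel design from
population variant tables, tumor/normal read-count simulation, allele-
specific copy-number (ASCN) inference, scar scoring, and the in-silico
experiments (purity dilution, depth titration, panel subsetting, ROC) that
establish where the method is reliable.

## Panel design rules

`apply_site_filters()` + `select_spaced()` implement the site-selection
rules for a non-exonic SNP backbone:

1. minor allele frequency strictly above 1% in all four configured
   populations (defaults `EAS`, `EUR`, `AFR`, `AMR`);
2. no exon base within 200 bp of the SNP (a SNP exactly 200 bp away
   passes — the boundary convention is ours and documented);
3. exact Hardy-Weinberg test p >= 1e-4 in every population (the exact
   conditional test enumerating heterozygote counts given allele counts;
   the source design says only "significant deviation", so the threshold
   is exposed in `design_config()`);
4. probe GC within [0.25, 0.75] when a GC value is available;
5. the genome is tiled into 50-kb windows and, per window, the candidate
   with the highest allele frequency in the ranking population (`EAS` by
   default, i.e. design for maximal heterozygosity in Chinese patients)
   is selected, ties broken towards the smaller coordinate for
   determinism.

Which four populations the original design used, and whether "Chinese"
means CHB+CHS or all of EAS, is not recorded; both are configuration
choices here, not constants. Filtering is a pure function of the candidate
set — input order never changes the surviving set.

## The observation model

At a germline-heterozygous SNP inside a tumor segment with allele-specific
copies $(n_A, n_B)$, tumor purity $p$ and sample ploidy $\psi$ (the
length-weighted mean total copy number), the expected B-allele fraction and
tumor/normal depth ratio are

$$ b = \frac{p\,n_B + (1-p)}{p\,(n_A+n_B) + 2(1-p)}, \qquad
   R = \frac{p\,(n_A+n_B) + 2(1-p)}{p\,\psi + 2(1-p)}. $$

`simulate_observations()` draws the germline genotype from the SNP's MAF
under Hardy-Weinberg, normal depth as Poisson at the target mean, tumor
depth as Poisson at mean-depth × $R$, and the tumor alternate count as
binomial with success probability $b$ (or $1-b$: the allele playing the
"B" role is randomized per site, and all downstream inference uses the
folded BAF $\min(v, 1-v)$, so orientation is irrelevant). Depths can be
made negative-binomial through an `overdispersion` argument; the default
is Poisson because the emulated experiments give no dispersion estimate.
There is no sequencing-error, GC-bias or FFPE-artifact model: passing the
simulation-based checks says the inference is correct *under this model*,
not that it is robust to platform artifacts real panels must handle.

## The synthetic-data generator

`simulate_truth_profile()` plants events on a diploid background so that,
by construction, scoring the noise-free truth segments returns exactly the
planted ledger — this contract is what all round-trip tests lean on:

* LOH events are interstitial $(1,0)$ cores of 20–40 Mb flanked by
  3.5–8 Mb $(2,1)$ buffers. Without buffers, each flanking breakpoint
  of a >15 Mb LOH segment against a long diploid stretch would itself
  count as an LST; the sub-11 Mb buffers suppress that side effect so
  one planted LOH contributes exactly one LOH and nothing else.
* TAI events are telomeric $(2,1)$ segments of 5–10 Mb: at least 3 Mb so
  smoothing keeps them, under 11 Mb so they generate no LST.
* LST events are adjacent $(2,1)$/$(2,2)$ blocks of 12–15 Mb each inside
  $(3,1)$ buffers: exactly one qualifying break.
* Decoys are sub-3 Mb $(3,1)$ fragments that the smoothing step must
  erase.

Events are placed uniformly at random within single chromosome arms
(packed towards the low end of each free slot so heavy event loads still
fit), separated from each other, from arm boundaries and from chromosome
ends by at least 5 Mb of background; TAI events instead claim a chromosome
end. An event set that cannot be placed raises an error naming the event
rather than silently dropping it. Purity is an attribute of the profile;
ploidy is always derived from the segments, never specified independently,
so the two cannot disagree.

## ASCN inference

`compute_signals()` turns counts into per-site logR and folded BAF. logR
is centred by library-size normalisation — `log2` of total-tumor over
total-normal reads — rather than by the genome-wide median. With median
centring the centring constant locks onto the modal copy-number state,
which makes the fitted ploidy collapse to the modal state's total copy
number; the library-size constant equals the $p\,\psi + 2(1-p)$ term of
the depth-ratio model (the panel samples the genome uniformly), so the
model applies with no free offset and absolute ploidy stays identifiable.

`segment_sites()` is recursive binary segmentation on the joint
(logR, folded BAF) signal: each signal standardised by a robust noise
estimate (median absolute successive difference), split accepted when the
summed variance-reduction gain exceeds a BIC-style penalty, default
$10\log n$ per chromosome, with at least 10 sites per segment. The penalty
is deliberately conservative: a missed 50-site event costs one scar count,
while systematic false breakpoints inflate LST everywhere.

`fit_purity_ploidy()` scans purity 0.10–1.00 (step 0.01) × ploidy 1.0–7.0
(step 0.1) exhaustively, scoring each grid point by a Gaussian
log-likelihood of the observed segment means around the best integer state
per segment (total copies ≤ 8), weighted by site counts over within-
segment scatter (floored at sd 0.02 for logR, 0.005 for BAF, so noiseless
input gets tight weights rather than infinite ones). Two numerical choices
matter:

* **Fold-bias correction.** The folded BAF of a balanced segment does not
  average 0.5 under binomial noise but $0.5 - E|V - 0.5|$ with
  $V \sim N(0.5, \sqrt{b(1-b)/d})$. The model predicts exactly the folded
  statistic the data provide (a closed-form folded-normal mean), so
  balanced segments are not mistaken for weakly imbalanced ones.
* **Sub-grid polish and the degeneracy tie-break.** The true ploidy
  rarely sits on the 0.1 grid, and the mixture model has a classic ridge
  of near-equivalent solutions (doubling, and more generally "one extra
  copy of each allele per tumor cell" at a compensating purity); which of
  them wins on the raw grid is decided by quantisation error, not signal.
  Each ploidy column is therefore refined within its half-step at the
  column's best purity, and refined solutions within a tolerance of the
  optimum are treated as ties resolved towards the **lowest ploidy**, with
  the identifiability flag set. The tolerance scales as
  $6\sqrt{\#\text{terms}}$ because the log-likelihood gap between
  degenerate solutions is finite-sample noise of that order, while
  genuinely different solutions differ by thousands. The same tie-break
  means a genuinely whole-genome-duplicated tumor would be reported at
  the lower of the equivalent ploidies, flagged — the standard behaviour
  of ASCN tools, made explicit.

`assign_ascn()` then gives every segment the integer state minimising the
weighted squared residual; segments without BAF support match on logR
alone and take the balanced split $n_B = \lfloor t/2 \rfloor$.

## Scar scoring conventions

`normalize_profile()` merges equal adjacent segments and iteratively
absorbs the shortest sub-3 Mb segment (equal flanks merge across it;
unequal flanks extend to its midpoint) until a fixpoint. The counting
rules leave a few conventions open; ours, all exposed as arguments:

* LOH requires $n_B = 0$ **and** $n_A \ge 1$ — a homozygous deletion is
  not loss of heterozygosity.
* "Whole chromosome" means the full covered extent (first to last covered
  base), so uncovered telomeric gaps do not turn a chromosome-wide LOH
  into a countable event.
* TAI counts maximal imbalanced *runs* with no minimum size beyond the
  3-Mb smoothing (`min_tai_size = 0`; published pipelines differ here).
* LST requires **both** flanks ≥ 11 Mb, and a break whose boundary lies
  inside the centromere interval (flanks on different arms) never counts.
* Sex chromosomes are excluded from all counts by default (`drop_sex`).
* The centromere table is an input (`read_genome()`), not a constant;
  the packaged GRCh37 coordinates are one standard choice.

Every counting rule is verified against an independent brute-force
enumerator on tens of thousands of random profiles, and the generator
contract closes the loop from the other side.

## Study conditions used by the packaged experiments

The validation experiments in the test suite and `scripts/acceptance.R`
run at desk scale on these fixed conditions:

* scar-definition oracle equivalence: 10,000 random ≤20-segment profiles
  on a 3-chromosome toy genome;
* generator round trips: 100 random event specifications on the GRCh37
  autosomes;
* purity/ploidy recovery: a 14-chromosome GRCh37 subset (chr9–chr22) with
  a 100-kb panel (~13,000 SNPs), purities {0.3, 0.5, 0.8, 1.0} × depths
  {200×, 300×}, tolerance ±0.05 purity / ±0.1 ploidy;
* purity dilution and depth titration: a scar-rich tumor (15 LOH + 20 TAI
  + 15 LST, HRD 50) and a near-diploid tumor on the full autosomes with a
  50-kb panel (~58,000 SNPs) at 300× and at {50–250}×;
* panel concordance: a 30-tumor cohort (purity 0.4–1.0, 300×) scored on
  the full 50-kb panel and its half-density subset (the acceptance script
  uses a 12-tumor cohort to stay fast while reporting the same
  statistics).

These sizes are the package's own choices for a reproducible desk-scale
study; the underlying functions take any genome, panel and depth.

## Known limitations

* No GC-content bias correction of depth and no subclonal (fractional)
  copy states; clonal tumors only.
* Count-level purity mixing (`mix_purity()`) emulates diluting a tumor
  *library* with a normal library. The resulting effective cell purity is
  `2f / (2f + psi (1 - f))`, not the read fraction `f` itself — a tumor
  with ploidy above 2 contributes more reads per cell. Fitted purities in
  dilution series follow the effective value, as they would in the
  corresponding wet-lab experiment.
* The binomial thinning of `downsample_depth()` models perfect random
  read subsampling; duplicate structure of real downsampling is ignored.
* Reported panels are coordinate sets; probe/oligo design, capture
  efficiency and on-target rates are out of scope.
* Below ~20% purity the fit degenerates (the purity grid floors at 0.10)
  and segment-state assignment becomes noise-driven: scores are unstable
  there rather than smoothly collapsing, which is why the recommended
  operating range — like that of the assay the package models — starts at
  30% purity.
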