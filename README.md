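# hrdkit

Homologous recombination deficiency (HRD) leaves quantifiable structural
scars in tumor genomes, and those scars — not just BRCA1/2 mutations —
predict response to PARP inhibitors and platinum chemotherapy. `hrdkit` is
an R toolkit for detecting HRD from targeted sequencing of a sparse,
non-exonic SNP backbone (one common SNP per ~50 kb) rather than from
whole-genome sequencing. It is written for bioinformaticians building or
evaluating SNP-backbone HRD assays: it covers panel design, synthetic
tumor simulation, allele-specific copy-number inference, scar scoring, and
the in-silico experiments that establish where the method is reliable.

## The score

For a tumor profile segmented into integer allele-specific copy numbers
(nA ≥ nB), three counts are summed:

* **HRD-LOH** — segments with nB = 0 (and at least one remaining copy)
  longer than 15 Mb but shorter than a whole chromosome;
* **TAI** — maximal allelically imbalanced runs (nA ≠ nB) reaching a
  sub-telomere without crossing the centromere;
* **LST** — breakpoints between adjacent segments of ≥ 11 Mb that differ
  in (nA, nB), counted after smoothing away all variation under 3 Mb.

`HRD = LOH + TAI + LST`, and `HRD ≥ 42` classifies the sample HRD
positive. Copy numbers come from per-SNP tumor/normal allele counts
through the purity–ploidy mixture model: at a germline-heterozygous site
in a segment (nA, nB) with tumor purity p and sample ploidy ψ,

    expected BAF        b = (p·nB + (1−p)) / (p·(nA+nB) + 2(1−p))
    expected depth ratio R = (p·(nA+nB) + 2(1−p)) / (p·ψ + 2(1−p))

fitted by exhaustive grid search over (p, ψ) with integer-state
assignment per segment.

## Worked example

Simulate a scar-rich tumor on the GRCh37 autosomes, sequence it in silico
over a 50-kb panel at 300×, and run the full inference pipeline:

```r
library(hrdkit)

genome <- grch37_genome(autosomes_only = TRUE)
truth <- simulate_truth_profile(
  genome,
  event_spec(n_loh = 10, n_tai = 18, n_lst = 14, n_decoy = 5),
  purity = 1, seed = 7
)
truth
#> <truth_profile> purity 1, ploidy 2.309, 160 segments; planted LOH=10 TAI=18 LST=14

panel <- uniform_panel(genome, spacing = 50000, seed = 8)
obs <- simulate_observations(truth, panel, mean_depth = 300, seed = 9)
fit <- fit_ascn(obs, genome)
glance(fit)
#> # A tibble: 1 × 6
#>   purity ploidy loglik identifiable n_segments n_sites
#>    <dbl>  <dbl>  <dbl> <lgl>             <int>   <int>
#> 1      1   2.31  -164. FALSE               165   57633

score_hrd(fit, genome)
#> <scar_scores> LOH=10 TAI=18 LST=14 | HRD=42 (positive at cutoff 42)
```

The fitted purity (1.00) and ploidy (2.31) match the simulated truth, and
all 42 planted events are recovered exactly, so the sample is called HRD
positive at the cutoff. (`identifiable = FALSE` records that a
ploidy-doubled solution fit equally well and the lowest-ploidy solution
was chosen — expected at purity 1.) `tidy(fit)` returns the segment table,
`autoplot(fit)` draws the logR/BAF tracks, and `run_dilution_series()` /
`run_depth_series()` / `panel_concordance()` rerun the pipeline across
purity, depth and panel-density conditions.

Panel design from a candidate table follows the same data-frame-in,
tibble-out style:

```r
cfg   <- design_config()              # MAF > 1%, 200-bp exon exclusion,
                                      # HWE p >= 1e-4, GC 25–75%, 50-kb windows
cand  <- read_candidates("candidates.tsv")   # or a VCF with AF_<pop> INFO keys
flt   <- apply_site_filters(cand, read_exons("exons.bed"), cfg)
panel <- select_spaced(flt, genome, cfg)
write_panel_bed(panel, "panel.bed")
```

A thin command-line front-end wraps the same functions
(`inst/cli/hrdkit.R`): `simulate`, `fit-ascn`, `score`, `design-panel`,
`het-bins`, `evaluate-dilution`, `evaluate-depth`.

## File formats

* **Genome build**: TSV `chrom`, `length`, `cen_start`, `cen_end` (bp;
  GRCh37 table and a toy genome ship in `inst/extdata/`). All internal
  coordinates are 0-based half-open; VCF positions are converted on read.
* **Observations**: TSV `chrom`, `pos`, `n_ref`, `n_alt`, `t_ref`,
  `t_alt`, `normal_gt` — a simplified seqz-like per-SNP dialect.
* **Segments**: TSV `chrom`, `start`, `end`, `n_sites`, `logR`, `baf`,
  `nA`, `nB`; scores as JSON; panels as single-base BED.

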