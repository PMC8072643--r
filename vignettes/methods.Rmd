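---
title: "Calling copy-number alterations and copy-neutral LOH from a backbone-SNP panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy-number alterations and copy-neutral LOH from a backbone-SNP panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onekaryo)
```

## The assay and the problem

Targeted sequencing panels for myeloid neoplasms capture a few dozen genes.
Adding a sparse genome-wide *backbone* of capture probes over common SNPs
turns the same sequencing run into a low-resolution karyotyping assay: binned
read depth reports copy number, and the allele balance at backbone SNPs
reports allelic state. The backbone modelled here carries 172,470 SNPs chosen
at population minor-allele frequencies (MAF) of 0.40–0.45, so roughly half
of them are heterozygous in any patient; the gene panel spans 40 recurrently
mutated myeloid genes; and typical on-target depth is ~319 ± 133×.

Two complementary signals are read off this design:

* **Binned depth.** Reads are counted in 1 Mb bins, normalized against a
  sex-matched reference cohort, and segmented. A deletion present in a
  fraction $f$ of cells shifts the normalized log2 ratio to
  $\log_2\!\big(1 - f/2\big)$; a gain to $\log_2\!\big(1 + f/2\big)$.
* **Mirrored B-allele frequency (mBAF).** At each SNP the count of the most
  common allele is divided by the combined count of the two most common
  alleles, folding the track into $[0.5, 1]$. Heterozygous SNPs sit near
  0.5 when the region is allelically balanced and drift upward under
  imbalance. For a lesion at clonal fraction $f$ the het band's expected
  position is

  | lesion | expected mBAF |
  |---|---|
  | none | $1/2$ |
  | copy-neutral LOH | $(1+f)/2$ |
  | deletion / monosomy | $1/(2-f)$ |
  | duplication / trisomy | $(1+f)/(2+f)$ |

  Each form is strictly increasing in $f$, so the observed band position
  inverts to a clonal-fraction estimate; all collapse to $1/2$ at $f = 0$.

Copy-neutral LOH (uniparental disomy) is the case that motivates the joint
design: total copy number stays 2, so depth is silent, while the het band
separates — only the BAF track sees it. Conversely, in a region that has
fully lost heterozygosity the het band merges into the homozygous band and
the *absence* of hets (a het-band deficit relative to the panel expectation
of $\overline{2m(1-m)} \approx 0.49$) becomes the signal, and the clonal
fraction is estimated as $1 - \text{observed}/\text{expected}$ band
occupancy instead of by band-median inversion.

## Pipeline

`run_sample()` chains the stages; each is exported on its own.

1. **`compute_baf()` / `call_het()`** — fold allele counts; SNPs under 20
   usable reads are dropped. The het threshold of mBAF ≤ 0.65 separates the
   het and homozygous bands with a negligible false-negative rate at depth
   300 given panel MAFs of 0.40–0.45.
2. **`normalize_depth()`** — median-of-ratios against ≥ 2 sex-matched
   reference samples; bins with zero reference coverage are masked.
3. **`segment_log2()`** — PELT least-squares changepoint search per
   chromosome. The per-changepoint penalty is $4\hat\sigma^2 \log n$ with
   $\hat\sigma^2$ estimated robustly from lag-1 differences: a BIC-style
   penalty that adapts to the observed bin noise.
4. **`classify_segment()`** — the decision table. Strong het-band
   separation (≥ 0.08) plus a log2 loss/gain (cut lines ∓0.1) gives
   DEL/DUP with combined evidence; strong separation on copy-neutral depth
   with cnLOH geometry (≥ 10 Mb and ≥ 200 informative het SNPs) gives
   CNLOH; a depth shift with no separation at all gives a depth-only call
   flagged for review (true homozygous stretches cannot show separation);
   weak separation (0.02–0.08) only corroborates a depth call. BAF- and
   depth-implied fractions that disagree by more than 0.4 yield an
   AMBIGUOUS event that is reported, never dropped.
5. **`baf_rescue()`** — a multiscale segment-versus-rest (circular
   binary segmentation style) scan of the BAF track with a z-threshold of
   5, run on two series: the het-band values (partial imbalance) and the
   all-SNP deviation from 0.5 (complete LOH, where the band has emptied).
   A left-versus-right split statistic has almost no power for a 1 Mb run
   embedded in a 150 Mb chromosome, which is why the segment-versus-rest
   form is used. Candidates sharpen the bin-resolution edges of
   overlapping depth events and, in depth-normal territory, surface
   lesions the depth caller missed; unconfirmed ones stay in a
   requires-orthogonal-confirmation tier.
6. **`refine_breakpoints()`** — each edge is re-localized by a
   least-squares split of the local SNP series inside a window that scales
   with the event span (capped at 5 Mb), and the SNPs immediately outside
   the refined edge define an *outer envelope*. All size and marker-count
   floors are tested on that envelope, so a lesion exactly at a floor is
   not lost to midpoint rounding. The clonal fraction is then re-estimated
   on the refined span — segment-level estimates are diluted by normal
   flanks whenever a changepoint lands a few bins off, which matters
   exactly at the reporting floor.
7. **Reporting floors** — CNAs ≥ 1 Mb; cnLOH ≥ 10 Mb with ≥ 200 het SNPs;
   clonal fraction ≥ 0.2. The fraction floor is applied to the upper
   confidence bound, so an event truly at 20% of cells is not rejected by
   estimator noise, while events confidently below the floor are.
8. **`flag_chromothripsis()`** — ≥ 4 alternating copy-number state
   switches within one arm.

### Numerical choices worth knowing about

* **Diploid baseline.** Normalizing by a sample's own median count biases
  the whole track when a large lesion shifts the median. Because the BAF
  run scan is independent of the depth baseline, it runs first, and the
  baseline is re-anchored on the median log2 of the bins *outside* every
  BAF candidate — allelically balanced territory defines diploid. (A
  segment-mean cluster anchor is the fallback when almost everything is
  flagged; an undersplit segment containing a lesion would otherwise drag
  the anchor.) The approach assumes less than half the genome is altered;
  a genome that is mostly aberrant (e.g. a fully deleted single-chromosome
  toy genome) has no diploid anchor and whole-genome ploidy shifts are out
  of scope.
* **Suppression confidence.** The 20%-of-cells reporting floor is applied
  as a one-sided 99.5% test (suppress only when the clonal fraction is
  confidently below 0.2): at an assay's sensitivity limit, hiding a real
  lesion is the costlier error, and a 95% bound would falsely suppress a
  few percent of lesions truly at the floor.
* **Folded-median bias.** The mirrored representation biases the band
  median upward: a perfectly balanced band with per-SNP noise $\sigma$ has
  folded median $0.5 + 0.674\sigma$ (~0.52 at depth 300). All separations
  and inversions therefore unfold the observed median through the
  folded-normal median equation (`unfold_median()`), which removes the
  null bias without touching strongly separated bands.
* **Noise scales.** The depth track and the het-band series use a robust
  lag-1-difference MAD; the all-SNP deviation series is bimodal (hets near
  0, homs near 0.5), where the difference MAD is badly mis-calibrated, so
  its plain standard deviation is used, and its baseline is the mean (the
  median of a bimodal series is bistable).
* **Ties and degenerate inputs.** Equal major/minor counts give mBAF
  exactly 0.5; all-masked chromosomes yield one flagged placeholder
  segment; events without informative flanking SNPs keep bin-resolution
  coordinates and a flag; too few het SNPs for a fraction estimate raises
  an explicit insufficient-evidence error, distinct from an estimate of 0.

## The synthetic-data generator

The generator (`make_panel()`, `simulate_sample()`,
`simulate_reference_cohort()`, `simulate_variant_table()`) emulates the
assay at its study conditions and is fully seeded. Per SNP, genotypes are
Hardy–Weinberg at the locus MAF; lesions adjust the expected allele
fraction of hets via a tumor-fraction-weighted copy mixture with the
affected haplotype randomized (the panel is unphased); allele counts are
binomial at a negative-binomial total depth (mean 319, size 5.9,
reproducing the ±133× spread). Bin counts are negative-binomial (mean
4000 per 1 Mb, matching ~14M reads over ~3100 genome-wide bins; size 200,
i.e. ~7% CV) around a shared log-normal per-bin capture-efficiency
profile, which is what makes unrelated samples correlate at ~0.97–0.99
as real binned capture coverage does. A read miscall rate of 0.002 feeds
the third-allele channel.

What the generator does *not* model: GC and mappability waves, probe-level
capture chemistry, read-level artifacts, phased haplotype blocks,
subclonal mixtures of more than one fraction per lesion, and
pseudoautosomal regions (XY samples simply carry one X dose). Passing
tests therefore demonstrate correctness of the statistical machinery
under the declared noise model, not robustness to every real-data
artifact; the QC correlation gate and the editable thresholds are the
intended adjustment points for real data.

Default test scales: a 150 Mb single-chromosome toy genome (~8,400
backbone SNPs, 150 bins) for lesion-level suites, a 370 Mb
three-chromosome genome for whole-chromosome lesions, 100 seeded
replicates per detection-limit grid point.

## Detection limits the package validates

`detection_limit_fraction()`, `detection_limit_cnloh_size()` and
`detection_limit_del_size()` re-derive the design's resolution claims on
the toy chromosome: a 60 Mb arm-level deletion is detectable (≥ 90/100
replicates) down to 20% of cells; cnLOH down to 10 Mb at 80% clonal
fraction (the 5 Mb grid point is excluded by the marker floor by
construction); fully clonal deletions down to 1 Mb (the 0.5 Mb point
falls below both the scan's power and the size floor).
`scripts/acceptance.R` recomputes all three grids from scratch.

## Variant workflow and risk models

Tumor-only small variants pass a population filter (`pop_maf > 0.01`
excludes as germline; the inequality is strict and missing frequencies
pass), then rule-based tiering from an editable YAML (hotspots and
database hits → pathogenic; truncating lesions in listed tumor
suppressors → likely pathogenic; otherwise VUS), with an advisory
germline-suspect flag for VAF in [0.45, 0.55] or ≥ 0.95 without LOH
support — advisory because tumor-only data cannot prove germline origin.
Pairwise co-occurrence and exclusivity are one-sided Fisher exact tests
(both tails reported) with Benjamini–Hochberg correction across all
pairs.

Risk scoring maps integrated events to ISCN-like labels, groups them
under the IPSS-R (five groups) or CPSS (three groups) cytogenetic
schemes, and sums component points from a versioned YAML transcription
of the published systems. cnLOH of 7q and 17p is grouped with the
corresponding deletion behind a flag (default on): both lesions
inactivate the same allele, so the depth-invisible one carries the same
prognosis. The molecular extensions (IPSS-Rm: EZH2/SF3B1/TP53; CPSS-Mol:
RUNX1/NRAS/SETBP1/ASXL1) are additive gene adjustments and are labelled
approximations in the config header; they should be recalibrated before
any clinical use. `compare_classifications()` builds the
baseline-versus-NGS transition matrix with per-patient
upstage/downstage labels.

## Known limitations

* One clonal fraction per lesion; no subclone deconvolution or phasing.
* Balanced translocations are invisible to both depth and BAF by design.
* Events below 20% of cells are suppressed by the reporting floor, which
  matches the assay's validated sensitivity but will hide smaller
  subclones.
* The single-caller depth stage accepts externally produced segment
  tables in the same format, but does not attempt to reproduce the
  idiosyncrasies of any specific external caller.
* The monosomy/trisomy relabelling requires unaffected chromosomes as a
  baseline (see the diploid-anchor note above).
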