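# onekaryo

Joint detection of copy-number alterations (CNAs), copy-neutral loss of
heterozygosity (cnLOH) and somatic mutation profiles from a **single
targeted sequencing run**, for myelodysplastic syndromes (MDS), chronic
myelomonocytic leukemia (CMML) and related myeloid neoplasms — plus the
IPSS-R / CPSS prognostic scoring that turns the integrated genotype into a
risk category.

The assay it models combines a 40-gene myeloid mutation panel with a sparse
genome-wide **backbone** of capture probes over 172,470 common SNPs
(population MAF 0.40–0.45, so ~half are heterozygous in any patient). Two
signals are extracted from the same reads:

* **binned read depth** (1 Mb bins, reference-normalized): a lesion in a
  fraction *f* of cells shifts the log2 ratio to log2(1 − f/2) for a loss
  and log2(1 + f/2) for a gain;
* **mirrored B-allele frequency** (mBAF): at each SNP, reads of the most
  common allele over reads of the two most common alleles, folded into
  [0.5, 1]. The heterozygous band sits at 1/2 when balanced and moves to
  (1+f)/2 under cnLOH, 1/(2−f) under deletion, (1+f)/(2+f) under
  duplication — closed forms the package inverts to estimate *f*.

cnLOH is depth-invisible but BAF-visible; a fully clonal deletion empties
the het band entirely and is read off the het deficit. The integrator
reconciles both tracks: depth segments are classified against the regional
het band, BAF-only lesions are rescued from depth-silent territory
(reported in a requires-orthogonal-confirmation tier), breakpoints are
refined to SNP resolution, and chromothripsis-like oscillation patterns
are flagged. Reporting floors follow the assay design: CNAs ≥ 1 Mb, cnLOH
≥ 10 Mb with ≥ 200 het SNPs, clonal fraction ≥ 20% of cells.

A fully seeded synthetic-data module simulates the whole assay (backbone
panel, per-SNP allele depths at 319 ± 133×, bin counts with a shared
capture-efficiency profile, reference cohorts, annotated variant tables)
with known ground truth, and is how the package validates itself.

## Worked example

```r
library(onekaryo)

genome <- toy_genome(lengths = c(`1` = 150e6))
config <- sim_config(n_snps = round(default_snp_density() * 150e6), seed = 5)
panel  <- make_panel(genome, config)
refs   <- simulate_reference_cohort(panel, 4, "XX", config, seed = 11)

truth  <- sim_truth(tibble::tibble(chrom = "1", start = 30e6, end = 90e6,
                                   type = "CNLOH", clonal_fraction = 0.5))
sample <- simulate_sample(panel, truth, config, seed = 43)

events <- sample$bins |>
  normalize_depth(refs) |>
  integrate_events(compute_baf(sample$allele_depths), genome,
                   integration_thresholds(), seed = 9)
events[, c("label", "start", "end", "event_type", "clonal_fraction", "evidence")]
#> # A tibble: 1 × 6
#>   label       start      end event_type clonal_fraction evidence
#>   <chr>       <dbl>    <dbl> <chr>                <dbl> <chr>
#> 1 cnLOH(1) 30032762 89996829 CNLOH                  0.5 depth_and_baf
```

A 60 Mb copy-neutral LOH implanted at 50% of cells comes back as one
`CNLOH` event with SNP-resolution breakpoints (within ~50 kb of the
implanted 30–90 Mb), a clonal fraction of 0.50, and combined
depth-and-BAF evidence — depth confirms copy neutrality while the het
band at mBAF ≈ 0.75 carries the signal. `plot_chromosome(bins, baf, "1",
events)` draws the log2 and mBAF panels with the call shaded.

Downstream, `classify_variants()` + `cooccurrence()` handle the
tumor-only variant table, and

```r
cl <- clinical_input("MDS", bm_blasts = 6, hemoglobin = 9.5,
                     platelets = 80, anc = 1.2)
risk_score("ipssr", cl, cytogenetic_risk(events, "ipssr"))
#> IPSSR score 4.5 -> Intermediate (cytogenetics: Good)
```

scores the patient; `run_sample()` chains all of it into one report
bundle and `run_cohort()` aggregates bundles into mutation frequencies,
co-occurrence tables and risk-transition matrices. A thin command-line
wrapper ships in `inst/cli/onekaryo.R` (`simulate` and `run` verbs).

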