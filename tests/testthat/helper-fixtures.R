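# shared fixtures, built in code and cached for the test process

# single 150 Mb toy chromosome at the default backbone SNP density, with a
# 4-sample reference cohort; the workhorse fixture of the caller tests
caller_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- toy_genome(lengths = c(`1` = 150e6))
      cfg <- sim_config(
        n_snps = as.integer(round(default_snp_density() * 150e6)),
        seed = 5)
      panel <- make_panel(g, cfg)
      refs <- simulate_reference_cohort(panel, 4, "XX", cfg, seed = 11)
      cache <<- list(genome = g, config = cfg, panel = panel, refs = refs,
                     thr = integration_thresholds(n_boot = 0))
    }
    cache
  }
})

# three-chromosome toy genome at default density, for whole-chromosome
# lesions (monosomy/trisomy calling needs unaffected chromosomes as the
# diploid baseline)
multi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- toy_genome()
      cfg <- sim_config(
        n_snps = as.integer(round(default_snp_density() * sum(g$length))),
        seed = 5)
      panel <- make_panel(g, cfg)
      refs <- simulate_reference_cohort(panel, 4, "XX", cfg, seed = 11)
      cache <<- list(genome = g, config = cfg, panel = panel, refs = refs,
                     thr = integration_thresholds(n_boot = 0))
    }
    cache
  }
})

# simulate one sample under `events` and run the full caller
run_caller <- function(fx, events, seed) {
  s <- simulate_sample(fx$panel, sim_truth(events), fx$config, seed = seed)
  integrate_events(normalize_depth(s$bins, fx$refs),
                   compute_baf(s$allele_depths),
                   fx$genome, fx$thr, seed = seed)
}

overlaps_truth <- function(events, truth_row, types, min_frac = 0.5) {
  if (nrow(events) == 0) return(FALSE)
  hit <- events$event_type %in% types & events$chrom == truth_row$chrom
  if (!any(hit)) return(FALSE)
  ov <- pmin(events$end[hit], truth_row$end) -
    pmax(events$start[hit], truth_row$start)
  any(ov / (truth_row$end - truth_row$start) >= min_frac)
}

# hand-built mirrored-BAF track: hets at a given mBAF, homs at ~1, evenly
# spaced; the deterministic substrate for decision-table unit tests
synthetic_baf <- function(chrom = "1", from = 0, to = 150e6,
                          spacing = 18000, het_mbaf = 0.5,
                          het_regions = NULL, depth = 300,
                          het_rate = 0.488, seed = 1) {
  withr::with_seed(seed, {
    pos <- seq(from + spacing, to, by = spacing)
    is_het <- stats::runif(length(pos)) < het_rate
    baf <- ifelse(is_het, het_mbaf, 0.999)
    if (!is.null(het_regions)) {
      for (i in seq_len(nrow(het_regions))) {
        idx <- is_het & pos > het_regions$start[i] & pos <= het_regions$end[i]
        baf[idx] <- het_regions$mbaf[i]
      }
    }
    tibble::tibble(chrom = chrom, pos = pos, pop_maf = 0.425,
                   depth_used = depth, baf = baf)
  })
}

flat_segment <- function(chrom = "1", start = 0, end = 150e6,
                         mean_log2 = 0, n_bins = 150) {
  tibble::tibble(chrom = chrom, start = start, end = end, n_bins = n_bins,
                 mean_log2 = mean_log2, masked = FALSE)
}
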