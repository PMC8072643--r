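# seeded detection-limit benchmarks on a toy chromosome; these drive the
# package's own validation of the assay's printed resolution and sensitivity
# claims (1 Mb CNA / 10 Mb cnLOH resolution, 20%-of-cells floor)

bench_genome <- function(chrom_length_bp = 150e6) {
  toy_genome(lengths = c(`1` = chrom_length_bp))
}

bench_config <- function(genome, seed = NULL) {
  sim_config(
    n_snps = as.integer(round(default_snp_density() *
                                genome_total_length(genome))),
    seed = seed
  )
}

# one simulate -> normalize -> integrate replicate; returns the event table
run_replicate <- function(panel, refs, truth, config, thresholds, seed) {
  s <- simulate_sample(panel, truth, config, seed = seed)
  baf <- compute_baf(s$allele_depths)
  bins <- normalize_depth(s$bins, refs)
  integrate_events(bins, baf, panel$genome, thresholds, seed = seed)
}

detected <- function(events, truth_row, types, min_overlap = 0.5) {
  if (nrow(events) == 0) return(FALSE)
  hit <- events$event_type %in% types & events$chrom == truth_row$chrom
  if (!any(hit)) return(FALSE)
  ov <- pmin(events$end[hit], truth_row$end) -
    pmax(events$start[hit], truth_row$start)
  any(ov / (truth_row$end - truth_row$start) >= min_overlap)
}

bench_setup <- function(seed, chrom_length_bp = 150e6) {
  genome <- bench_genome(chrom_length_bp)
  config <- bench_config(genome)
  panel <- make_panel(genome, config, seed = child_seed(seed, 1))
  refs <- simulate_reference_cohort(panel, 4, "XX", config,
                                    seed = child_seed(seed, 2))
  thresholds <- integration_thresholds(n_boot = 0)
  list(genome = genome, config = config, panel = panel, refs = refs,
       thresholds = thresholds)
}

detection_rate <- function(setup, truth_fn, types, n_rep, seed) {
  hits <- vapply(seq_len(n_rep), function(r) {
    rep_seed <- child_seed(seed, 100 + r)
    truth_row <- with_seed_if(rep_seed, truth_fn())
    truth <- sim_truth(truth_row)
    ev <- run_replicate(setup$panel, setup$refs, truth, setup$config,
                        setup$thresholds, seed = child_seed(rep_seed, 3))
    detected(ev, truth_row, types)
  }, logical(1))
  mean(hits)
}

#' Detection limit in clonal fraction for an arm-level deletion
#'
#' Simulates a 60 Mb deletion on a 150 Mb toy chromosome (default backbone
#' SNP density, 319x depth, 1 Mb bins) at each clonal fraction of the grid,
#' runs the full caller, and reports the per-fraction detection rate over
#' `n_rep` seeded replicates together with the smallest fraction detected in
#' at least `pass_rate` of them.
#'
#' @param fractions clonal-fraction grid (default 0.1, 0.2, 0.3, 0.4).
#' @param n_rep replicates per grid point (default 100).
#' @param seed base seed.
#' @param pass_rate required detection rate (default 0.9).
#' @param del_size_bp deletion span (default 60 Mb).
#' @return list with `grid` (tibble fraction/rate) and `limit` (smallest
#'   passing fraction, `NA` if none).
#' @export
detection_limit_fraction <- function(fractions = c(0.1, 0.2, 0.3, 0.4),
                                     n_rep = 100, seed = 1,
                                     pass_rate = 0.9,
                                     del_size_bp = 60e6) {
  setup <- bench_setup(seed)
  len <- setup$genome$length[1]
  rates <- vapply(fractions, function(f) {
    detection_rate(
      setup,
      function() {
        start <- runif(1, 5e6, len - del_size_bp - 5e6)
        tibble::tibble(chrom = "1", start = start,
                       end = start + del_size_bp, type = "DEL",
                       clonal_fraction = f)
      },
      types = c("DEL", "MONOSOMY"), n_rep = n_rep,
      seed = child_seed(seed, round(1000 * f)))
  }, numeric(1))
  grid <- tibble::tibble(fraction = fractions, rate = rates)
  passing <- fractions[rates >= pass_rate]
  list(grid = grid,
       limit = if (length(passing) > 0) min(passing) else NA_real_)
}

#' Detection limit in size for copy-neutral LOH
#'
#' Simulates cnLOH segments of each grid size at clonal fraction
#' `clonal_fraction` on the toy chromosome and reports the smallest size
#' called as CNLOH in at least `pass_rate` of replicates.
#'
#' @param sizes_mb cnLOH span grid in Mb (default 5, 10, 20, 40).
#' @param clonal_fraction default 0.8.
#' @inheritParams detection_limit_fraction
#' @return list with `grid` (tibble size_mb/rate) and `limit` in Mb.
#' @export
detection_limit_cnloh_size <- function(sizes_mb = c(5, 10, 20, 40),
                                       clonal_fraction = 0.8,
                                       n_rep = 100, seed = 1,
                                       pass_rate = 0.9) {
  setup <- bench_setup(seed)
  len <- setup$genome$length[1]
  rates <- vapply(sizes_mb, function(sz) {
    detection_rate(
      setup,
      function() {
        start <- runif(1, 5e6, len - sz * 1e6 - 5e6)
        tibble::tibble(chrom = "1", start = start, end = start + sz * 1e6,
                       type = "CNLOH", clonal_fraction = clonal_fraction)
      },
      types = "CNLOH", n_rep = n_rep,
      seed = child_seed(seed, 2000 + round(10 * sz)))
  }, numeric(1))
  grid <- tibble::tibble(size_mb = sizes_mb, rate = rates)
  passing <- sizes_mb[rates >= pass_rate]
  list(grid = grid,
       limit = if (length(passing) > 0) min(passing) else NA_real_)
}

#' Detection limit in size for clonal deletions
#'
#' Simulates fully clonal (f = 1) deletions of each grid size and reports
#' the smallest size called as DEL in at least `pass_rate` of replicates.
#'
#' @param sizes_mb deletion span grid in Mb (default 0.5, 1, 2, 5).
#' @inheritParams detection_limit_cnloh_size
#' @return list with `grid` and `limit` in Mb.
#' @export
detection_limit_del_size <- function(sizes_mb = c(0.5, 1, 2, 5),
                                     clonal_fraction = 1.0,
                                     n_rep = 100, seed = 1,
                                     pass_rate = 0.9) {
  setup <- bench_setup(seed)
  len <- setup$genome$length[1]
  rates <- vapply(sizes_mb, function(sz) {
    detection_rate(
      setup,
      function() {
        start <- runif(1, 5e6, len - sz * 1e6 - 5e6)
        tibble::tibble(chrom = "1", start = start, end = start + sz * 1e6,
                       type = "DEL", clonal_fraction = clonal_fraction)
      },
      types = "DEL", n_rep = n_rep,
      seed = child_seed(seed, 3000 + round(10 * sz)))
  }, numeric(1))
  grid <- tibble::tibble(size_mb = sizes_mb, rate = rates)
  passing <- sizes_mb[rates >= pass_rate]
  list(grid = grid,
       limit = if (length(passing) > 0) min(passing) else NA_real_)
}
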