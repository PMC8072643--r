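# synthetic assay generator

test_that("panel placement respects counts, bounds, ordering and determinism", {
  g <- toy_genome()
  cfg <- sim_config(n_snps = 2000L, seed = 7)
  p1 <- make_panel(g, cfg)
  p2 <- make_panel(g, cfg)
  expect_identical(p1$snps, p2$snps)
  expect_equal(nrow(p1$snps), 2000)
  expect_true(all(p1$snps$pop_maf >= 0.40 & p1$snps$pop_maf <= 0.45))
  by_chrom <- split(p1$snps$pos, p1$snps$chrom)
  expect_true(all(vapply(by_chrom, function(x) all(diff(x) > 0),
                         logical(1))))
  expect_false(anyDuplicated(p1$snps[, c("chrom", "pos")]) > 0)
  # allocation proportional to chromosome length
  counts <- table(p1$snps$chrom)[g$chrom]
  expect_equal(as.numeric(counts) / 2000, g$length / sum(g$length),
               tolerance = 0.01)
})

test_that("empty and infeasible panel requests are handled", {
  g <- toy_genome()
  expect_equal(nrow(make_panel(g, sim_config(n_snps = 0L, seed = 1))$snps), 0)
  expect_error(make_panel(g, sim_config(n_snps = 2e6, seed = 1)),
               class = "onekaryo_density_error")
})

test_that("simulated depth and heterozygosity match the configuration", {
  g <- toy_genome()
  cfg <- sim_config(n_snps = 20000L, seed = 3)
  panel <- make_panel(g, cfg)
  s <- simulate_sample(panel, sim_truth(), cfg, seed = 8)
  depth <- s$allele_depths$ref_count + s$allele_depths$alt_count +
    s$allele_depths$other_count
  expect_equal(mean(depth), cfg$mean_depth, tolerance = 0.02)
  # depth spread follows the negative-binomial parameterization
  expect_equal(stats::sd(depth),
               sqrt(cfg$mean_depth + cfg$mean_depth^2 / cfg$depth_dispersion),
               tolerance = 0.05)
  h_obs <- mean(s$allele_depths$genotype == 1)
  h_exp <- mean(2 * panel$snps$pop_maf * (1 - panel$snps$pop_maf))
  expect_equal(h_obs, h_exp, tolerance = 0.01)
})

test_that("event-free het SNPs sit at balanced mirrored BAF at high depth", {
  g <- toy_genome(lengths = c(`1` = 30e6))
  cfg <- sim_config(n_snps = 2000L, mean_depth = 10000,
                    depth_dispersion = 1e6, seed = 2)
  panel <- make_panel(g, cfg)
  s <- simulate_sample(panel, sim_truth(), cfg, seed = 4)
  baf <- compute_baf(s$allele_depths)
  het <- baf$baf[s$allele_depths$genotype == 1]
  expect_equal(mean(het), 0.5, tolerance = 0.02)
})

test_that("fully clonal cnLOH drives regional het SNPs to homozygosity", {
  g <- toy_genome(lengths = c(`1` = 60e6))
  cfg <- sim_config(n_snps = 3000L, seed = 2)
  panel <- make_panel(g, cfg)
  truth <- tibble::tibble(chrom = "1", start = 10e6, end = 50e6,
                          type = "CNLOH", clonal_fraction = 1)
  s <- simulate_sample(panel, sim_truth(truth), cfg, seed = 4)
  baf <- compute_baf(s$allele_depths)
  inside <- baf$pos > 10e6 & baf$pos <= 50e6 & baf$genotype == 1
  # one allele's counts collapse to the sequencing-error level
  expect_true(mean(baf$count_minor[inside] /
                     baf$depth_used[inside]) < 0.01)
})

test_that("a half-clonal deletion scales bin counts by the copy mixture", {
  # expected ratio (0.5*2 + 0.5*1)/2 = 0.75; averaged over >= 1000 bins
  g <- toy_genome(lengths = c(`1` = 3000e6))
  cfg <- sim_config(n_snps = 1000L, bin_profile_sd = 0, seed = 2)
  panel <- make_panel(g, cfg)
  truth <- tibble::tibble(chrom = "1", start = 500e6, end = 1700e6,
                          type = "DEL", clonal_fraction = 0.5)
  s <- simulate_sample(panel, sim_truth(truth), cfg, seed = 4)
  inside <- s$bins$bin_start >= 500e6 & s$bins$bin_end <= 1700e6
  expect_gte(sum(inside), 1000)
  expect_equal(mean(s$bins$count[inside]) / mean(s$bins$count[!inside]),
               0.75, tolerance = 0.02)
})

test_that("events outside chromosome bounds or invalid fractions error", {
  g <- toy_genome(lengths = c(`1` = 30e6))
  cfg <- sim_config(n_snps = 500L, seed = 2)
  panel <- make_panel(g, cfg)
  bad <- tibble::tibble(chrom = "1", start = 10e6, end = 40e6,
                        type = "DEL", clonal_fraction = 0.5)
  expect_error(simulate_sample(panel, sim_truth(bad), cfg, seed = 1),
               class = "onekaryo_validation_error")
  expect_error(
    sim_truth(tibble::tibble(chrom = "1", start = 1, end = 2, type = "DEL",
                             clonal_fraction = 1.2)),
    class = "onekaryo_validation_error")
  expect_error(
    sim_truth(tibble::tibble(chrom = "1", start = c(1e6, 2e6),
                             end = c(5e6, 6e6), type = "DEL",
                             clonal_fraction = 0.5)),
    class = "onekaryo_validation_error")
})

test_that("variant table generator honours its contracts", {
  expect_equal(nrow(simulate_variant_table(0)), 0)
  v_all_germ <- simulate_variant_table(50, fraction_germline_like = 1,
                                       seed = 3)
  expect_true(all(v_all_germ$pop_maf > 0.01))
  v1 <- simulate_variant_table(100, 0.3, seed = 9)
  v2 <- simulate_variant_table(100, 0.3, seed = 9)
  expect_identical(v1, v2)
  expect_true(all(v1$vaf >= 0.02 & v1$vaf <= 1))
  expect_error(simulate_variant_table(10, fraction_germline_like = 2),
               class = "onekaryo_validation_error")
})

test_that("reference cohorts are sex-dosed, labelled and reproducible", {
  g <- hg19_genome()
  cfg <- sim_config(n_snps = 1000L, seed = 2)
  panel <- make_panel(g, cfg)
  refs <- simulate_reference_cohort(panel, 4, c("XX", "XX", "XY", "XY"),
                                    cfg, seed = 6)
  expect_equal(dplyr::n_distinct(refs$sample_id), 4)
  xx <- dplyr::filter(refs, sex == "XX")
  xy <- dplyr::filter(refs, sex == "XY")
  ratio_x <- mean(xy$count[xy$chrom == "X"]) /
    mean(xx$count[xx$chrom == "X"])
  expect_equal(ratio_x, 0.5, tolerance = 0.05)
  expect_true(all(xx$count[xx$chrom == "Y"] == 0))
  refs2 <- simulate_reference_cohort(panel, 4, c("XX", "XX", "XY", "XY"),
                                     cfg, seed = 6)
  expect_identical(refs, refs2)
  expect_error(simulate_reference_cohort(panel, 0, "XX", cfg),
               class = "onekaryo_validation_error")
})

test_that("forward-simulated mirrored BAF matches the closed forms", {
  # at depth 1000, the simulated het mBAF mean tracks expected_mbaf within
  # a few binomial standard errors for every lesion type and fraction
  g <- toy_genome(lengths = c(`1` = 60e6))
  cfg <- sim_config(n_snps = 3000L, mean_depth = 1000,
                    depth_dispersion = 1e6, seed = 2)
  panel <- make_panel(g, cfg)
  for (type in c("CNLOH", "DEL", "DUP")) {
    for (f in c(0, 0.25, 0.5, 0.75, 1)) {
      truth <- if (f == 0) sim_truth() else
        sim_truth(tibble::tibble(chrom = "1", start = 5e6, end = 55e6,
                                 type = type, clonal_fraction = f))
      s <- simulate_sample(panel, truth, cfg,
                           seed = 100 + round(100 * f))
      baf <- compute_baf(s$allele_depths)
      het <- baf$genotype == 1 & baf$pos > 5e6 & baf$pos <= 55e6
      m_exp <- expected_mbaf(type, f)
      m_obs <- mean(baf$baf[het])
      # folding inflates the mean near 0.5 by ~0.6 sigma at most
      expect_lt(abs(m_obs - m_exp), 0.02)
    }
  }
})
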