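# depth/BAF event integrator

test_that("threshold container validates its geometry", {
  expect_error(integration_thresholds(min_cna_size_bp = 2e7,
                                      min_cnloh_size_bp = 1e7),
               class = "onekaryo_validation_error")
  thr <- integration_thresholds()
  expect_equal(thr$min_cnloh_size_bp, 1e7)
  expect_equal(thr$min_cnloh_het_snps, 200)
})

test_that("decision table: balanced BAF on neutral depth is NORMAL", {
  baf <- synthetic_baf(het_mbaf = 0.5)
  ev <- classify_segment(flat_segment(mean_log2 = 0), baf,
                         integration_thresholds(n_boot = 0))
  expect_equal(ev$event_type, "NORMAL")
})

test_that("decision table: deep loss with collapsed het band is a clonal DEL", {
  baf <- synthetic_baf(het_mbaf = 0.5, het_regions = tibble::tibble(
    start = 40e6, end = 100e6, mbaf = 0.999))
  seg <- flat_segment(start = 40e6, end = 100e6, mean_log2 = -1, n_bins = 60)
  ev <- classify_segment(seg, baf, integration_thresholds(n_boot = 0))
  expect_equal(ev$event_type, "DEL")
  expect_equal(ev$clonal_fraction, 1, tolerance = 0.05)
  expect_equal(ev$evidence, "depth_and_baf")
})

test_that("decision table: neutral depth with separated band over 59 Mb is cnLOH", {
  baf <- synthetic_baf(het_mbaf = 0.5, het_regions = tibble::tibble(
    start = 40e6, end = 99e6, mbaf = 0.75))
  seg <- flat_segment(start = 40e6, end = 99e6, mean_log2 = 0, n_bins = 59)
  ev <- classify_segment(seg, baf, integration_thresholds(n_boot = 0))
  expect_equal(ev$event_type, "CNLOH")
  expect_equal(ev$clonal_fraction, 0.5, tolerance = 0.02)
  expect_gte(ev$n_het_snps, 200)
})

test_that("depth shift without separation is a flagged depth-only call", {
  baf <- synthetic_baf(het_mbaf = 0.5)
  seg <- flat_segment(start = 40e6, end = 80e6, mean_log2 = -0.4,
                      n_bins = 40)
  ev <- classify_segment(seg, baf, integration_thresholds(n_boot = 0))
  expect_equal(ev$event_type, "DEL")
  expect_equal(ev$evidence, "depth_only")
  expect_match(ev$flags, "no_baf_separation")
})

test_that("irreconcilable depth and BAF fractions produce AMBIGUOUS", {
  # band says f ~ 0.2, depth says f ~ 1: conflict must surface, not vanish
  baf <- synthetic_baf(het_mbaf = 0.5, het_regions = tibble::tibble(
    start = 40e6, end = 100e6, mbaf = 0.555))
  seg <- flat_segment(start = 40e6, end = 100e6, mean_log2 = -1, n_bins = 60)
  ev <- classify_segment(seg, baf, integration_thresholds(n_boot = 0))
  expect_equal(ev$event_type, "AMBIGUOUS")
  expect_true(ev$requires_confirmation)
  expect_match(ev$flags, "conflict")
})

test_that("baf_rescue: a balanced genome yields no candidates", {
  baf <- synthetic_baf(het_mbaf = 0.5)
  segs <- dplyr::mutate(flat_segment(mean_log2 = 0), masked = FALSE)
  expect_equal(nrow(baf_rescue(baf, segs, integration_thresholds())), 0)
})

test_that("baf_rescue: a 16.7 Mb depth-neutral imbalance becomes one candidate", {
  baf <- synthetic_baf(het_mbaf = 0.5, het_regions = tibble::tibble(
    start = 60e6, end = 76.7e6, mbaf = 0.62))
  segs <- flat_segment(mean_log2 = 0)
  cand <- baf_rescue(baf, segs, integration_thresholds())
  expect_equal(nrow(cand), 1)
  expect_equal(cand$evidence, "baf_only")
  expect_equal(cand$start / 1e6, 60, tolerance = 0.01)
  expect_equal(cand$end / 1e6, 76.7, tolerance = 0.01)
})

test_that("a 5 Mb depth-neutral imbalance run is never reported as cnLOH", {
  fx <- caller_fixture()
  truth <- tibble::tibble(chrom = "1", start = 70e6, end = 75e6,
                          type = "CNLOH", clonal_fraction = 0.8)
  for (r in 1:5) {
    ev <- run_caller(fx, truth, seed = 400 + r)
    expect_false(any(ev$event_type == "CNLOH"))
  }
})

test_that("breakpoints refine to sub-bin accuracy on simulated truth", {
  fx <- caller_fixture()
  hits <- 0; errs <- c()
  for (r in 1:20) {
    st <- withr::with_seed(r, runif(1, 20e6, 70e6))
    truth <- tibble::tibble(chrom = "1", start = st, end = st + 60e6,
                            type = "DEL", clonal_fraction = 0.6)
    ev <- run_caller(fx, truth, seed = 500 + r)
    del <- ev[ev$event_type == "DEL", ]
    if (nrow(del) == 1) {
      hits <- hits + 1
      errs <- c(errs, abs(del$start - st), abs(del$end - (st + 60e6)))
    }
  }
  expect_gte(hits, 19)
  # within one bin in >= 95% of breakpoints, and typically within a few
  # SNP spacings
  expect_gte(mean(errs <= 1e6), 0.95)
  expect_lt(median(errs), 1e5)
})

test_that("whole-chromosome lesions are relabelled monosomy/trisomy", {
  fx <- multi_fixture()
  ev <- run_caller(fx, tibble::tibble(chrom = "3", start = 0, end = 100e6,
                                      type = "MONOSOMY",
                                      clonal_fraction = 0.8), seed = 61)
  expect_equal(ev$event_type, "MONOSOMY")
  expect_equal(ev$start, 0)
  expect_equal(ev$end, 100e6)
  expect_equal(ev$label, "-3")
  ev2 <- run_caller(fx, tibble::tibble(chrom = "3", start = 0, end = 100e6,
                                       type = "TRISOMY",
                                       clonal_fraction = 0.6), seed = 62)
  expect_equal(ev2$event_type, "TRISOMY")
  expect_equal(ev2$label, "+3")
})

test_that("refinement leaves events without informative SNPs flagged", {
  baf <- synthetic_baf(het_mbaf = 0.5)
  ev <- tibble::tibble(chrom = "2", start = 10e6, end = 20e6,
                       outer_start = 10e6, outer_end = 20e6,
                       event_type = "DEL", clonal_fraction = 0.5,
                       ci_low = NA_real_, ci_high = NA_real_,
                       evidence = "depth_only", n_het_snps = 0L,
                       n_bins = 10L, requires_confirmation = FALSE,
                       flags = "", label = NA_character_)
  out <- refine_breakpoints(ev, baf, integration_thresholds())
  expect_equal(out$start, 10e6)
  expect_match(out$flags, "breakpoint_bin_resolution")
})

test_that("chromothripsis flagging counts oscillating switches per arm", {
  g <- toy_genome(lengths = c(`1` = 150e6))
  one_del <- tibble::tibble(chrom = "1", start = 70e6, end = 80e6,
                            event_type = "DEL")
  expect_false(any(flag_chromothripsis(one_del, g)$flagged))
  osc <- tibble::tibble(chrom = "1",
                        start = c(62, 66, 70, 74, 78) * 1e6,
                        end = c(64, 68, 72, 76, 80) * 1e6,
                        event_type = "DEL")
  fl <- flag_chromothripsis(osc, g)
  expect_true(fl$flagged[fl$chrom == "1" & fl$arm == "q"])
  empty <- one_del[0, ]
  expect_false(any(flag_chromothripsis(empty, g)$flagged))
})

test_that("oscillating simulated lesions raise the chromothripsis flag", {
  fx <- caller_fixture()
  truth <- tibble::tibble(
    chrom = "1",
    start = c(62, 68, 74, 80, 86) * 1e6,
    end = c(65, 71, 77, 83, 89) * 1e6,
    type = "DEL", clonal_fraction = 0.9)
  ev <- run_caller(fx, truth, seed = 71)
  ct <- attr(ev, "chromothripsis")
  expect_true(any(ct$flagged))
})

test_that("event types and fractions recover end-to-end on seeded genomes", {
  fx <- multi_fixture()
  cases <- tidyr::expand_grid(
    type = c("DEL", "CNLOH", "TRISOMY", "MONOSOMY", "DUP"),
    f = c(0.2, 0.4, 0.8), rep = 1:4)
  all_events <- list()
  results <- purrr::pmap_lgl(cases, function(type, f, rep) {
    whole <- type %in% c("MONOSOMY", "TRISOMY")
    span <- switch(type, DEL = 60e6, CNLOH = 59e6, DUP = 64e6, 100e6)
    chrom <- if (whole) "3" else "1"
    st <- if (whole) 0 else
      withr::with_seed(rep * 17 + round(100 * f), runif(1, 5e6, 80e6))
    truth <- tibble::tibble(chrom = chrom, start = st, end = st + span,
                            type = type, clonal_fraction = f)
    ev <- run_caller(fx, truth, seed = 1000 + rep * 31 + round(100 * f) +
                       nchar(type))
    all_events[[length(all_events) + 1]] <<- ev
    types_ok <- switch(type, MONOSOMY = c("MONOSOMY", "DEL"),
                       TRISOMY = c("TRISOMY", "DUP"), type)
    overlaps_truth(ev, truth, types_ok)
  })
  high <- cases$f >= 0.4
  expect_gte(mean(results[high]), 0.95)
  expect_gte(mean(results[!high]), 0.80)
  # hard invariants over everything the caller reported
  ev_all <- dplyr::bind_rows(all_events)
  cnloh <- ev_all[ev_all$event_type == "CNLOH", ]
  expect_true(all(cnloh$outer_end - cnloh$outer_start >= 1e7))
  expect_true(all(cnloh$n_het_snps >= 200))
  expect_true(all(!is.na(ev_all$evidence)))
  # monosomy and cnLOH never overlap on the same region
  mono <- ev_all[ev_all$event_type == "MONOSOMY", ]
  if (nrow(mono) > 0 && nrow(cnloh) > 0) {
    for (i in seq_len(nrow(mono))) {
      expect_false(any(cnloh$chrom == mono$chrom[i] &
                         cnloh$start < mono$end[i] &
                         cnloh$end > mono$start[i]))
    }
  }
})

test_that("event-free samples yield no confirmed events", {
  fx <- caller_fixture()
  for (r in 1:5) {
    ev <- run_caller(fx, NULL, seed = 900 + r)
    expect_equal(sum(ev$event_type != "AMBIGUOUS"), 0)
  }
})
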