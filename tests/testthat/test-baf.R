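# mirrored-BAF engine

test_that("compute_baf folds counts of the two most common alleles", {
  d <- tibble::tibble(chrom = "1", pos = c(1, 2, 3) * 1e6,
                      ref_count = c(30, 60, 45), alt_count = c(30, 0, 15))
  b <- compute_baf(d)
  expect_equal(b$baf, c(0.5, 1.0, 0.75))
  expect_true(all(b$baf >= 0.5 & b$baf <= 1))
  expect_equal(b$depth_used, c(60, 60, 60))
})

test_that("compute_baf handles a dominant error allele and low depth", {
  d <- tibble::tibble(chrom = "1", pos = c(1e6, 2e6),
                      ref_count = c(5, 100), alt_count = c(4, 40),
                      other_count = c(30, 2))
  b <- compute_baf(d, min_depth = 20)
  # first locus: the two most common alleles are other (30) and ref (5)
  expect_equal(b$count_major[1], 30)
  expect_equal(b$count_minor[1], 5)
  expect_equal(b$baf[1], 30 / 35)
  expect_equal(b$baf[2], 100 / 140)
  b_low <- compute_baf(dplyr::mutate(d, ref_count = c(5, 8),
                                     alt_count = c(4, 6),
                                     other_count = 0))
  expect_true(all(is.na(b_low$baf)))
  expect_error(compute_baf(dplyr::mutate(d, ref_count = -1)),
               class = "onekaryo_validation_error")
})

test_that("het calling applies the threshold inclusively", {
  b <- compute_baf(tibble::tibble(
    chrom = "1", pos = c(1, 2, 3, 4) * 1e6,
    ref_count = c(30, 60, 33, 39), alt_count = c(30, 0, 17, 21)))
  h <- call_het(b, het_max_baf = 0.65)
  expect_equal(h$is_het, c(TRUE, FALSE, FALSE, TRUE))  # 0.66 is above 0.65
  expect_error(call_het(b, het_max_baf = 1),
               class = "onekaryo_validation_error")
  masked <- call_het(b, exclude_regions = tibble::tibble(
    chrom = "1", start = 0.5e6, end = 2.5e6))
  expect_equal(masked$in_candidate, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("expected mirrored BAF closed forms and limits hold", {
  expect_equal(expected_mbaf("CNLOH", 1), 1)
  expect_equal(expected_mbaf("CNLOH", 0.5), 0.75)
  expect_equal(expected_mbaf("DEL", 1), 1)
  expect_equal(expected_mbaf("DUP", 1), 2 / 3)
  # all types collapse to 0.5 with no tumor
  for (type in c("NORMAL", "CNLOH", "DEL", "DUP", "TRISOMY", "MONOSOMY")) {
    expect_equal(expected_mbaf(type, 0), 0.5)
  }
  # strictly increasing in f
  f <- seq(0, 1, by = 0.01)
  for (type in c("CNLOH", "DEL", "DUP")) {
    expect_true(all(diff(expected_mbaf(type, f)) > 0))
  }
  expect_error(expected_mbaf("INVERSION", 0.5),
               class = "onekaryo_validation_error")
  expect_error(expected_mbaf("DEL", 1.5),
               class = "onekaryo_validation_error")
})

test_that("expected mBAF for a half-clonal deletion matches forward simulation", {
  # brute-force oracle: binomial allele counts at depth 1e4 for het SNPs
  # carrying a deletion in half the cells
  p_alt <- withr::with_seed(1, {
    u <- stats::rbinom(4000, 1, 0.5)
    (1 - 0.5 + u * 0.5) / (2 - 0.5)
  })
  counts <- withr::with_seed(2, stats::rbinom(4000, 10000, p_alt))
  mbaf <- pmax(counts, 10000 - counts) / 10000
  expect_equal(mean(mbaf), expected_mbaf("DEL", 0.5), tolerance = 0.001)
  expect_equal(expected_mbaf("DEL", 0.5), 2 / 3, tolerance = 1e-9)
})

test_that("clonal fraction inversion recovers the closed forms", {
  expect_equal(estimate_clonal_fraction(rep(0.75, 300), "CNLOH",
                                        n_boot = 0)$f_hat, 0.5)
  expect_equal(estimate_clonal_fraction(rep(1, 300), "DEL",
                                        n_boot = 0)$f_hat, 1)
  # DUP at median 0.6 -> f = 0.5, cross-checked by forward simulation
  expect_equal(estimate_clonal_fraction(rep(0.6, 300), "DUP",
                                        n_boot = 0)$f_hat, 0.5)
  m_sim <- withr::with_seed(3, {
    u <- stats::rbinom(5000, 1, 0.5)
    p <- (1 + u * 0.5) / 2.5
    counts <- stats::rbinom(5000, 10000, p)
    median(pmax(counts, 10000 - counts) / 10000)
  })
  expect_equal(m_sim, 0.6, tolerance = 0.005)
})

test_that("too few het SNPs raises insufficient evidence, not zero", {
  expect_error(estimate_clonal_fraction(rep(0.75, 5), "CNLOH"),
               class = "onekaryo_insufficient_evidence")
})

test_that("bootstrap intervals bracket the estimate deterministically", {
  baf <- withr::with_seed(4, 0.75 + rnorm(400, 0, 0.02))
  e1 <- estimate_clonal_fraction(baf, "CNLOH", n_boot = 200, seed = 9)
  e2 <- estimate_clonal_fraction(baf, "CNLOH", n_boot = 200, seed = 9)
  expect_identical(tidy(e1), tidy(e2))
  expect_lte(e1$ci_low, e1$f_hat)
  expect_gte(e1$ci_high, e1$f_hat)
  expect_equal(e1$f_hat, 0.5, tolerance = 0.02)
})

test_that("clonal-fraction recovery is within 0.05 across lesion types", {
  # parameter-recovery suite: >= 200 het SNPs at depth 300 over the
  # fraction grid, forward-simulated from the closed forms
  for (type in c("CNLOH", "DEL", "DUP")) {
    for (f in seq(0.2, 1, by = 0.2)) {
      m <- expected_mbaf(type, f)
      sim <- withr::with_seed(round(1000 * f) + nchar(type), {
        n_tot <- 600
        is_het <- stats::runif(n_tot) < 0.488
        if (type == "DEL" && f == 1) {
          # het SNPs are gone entirely in a pure clonal deletion
          is_het[] <- is_het & FALSE
        }
        u <- stats::rbinom(n_tot, 1, 0.5)
        p <- ifelse(is_het,
                    ifelse(u == 1, m, 1 - m),
                    ifelse(stats::runif(n_tot) < 0.5, 0.002, 0.998))
        counts <- stats::rbinom(n_tot, 300, p)
        pmax(counts, 300 - counts) / 300
      })
      band <- sim[sim <= 0.97]
      est <- tryCatch(
        estimate_clonal_fraction(band, type, n_boot = 0,
                                 n_total_snps = length(sim),
                                 fold_sigma = 0.5 / sqrt(300)),
        onekaryo_insufficient_evidence = function(e) list(f_hat = 1))
      expect_lt(abs(est$f_hat - f), 0.05)
    }
  }
})

test_that("unfolding removes the balanced-band median bias", {
  sigma <- 0.5 / sqrt(300)
  folded_null <- withr::with_seed(5, {
    counts <- stats::rbinom(20000, 300, 0.5)
    median(pmax(counts, 300 - counts) / 300)
  })
  # binomial lattice discreteness leaves a small residual; the correction
  # must remove most of the ~0.02 folded-median bias
  expect_lt(abs(unfold_median(folded_null, sigma) - 0.5), 0.01)
  # a strongly separated band is (almost) unaffected
  expect_equal(unfold_median(0.9, sigma), 0.9, tolerance = 1e-3)
})
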