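# mirrored B-allele frequency engine: BAF computation, het calling,
# closed-form expected mBAF per lesion type, clonal-fraction estimation

#' Compute the mirrored B-allele frequency track
#'
#' At each SNP the two most common allele counts are identified and the BAF
#' is the major count divided by the sum of the two; the track is therefore
#' folded ("mirrored") into \[0.5, 1\] by construction. Loci with fewer than
#' `min_depth` reads over the two major alleles get `baf = NA` and are
#' excluded downstream.
#'
#' @param depths tibble with columns `chrom`, `pos`, `ref_count`, `alt_count`
#'   and optionally `other_count` (and any extra columns, which are kept).
#' @param min_depth minimum usable depth (default 20).
#' @return the input with `count_major`, `count_minor`, `depth_used` and
#'   `baf` columns appended.
#' @export
#' @examples
#' compute_baf(tibble::tibble(chrom = "1", pos = 1:3,
#'                            ref_count = c(30, 60, 45),
#'                            alt_count = c(30, 0, 15)))
compute_baf <- function(depths, min_depth = 20) {
  assert_columns(depths, c("chrom", "pos", "ref_count", "alt_count"))
  if (min_depth < 1) {
    stop_onekaryo("min_depth must be >= 1",
                  class = "onekaryo_validation_error")
  }
  other <- if ("other_count" %in% names(depths)) depths$other_count else 0
  assert_non_negative(depths$ref_count, "ref_count")
  assert_non_negative(depths$alt_count, "alt_count")
  assert_non_negative(other, "other_count")
  if (nrow(depths) == 0) {
    return(dplyr::mutate(depths, count_major = numeric(),
                         count_minor = numeric(), depth_used = numeric(),
                         baf = numeric()))
  }
  other <- rep_len(other, nrow(depths))
  total <- depths$ref_count + depths$alt_count + other
  major <- pmax(depths$ref_count, depths$alt_count, other)
  minor <- total - major - pmin(depths$ref_count, depths$alt_count, other)
  depth_used <- major + minor
  baf <- ifelse(depth_used >= min_depth, major / depth_used, NA_real_)
  dplyr::mutate(depths, count_major = major, count_minor = minor,
                depth_used = depth_used, baf = baf)
}

#' Call heterozygous loci on a mirrored BAF track
#'
#' A locus is called heterozygous when its mirrored BAF does not exceed
#' `het_max_baf`. With backbone MAFs of 0.40-0.45 and depth >= 20, a simple
#' threshold separates the het band (centred at 0.5 in diploid regions) from
#' homozygous loci (near 1). The threshold is meant to be calibrated on
#' diploid territory: when `exclude_regions` (a tibble chrom/start/end of
#' candidate lesions) is supplied, loci inside those regions keep their
#' threshold call but are flagged `in_candidate = TRUE` so callers can
#' restrict genome-wide het-rate estimation to undisturbed territory.
#'
#' @param baf_points output of [compute_baf()].
#' @param het_max_baf upper mirrored-BAF bound for a het call (default 0.65);
#'   must lie in \[0.5, 1).
#' @param exclude_regions optional candidate-lesion mask.
#' @return `baf_points` with logical `is_het` (and `in_candidate` if a mask
#'   was given).
#' @export
call_het <- function(baf_points, het_max_baf = 0.65, exclude_regions = NULL) {
  if (het_max_baf < 0.5 || het_max_baf >= 1) {
    stop_onekaryo("het_max_baf must lie in [0.5, 1)",
                  class = "onekaryo_validation_error")
  }
  out <- dplyr::mutate(baf_points,
                       is_het = !is.na(.data$baf) & .data$baf <= het_max_baf)
  if (!is.null(exclude_regions) && nrow(exclude_regions) > 0) {
    inside <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(exclude_regions))) {
      inside <- inside | (out$chrom == exclude_regions$chrom[i] &
                            out$pos > exclude_regions$start[i] &
                            out$pos <= exclude_regions$end[i])
    }
    out$in_candidate <- inside
  }
  out
}

#' Expected mirrored BAF of a heterozygous SNP under a lesion
#'
#' Closed forms of standard allelic-imbalance algebra for a lesion present in
#' a fraction `f` of cells: `NORMAL -> 1/2`; `CNLOH -> (1+f)/2`;
#' `DEL`/`MONOSOMY -> 1/(2-f)`; `DUP`/`TRISOMY -> (1+f)/(2+f)`.
#' All collapse to 0.5 at `f = 0`.
#'
#' @param event_type one of NORMAL, DEL, DUP, TRISOMY, MONOSOMY, CNLOH
#'   (vectorized).
#' @param f clonal fraction in \[0, 1\] (vectorized).
#' @return expected mirrored BAF in \[0.5, 1\].
#' @export
#' @examples
#' expected_mbaf("CNLOH", c(0, 0.5, 1))
expected_mbaf <- function(event_type, f) {
  if (any(f < 0 | f > 1)) {
    stop_onekaryo("f must lie in [0, 1]",
                  class = "onekaryo_validation_error")
  }
  n <- max(length(event_type), length(f))
  event_type <- rep_len(event_type, n)
  f <- rep_len(f, n)
  known <- c("NORMAL", "DEL", "DUP", "TRISOMY", "MONOSOMY", "CNLOH")
  if (!all(event_type %in% known)) {
    stop_onekaryo(paste0("unknown event type(s): ",
                         paste(setdiff(event_type, known), collapse = ", ")),
                  class = "onekaryo_validation_error")
  }
  dplyr::case_when(
    event_type == "NORMAL" ~ 0.5,
    event_type == "CNLOH" ~ (1 + f) / 2,
    event_type %in% c("DEL", "MONOSOMY") ~ 1 / (2 - f),
    event_type %in% c("DUP", "TRISOMY") ~ (1 + f) / (2 + f)
  )
}

#' Invert the expected mirrored BAF to a clonal fraction
#'
#' @param event_type lesion type (CNLOH, DEL/MONOSOMY or DUP/TRISOMY).
#' @param m observed mirrored BAF of the het band, in \[0.5, 1\].
#' @return clonal fraction clamped to \[0, 1\].
#' @export
invert_mbaf <- function(event_type, m) {
  n <- max(length(event_type), length(m))
  event_type <- rep_len(event_type, n)
  m <- rep_len(m, n)
  f <- dplyr::case_when(
    event_type == "CNLOH" ~ 2 * m - 1,
    event_type %in% c("DEL", "MONOSOMY") ~ 2 - 1 / m,
    event_type %in% c("DUP", "TRISOMY") ~ (2 * m - 1) / pmax(1 - m, 1e-12),
    TRUE ~ NA_real_
  )
  pmin(pmax(f, 0), 1)
}

#' Estimate the clonal fraction of a lesion from regional het SNPs
#'
#' Inverts the closed-form expected mirrored BAF at the median mBAF of the
#' heterozygous SNPs in a lesion region and attaches a percentile bootstrap
#' interval over SNPs. When the het band has collapsed into the homozygous
#' band (near-complete LOH under a deletion or cnLOH, recognisable as a
#' het-band occupancy far below the panel expectation), the fraction is
#' estimated from the het-band deficit `1 - observed/expected` instead, since
#' the band median is then uninformative. Supply `n_total_snps` (all usable
#' SNPs in the region) to enable the deficit route.
#'
#' @param het_baf het-band mirrored BAF values in the region (numeric), i.e.
#'   `baf` of SNPs below the homozygous boundary.
#' @param event_type lesion type whose closed form is inverted.
#' @param n_boot bootstrap replicates for the percentile interval
#'   (default 200; 0 skips the interval).
#' @param seed integer seed for the bootstrap.
#' @param min_het_snps minimum usable het SNPs (default 20); fewer raises an
#'   insufficient-evidence error (distinct from an estimate of 0).
#' @param n_total_snps total usable SNPs in the region (optional).
#' @param expected_het_rate panel het expectation (default 0.488, i.e.
#'   `mean(2 maf (1-maf))` over MAF 0.40-0.45).
#' @param fold_sigma per-SNP noise scale used to correct the folded-median
#'   bias (see [unfold_median()]); `NULL` skips the correction.
#' @return object of class `clonal_fraction`: list with `event_type`,
#'   `f_hat`, `ci_low`, `ci_high`, `n_het_snps`, `method`.
#' @export
estimate_clonal_fraction <- function(het_baf, event_type, n_boot = 200,
                                     seed = NULL, min_het_snps = 20,
                                     n_total_snps = NULL,
                                     expected_het_rate = 0.488,
                                     fold_sigma = NULL) {
  het_baf <- het_baf[!is.na(het_baf)]
  n_het <- length(het_baf)
  deficit_route <- FALSE
  if (!is.null(n_total_snps) && n_total_snps > 0) {
    occupancy <- n_het / (n_total_snps * expected_het_rate)
    if (occupancy < 0.5 && event_type %in% c("DEL", "MONOSOMY", "CNLOH")) {
      deficit_route <- TRUE
    }
  }
  if (!deficit_route && n_het < min_het_snps) {
    stop_onekaryo(
      sprintf("only %d het SNPs in region (need >= %d)", n_het, min_het_snps),
      class = "onekaryo_insufficient_evidence"
    )
  }
  point <- function(bafs, n_band) {
    if (deficit_route) {
      pmin(pmax(1 - n_band / (n_total_snps * expected_het_rate), 0), 1)
    } else {
      m <- median(bafs)
      if (!is.null(fold_sigma) && !is.na(fold_sigma)) {
        m <- unfold_median(m, fold_sigma)
      }
      invert_mbaf(event_type, m)
    }
  }
  f_hat <- point(het_baf, n_het)
  # analytic normal interval: delta method through the inversion (bootstrap
  # below overrides it when requested)
  se_f <- if (deficit_route) {
    sqrt(n_het + 1) / (n_total_snps * expected_het_rate)
  } else {
    m <- median(het_baf)
    se_m <- 1.2533 * stats::sd(het_baf) / sqrt(n_het)
    deriv <- switch(event_type,
                    CNLOH = 2,
                    DEL = , MONOSOMY = 1 / m^2,
                    DUP = , TRISOMY = 1 / max(1 - m, 1e-6)^2,
                    2)
    se_m * deriv
  }
  ci <- c(max(f_hat - 1.96 * se_f, 0), min(f_hat + 1.96 * se_f, 1))
  if (n_boot > 0 && n_het > 1) {
    boots <- with_seed_if(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n_het, n_het, replace = TRUE)
        point(het_baf[idx], n_het)
      }, numeric(1))
    })
    ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
    ci[1] <- min(ci[1], f_hat)
    ci[2] <- max(ci[2], f_hat)
  }
  structure(
    list(event_type = event_type, f_hat = f_hat,
         ci_low = ci[1], ci_high = ci[2], n_het_snps = n_het,
         method = if (deficit_route) "het_deficit" else "mbaf_inversion"),
    class = "clonal_fraction"
  )
}

#' @export
print.clonal_fraction <- function(x, ...) {
  cat(sprintf(
    "Clonal fraction (%s): %.3f [%.3f, %.3f], %d het SNPs (%s)\n",
    x$event_type, x$f_hat, x$ci_low, x$ci_high, x$n_het_snps, x$method))
  invisible(x)
}

#' @export
tidy.clonal_fraction <- function(x, ...) {
  tibble::tibble(event_type = x$event_type, f_hat = x$f_hat,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_het_snps = x$n_het_snps, method = x$method)
}

#' Unfold a mirrored-BAF band median
#'
#' The mirrored (folded) representation biases the band median upward: a
#' perfectly balanced het band with per-SNP noise `sigma` has folded median
#' `0.5 + 0.674 sigma`, not 0.5. Given the observed folded median and the
#' binomial noise scale, this solves the folded-normal median equation for
#' the underlying band centre, removing the bias without affecting strongly
#' separated bands (where folding is negligible).
#'
#' @param m observed folded band median in \[0.5, 1\].
#' @param sigma per-SNP mirrored-BAF noise standard deviation.
#' @return estimated band centre in \[0.5, 1\].
#' @export
unfold_median <- function(m, sigma) {
  if (is.na(m) || is.na(sigma) || sigma <= 0) return(m)
  g <- function(mu) {
    stats::pnorm((m - mu) / sigma) - stats::pnorm((1 - m - mu) / sigma) - 0.5
  }
  if (g(0.5) <= 0) return(0.5)        # at or below the balanced null median
  if (g(m) >= 0) return(m)
  stats::uniroot(g, c(0.5, m), tol = 1e-6)$root
}

# Regional BAF summary used by the integrator: identifies the het band
# (mBAF below the homozygous boundary), its occupancy relative to the panel
# expectation, and the separation of its median from 0.5.
baf_region_summary <- function(baf_points, chrom, start, end,
                               hom_min_baf = 0.97,
                               expected_het_rate = 0.488) {
  pts <- baf_points[baf_points$chrom == chrom & baf_points$pos > start &
                      baf_points$pos <= end & !is.na(baf_points$baf), ,
                    drop = FALSE]
  n_snps <- nrow(pts)
  in_band <- pts$baf <= hom_min_baf
  band <- pts$baf[in_band]
  n_band <- length(band)
  expected_het <- n_snps * expected_het_rate
  occupancy <- if (expected_het > 0) n_band / expected_het else NA_real_
  loh_complete <- !is.na(occupancy) && occupancy < 0.5
  median_band <- if (n_band > 0) median(band) else NA_real_
  # binomial noise scale of the band, for the folded-median bias correction
  fold_sigma <- if (n_band > 0 && "depth_used" %in% names(pts)) {
    0.5 / sqrt(max(median(pts$depth_used[in_band]), 1))
  } else NA_real_
  band_center <- if (n_band > 0) unfold_median(median_band, fold_sigma) else
    NA_real_
  separation <- if (loh_complete) 0.5
  else if (n_band > 0) band_center - 0.5 else NA_real_
  list(n_snps = n_snps, n_band = n_band,
       n_het_informative = if (loh_complete) round(expected_het) else n_band,
       occupancy = occupancy, loh_complete = loh_complete,
       median_band_mbaf = median_band, band_center = band_center,
       fold_sigma = fold_sigma, separation = separation,
       band_baf = band)
}
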