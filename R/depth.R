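# read-depth caller: sex-stratified reference normalization, log2 ratios and
# least-squares changepoint segmentation of binned counts

#' Normalize binned read counts against a reference cohort
#'
#' Median-of-ratios normalization: each sample's bin counts are first divided
#' by its own median autosomal count, then by the per-bin median of the same
#' quantity across sex-matched reference samples. Bins whose reference median
#' is zero are masked (`normalized_ratio = NA`). The log2 of the normalized
#' ratio is the segmentation substrate.
#'
#' @param sample_bins tibble: chrom, bin_start, bin_end, count.
#' @param reference_cohort tidy tibble from [simulate_reference_cohort()] (or
#'   the same columns plus `sample_id`, `sex`).
#' @param sex sample sex ("XX"/"XY"); at least two sex-matched reference
#'   samples are required unless `allow_mixed_reference = TRUE`.
#' @param allow_mixed_reference fall back to the whole cohort when too few
#'   sex-matched references exist.
#' @return `sample_bins` with `normalized_ratio` and `log2_ratio` appended.
#' @export
normalize_depth <- function(sample_bins, reference_cohort, sex = "XX",
                            allow_mixed_reference = FALSE) {
  assert_columns(sample_bins, c("chrom", "bin_start", "bin_end", "count"))
  assert_columns(reference_cohort,
                 c("sample_id", "sex", "chrom", "bin_start", "bin_end",
                   "count"))
  refs <- dplyr::filter(reference_cohort, .data$sex == !!sex)
  if (dplyr::n_distinct(refs$sample_id) < 2) {
    if (allow_mixed_reference) {
      refs <- reference_cohort
    } else {
      stop_onekaryo(
        paste0("fewer than 2 sex-matched reference samples; rerun with ",
               "allow_mixed_reference = TRUE to use the whole cohort"),
        class = "onekaryo_reference_error"
      )
    }
  }
  autosomes <- setdiff(unique(sample_bins$chrom), c("X", "Y"))
  s_med <- median(sample_bins$count[sample_bins$chrom %in% autosomes])
  if (!isTRUE(s_med > 0)) {
    stop_onekaryo("sample median autosomal count is zero",
                  class = "onekaryo_validation_error")
  }
  ref_profile <- refs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel = .data$count /
                    median(.data$count[.data$chrom %in% autosomes])) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$chrom, .data$bin_start, .data$bin_end) |>
    dplyr::summarise(ref_median = median(.data$rel), .groups = "drop")
  out <- sample_bins |>
    dplyr::left_join(ref_profile, by = c("chrom", "bin_start", "bin_end")) |>
    dplyr::mutate(
      normalized_ratio = ifelse(
        !is.na(.data$ref_median) & .data$ref_median > 0,
        (.data$count / s_med) / .data$ref_median, NA_real_),
      log2_ratio = log2(.data$normalized_ratio)
    ) |>
    dplyr::select(-"ref_median")
  out$log2_ratio[is.infinite(out$log2_ratio)] <- NA_real_
  # recentre to the dominant copy-number state: a large lesion drags the
  # sample's median count and would otherwise offset the whole track; the
  # autosomal median log2 is taken as the diploid baseline (valid while
  # less than half the genome is altered)
  baseline <- median(out$log2_ratio[out$chrom %in% autosomes], na.rm = TRUE)
  if (is.finite(baseline)) {
    out$log2_ratio <- out$log2_ratio - baseline
    out$normalized_ratio <- out$normalized_ratio / 2^baseline
  }
  out
}

#' Sample-to-reference profile correlation (QC)
#'
#' Pearson correlation between a sample's raw bin counts and the per-bin
#' median reference profile, the quality metric used to decide whether a
#' sample resembles its normalization cohort. Samples below `qc_floor` are
#' flagged, not dropped.
#'
#' @inheritParams normalize_depth
#' @param qc_floor correlation below which the sample is flagged
#'   (default 0.74, the lower end of the validated assay's observed range).
#' @return list with `correlation`, `n_bins`, `flagged`.
#' @export
reference_correlation <- function(sample_bins, reference_cohort,
                                  qc_floor = 0.74) {
  assert_columns(sample_bins, c("chrom", "bin_start", "bin_end", "count"))
  ref_profile <- reference_cohort |>
    dplyr::group_by(.data$chrom, .data$bin_start, .data$bin_end) |>
    dplyr::summarise(ref_count = median(.data$count), .groups = "drop")
  joined <- dplyr::inner_join(sample_bins, ref_profile,
                              by = c("chrom", "bin_start", "bin_end"))
  joined <- joined[complete.cases(joined[, c("count", "ref_count")]), ]
  if (nrow(joined) < 100) {
    stop_onekaryo("fewer than 100 shared usable bins",
                  class = "onekaryo_validation_error")
  }
  if (stats::sd(joined$count) == 0 || stats::sd(joined$ref_count) == 0) {
    stop_onekaryo("zero-variance coverage profile; correlation undefined",
                  class = "onekaryo_degenerate_error")
  }
  r <- cor(joined$count, joined$ref_count)
  list(correlation = r, n_bins = nrow(joined), flagged = r < qc_floor)
}

# ---- changepoint machinery -------------------------------------------------

# robust noise variance from lag-1 differences
robust_sigma2 <- function(x) {
  d <- diff(x)
  if (length(d) < 2) return(1e-8)
  max((mad(d) / sqrt(2))^2, 1e-8)
}

# PELT for change in mean under a squared-error cost; returns 0-based
# changepoint boundaries (excluding 0 and n). beta is the per-changepoint
# penalty on the SSE scale.
pelt_mean <- function(x, beta) {
  n <- length(x)
  if (n < 2) return(integer(0))
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  seg_cost <- function(s, t) {
    # cost of segment (s, t], s and t 0-based boundaries, vectorized over s
    len <- t - s
    (cs2[t + 1] - cs2[s + 1]) - (cs[t + 1] - cs[s + 1])^2 / len
  }
  f <- c(-beta, rep(Inf, n))
  prev <- integer(n + 1)
  cands <- 0L
  for (t in seq_len(n)) {
    costs <- f[cands + 1L] + beta + seg_cost(cands, t)
    best <- which.min(costs)
    f[t + 1L] <- costs[best]
    prev[t + 1L] <- cands[best]
    keep <- (f[cands + 1L] + seg_cost(cands, t)) <= f[t + 1L]
    cands <- c(cands[keep], t)
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1L]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

# Multiscale one-sided run scan (circular-binary-segmentation style): slides
# windows of dyadic widths and marks every window whose mean exceeds the
# out-of-window mean by z_thresh noise units. A segment-versus-rest
# statistic keeps power for short runs embedded in a long series, which a
# plain left-versus-right binary split lacks. Returns a list of 1-based
# index intervals (unions of significant windows).
scan_runs <- function(x, z_thresh, min_size, sigma) {
  n <- length(x)
  sigma <- max(sigma, 1e-6)
  if (n < 2 * min_size) return(list())
  cs <- c(0, cumsum(x))
  tot <- cs[n + 1]
  mark <- numeric(n + 2)
  found <- FALSE
  w <- as.integer(min_size)
  while (w <= n %/% 2) {
    win <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    z <- (win / w - (tot - win) / (n - w)) /
      (sigma * sqrt(1 / w + 1 / (n - w)))
    hit <- which(z >= z_thresh)
    if (length(hit) > 0) {
      mark[hit] <- mark[hit] + 1
      mark[hit + w] <- mark[hit + w] - 1
      found <- TRUE
    }
    w <- w * 2L
  }
  if (!found) return(list())
  inside <- cumsum(mark[1:n]) > 0
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  # the union of significant windows overshoots broad runs; localize each
  # run's edges with a least-squares split on either side of its peak
  lapply(keep, function(k) {
    a <- max(1L, starts[k] - as.integer(min_size))
    b <- min(n, ends[k] + as.integer(min_size))
    centre <- run_centre(x, a, b, min_size)
    left <- if (centre - a >= 4) {
      sp <- ls_split(x[a:centre])
      if (is.na(sp)) a else a + sp
    } else a
    right <- if (b - centre >= 4) {
      sp <- ls_split(x[centre:b])
      if (is.na(sp)) b else centre + sp - 1L
    } else b
    if (right <= left) c(starts[k], ends[k]) else c(left, right)
  })
}

# position of the maximal sliding-window mean at the finest scale
run_centre <- function(x, a, b, w) {
  seg <- x[a:b]
  m <- length(seg)
  w <- min(as.integer(w), m)
  cs <- c(0, cumsum(seg))
  means <- (cs[(w + 1):(m + 1)] - cs[1:(m - w + 1)]) / w
  a + which.max(means) - 1L + w %/% 2L
}

# best single change-in-mean split of a series (1-based index of the last
# point of the left part); NA when too short
ls_split <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_integer_)
  cs <- cumsum(x)
  k <- 1:(n - 1)
  gain <- (cs[k] / k - (cs[n] - cs[k]) / (n - k))^2 * k * (n - k) / n
  which.max(gain)
}

#' Segment a log2-ratio track into constant-mean intervals
#'
#' Per chromosome, masked bins are dropped and the remaining log2 ratios are
#' segmented with a PELT least-squares changepoint search. The per-changepoint
#' penalty is `penalty_mult * sigma2 * log(n)` where `sigma2` is a robust
#' (median-absolute-deviation of lag-1 differences) noise variance estimate:
#' a BIC-style penalty that scales with the observed bin noise rather than a
#' hard-coded constant.
#'
#' @param bins output of [normalize_depth()] (needs `log2_ratio`).
#' @param penalty optional explicit per-changepoint SSE penalty.
#' @param penalty_mult multiplier of the BIC-style default penalty
#'   (default 4).
#' @return tibble of segments: chrom, start, end, n_bins, mean_log2, masked.
#'   A chromosome whose bins are all masked yields one segment with
#'   `masked = TRUE` and `mean_log2 = NA`.
#' @export
segment_log2 <- function(bins, penalty = NULL, penalty_mult = 4) {
  assert_columns(bins, c("chrom", "bin_start", "bin_end", "log2_ratio"))
  purrr::map_dfr(split(bins, factor(bins$chrom, unique(bins$chrom))),
                 function(b) {
    b <- dplyr::arrange(b, .data$bin_start)
    usable <- !is.na(b$log2_ratio)
    if (!any(usable)) {
      return(tibble::tibble(chrom = b$chrom[1], start = min(b$bin_start),
                            end = max(b$bin_end), n_bins = nrow(b),
                            mean_log2 = NA_real_, masked = TRUE))
    }
    bu <- b[usable, ]
    x <- bu$log2_ratio
    n <- length(x)
    beta <- penalty %||% (penalty_mult * robust_sigma2(x) * log(max(n, 2)))
    cps <- if (n >= 2) pelt_mean(x, beta) else integer(0)
    bounds <- c(0, cps, n)
    purrr::map_dfr(seq_len(length(bounds) - 1), function(i) {
      lo <- bounds[i] + 1
      hi <- bounds[i + 1]
      tibble::tibble(
        chrom = bu$chrom[1],
        start = if (i == 1) min(b$bin_start) else bu$bin_start[lo],
        end = if (i == length(bounds) - 1) max(b$bin_end) else bu$bin_end[hi],
        n_bins = hi - lo + 1L,
        mean_log2 = mean(x[lo:hi]),
        masked = FALSE
      )
    })
  })
}

#' Diploid baseline from the dominant segment state
#'
#' A sample's median-count normalization is biased when a sizeable share of
#' the genome is altered; the unbiased baseline is the copy-number state
#' carrying most bins. Segment means are clustered within `tol` and the
#' bin-weighted mean of the heaviest cluster is returned; subtracting it
#' recentres the dominant state at log2 = 0 (valid while less than half the
#' genome is altered).
#'
#' @param segments output of [segment_log2()].
#' @param tol cluster half-width on the log2 scale (default 0.05).
#' @return baseline log2 offset (numeric scalar; 0 when undeterminable).
#' @export
segment_baseline <- function(segments, tol = 0.05) {
  s <- segments[!segments$masked & !is.na(segments$mean_log2) &
                  !segments$chrom %in% c("X", "Y"), , drop = FALSE]
  if (nrow(s) == 0) return(0)
  weight <- vapply(seq_len(nrow(s)), function(i) {
    sum(s$n_bins[abs(s$mean_log2 - s$mean_log2[i]) <= tol])
  }, numeric(1))
  i <- which.max(weight)
  keep <- abs(s$mean_log2 - s$mean_log2[i]) <= tol
  sum(s$mean_log2[keep] * s$n_bins[keep]) / sum(s$n_bins[keep])
}

# mean log2 over an arbitrary interval, overlap-weighted
region_mean_log2 <- function(bins, chrom, start, end) {
  b <- bins[bins$chrom == chrom & !is.na(bins$log2_ratio), , drop = FALSE]
  ov <- pmax(0, pmin(b$bin_end, end) - pmax(b$bin_start, start))
  if (sum(ov) == 0) {
    return(list(mean_log2 = NA_real_, n_bins = 0L, coverage_frac = 1))
  }
  hit <- ov > 0
  list(mean_log2 = sum(b$log2_ratio * ov) / sum(ov),
       n_bins = sum(hit),
       # share of the overlapped bins actually covered by the interval: a
       # sub-bin lesion's depth signal is attenuated by this factor
       coverage_frac = sum(ov) / sum(b$bin_end[hit] - b$bin_start[hit]))
}
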