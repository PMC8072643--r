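# event integrator: reconcile depth segments with the mirrored-BAF track into
# classified genomic events with clonal fractions and refined breakpoints

#' Integration thresholds
#'
#' Tunable cut lines of the depth/BAF decision table. Defaults encode the
#' assay's stated resolutions: 1 Mb for copy-number alterations, 10 Mb with
#' at least 200 het SNPs for copy-neutral LOH, and a 20 percent-of-cells
#' reporting floor. The strong-separation threshold 0.08 sits just under the
#' 0.10 mirrored-BAF shift of a cnLOH at the 20% detection floor; the weak
#' floor 0.02 only guards against residual bias when corroborating a depth
#' call.
#'
#' @param min_cna_size_bp minimum reported CNA span (default 1e6).
#' @param min_cnloh_size_bp minimum reported cnLOH span (default 1e7; must be
#'   >= `min_cna_size_bp`).
#' @param min_cnloh_het_snps minimum informative het SNPs in a cnLOH
#'   (default 200).
#' @param mbaf_separation_min het-band separation treated as standalone BAF
#'   evidence (default 0.08).
#' @param weak_separation_min separation treated as corroborating evidence
#'   for a depth call (default 0.02).
#' @param log2_loss_max,log2_gain_min log2-ratio cut lines; the open interval
#'   between them is the copy-neutral band (defaults -0.1 / 0.1).
#' @param hom_min_baf mirrored BAF above which a locus is treated as part of
#'   the homozygous band (default 0.97).
#' @param min_clonal_fraction_report smallest clonal fraction reported
#'   (default 0.2).
#' @param min_het_snps_cf het SNPs needed for a BAF clonal-fraction estimate.
#' @param ambiguous_f_diff disagreement between BAF- and depth-implied
#'   fractions beyond which an event is tagged AMBIGUOUS (default 0.4).
#' @param whole_chrom_fraction span fraction above which a DEL/DUP is
#'   relabelled MONOSOMY/TRISOMY (default 0.9).
#' @param rescue_z CUSUM z threshold of the BAF-only rescue scan (default 5).
#' @param rescue_min_snps minimum SNPs per rescue segment (default 20).
#' @param refine_window_bp half-window around a breakpoint searched during
#'   SNP-level refinement (default 2e6).
#' @param chromothripsis_min_switches copy-number state switches within one
#'   arm that trigger the chromothripsis flag (default 4).
#' @param n_boot bootstrap replicates for clonal-fraction intervals.
#' @return list of class `integration_thresholds`.
#' @export
integration_thresholds <- function(min_cna_size_bp = 1e6,
                                   min_cnloh_size_bp = 1e7,
                                   min_cnloh_het_snps = 200,
                                   mbaf_separation_min = 0.08,
                                   weak_separation_min = 0.02,
                                   log2_loss_max = -0.1,
                                   log2_gain_min = 0.1,
                                   hom_min_baf = 0.97,
                                   min_clonal_fraction_report = 0.2,
                                   min_het_snps_cf = 20,
                                   ambiguous_f_diff = 0.4,
                                   whole_chrom_fraction = 0.9,
                                   rescue_z = 5,
                                   rescue_min_snps = 20,
                                   refine_window_bp = 5e6,
                                   chromothripsis_min_switches = 4,
                                   n_boot = 100) {
  if (min_cnloh_size_bp < min_cna_size_bp) {
    stop_onekaryo("min_cnloh_size_bp must be >= min_cna_size_bp",
                  class = "onekaryo_validation_error")
  }
  structure(as.list(environment()), class = "integration_thresholds")
}

safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
safe_max <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)

empty_events <- function() {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    outer_start = numeric(), outer_end = numeric(),
    event_type = character(), clonal_fraction = numeric(),
    ci_low = numeric(), ci_high = numeric(),
    evidence = character(), n_het_snps = integer(), n_bins = integer(),
    requires_confirmation = logical(), flags = character(),
    label = character()
  )
}

# depth-implied clonal fraction given the log2 ratio and direction
depth_fraction <- function(mean_log2, direction) {
  r <- 2^mean_log2
  f <- if (direction == "loss") 2 * (1 - r) else 2 * (r - 1)
  pmin(pmax(f, 0), 1)
}

# The decision table shared by depth segments and BAF-rescue candidates.
# Returns a one-row tibble (event_type possibly "NORMAL" or "AMBIGUOUS").
classify_core <- function(chrom, start, end, mean_log2, n_bins, summ, thr,
                          seed = NULL, bin_sigma = NA_real_,
                          outer_start = start, outer_end = end,
                          coverage_frac = 1) {
  # size floors act on the outer SNP envelope, so a lesion exactly at a
  # floor is not lost to inner-span rounding
  size <- outer_end - outer_start
  sep <- summ$separation
  strong <- !is.na(sep) && sep >= thr$mbaf_separation_min
  weak <- !is.na(sep) && sep >= thr$weak_separation_min
  loss <- !is.na(mean_log2) && mean_log2 <= thr$log2_loss_max
  gain <- !is.na(mean_log2) && mean_log2 >= thr$log2_gain_min

  type <- "NORMAL"
  evidence <- NA_character_
  flags <- character(0)
  req_conf <- FALSE
  if (strong || weak) {
    if (loss) {
      type <- "DEL"; evidence <- "depth_and_baf"
    } else if (gain) {
      type <- "DUP"; evidence <- "depth_and_baf"
    } else if (strong) {
      if (size >= thr$min_cnloh_size_bp &&
          summ$n_het_informative >= thr$min_cnloh_het_snps) {
        type <- "CNLOH"; evidence <- "depth_and_baf"
      } else {
        # allelic imbalance without depth support and without cnLOH geometry:
        # real but uninterpretable alone, mirror of the FISH-confirmation tier
        type <- "AMBIGUOUS"; evidence <- "baf_only"
        req_conf <- TRUE
        flags <- c(flags, "separation_without_depth_support")
      }
    }
  } else if (loss) {
    type <- "DEL"; evidence <- "depth_only"
    flags <- c(flags, "no_baf_separation")
  } else if (gain) {
    type <- "DUP"; evidence <- "depth_only"
    flags <- c(flags, "no_baf_separation")
  }

  cf <- list(f_hat = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  if (type %in% c("DEL", "DUP", "CNLOH")) {
    if (evidence == "depth_and_baf" || type == "CNLOH") {
      cf_try <- tryCatch(
        estimate_clonal_fraction(
          summ$band_baf, type, n_boot = thr$n_boot, seed = seed,
          min_het_snps = thr$min_het_snps_cf,
          n_total_snps = summ$n_snps,
          expected_het_rate = summ$expected_het_rate %||% 0.488,
          fold_sigma = summ$fold_sigma),
        onekaryo_insufficient_evidence = function(e) NULL)
      if (is.null(cf_try)) {
        evidence <- "depth_only"
        flags <- c(flags, "too_few_het_snps_for_baf_fraction")
        cf$f_hat <- depth_fraction(mean_log2,
                                   if (type == "DEL") "loss" else "gain")
      } else {
        cf <- cf_try
        if (identical(cf$method, "het_deficit")) {
          flags <- c(flags, "het_deficit_fraction")
        }
        # depth/BAF fraction consistency check
        if (evidence == "depth_and_baf" && type != "CNLOH" &&
            !is.na(mean_log2)) {
          f_depth <- min(depth_fraction(mean_log2,
                                        if (type == "DEL") "loss" else
                                          "gain") / max(coverage_frac, 0.1),
                         1)
          if (abs(f_depth - cf$f_hat) > thr$ambiguous_f_diff) {
            type <- "AMBIGUOUS"
            req_conf <- TRUE
            flags <- c(flags, "depth_baf_fraction_conflict")
          }
        }
      }
    } else {
      cf$f_hat <- depth_fraction(mean_log2,
                                 if (type == "DEL") "loss" else "gain")
    }
    if (is.na(cf$ci_low %||% NA_real_) && !is.na(bin_sigma) && n_bins > 0 &&
        !is.na(cf$f_hat)) {
      # depth-implied fraction: delta method through f = 2(1 - 2^L)
      se_f <- 2 * log(2) * 2^mean_log2 * bin_sigma / sqrt(n_bins)
      cf$ci_low <- max(cf$f_hat - 1.96 * se_f, 0)
      cf$ci_high <- min(cf$f_hat + 1.96 * se_f, 1)
    }
  }

  tibble::tibble(
    chrom = chrom, start = start, end = end,
    outer_start = start, outer_end = end,
    event_type = type, clonal_fraction = cf$f_hat,
    ci_low = cf$ci_low %||% NA_real_, ci_high = cf$ci_high %||% NA_real_,
    evidence = evidence, n_het_snps = as.integer(summ$n_het_informative),
    n_bins = as.integer(n_bins),
    requires_confirmation = req_conf,
    flags = paste(flags, collapse = ";"),
    label = NA_character_
  )
}

region_summary_for <- function(baf_points, chrom, start, end, thr,
                               haploid_chroms = character(0)) {
  h_exp <- if (chrom %in% haploid_chroms) 0 else {
    pts <- baf_points[baf_points$chrom == chrom &
                        baf_points$pos > start & baf_points$pos <= end, ,
                      drop = FALSE]
    if ("pop_maf" %in% names(pts) && nrow(pts) > 0) {
      mean(2 * pts$pop_maf * (1 - pts$pop_maf))
    } else 0.488
  }
  s <- baf_region_summary(baf_points, chrom, start, end,
                          hom_min_baf = thr$hom_min_baf,
                          expected_het_rate = max(h_exp, 1e-9))
  if (h_exp == 0) {
    s$occupancy <- NA_real_
    s$loh_complete <- FALSE
    s$separation <- if (s$n_band > 0) s$median_band_mbaf - 0.5 else NA_real_
    s$n_het_informative <- s$n_band
  }
  s$expected_het_rate <- max(h_exp, 1e-9)
  s
}

#' Classify one depth segment against the regional BAF evidence
#'
#' Applies the depth/BAF decision table: strong het-band separation plus a
#' log2 loss or gain yields DEL/DUP with combined evidence; strong separation
#' on copy-neutral depth with cnLOH geometry (span >= 10 Mb, >= 200 het SNPs)
#' yields CNLOH; a depth shift without any separation yields a depth-only
#' call flagged for review (true homozygous regions cannot show separation);
#' everything else is NORMAL. Irreconcilable depth and BAF clonal fractions
#' produce an AMBIGUOUS event that is never silently dropped.
#'
#' @param segment one-row segment tibble from [segment_log2()].
#' @param baf_points BAF track from [compute_baf()] (with `pop_maf` if
#'   available).
#' @param thresholds an [integration_thresholds()].
#' @param haploid_chroms chromosomes carried in one copy (e.g. X/Y in an XY
#'   sample), excluded from het-band logic.
#' @param seed seed for the bootstrap interval.
#' @return one-row event tibble; `event_type` is `"NORMAL"` when nothing is
#'   called.
#' @export
classify_segment <- function(segment, baf_points,
                             thresholds = integration_thresholds(),
                             haploid_chroms = character(0), seed = NULL,
                             bin_sigma = NA_real_) {
  summ <- region_summary_for(baf_points, segment$chrom, segment$start,
                             segment$end, thresholds, haploid_chroms)
  classify_core(segment$chrom, segment$start, segment$end,
                segment$mean_log2, segment$n_bins, summ, thresholds,
                seed = seed, bin_sigma = bin_sigma)
}

#' Scan depth-normal territory for BAF-only lesion candidates
#'
#' Within regions where the depth caller saw nothing, runs a recursive
#' CUSUM split on the het-band mirrored BAF (sensitive to partial allelic
#' imbalance) and on the all-SNP deviation-from-0.5 series (sensitive to
#' complete LOH, where the het band has merged into the homozygous band) and
#' emits candidate intervals whose het-band separation or het deficit stands
#' out. Candidates carry `evidence = "baf_only"` and are meant to be
#' re-classified against the regional depth by the integrator; unconfirmed
#' ones remain in a requires-orthogonal-confirmation tier.
#'
#' @param baf_points BAF track.
#' @param depth_segments segments from [segment_log2()]; spans whose
#'   `mean_log2` lies inside the copy-neutral band are scanned.
#' @param thresholds an [integration_thresholds()].
#' @param haploid_chroms see [classify_segment()].
#' @return tibble of candidates: chrom, start, end, outer_start, outer_end,
#'   n_snps, separation, evidence.
#' @export
baf_rescue <- function(baf_points, depth_segments,
                       thresholds = integration_thresholds(),
                       haploid_chroms = character(0)) {
  thr <- thresholds
  # scan everything that was segmented: candidates inside depth-altered
  # territory sharpen the depth caller's bin-level edges, candidates in
  # depth-normal territory become rescue events
  scan_regions <- depth_segments |>
    dplyr::filter(!.data$masked, !.data$chrom %in% haploid_chroms) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  if (nrow(scan_regions) == 0) return(empty_events()[0, 1:5])
  out <- purrr::map_dfr(seq_len(nrow(scan_regions)), function(i) {
    reg <- scan_regions[i, ]
    pts <- baf_points[baf_points$chrom == reg$chrom &
                        baf_points$pos > reg$start &
                        baf_points$pos <= reg$end &
                        !is.na(baf_points$baf), , drop = FALSE]
    pts <- dplyr::arrange(pts, .data$pos)
    if (nrow(pts) < 2 * thr$rescue_min_snps) return(NULL)
    collect <- function(series, positions, sigma, keep) {
      runs <- scan_runs(series, thr$rescue_z, thr$rescue_min_snps, sigma)
      purrr::compact(purrr::map(runs, function(rg) {
        lo <- rg[1]; hi <- rg[2]
        if (!keep(series[lo:hi])) return(NULL)
        list(start = positions[lo], end = positions[hi],
             outer_start = positions[max(lo - 1, 1)],
             outer_end = positions[min(hi + 1, length(positions))],
             n = hi - lo + 1)
      }))
    }
    cands <- list()
    # route 1: het-band shift (partial allelic imbalance); band noise is
    # unimodal, so the lag-1 difference MAD is the right noise scale
    band_idx <- which(pts$baf <= thr$hom_min_baf)
    if (length(band_idx) >= 2 * thr$rescue_min_snps) {
      x <- pts$baf[band_idx]
      band_depth <- pts$depth_used[band_idx]
      cands <- c(cands, collect(
        x, pts$pos[band_idx], sqrt(robust_sigma2(x)),
        keep = function(vals) {
          # fold-bias-corrected separation of the run
          sig <- 0.5 / sqrt(max(median(band_depth), 1))
          unfold_median(median(vals), sig) - 0.5 >= thr$weak_separation_min
        }))
    }
    # route 2: deviation-from-0.5 of all SNPs (catches complete LOH, where
    # the het band has emptied); this series is bimodal, so its plain sd is
    # the per-point noise scale and the mean (not the bistable median) is
    # the baseline
    v <- abs(pts$baf - 0.5)
    cands <- c(cands, collect(
      v, pts$pos, stats::sd(v),
      keep = function(vals) mean(vals) > mean(v) + 0.1))
    if (length(cands) == 0) return(NULL)
    purrr::map_dfr(cands, function(cc) {
      tibble::tibble(chrom = reg$chrom, start = cc$start, end = cc$end,
                     outer_start = cc$outer_start, outer_end = cc$outer_end,
                     n_snps = cc$n, evidence = "baf_only")
    })
  })
  if (nrow(out) == 0) return(out)
  # drop candidates below the CNA size floor, measured on the outer envelope
  out <- dplyr::filter(out,
                       .data$outer_end - .data$outer_start >=
                         thr$min_cna_size_bp)
  if (nrow(out) == 0) return(out)
  # merge overlapping candidates from the two routes
  out <- out |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(grp = cumsum(.data$start >
                                 dplyr::lag(cummax(.data$end),
                                            default = -Inf))) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     outer_start = min(.data$outer_start),
                     outer_end = max(.data$outer_end),
                     n_snps = max(.data$n_snps), evidence = "baf_only",
                     .groups = "drop") |>
    dplyr::select(-"grp")
  out
}

#' Refine event breakpoints to SNP resolution
#'
#' Each breakpoint is re-localized inside a window around the bin- or
#' run-level edge by a least-squares single split of the relevant mirrored
#' BAF series (het band for partial-fraction lesions; deviation from 0.5 of
#' all SNPs when the het band has collapsed). The refined edge is the
#' midpoint between the two SNPs straddling the split; the SNPs immediately
#' outside become the outer envelope used by size filters. Events without
#' informative flanking SNPs keep their coordinates and are flagged
#' `breakpoint_bin_resolution`.
#'
#' @param event one-row event tibble.
#' @param baf_points BAF track.
#' @param thresholds an [integration_thresholds()].
#' @param genome genome tibble (for clamping to chromosome ends).
#' @return the event with refined `start`/`end`/`outer_start`/`outer_end`.
#' @export
refine_breakpoints <- function(event, baf_points,
                               thresholds = integration_thresholds(),
                               genome = NULL) {
  thr <- thresholds
  pts <- baf_points[baf_points$chrom == event$chrom &
                      !is.na(baf_points$baf), , drop = FALSE]
  pts <- dplyr::arrange(pts, .data$pos)
  use_band <- !identical(event$event_type, "MONOSOMY") &&
    event$n_het_snps > 0 && !grepl("het_deficit", event$flags %||% "")
  # the search window scales with the event: it must cover the edge's
  # uncertainty but exclude the event's other edge, or a single split is
  # ill-posed for short events
  span <- event$end - event$start
  half_w <- max(min(thr$refine_window_bp, span / 2), 4e5)
  refine_edge <- function(edge, side) {
    w <- half_w
    win <- pts[pts$pos > edge - w & pts$pos <= edge + w, , drop = FALSE]
    series <- if (use_band) {
      win[win$baf <= thr$hom_min_baf, , drop = FALSE]
    } else win
    x <- if (use_band) series$baf else abs(series$baf - 0.5)
    if (length(x) < 6) return(NULL)
    n <- length(x)
    k <- 2:(n - 2)
    cs <- cumsum(x)
    tot <- cs[n]
    mean_l <- cs[k] / k
    mean_r <- (tot - cs[k]) / (n - k)
    sigma <- max(sqrt(robust_sigma2(x)), 1e-6)
    z <- abs(mean_l - mean_r) / (sigma * sqrt(1 / k + 1 / (n - k)))
    i <- which.max(z)
    if (z[i] < 2) return(NULL)
    split_k <- k[i]
    list(mid = (series$pos[split_k] + series$pos[split_k + 1]) / 2,
         outer = if (side == "start") series$pos[max(split_k - 1, 1)]
         else series$pos[min(split_k + 2, n)])
  }
  flags <- event$flags
  rs <- refine_edge(event$start, "start")
  re <- refine_edge(event$end, "end")
  if (is.null(rs) && is.null(re)) {
    event$flags <- paste(c(flags[nzchar(flags)],
                           "breakpoint_bin_resolution"), collapse = ";")
    return(event)
  }
  if (!is.null(rs)) {
    event$start <- rs$mid
    event$outer_start <- min(rs$outer, rs$mid)
  }
  if (!is.null(re)) {
    event$end <- re$mid
    event$outer_end <- max(re$outer, re$mid)
  }
  if (!is.null(genome)) {
    len <- chrom_length(genome, event$chrom)
    event$end <- min(event$end, len)
    event$outer_end <- min(event$outer_end, len)
    event$start <- max(event$start, 0)
    event$outer_start <- max(event$outer_start, 0)
  }
  if (event$end <= event$start) {
    event$end <- event$outer_end
    event$start <- event$outer_start
  }
  event
}

#' Flag chromothripsis-like chromosomes
#'
#' A chromosome arm carrying at least `min_switches` alternating copy-number
#' state switches (counting transitions through intervening normal territory)
#' is flagged as chromothripsis-like: a cluster of oscillating deletions and
#' duplications rather than one contiguous lesion.
#'
#' @param events event tibble.
#' @param genome genome tibble (for arm assignment).
#' @param min_switches default 4.
#' @return tibble: chrom, arm, n_events, n_switches, flagged.
#' @export
flag_chromothripsis <- function(events, genome, min_switches = 4) {
  cna <- dplyr::filter(events, .data$event_type %in% c("DEL", "DUP"))
  combos <- expand.grid(chrom = genome$chrom, arm = c("p", "q"),
                        stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    ch <- combos$chrom[i]; arm <- combos$arm[i]
    cen <- genome$centromere[genome$chrom == ch]
    len <- genome$length[genome$chrom == ch]
    lo <- if (arm == "p") 0 else cen
    hi <- if (arm == "p") cen else len
    ev <- cna |>
      dplyr::filter(.data$chrom == ch, .data$start < hi, .data$end > lo) |>
      dplyr::arrange(.data$start)
    if (nrow(ev) == 0) {
      return(tibble::tibble(chrom = ch, arm = arm, n_events = 0L,
                            n_switches = 0L, flagged = FALSE))
    }
    states <- character(0)
    prev_end <- lo
    for (j in seq_len(nrow(ev))) {
      if (ev$start[j] > prev_end) states <- c(states, "NORMAL")
      states <- c(states, ev$event_type[j])
      prev_end <- max(prev_end, ev$end[j])
    }
    if (prev_end < hi) states <- c(states, "NORMAL")
    n_sw <- sum(states[-1] != states[-length(states)]) +
      (states[1] != "NORMAL") + (states[length(states)] != "NORMAL")
    tibble::tibble(chrom = ch, arm = arm, n_events = nrow(ev),
                   n_switches = as.integer(n_sw),
                   flagged = n_sw >= min_switches)
  })
}

iscn_like_label <- function(event, genome) {
  ch <- event$chrom
  if (event$event_type == "MONOSOMY") return(paste0("-", ch))
  if (event$event_type == "TRISOMY") return(paste0("+", ch))
  cen <- genome$centromere[genome$chrom == ch]
  arm <- if (event$end <= cen) "p" else if (event$start >= cen) "q" else ""
  kind <- switch(event$event_type, DEL = "del", DUP = "dup",
                 CNLOH = "cnLOH", AMBIGUOUS = "amb")
  sprintf("%s(%s%s)", kind, ch, arm)
}

#' Integrate depth and BAF evidence into classified genomic events
#'
#' The end-to-end caller: segments the normalized log2 track, classifies each
#' segment against the regional het-band evidence, rescues BAF-only lesions
#' from depth-normal territory, refines all breakpoints to SNP resolution,
#' enforces the size / marker-count / clonal-fraction reporting floors
#' (measured on the outer SNP envelope, so a lesion exactly at a floor is not
#' lost to midpoint rounding), relabels whole-chromosome losses and gains as
#' MONOSOMY/TRISOMY, and attaches chromothripsis flags.
#'
#' @param bins output of [normalize_depth()].
#' @param baf_points output of [compute_baf()] (with `pop_maf` if available).
#' @param genome genome tibble.
#' @param thresholds an [integration_thresholds()].
#' @param sex sample sex; X/Y territory of XY samples is excluded from
#'   het-band logic.
#' @param seed seed for bootstrap intervals.
#' @return tibble of events (class `onekaryo_events`) with a
#'   `chromothripsis` attribute tibble.
#' @export
integrate_events <- function(bins, baf_points, genome,
                             thresholds = integration_thresholds(),
                             sex = "XX", seed = NULL) {
  thr <- thresholds
  haploid <- if (sex == "XY") c("X", "Y") else "Y"
  segs <- segment_log2(bins)
  # The BAF run scan is independent of the depth baseline, so it runs
  # first; allelically balanced territory (bins outside every BAF
  # candidate) then anchors the diploid baseline. Anchoring on segment
  # means alone fails when the segmenter has not split a lesion out of its
  # flank: the mixed segment drags the baseline toward the lesion.
  cands <- baf_rescue(baf_points, segs, thr, haploid)
  in_cand <- rep(FALSE, nrow(bins))
  if (nrow(cands) > 0) {
    for (i in seq_len(nrow(cands))) {
      in_cand <- in_cand | (bins$chrom == cands$chrom[i] &
                              bins$bin_start < cands$end[i] &
                              bins$bin_end > cands$start[i])
    }
  }
  anchor <- bins$log2_ratio[!in_cand & !bins$chrom %in% c("X", "Y") &
                              !is.na(bins$log2_ratio)]
  baseline <- if (length(anchor) >= 10) median(anchor) else
    segment_baseline(segs)
  bins$log2_ratio <- bins$log2_ratio - baseline
  segs$mean_log2 <- segs$mean_log2 - baseline
  usable <- bins$log2_ratio[!is.na(bins$log2_ratio) &
                              !bins$chrom %in% c("X", "Y")]
  bin_sigma <- if (length(usable) > 3) sqrt(robust_sigma2(usable)) else
    NA_real_
  seg_rows <- dplyr::filter(segs, !.data$masked)
  events <- purrr::map_dfr(seq_len(nrow(seg_rows)), function(i) {
    classify_segment(seg_rows[i, ], baf_points, thr, haploid,
                     seed = child_seed(seed, i), bin_sigma = bin_sigma)
  })
  if (nrow(events) == 0) events <- empty_events()

  # BAF candidates: snap depth-event edges, then emit rescue events
  if (nrow(cands) > 0) {
    # a rescue interval is SNP-accurate where depth changepoints are bin- or
    # worse accurate: snap the edges of depth events it corroborates
    for (i in seq_len(nrow(events))) {
      if (!events$event_type[i] %in% c("DEL", "DUP", "CNLOH")) next
      ov <- pmin(events$end[i], cands$end) - pmax(events$start[i],
                                                  cands$start)
      recip <- ov / pmax(events$end[i] - events$start[i],
                         cands$end - cands$start)
      j <- which(cands$chrom == events$chrom[i] & recip >= 0.5)
      if (length(j) > 1) j <- j[which.max(recip[j])]
      if (length(j) == 1) {
        events$start[i] <- cands$start[j]
        events$end[i] <- cands$end[j]
        events$outer_start[i] <- cands$outer_start[j]
        events$outer_end[i] <- cands$outer_end[j]
        events$flags[i] <- paste(
          c(events$flags[i][nzchar(events$flags[i])], "baf_refined_edges"),
          collapse = ";")
      }
    }
    called <- dplyr::filter(events, .data$event_type != "NORMAL")
    rescue_events <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
      cc <- cands[i, ]
      overlaps <- any(called$chrom == cc$chrom &
                        called$start < cc$end & called$end > cc$start)
      if (overlaps) return(NULL)
      dm <- region_mean_log2(bins, cc$chrom, cc$start, cc$end)
      summ <- region_summary_for(baf_points, cc$chrom, cc$start, cc$end,
                                 thr, haploid)
      ev <- classify_core(cc$chrom, cc$start, cc$end, dm$mean_log2,
                          dm$n_bins, summ, thr,
                          seed = child_seed(seed, 1000 + i),
                          bin_sigma = bin_sigma,
                          outer_start = cc$outer_start,
                          outer_end = cc$outer_end,
                          coverage_frac = dm$coverage_frac)
      if (ev$event_type == "NORMAL") return(NULL)
      # a BAF-discovered candidate must keep BAF support after the
      # bias-corrected re-check; depth alone re-tests what the segmenter
      # already rejected
      if (identical(ev$evidence, "depth_only")) return(NULL)
      ev$outer_start <- cc$outer_start
      ev$outer_end <- cc$outer_end
      if (ev$evidence == "depth_and_baf" && ev$event_type != "CNLOH") {
        ev$flags <- paste(c(ev$flags[nzchar(ev$flags)], "baf_rescued"),
                          collapse = ";")
      }
      ev
    })
    events <- dplyr::bind_rows(events, rescue_events)
  }

  events <- dplyr::filter(events, .data$event_type != "NORMAL")
  if (nrow(events) == 0) {
    out <- empty_events()
    attr(out, "chromothripsis") <- flag_chromothripsis(
      out, genome, thr$chromothripsis_min_switches)
    class(out) <- c("onekaryo_events", class(out))
    return(out)
  }

  # merge touching same-type depth segments (PELT may split long lesions)
  events <- events |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom, .data$event_type) |>
    dplyr::mutate(new_run = cumsum(
      .data$start > dplyr::lag(.data$end, default = -Inf) + 1)) |>
    dplyr::group_by(.data$chrom, .data$event_type, .data$new_run) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      outer_start = min(.data$outer_start), outer_end = max(.data$outer_end),
      clonal_fraction = sum(.data$clonal_fraction * .data$n_het_snps,
                            na.rm = TRUE) /
        max(sum(.data$n_het_snps[!is.na(.data$clonal_fraction)]), 1),
      ci_low = safe_min(.data$ci_low), ci_high = safe_max(.data$ci_high),
      evidence = dplyr::first(.data$evidence),
      n_het_snps = sum(.data$n_het_snps), n_bins = sum(.data$n_bins),
      requires_confirmation = any(.data$requires_confirmation),
      flags = paste(unique(.data$flags[nzchar(.data$flags)]),
                    collapse = ";"),
      .groups = "drop") |>
    dplyr::select(-"new_run")
  events$clonal_fraction[is.nan(events$clonal_fraction)] <- NA_real_

  # breakpoint refinement (skip whole-chromosome spans below)
  events <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    refine_breakpoints(events[i, ], baf_points, thr, genome)
  })

  # re-quantify the clonal fraction on the refined span: segment-level
  # estimates are diluted by normal flanks when changepoints land a few bins
  # off, which matters exactly at the reporting floor
  events <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    if (!ev$event_type %in% c("DEL", "DUP", "CNLOH") ||
        identical(ev$evidence, "depth_only")) {
      return(ev)
    }
    summ <- region_summary_for(baf_points, ev$chrom, ev$start, ev$end, thr,
                               haploid)
    cf <- tryCatch(
      estimate_clonal_fraction(
        summ$band_baf, ev$event_type, n_boot = thr$n_boot,
        seed = child_seed(seed, 5000 + i),
        min_het_snps = thr$min_het_snps_cf, n_total_snps = summ$n_snps,
        expected_het_rate = summ$expected_het_rate,
        fold_sigma = summ$fold_sigma),
      onekaryo_insufficient_evidence = function(e) NULL)
    if (!is.null(cf)) {
      ev$clonal_fraction <- cf$f_hat
      ev$ci_low <- cf$ci_low
      ev$ci_high <- cf$ci_high
      ev$n_het_snps <- as.integer(summ$n_het_informative)
    }
    ev
  })

  # reporting floors on the outer envelope
  keep <- rep(TRUE, nrow(events))
  env_size <- events$outer_end - events$outer_start
  keep[events$event_type %in% c("DEL", "DUP") &
         env_size < thr$min_cna_size_bp] <- FALSE
  keep[events$event_type == "CNLOH" &
         (env_size < thr$min_cnloh_size_bp |
            events$n_het_snps < thr$min_cnloh_het_snps)] <- FALSE
  # the reporting floor suppresses only lesions confidently below it:
  # a 99.5% one-sided bound, since hiding a real lesion at the assay's
  # sensitivity limit is the costly error
  se_f <- (events$ci_high - events$clonal_fraction) / 1.96
  f_bound <- ifelse(is.na(events$ci_high), events$clonal_fraction,
                    events$clonal_fraction + 2.58 * se_f)
  keep[!is.na(f_bound) & f_bound < thr$min_clonal_fraction_report &
         events$event_type != "AMBIGUOUS"] <- FALSE
  events <- events[keep, , drop = FALSE]

  # whole-chromosome relabelling
  if (nrow(events) > 0) {
    len <- chrom_length(genome, events$chrom)
    whole <- (events$end - events$start) >= thr$whole_chrom_fraction * len
    events$event_type[whole & events$event_type == "DEL"] <- "MONOSOMY"
    events$event_type[whole & events$event_type == "DUP"] <- "TRISOMY"
    events$start[whole] <- 0
    events$end[whole] <- len[whole]
    events$outer_start[whole] <- 0
    events$outer_end[whole] <- len[whole]
  }

  events$label <- purrr::map_chr(seq_len(nrow(events)), function(i) {
    iscn_like_label(events[i, ], genome)
  })
  events <- dplyr::arrange(events, .data$chrom, .data$start)
  attr(events, "chromothripsis") <- flag_chromothripsis(
    events, genome, thr$chromothripsis_min_switches)
  class(events) <- c("onekaryo_events", class(events))
  events
}
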