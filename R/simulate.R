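# synthetic assay generator: backbone SNP panel, per-sample allele depths,
# binned counts, reference cohorts and annotated variant tables

#' Simulation configuration
#'
#' Bundles the assay-level parameters of the synthetic generator. Defaults
#' reproduce the assay the package models: a backbone of 172,470 genome-wide
#' SNPs chosen at population minor-allele frequencies of 0.40-0.45, mean
#' on-SNP depth of 319x with a negative-binomial spread matching the reported
#' +/- 133x standard deviation, and 1 Mb depth bins.
#'
#' @param n_snps number of backbone SNPs to place on the genome.
#' @param maf_low,maf_high bounds of the population minor-allele frequency
#'   from which each SNP's MAF is drawn uniformly. Must satisfy
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param mean_depth expected per-SNP sequencing depth (reads).
#' @param depth_dispersion negative-binomial size parameter of the per-SNP
#'   depth; the default 5.9 reproduces a 319 +/- 133x depth distribution
#'   (`sd^2 = mu + mu^2/size`).
#' @param mean_bin_count expected reads per 1 Mb depth bin; the default 4000
#'   corresponds to ~14M mapped reads spread over ~3100 genome-wide bins.
#' @param bin_dispersion negative-binomial size of bin counts (default 200,
#'   i.e. ~7% coefficient of variation, typical of 1 Mb binned capture
#'   coverage).
#' @param bin_size depth bin width in bp (>= 1e5; default 1 Mb).
#' @param error_rate per-read probability of miscalling the allele.
#' @param bin_profile_sd log-scale spread of the per-bin capture-efficiency
#'   profile shared by all samples of an assay (default 0.5); this is what
#'   makes unrelated samples' raw bin counts correlate strongly, as binned
#'   capture coverage does in practice.
#' @param profile_seed fixed seed of the shared efficiency profile; samples
#'   simulated under the same configuration share the same profile.
#' @param sex `"XX"` or `"XY"`; XY samples receive a single dose of chrX/chrY.
#' @param seed default seed applied by the generator functions when they are
#'   not given one explicitly; `NULL` leaves the RNG stream untouched.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 172470L,
                       maf_low = 0.40, maf_high = 0.45,
                       mean_depth = 319,
                       depth_dispersion = 5.9,
                       mean_bin_count = 4000,
                       bin_dispersion = 200,
                       bin_size = 1e6,
                       error_rate = 0.002,
                       bin_profile_sd = 0.5,
                       profile_seed = 191947L,
                       sex = c("XX", "XY"),
                       seed = NULL) {
  sex <- match.arg(sex)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop_onekaryo("need 0 < maf_low <= maf_high <= 0.5",
                  class = "onekaryo_validation_error")
  }
  if (mean_depth <= 0 || mean_bin_count <= 0) {
    stop_onekaryo("mean_depth and mean_bin_count must be positive",
                  class = "onekaryo_validation_error")
  }
  if (bin_size < 1e5) {
    stop_onekaryo("bin_size must be at least 1e5 bp",
                  class = "onekaryo_validation_error")
  }
  structure(
    list(n_snps = as.integer(n_snps), maf_low = maf_low, maf_high = maf_high,
         mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         mean_bin_count = mean_bin_count, bin_dispersion = bin_dispersion,
         bin_size = bin_size, error_rate = error_rate,
         bin_profile_sd = bin_profile_sd, profile_seed = profile_seed,
         sex = sex, seed = seed),
    class = "sim_config"
  )
}

#' The 40-gene myeloid mutation panel
#'
#' Gene symbols recurrently mutated in MDS, MDS/MPN and CMML that the capture
#' design targets alongside the SNP backbone.
#'
#' @return character vector of 40 gene symbols.
#' @export
mds_gene_panel <- function() {
  c("ASXL1", "BCOR", "BCORL1", "CALR", "CBL", "CEBPA", "CSF3R", "CUX1",
    "DDX41", "DNMT3A", "ETNK1", "ETV6", "EZH2", "FLT3", "GATA2", "GNB1",
    "IDH1", "IDH2", "JAK2", "KIT", "KRAS", "MPL", "NF1", "NPM1", "NRAS",
    "PHF6", "PPM1D", "PTPN11", "RAD21", "RUNX1", "SETBP1", "SF3B1", "SH2B3",
    "SRSF2", "STAG2", "TET2", "TP53", "U2AF1", "WT1", "ZRSR2")
}

#' Build a backbone SNP panel
#'
#' Places `config$n_snps` SNP loci across the genome, allocated to
#' chromosomes proportionally to their length, with near-uniform spacing plus
#' jitter, and draws each locus' population MAF uniformly from
#' `[maf_low, maf_high]`. Also lays the 40 target genes out as gene-labelled
#' intervals (cosmetic for simulation purposes).
#'
#' @param genome genome tibble (see [toy_genome()]).
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list of class `panel_design` with elements `snps` (tibble: chrom,
#'   pos, ref_allele, alt_allele, pop_maf), `target_regions`, `genome`,
#'   `genome_build_label`.
#' @export
#' @examples
#' p <- make_panel(toy_genome(), sim_config(n_snps = 2000, seed = 1))
#' nrow(p$snps)
make_panel <- function(genome, config = sim_config(), seed = config$seed) {
  n <- config$n_snps
  total <- genome_total_length(genome)
  if (n > total / 500) {
    stop_onekaryo(
      sprintf("requested %d SNPs exceeds 1 per 500 bp of genome (%.0f bp)",
              n, total),
      class = "onekaryo_density_error"
    )
  }
  snps <- with_seed_if(seed, {
    if (n == 0) {
      tibble::tibble(chrom = character(), pos = numeric(),
                     ref_allele = character(), alt_allele = character(),
                     pop_maf = numeric())
    } else {
      n_per <- round(n * genome$length / total)
      # keep the total exact after rounding
      diff_n <- n - sum(n_per)
      if (diff_n != 0) n_per[1] <- n_per[1] + diff_n
      purrr::pmap_dfr(
        list(genome$chrom, genome$length, n_per),
        function(chrom, len, k) {
          if (k <= 0) return(NULL)
          spacing <- len / k
          pos <- (seq_len(k) - 0.5) * spacing +
            runif(k, -0.45, 0.45) * spacing
          pos <- sort(round(pmin(pmax(pos, 1), len)))
          pos <- unique(pos)
          bases <- c("A", "C", "G", "T")
          ref <- sample(bases, length(pos), replace = TRUE)
          alt <- purrr::map_chr(ref, ~ sample(setdiff(bases, .x), 1))
          tibble::tibble(
            chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
            pop_maf = runif(length(pos), config$maf_low, config$maf_high)
          )
        }
      )
    }
  })
  genes <- mds_gene_panel()
  # spread target genes across the first autosome for labelling purposes
  tg_chrom <- genome$chrom[1]
  tg_start <- seq(1e6, chrom_length(genome, tg_chrom) - 2e6,
                  length.out = length(genes))
  target_regions <- tibble::tibble(
    gene = genes, chrom = tg_chrom,
    start = round(tg_start), end = round(tg_start) + 5e4
  )
  structure(
    list(snps = snps, target_regions = target_regions, genome = genome,
         genome_build_label = if (identical(genome, hg19_genome()))
           "GRCh37/hg19" else "custom"),
    class = "panel_design"
  )
}

#' Ground-truth event and variant sets for simulation
#'
#' @param events tibble with columns `chrom`, `start`, `end`, `type` (one of
#'   DEL, DUP, TRISOMY, MONOSOMY, CNLOH) and `clonal_fraction` in \[0, 1\].
#' @param variants optional tibble of ground-truth small variants
#'   (`gene`, `vaf`, `pop_maf`, `tier`).
#' @param allow_overlap permit overlapping events on a chromosome (used for
#'   chromothripsis-like oscillation fixtures).
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(events = NULL, variants = NULL, allow_overlap = FALSE) {
  if (is.null(events)) {
    events <- tibble::tibble(chrom = character(), start = numeric(),
                             end = numeric(), type = character(),
                             clonal_fraction = numeric())
  }
  assert_columns(events, c("chrom", "start", "end", "type", "clonal_fraction"),
                 "truth events")
  bad_type <- setdiff(events$type,
                      c("DEL", "DUP", "TRISOMY", "MONOSOMY", "CNLOH"))
  if (length(bad_type) > 0) {
    stop_onekaryo(paste0("unknown event type(s): ",
                         paste(bad_type, collapse = ", ")),
                  class = "onekaryo_validation_error")
  }
  if (any(events$clonal_fraction < 0 | events$clonal_fraction > 1)) {
    stop_onekaryo("clonal_fraction must lie in [0, 1]",
                  class = "onekaryo_validation_error")
  }
  if (any(events$end <= events$start)) {
    stop_onekaryo("event end must exceed start",
                  class = "onekaryo_validation_error")
  }
  if (!allow_overlap && nrow(events) > 1) {
    ov <- events |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(overlaps = .data$start < dplyr::lag(.data$end,
                                                        default = -Inf)) |>
      dplyr::ungroup()
    if (any(ov$overlaps)) {
      stop_onekaryo("truth events overlap; use allow_overlap = TRUE",
                    class = "onekaryo_validation_error")
    }
  }
  structure(list(events = events, variants = variants), class = "sim_truth")
}

event_copy_number <- function(type) {
  c(DEL = 1, MONOSOMY = 1, DUP = 3, TRISOMY = 3, CNLOH = 2)[type]
}

# per-SNP event annotation: returns type ("" if none) and clonal fraction
annotate_positions <- function(chrom, pos, events) {
  type <- rep("", length(pos))
  f <- rep(0, length(pos))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      hit <- chrom == events$chrom[i] & pos > events$start[i] &
        pos <= events$end[i]
      type[hit] <- events$type[i]
      f[hit] <- events$clonal_fraction[i]
    }
  }
  list(type = type, f = f)
}

#' Simulate one sample's allele depths and bin counts
#'
#' Per SNP, a germline genotype is drawn from Hardy-Weinberg proportions at
#' the locus MAF; the lesion-adjusted expected alternate-allele fraction in a
#' tumor-fraction-weighted mixture of normal and aberrant cells determines
#' binomial allele counts at a negative-binomial total depth. Per bin, total
#' counts scale with the mixture copy number. Heterozygous SNPs are assigned
#' the affected haplotype at random, which is what produces the mirrored-BAF
#' split bands characteristic of subclonal lesions.
#'
#' @param panel a `panel_design` from [make_panel()].
#' @param truth a [sim_truth()].
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `allele_depths` (tibble: chrom, pos, pop_maf, genotype,
#'   ref_count, alt_count, other_count) and `bins` (tibble: chrom, bin_start,
#'   bin_end, count).
#' @export
simulate_sample <- function(panel, truth = sim_truth(), config = sim_config(),
                            seed = config$seed) {
  stopifnot(inherits(panel, "panel_design"), inherits(truth, "sim_truth"))
  genome <- panel$genome
  events <- truth$events
  if (nrow(events) > 0) {
    len <- chrom_length(genome, events$chrom)
    if (any(is.na(len)) || any(events$end > len) || any(events$start < 0)) {
      stop_onekaryo("truth events fall outside chromosome bounds",
                    class = "onekaryo_validation_error")
    }
  }
  with_seed_if(seed, {
    snps <- panel$snps
    n <- nrow(snps)
    ann <- annotate_positions(snps$chrom, snps$pos, events)
    base_cn <- ifelse(snps$chrom %in% c("X", "Y") & config$sex == "XY", 1, 2)
    drop_y <- snps$chrom == "Y" & config$sex == "XX"
    cn_ev <- ifelse(ann$type == "", base_cn,
                    unname(event_copy_number(ann$type)))
    f <- ann$f
    copies <- base_cn * (1 - f) + cn_ev * f

    # genotype: number of alt alleles under HWE (haploid on single-dose chroms)
    g <- integer(n)
    dip <- base_cn == 2
    g[dip] <- rbinom(sum(dip), 2, snps$pop_maf[dip])
    g[!dip] <- rbinom(sum(!dip), 1, snps$pop_maf[!dip])

    # expected alt fraction given the lesion; the affected haplotype of a het
    # SNP is random (unphased backbone)
    u <- rbinom(n, 1, 0.5)
    alt_copies <- numeric(n)
    het <- dip & g == 1
    alt_copies[g == 0] <- 0
    alt_copies[dip & g == 2] <- copies[dip & g == 2]
    alt_copies[!dip & g == 1] <- copies[!dip & g == 1]
    if (any(het)) {
      ty <- ann$type[het]; fh <- f[het]; uh <- u[het]
      ac <- (1 - fh) + uh * fh            # DEL / MONOSOMY: kept allele is u
      ac[ty %in% c("DUP", "TRISOMY")] <-
        1 + uh[ty %in% c("DUP", "TRISOMY")] * fh[ty %in% c("DUP", "TRISOMY")]
      ac[ty == "CNLOH"] <-
        (1 - fh[ty == "CNLOH"]) + 2 * uh[ty == "CNLOH"] * fh[ty == "CNLOH"]
      ac[ty == ""] <- 1
      alt_copies[het] <- ac
    }
    p_alt <- ifelse(copies > 0, alt_copies / copies, 0)

    depth <- rnbinom(n, mu = config$mean_depth * copies / 2,
                     size = config$depth_dispersion)
    depth[drop_y] <- 0L
    other <- rbinom(n, depth, config$error_rate)
    rem <- depth - other
    e <- config$error_rate
    alt <- rbinom(n, rem, p_alt * (1 - 2 * e) + e)
    allele_depths <- tibble::tibble(
      chrom = snps$chrom, pos = snps$pos, pop_maf = snps$pop_maf,
      genotype = g, ref_count = rem - alt, alt_count = alt,
      other_count = other
    )

    bins <- simulate_bins(genome, events, config)
    list(allele_depths = allele_depths, bins = bins)
  })
}

make_bins <- function(genome, bin_size) {
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(chrom = genome$chrom[i], bin_start = starts,
                   bin_end = pmin(starts + bin_size, len))
  })
}

# deterministic shared capture-efficiency profile for a bin layout
bin_efficiency <- function(n_bins, config) {
  if (config$bin_profile_sd <= 0) return(rep(1, n_bins))
  withr::with_seed(config$profile_seed, {
    stats::rlnorm(n_bins, -config$bin_profile_sd^2 / 2,
                  config$bin_profile_sd)
  })
}

simulate_bins <- function(genome, events, config) {
  bins <- make_bins(genome, config$bin_size)
  efficiency <- bin_efficiency(nrow(bins), config)
  factor <- rep(1, nrow(bins))
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      cn <- unname(event_copy_number(events$type[i]))
      f <- events$clonal_fraction[i]
      ov <- pmax(0, pmin(bins$bin_end, events$end[i]) -
                   pmax(bins$bin_start, events$start[i]))
      frac <- ov / (bins$bin_end - bins$bin_start)
      frac[bins$chrom != events$chrom[i]] <- 0
      factor <- factor + frac * f * (cn - 2) / 2
    }
  }
  sex_dose <- ifelse(bins$chrom %in% c("X", "Y") & config$sex == "XY", 0.5, 1)
  sex_dose[bins$chrom == "Y" & config$sex == "XX"] <- 0
  width_frac <- (bins$bin_end - bins$bin_start) / config$bin_size
  mu <- config$mean_bin_count * efficiency * factor * sex_dose * width_frac
  bins$count <- rnbinom(nrow(bins), mu = mu, size = config$bin_dispersion)
  bins
}

#' Simulate an event-free reference cohort
#'
#' Generates sex-labelled, event-free bin-count profiles with independent
#' noise, as used for sex-stratified depth normalization.
#'
#' @inheritParams simulate_sample
#' @param n_samples number of reference samples (>= 1).
#' @param sexes character vector recycled to `n_samples` (`"XX"`/`"XY"`).
#' @return tidy tibble: sample_id, sex, chrom, bin_start, bin_end, count.
#' @export
simulate_reference_cohort <- function(panel, n_samples, sexes = "XX",
                                      config = sim_config(),
                                      seed = config$seed) {
  if (n_samples < 1) {
    stop_onekaryo("n_samples must be >= 1",
                  class = "onekaryo_validation_error")
  }
  sexes <- rep_len(sexes, n_samples)
  purrr::map_dfr(seq_len(n_samples), function(i) {
    cfg <- config
    cfg$sex <- sexes[i]
    b <- with_seed_if(child_seed(seed, i),
                      simulate_bins(panel$genome,
                                    sim_truth()$events, cfg))
    dplyr::mutate(b, sample_id = sprintf("ref%02d", i), sex = sexes[i],
                  .before = 1)
  })
}

#' Simulate an annotated small-variant table
#'
#' Emits a pre-annotated variant table of the kind consumed by the variant
#' filtering workflow: somatic-like rows (hotspots, truncating lesions and
#' passenger missense at sub-clonal VAFs) and germline-like rows (population
#' MAF above 1%, VAF near 0.5 or 1). A `truth_tier` column records the
#' generator's intent for filter testing.
#'
#' @param n_variants number of rows.
#' @param fraction_germline_like fraction of rows drawn from the germline-like
#'   generator (pop_maf > 0.01).
#' @param sample_ids optional pool of sample ids to attach.
#' @param seed integer seed.
#' @return tibble of annotated variants.
#' @export
simulate_variant_table <- function(n_variants, fraction_germline_like = 0.3,
                                   sample_ids = "S1", seed = NULL) {
  if (fraction_germline_like < 0 || fraction_germline_like > 1) {
    stop_onekaryo("fraction_germline_like must lie in [0, 1]",
                  class = "onekaryo_validation_error")
  }
  if (n_variants == 0) {
    return(tibble::tibble(
      sample_id = character(), gene = character(), chrom = character(),
      pos = numeric(), ref = character(), alt = character(),
      protein_change = character(), consequence = character(),
      vaf = numeric(), pop_maf = numeric(), somatic_db = logical(),
      clinvar_pathogenic = logical(), truth_tier = character()
    ))
  }
  with_seed_if(seed, {
    genes <- mds_gene_panel()
    hotspots <- tibble::tribble(
      ~gene, ~protein_change,
      "SF3B1", "K700E",
      "SRSF2", "P95H",
      "SRSF2", "P95L",
      "SRSF2", "P95R",
      "JAK2", "V617F",
      "IDH2", "R140Q",
      "TP53", "R273H"
    )
    germline <- rbinom(n_variants, 1, fraction_germline_like) == 1
    kind <- ifelse(germline, "germline",
                   sample(c("hotspot", "truncating", "missense"),
                          n_variants, replace = TRUE,
                          prob = c(0.25, 0.3, 0.45)))
    hs_idx <- sample(nrow(hotspots), n_variants, replace = TRUE)
    suppressors <- c("TP53", "TET2", "ASXL1", "EZH2", "RUNX1", "BCOR",
                     "ZRSR2", "STAG2", "PHF6", "WT1")
    gene <- dplyr::case_when(
      kind == "hotspot" ~ hotspots$gene[hs_idx],
      # truncating driver lesions concentrate in tumor suppressors
      kind == "truncating" ~ sample(suppressors, n_variants, replace = TRUE),
      TRUE ~ sample(genes, n_variants, replace = TRUE))
    protein_change <- dplyr::case_when(
      kind == "hotspot" ~ hotspots$protein_change[hs_idx],
      kind == "truncating" ~ sprintf("Q%dX", sample(50:900, n_variants,
                                                    replace = TRUE)),
      TRUE ~ sprintf("%s%d%s", sample(LETTERS, n_variants, replace = TRUE),
                     sample(50:900, n_variants, replace = TRUE),
                     sample(LETTERS, n_variants, replace = TRUE))
    )
    consequence <- dplyr::case_when(
      kind == "truncating" ~ sample(c("stop_gained", "frameshift"),
                                    n_variants, replace = TRUE),
      TRUE ~ "missense"
    )
    vaf <- dplyr::case_when(
      kind == "germline" ~ pmin(1, pmax(0.02, rnorm(n_variants, 0.5, 0.02))),
      TRUE ~ runif(n_variants, 0.05, 0.6)
    )
    # germline-like rows sit above the 1% population-frequency filter line
    pop_maf <- ifelse(germline, runif(n_variants, 0.0101, 0.05),
                      ifelse(runif(n_variants) < 0.2,
                             runif(n_variants, 0, 0.005), 0))
    truth_tier <- dplyr::case_when(
      kind == "germline" ~ "excluded_germline",
      kind == "hotspot" ~ "pathogenic",
      kind == "truncating" ~ "likely_pathogenic",
      TRUE ~ "VUS"
    )
    tibble::tibble(
      sample_id = sample(sample_ids, n_variants, replace = TRUE),
      gene = gene,
      chrom = as.character(sample(1:22, n_variants, replace = TRUE)),
      pos = sample.int(1e8, n_variants, replace = TRUE),
      ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      protein_change = protein_change, consequence = consequence,
      vaf = vaf, pop_maf = pop_maf,
      somatic_db = kind == "hotspot",
      clinvar_pathogenic = kind == "hotspot" & runif(n_variants) < 0.5,
      truth_tier = truth_tier
    )
  })
}
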