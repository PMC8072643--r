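# tumor-only small-variant workflow: population filtering, tier
# classification against editable rules, co-occurrence testing, burden

#' Exclude population polymorphisms
#'
#' Tumor-only germline filtering on population databases: a variant whose
#' population minor-allele frequency exceeds `maf_threshold` is tiered
#' `excluded_germline`. The inequality is strict (a variant at exactly the
#' threshold is retained) and missing population frequencies pass the filter.
#' Idempotent.
#'
#' @param variants annotated variant tibble with a `pop_maf` column (NA
#'   allowed).
#' @param maf_threshold default 0.01.
#' @return `variants` with `tier` and `filter_reason` updated.
#' @export
filter_population <- function(variants, maf_threshold = 0.01) {
  assert_columns(variants, "pop_maf")
  if (!"tier" %in% names(variants)) variants$tier <- NA_character_
  if (!"filter_reason" %in% names(variants)) {
    variants$filter_reason <- NA_character_
  }
  hit <- !is.na(variants$pop_maf) & variants$pop_maf > maf_threshold
  variants$tier[hit] <- "excluded_germline"
  variants$filter_reason[hit] <- sprintf("pop_maf > %g", maf_threshold)
  variants
}

#' Load the tiering rule set
#'
#' The pathogenicity rules are data, not code: a YAML file listing hotspot
#' protein changes, tumor-suppressor genes whose truncating variants are
#' likely pathogenic, and the database flags that promote a variant. The
#' shipped defaults approximate published myeloid-panel guideline logic and
#' are meant to be edited.
#'
#' @param path YAML file; defaults to the shipped rule set.
#' @return named list of rules.
#' @export
tier_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tier_rules.yaml",
                                package = "onekaryo")
  yaml::read_yaml(path)
}

#' Tier variants by pathogenicity rules
#'
#' Applies, in order: known hotspot or database-pathogenic -> `pathogenic`;
#' truncating consequence in a listed tumor-suppressor -> `likely_pathogenic`;
#' everything else -> `VUS`. Rows already excluded by [filter_population()]
#' keep their tier. A variant-read-frequency heuristic additionally flags
#' germline-suspect rows (VAF in \[0.45, 0.55\] or >= 0.95 without
#' loss-of-heterozygosity support); the flag is advisory and never excludes.
#' Every fired rule is recorded in `rule_fired`.
#'
#' @param variants variant tibble (columns `gene`, `protein_change`,
#'   `consequence`, `vaf`, optional `somatic_db`, `clinvar_pathogenic`,
#'   `loh_support`).
#' @param rules list from [tier_rules()].
#' @return tibble with `tier`, `rule_fired`, `germline_suspect`.
#' @export
classify_variants <- function(variants, rules = tier_rules()) {
  assert_columns(variants, c("gene", "protein_change", "consequence", "vaf"))
  unknown <- setdiff(names(rules$hotspots), mds_gene_panel())
  if (length(unknown) > 0) {
    stop_onekaryo(paste0("hotspot rule for gene(s) outside the panel: ",
                         paste(unknown, collapse = ", ")),
                  class = "onekaryo_config_error")
  }
  v <- variants
  if (!"tier" %in% names(v)) v$tier <- NA_character_
  if (!"somatic_db" %in% names(v)) v$somatic_db <- FALSE
  if (!"clinvar_pathogenic" %in% names(v)) v$clinvar_pathogenic <- FALSE
  if (!"loh_support" %in% names(v)) v$loh_support <- FALSE
  hotspot_key <- unlist(purrr::imap(rules$hotspots,
                                    ~ paste(.y, .x, sep = ":")))
  key <- paste(v$gene, v$protein_change, sep = ":")
  is_hotspot <- key %in% hotspot_key
  is_db <- (v$somatic_db %in% TRUE) | (v$clinvar_pathogenic %in% TRUE)
  is_trunc <- v$consequence %in% rules$truncating_consequences &
    v$gene %in% rules$tumor_suppressors
  keep <- is.na(v$tier)  # do not overwrite population exclusions
  v$tier[keep & (is_hotspot | is_db)] <- "pathogenic"
  v$tier[keep & !(is_hotspot | is_db) & is_trunc] <- "likely_pathogenic"
  v$tier[keep & is.na(v$tier)] <- "VUS"
  v$rule_fired <- dplyr::case_when(
    !keep ~ "population_filter",
    is_hotspot ~ "hotspot",
    is_db ~ "database_pathogenic",
    is_trunc ~ "truncating_in_tumor_suppressor",
    TRUE ~ "default_vus"
  )
  v$germline_suspect <- (v$vaf >= 0.45 & v$vaf <= 0.55) |
    (v$vaf >= 0.95 & !(v$loh_support %in% TRUE))
  v
}

#' Pairwise mutation co-occurrence and exclusivity
#'
#' For every unordered gene pair, a one-sided Fisher exact test of the 2x2
#' sample-by-mutation table in each direction: co-occurrence (greater) and
#' mutual exclusivity (less). The reported `p_one_sided` is the smaller tail
#' and `direction` names it; Benjamini-Hochberg correction is applied across
#' all pairs. Pairs with a degenerate margin (a gene mutated in no or all
#' samples) are emitted with `p = 1` and flagged.
#'
#' @param mutation_matrix samples x genes binary matrix, or a tibble whose
#'   first column is `sample_id` and remaining columns are 0/1 gene
#'   indicators.
#' @return tibble: gene_a, gene_b, both, a_only, b_only, neither,
#'   p_cooccurrence, p_exclusivity, p_one_sided, direction, q_bh, degenerate.
#' @export
#' @examples
#' m <- matrix(rbinom(40, 1, 0.3), 10, 4,
#'             dimnames = list(NULL, c("TET2", "SF3B1", "TP53", "ASXL1")))
#' cooccurrence(m)
cooccurrence <- function(mutation_matrix) {
  if (is.data.frame(mutation_matrix)) {
    ids <- which(vapply(mutation_matrix, is.numeric, logical(1)))
    m <- as.matrix(mutation_matrix[, ids, drop = FALSE])
  } else {
    m <- as.matrix(mutation_matrix)
  }
  storage.mode(m) <- "integer"
  genes <- colnames(m)
  mutated <- colSums(m) > 0
  if (sum(mutated) < 2) {
    stop_onekaryo("need at least 2 genes with at least 1 mutated sample",
                  class = "onekaryo_validation_error")
  }
  pairs <- utils::combn(seq_along(genes), 2)
  n <- nrow(m)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- m[, i]; b <- m[, j]
    both <- sum(a & b); a_only <- sum(a & !b)
    b_only <- sum(!a & b); neither <- sum(!a & !b)
    degenerate <- sum(a) %in% c(0, n) || sum(b) %in% c(0, n)
    if (degenerate) {
      p_co <- 1; p_ex <- 1
    } else {
      tab <- matrix(c(both, a_only, b_only, neither), 2)
      p_co <- fisher.test(tab, alternative = "greater")$p.value
      p_ex <- fisher.test(tab, alternative = "less")$p.value
    }
    tibble::tibble(
      gene_a = genes[i], gene_b = genes[j],
      both = both, a_only = a_only, b_only = b_only, neither = neither,
      p_cooccurrence = p_co, p_exclusivity = p_ex,
      p_one_sided = min(p_co, p_ex),
      direction = ifelse(p_co <= p_ex, "co-occurrence", "exclusivity"),
      degenerate = degenerate
    )
  })
  out$q_bh <- p.adjust(out$p_one_sided, method = "BH")
  out
}

#' Per-sample mutation burden
#'
#' Counts pathogenic plus likely pathogenic variants per sample; the other
#' tiers do not contribute.
#'
#' @param variants tiered variant tibble with `sample_id` and `tier`.
#' @param sample_ids optional full cohort (so samples without retained
#'   variants count as 0).
#' @return tibble: sample_id, n_deleterious.
#' @export
summarize_burden <- function(variants, sample_ids = NULL) {
  assert_columns(variants, c("sample_id", "tier"))
  counts <- variants |>
    dplyr::filter(.data$tier %in% c("pathogenic", "likely_pathogenic")) |>
    dplyr::count(.data$sample_id, name = "n_deleterious")
  ids <- sample_ids %||% unique(variants$sample_id)
  tibble::tibble(sample_id = ids) |>
    dplyr::left_join(counts, by = "sample_id") |>
    dplyr::mutate(n_deleterious = dplyr::coalesce(.data$n_deleterious, 0L))
}

#' Oncoprint-ready mutation matrix
#'
#' @param variants tiered variant tibble.
#' @param sample_ids optional cohort; defaults to samples present.
#' @param tiers tiers counted as mutated.
#' @return tibble with `sample_id` and one 0/1 column per mutated gene.
#' @export
mutation_matrix <- function(variants, sample_ids = NULL,
                            tiers = c("pathogenic", "likely_pathogenic")) {
  ids <- sample_ids %||% unique(variants$sample_id)
  v <- dplyr::filter(variants, .data$tier %in% tiers)
  wide <- v |>
    dplyr::distinct(.data$sample_id, .data$gene) |>
    dplyr::mutate(mut = 1L) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mut",
                       values_fill = 0L)
  tibble::tibble(sample_id = ids) |>
    dplyr::left_join(wide, by = "sample_id") |>
    dplyr::mutate(dplyr::across(-"sample_id", ~ dplyr::coalesce(.x, 0L)))
}
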