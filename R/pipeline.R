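# end-to-end orchestration: per-sample pipeline and cohort aggregation

#' Run the full per-sample pipeline
#'
#' BAF computation and het calling, reference-normalized depth, depth/BAF
#' event integration, variant tiering and risk scoring, returned as one
#' report bundle. Deterministic under a fixed seed; no input is mutated.
#'
#' @param sample_id identifier used in outputs.
#' @param allele_depths per-SNP allele-count tibble (chrom, pos, ref_count,
#'   alt_count, optional other_count, pop_maf).
#' @param sample_bins raw bin-count tibble (chrom, bin_start, bin_end,
#'   count).
#' @param reference_cohort tidy reference bin table (see
#'   [simulate_reference_cohort()]).
#' @param genome genome tibble.
#' @param variants optional annotated variant tibble for this sample.
#' @param clinical optional [clinical_input()].
#' @param thresholds an [integration_thresholds()].
#' @param sex sample sex.
#' @param min_depth minimum usable SNP depth for the BAF track.
#' @param seed integer seed.
#' @param out_dir optional directory; when given, events/variants TSV and a
#'   risk/provenance JSON are written.
#' @return list of class `onekaryo_report`: events, variants, risk, qc,
#'   baf, bins, provenance.
#' @export
run_sample <- function(sample_id, allele_depths, sample_bins,
                       reference_cohort, genome, variants = NULL,
                       clinical = NULL,
                       thresholds = integration_thresholds(),
                       sex = "XX", min_depth = 20, seed = NULL,
                       out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_onekaryo(sprintf("stage '%s' failed for sample %s: %s", name,
                            sample_id, conditionMessage(e)),
                    class = "onekaryo_stage_error")
    })
  }
  baf <- stage("baf", {
    call_het(compute_baf(allele_depths, min_depth = min_depth))
  })
  qc <- stage("qc", reference_correlation(sample_bins, reference_cohort))
  bins <- stage("normalize",
                normalize_depth(sample_bins, reference_cohort, sex = sex))
  events <- stage("integrate",
                  integrate_events(bins, baf, genome, thresholds, sex = sex,
                                   seed = seed))
  tiered <- NULL
  mutated_genes <- character(0)
  if (!is.null(variants) && nrow(variants) > 0) {
    tiered <- stage("variants",
                    classify_variants(filter_population(variants)))
    mutated_genes <- unique(
      tiered$gene[tiered$tier %in% c("pathogenic", "likely_pathogenic")])
  }
  risk <- NULL
  if (!is.null(clinical)) {
    risk <- stage("risk", {
      if (clinical$disease == "CMML") {
        grp <- cytogenetic_risk(events, "cpss")
        list(cpss = risk_score("cpss", clinical, grp, mutated_genes),
             cpss_mol = risk_score("cpss_mol", clinical, grp,
                                   mutated_genes))
      } else {
        grp <- cytogenetic_risk(events, "ipssr")
        list(ipssr = risk_score("ipssr", clinical, grp, mutated_genes),
             ipssrm = risk_score("ipssrm", clinical, grp, mutated_genes))
      }
    })
  }
  provenance <- list(
    sample_id = sample_id, sex = sex, seed = seed,
    thresholds = unclass(thresholds)[!vapply(unclass(thresholds),
                                             is.function, logical(1))],
    min_depth = min_depth,
    package_version = as.character(utils::packageVersion("onekaryo")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  bundle <- structure(
    list(sample_id = sample_id, events = events, variants = tiered,
         risk = risk, qc = qc, baf = baf, bins = bins,
         provenance = provenance),
    class = "onekaryo_report")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.onekaryo_report <- function(x, ...) {
  cat(sprintf("Sample %s: %d event(s), %s variant(s), reference r = %.3f\n",
              x$sample_id, nrow(x$events),
              if (is.null(x$variants)) "no" else nrow(x$variants),
              x$qc$correlation))
  if (nrow(x$events) > 0) {
    print(dplyr::select(tibble::as_tibble(x$events), "label", "chrom",
                        "start", "end", "event_type", "clonal_fraction",
                        "evidence"))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' @param bundle an `onekaryo_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- file.path(dir, bundle$sample_id)
  write_tsv_report(tibble::as_tibble(bundle$events),
                   paste0(pfx, ".events.tsv"))
  if (!is.null(bundle$variants)) {
    write_tsv_report(bundle$variants, paste0(pfx, ".variants.tsv"))
  }
  risk_json <- purrr::map(bundle$risk, function(r) {
    list(model = r$model, score = r$score, category = r$category,
         cytogenetic_group = r$cytogenetic_group,
         audit = as.list(r$audit))
  })
  jsonlite::write_json(
    list(sample_id = bundle$sample_id, risk = risk_json,
         qc = bundle$qc[c("correlation", "n_bins", "flagged")],
         provenance = bundle$provenance),
    paste0(pfx, ".report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Aggregate per-sample bundles into a cohort summary
#'
#' @param bundles list of `onekaryo_report` objects.
#' @param baseline_categories optional tibble (patient_id, category, model)
#'   of a baseline classification to compare risk categories against.
#' @return list of class `onekaryo_cohort`: per-sample event table, mutation
#'   frequencies, burden, co-occurrence (when >= 2 mutated genes), mutation
#'   matrix, risk table, failed samples.
#' @export
run_cohort <- function(bundles, baseline_categories = NULL) {
  if (length(bundles) < 1) {
    stop_onekaryo("need at least one sample bundle",
                  class = "onekaryo_validation_error")
  }
  ok <- vapply(bundles, inherits, logical(1), "onekaryo_report")
  failed <- vapply(bundles[!ok], function(b) {
    (b$sample_id %||% "<unknown>")
  }, character(1))
  bundles <- bundles[ok]
  events <- purrr::map_dfr(bundles, function(b) {
    dplyr::mutate(tibble::as_tibble(b$events), sample_id = b$sample_id,
                  .before = 1)
  })
  variants <- purrr::map_dfr(bundles, function(b) {
    if (is.null(b$variants)) NULL else b$variants
  })
  ids <- vapply(bundles, `[[`, character(1), "sample_id")
  mm <- NULL
  freqs <- NULL
  burden <- NULL
  cooc <- NULL
  if (nrow(variants) > 0) {
    mm <- mutation_matrix(variants, sample_ids = ids)
    burden <- summarize_burden(variants, sample_ids = ids)
    freqs <- mm |>
      tidyr::pivot_longer(-"sample_id", names_to = "gene",
                          values_to = "mut") |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(n_mutated = sum(.data$mut),
                       frequency = mean(.data$mut), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$frequency))
    if (sum(colSums(mm[, -1, drop = FALSE]) > 0) >= 2) {
      cooc <- cooccurrence(mm)
    }
  }
  risk <- purrr::map_dfr(bundles, function(b) {
    if (is.null(b$risk)) return(NULL)
    purrr::map_dfr(b$risk, function(r) {
      tibble::tibble(patient_id = b$sample_id, model = r$model,
                     score = r$score, category = r$category,
                     cytogenetic_group = r$cytogenetic_group)
    })
  })
  comparison <- NULL
  if (!is.null(baseline_categories) && nrow(risk) > 0) {
    comparison <- purrr::map(
      unique(baseline_categories$model), function(m) {
        compare_classifications(
          dplyr::filter(baseline_categories, .data$model == m),
          dplyr::filter(risk, .data$model == m), model = m)
      })
    names(comparison) <- unique(baseline_categories$model)
  }
  structure(list(events = events, mutation_frequencies = freqs,
                 burden = burden, cooccurrence = cooc,
                 mutation_matrix = mm, risk = risk,
                 comparison = comparison, failed = failed),
            class = "onekaryo_cohort")
}

#' @export
print.onekaryo_cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d sample(s), %d event(s)%s\n",
              dplyr::n_distinct(c(x$events$sample_id,
                                  x$burden$sample_id)),
              nrow(x$events),
              if (length(x$failed) > 0)
                sprintf(", %d failed", length(x$failed)) else ""))
  invisible(x)
}
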