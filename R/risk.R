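# prognostic risk models: cytogenetic grouping of integrated events and
# IPSS-R / CPSS scoring with molecular extensions

#' Load the prognostic scoring tables
#'
#' All component points and category bins live in a shipped, editable YAML
#' file; the molecular gene adjustments are approximations of the published
#' molecular model extensions (see the file header).
#'
#' @param path optional alternative YAML file.
#' @return named list of model tables.
#' @export
risk_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "risk_tables.yaml",
                                package = "onekaryo")
  yaml::read_yaml(path)
}

#' Clinical input record
#'
#' @param disease "MDS", "CMML" or "MDS/MPN".
#' @param bm_blasts bone-marrow blast percentage (0-30).
#' @param hemoglobin g/dL.
#' @param platelets x10^9/L.
#' @param anc absolute neutrophil count, x10^9/L.
#' @param wbc white blood cells, x10^9/L (CPSS).
#' @param transfusion_dependent logical (CPSS).
#' @param who_subtype free-text WHO label.
#' @return list of class `clinical_input`.
#' @export
clinical_input <- function(disease = c("MDS", "CMML", "MDS/MPN"),
                           bm_blasts = NA, hemoglobin = NA, platelets = NA,
                           anc = NA, wbc = NA,
                           transfusion_dependent = NA,
                           who_subtype = NA_character_) {
  disease <- match.arg(disease)
  vals <- c(bm_blasts = bm_blasts, hemoglobin = hemoglobin,
            platelets = platelets, anc = anc, wbc = wbc)
  if (any(!is.na(vals) & vals < 0)) {
    stop_onekaryo("clinical counts must be non-negative",
                  class = "onekaryo_validation_error")
  }
  if (!is.na(bm_blasts) && bm_blasts > 30) {
    stop_onekaryo("bm_blasts above 30% is outside the MDS/CMML range",
                  class = "onekaryo_validation_error")
  }
  structure(list(disease = disease, bm_blasts = bm_blasts,
                 hemoglobin = hemoglobin, platelets = platelets, anc = anc,
                 wbc = wbc, transfusion_dependent = transfusion_dependent,
                 who_subtype = who_subtype),
            class = "clinical_input")
}

# canonical lesion labels from an event table (or pass labels directly)
event_labels <- function(events, cnloh_upstage = TRUE) {
  labs <- if (is.character(events)) events
  else if (nrow(events) == 0) character(0)
  else events$label
  if (cnloh_upstage) {
    # cnLOH of 7q / 17p carries the prognosis of the matching deletion;
    # cnLOH elsewhere is dropped from grouping by the caller
    labs[labs == "cnLOH(7q)"] <- "del(7q)"
    labs[labs == "cnLOH(17p)"] <- "del(17p)"
  }
  labs
}

#' Cytogenetic risk group from integrated events
#'
#' Maps a lesion list to the five IPSS-R cytogenetic groups or the three
#' CPSS groups. Copy-neutral LOH of 7q and 17p is grouped with the
#' corresponding deletion when `cnloh_upstage = TRUE` (the default): both
#' lesions inactivate the same allele, so a depth-invisible cnLOH carries
#' the deletion's prognosis. Other cnLOH and AMBIGUOUS events do not count
#' as abnormalities. Three or more relevant abnormalities form a complex
#' karyotype.
#'
#' @param events an event tibble from [integrate_events()] (uses `label` and
#'   `event_type`) or a character vector of ISCN-like labels such as
#'   `"del(5q)"`, `"-7"`, `"+8"`, `"cnLOH(7q)"`.
#' @param model `"ipssr"` or `"cpss"`.
#' @param cnloh_upstage treat cnLOH(7q)/cnLOH(17p) as del(7q)/del(17p).
#' @param include_baf_only count events that still require orthogonal
#'   confirmation (default FALSE).
#' @return group label (character scalar).
#' @export
#' @examples
#' cytogenetic_risk(c("del(5q)"), "ipssr")
#' cytogenetic_risk(c("cnLOH(7q)"), "cpss")
cytogenetic_risk <- function(events, model = c("ipssr", "cpss"),
                             cnloh_upstage = TRUE,
                             include_baf_only = FALSE) {
  model <- match.arg(model)
  if (!is.character(events) && nrow(events) > 0 && !include_baf_only) {
    events <- dplyr::filter(events, !.data$requires_confirmation)
  }
  labs <- event_labels(events, cnloh_upstage)
  labs <- labs[!grepl("^(cnLOH|amb)", labs)]
  n <- length(labs)
  if (model == "ipssr") {
    if (n == 0) return("Good")
    if (n > 3) return("Very Poor")
    poor_single <- c("-7", "del(3q)", "inv(3)", "t(3q)")
    if (n == 3) return("Poor")
    if (n == 1) {
      if (labs %in% c("-Y", "del(11q)")) return("Very Good")
      if (labs %in% c("del(5q)", "del(12p)", "del(20q)")) return("Good")
      if (labs %in% poor_single) return("Poor")
      return("Intermediate")
    }
    # doubles
    if (any(labs %in% c("-7", "del(7q)"))) return("Poor")
    if (any(labs == "del(5q)")) return("Good")
    return("Intermediate")
  }
  # CPSS three-group scheme
  if (n == 0 || all(labs == "-Y")) return("Low")
  chr7 <- grepl("\\(7[pq]?\\)|^-7$", labs)
  if (n >= 3 || any(labs == "+8") || any(chr7)) return("High")
  "Intermediate"
}

bin_points_max <- function(x, bins) {
  for (b in bins) if (x <= b$max) return(b$points)
  stop_onekaryo("value outside configured bins",
                class = "onekaryo_config_error")
}

bin_points_min <- function(x, bins) {
  for (b in bins) if (x >= b$min) return(b$points)
  stop_onekaryo("value outside configured bins",
                class = "onekaryo_config_error")
}

category_of <- function(score, bins) {
  for (b in bins) if (score <= b$max) return(b$label)
  stop_onekaryo("score outside configured category bins",
                class = "onekaryo_config_error")
}

require_fields <- function(clinical, fields, model) {
  vals <- unlist(clinical[fields], use.names = TRUE)
  miss <- fields[is.na(vals)]
  if (length(miss) > 0) {
    stop_onekaryo(sprintf("model %s requires clinical field(s): %s", model,
                          paste(miss, collapse = ", ")),
                  class = "onekaryo_missing_field_error")
  }
}

#' Compute a prognostic risk score
#'
#' Deterministic table lookup over the shipped configuration: IPSS-R sums
#' cytogenetic, blast, hemoglobin, platelet and neutrophil points; CPSS sums
#' cytogenetic group, WHO subtype (blasts), proliferative WBC and transfusion
#' dependence; the molecular variants add gene-presence adjustments (IPSS-Rm:
#' EZH2/SF3B1/TP53; CPSS-Mol: RUNX1/NRAS/SETBP1/ASXL1). The result records
#' every component's points in an audit trail.
#'
#' @param model one of `"ipssr"`, `"ipssrm"`, `"cpss"`, `"cpss_mol"`.
#' @param clinical a [clinical_input()].
#' @param cytogenetic_group group label from [cytogenetic_risk()] (IPSS-R
#'   scheme for ipssr/ipssrm, CPSS scheme for cpss/cpss_mol).
#' @param mutations character vector of genes carrying deleterious mutations.
#' @param config tables from [risk_config()].
#' @return object of class `risk_result`: model, score, category,
#'   cytogenetic_group, audit (named numeric of component points).
#' @export
#' @examples
#' cl <- clinical_input("MDS", bm_blasts = 12, hemoglobin = 7.5,
#'                      platelets = 40, anc = 0.5)
#' risk_score("ipssr", cl, "Poor")
risk_score <- function(model = c("ipssr", "ipssrm", "cpss", "cpss_mol"),
                       clinical, cytogenetic_group, mutations = character(),
                       config = risk_config()) {
  model <- match.arg(model)
  if (clinical$disease == "MDS/MPN" && model %in% c("ipssr", "ipssrm")) {
    warning("MDS/MPN scored with the MDS model (IPSS-R) by convention",
            call. = FALSE)
  }
  audit <- c()
  if (model %in% c("ipssr", "ipssrm")) {
    require_fields(clinical, c("bm_blasts", "hemoglobin", "platelets", "anc"),
                   model)
    tab <- config$ipssr
    cyto_pts <- tab$cytogenetic_points[[cytogenetic_group]]
    if (is.null(cyto_pts)) {
      stop_onekaryo(sprintf("unknown IPSS-R cytogenetic group '%s'",
                            cytogenetic_group),
                    class = "onekaryo_config_error")
    }
    audit <- c(cytogenetics = cyto_pts,
               blasts = bin_points_max(clinical$bm_blasts, tab$blasts),
               hemoglobin = bin_points_min(clinical$hemoglobin,
                                           tab$hemoglobin),
               platelets = bin_points_min(clinical$platelets, tab$platelets),
               anc = bin_points_min(clinical$anc, tab$anc))
    score <- sum(audit)
    cats <- tab$categories
    if (model == "ipssrm") {
      gp <- unlist(config$ipssrm$gene_points)
      adj <- sum(gp[names(gp) %in% mutations])
      audit <- c(audit, mutation_adjustment = adj)
      score <- max(score + adj, 0)
      cats <- config$ipssrm$categories
    }
  } else {
    require_fields(clinical, c("bm_blasts", "wbc", "transfusion_dependent"),
                   model)
    tab <- config$cpss
    cyto_pts <- tab$cytogenetic_points[[cytogenetic_group]]
    if (is.null(cyto_pts)) {
      stop_onekaryo(sprintf("unknown CPSS cytogenetic group '%s'",
                            cytogenetic_group),
                    class = "onekaryo_config_error")
    }
    who_pts <- as.numeric(clinical$bm_blasts >= tab$blasts_who_threshold)
    wbc_pts <- as.numeric(clinical$wbc >= tab$wbc_high_threshold)
    if (model == "cpss") {
      audit <- c(cytogenetics = cyto_pts, who_subtype = who_pts,
                 wbc = wbc_pts,
                 transfusion = as.numeric(clinical$transfusion_dependent))
      score <- sum(audit)
      cats <- tab$categories
    } else {
      mtab <- config$cpss_mol
      gp <- unlist(mtab$gene_points)
      genetic <- cyto_pts + sum(gp[names(gp) %in% mutations])
      genetic_group <- min(genetic, mtab$genetic_group_max)
      audit <- c(genetic_group = genetic_group,
                 blasts = as.numeric(clinical$bm_blasts >=
                                       mtab$blasts_threshold),
                 wbc = wbc_pts,
                 transfusion = as.numeric(clinical$transfusion_dependent))
      score <- sum(audit)
      cats <- mtab$categories
    }
  }
  structure(list(model = model, score = score,
                 category = category_of(score, cats),
                 cytogenetic_group = cytogenetic_group,
                 mutations = mutations, audit = audit),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("%s score %.1f -> %s (cytogenetics: %s)\n",
              toupper(x$model), x$score, x$category, x$cytogenetic_group))
  invisible(x)
}

#' @export
tidy.risk_result <- function(x, ...) {
  tibble::tibble(component = names(x$audit), points = unname(x$audit))
}

#' @export
glance.risk_result <- function(x, ...) {
  tibble::tibble(model = x$model, score = x$score, category = x$category,
                 cytogenetic_group = x$cytogenetic_group,
                 n_mutations = length(x$mutations))
}

#' Category order of a risk model
#' @param model model name as in [risk_score()].
#' @param config tables from [risk_config()].
#' @return character vector, best to worst.
#' @export
risk_categories <- function(model, config = risk_config()) {
  key <- switch(model, ipssr = "ipssr", ipssrm = "ipssrm", cpss = "cpss",
                cpss_mol = "cpss_mol")
  vapply(config[[key]]$categories, `[[`, character(1), "label")
}

#' Compare two classifications of the same patients
#'
#' Builds the category-transition matrix between a baseline classification
#' (e.g. from conventional cytogenetics) and a comparison classification
#' (e.g. from sequencing-derived events), with row-normalized percentages,
#' and labels every patient confirmed / upstaged / downstaged.
#'
#' @param results_a,results_b tibbles with `patient_id` and `category`
#'   (factors or characters); `results_a` is the baseline.
#' @param model model name, used to order categories.
#' @param config tables from [risk_config()].
#' @return list of class `risk_comparison`: `transitions` (long tibble with
#'   counts and row percentages), `per_patient`, `unpaired`.
#' @export
compare_classifications <- function(results_a, results_b, model = "ipssr",
                                    config = risk_config()) {
  assert_columns(results_a, c("patient_id", "category"), "results_a")
  assert_columns(results_b, c("patient_id", "category"), "results_b")
  cats <- risk_categories(model, config)
  paired <- dplyr::inner_join(results_a, results_b, by = "patient_id",
                              suffix = c("_a", "_b"))
  unpaired <- setdiff(union(results_a$patient_id, results_b$patient_id),
                      paired$patient_id)
  lv_a <- factor(paired$category_a, levels = cats)
  lv_b <- factor(paired$category_b, levels = cats)
  tab <- table(from = lv_a, to = lv_b)
  transitions <- as.data.frame(tab, stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq") |>
    dplyr::group_by(.data$from) |>
    dplyr::mutate(pct = ifelse(sum(.data$n) > 0,
                               100 * .data$n / sum(.data$n), 0)) |>
    dplyr::ungroup()
  per_patient <- paired |>
    dplyr::mutate(direction = dplyr::case_when(
      as.integer(factor(.data$category_b, cats)) >
        as.integer(factor(.data$category_a, cats)) ~ "upstage",
      as.integer(factor(.data$category_b, cats)) <
        as.integer(factor(.data$category_a, cats)) ~ "downstage",
      TRUE ~ "confirmed"))
  structure(list(transitions = transitions, per_patient = per_patient,
                 unpaired = unpaired, model = model, categories = cats),
            class = "risk_comparison")
}

#' @export
print.risk_comparison <- function(x, ...) {
  conf <- mean(x$per_patient$direction == "confirmed") * 100
  cat(sprintf("%s: %d paired patients, %.0f%% confirmed, %d unpaired\n",
              toupper(x$model), nrow(x$per_patient), conf,
              length(x$unpaired)))
  invisible(x)
}

#' @export
tidy.risk_comparison <- function(x, ...) x$transitions

#' @export
glance.risk_comparison <- function(x, ...) {
  d <- x$per_patient$direction
  tibble::tibble(model = x$model, n = length(d),
                 confirmed = sum(d == "confirmed"),
                 upstaged = sum(d == "upstage"),
                 downstaged = sum(d == "downstage"),
                 unpaired = length(x$unpaired))
}
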