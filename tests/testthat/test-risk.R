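# cytogenetic grouping and prognostic scoring

test_that("cytogenetic grouping covers the canonical single-lesion table", {
  expect_equal(cytogenetic_risk(character(0), "ipssr"), "Good")
  expect_equal(cytogenetic_risk("-Y", "ipssr"), "Very Good")
  expect_equal(cytogenetic_risk("del(5q)", "ipssr"), "Good")
  expect_equal(cytogenetic_risk("del(7q)", "ipssr"), "Intermediate")
  expect_equal(cytogenetic_risk("-7", "ipssr"), "Poor")
  expect_equal(cytogenetic_risk(c("del(5q)", "+8"), "ipssr"), "Good")
  expect_equal(cytogenetic_risk(c("del(5q)", "del(7q)"), "ipssr"), "Poor")
  expect_equal(cytogenetic_risk(c("+8", "del(20q)", "del(12p)"), "ipssr"),
               "Poor")
  expect_equal(cytogenetic_risk(c("+8", "del(20q)", "del(12p)", "-18"),
                                "ipssr"), "Very Poor")
  expect_equal(cytogenetic_risk(character(0), "cpss"), "Low")
  expect_equal(cytogenetic_risk("+8", "cpss"), "High")
  expect_equal(cytogenetic_risk("del(20q)", "cpss"), "Intermediate")
})

test_that("cnLOH of 7q/17p is grouped with its deletion when the flag is on", {
  expect_equal(cytogenetic_risk("cnLOH(7q)", "ipssr"),
               cytogenetic_risk("del(7q)", "ipssr"))
  expect_equal(cytogenetic_risk("cnLOH(17p)", "ipssr"),
               cytogenetic_risk("del(17p)", "ipssr"))
  expect_equal(cytogenetic_risk("cnLOH(7q)", "cpss"), "High")
  # flag off: copy-neutral lesions vanish from grouping
  expect_equal(cytogenetic_risk("cnLOH(7q)", "ipssr",
                                cnloh_upstage = FALSE), "Good")
  # cnLOH elsewhere never counts as a CNA
  expect_equal(cytogenetic_risk("cnLOH(4q)", "ipssr"), "Good")
})

test_that("reclassifying monosomy 7 as 7q cnLOH records a downstage", {
  grp_before <- cytogenetic_risk("-7", "ipssr")
  grp_after <- cytogenetic_risk("cnLOH(7q)", "ipssr")
  expect_equal(grp_before, "Poor")
  expect_equal(grp_after, "Intermediate")
  cl <- clinical_input("MDS", bm_blasts = 7, hemoglobin = 9,
                       platelets = 80, anc = 0.5)
  cmp <- compare_classifications(
    tibble::tibble(patient_id = "p1",
                   category = risk_score("ipssr", cl, grp_before)$category),
    tibble::tibble(patient_id = "p1",
                   category = risk_score("ipssr", cl, grp_after)$category))
  expect_equal(cmp$per_patient$direction, "downstage")
})

test_that("IPSS-R component points and category bins reproduce the scheme", {
  cl <- clinical_input("MDS", bm_blasts = 12, hemoglobin = 7.5,
                       platelets = 40, anc = 0.5)
  r <- risk_score("ipssr", cl, "Very Good")
  # 0 + 3 + 1.5 + 1 + 0.5 = 6
  expect_equal(r$score, 6)
  expect_equal(r$category, "High")
  cl2 <- clinical_input("MDS", bm_blasts = 12, hemoglobin = 9,
                        platelets = 80, anc = 1.5)
  r2 <- risk_score("ipssr", cl2, "Intermediate")
  # 2 + 3 + 1 + 0.5 + 0 = 6.5 -> Very High
  expect_equal(r2$score, 6.5)
  expect_equal(r2$category, "Very High")
  expect_equal(sum(tidy(r2)$points), r2$score)
})

test_that("CPSS all-zero components score 0 and classify Low", {
  cl <- clinical_input("CMML", bm_blasts = 4, hemoglobin = 11,
                       platelets = 150, anc = 2, wbc = 9,
                       transfusion_dependent = FALSE)
  r <- risk_score("cpss", cl, "Low")
  expect_equal(r$score, 0)
  expect_equal(r$category, "Low")
  cl2 <- clinical_input("CMML", bm_blasts = 12, hemoglobin = 9,
                        platelets = 60, anc = 2, wbc = 20,
                        transfusion_dependent = TRUE)
  r2 <- risk_score("cpss", cl2, "High")
  expect_equal(r2$score, 5)
  expect_equal(r2$category, "High")
})

test_that("molecular models reduce to the base model without mutations", {
  cl <- clinical_input("MDS", bm_blasts = 3, hemoglobin = 10.5,
                       platelets = 120, anc = 1.2)
  base <- risk_score("ipssr", cl, "Good")
  mol <- risk_score("ipssrm", cl, "Good")
  expect_equal(mol$score, base$score)
  mol_mut <- risk_score("ipssrm", cl, "Good", mutations = c("TP53", "EZH2"))
  expect_gt(mol_mut$score, base$score)
  clc <- clinical_input("CMML", bm_blasts = 4, hemoglobin = 11,
                        platelets = 150, anc = 2, wbc = 9,
                        transfusion_dependent = FALSE)
  expect_equal(risk_score("cpss_mol", clc, "Low")$category, "Low")
  expect_equal(risk_score("cpss_mol", clc, "Low",
                          mutations = "RUNX1")$category, "Intermediate-2")
})

test_that("missing clinical fields raise errors naming the field", {
  cl <- clinical_input("MDS", bm_blasts = 5, hemoglobin = 10)
  expect_error(risk_score("ipssr", cl, "Good"), "platelets",
               class = "onekaryo_missing_field_error")
  expect_error(risk_score("cpss",
                          clinical_input("CMML", bm_blasts = 5), "Low"),
               "wbc", class = "onekaryo_missing_field_error")
  expect_error(risk_score("ipssr", clinical_input("MDS", bm_blasts = 5,
                                                  hemoglobin = 10,
                                                  platelets = 100,
                                                  anc = 1),
                          "NotAGroup"),
               class = "onekaryo_config_error")
})

test_that("risk scores are monotone in every component", {
  cfg <- risk_config()
  cyto <- names(cfg$ipssr$cytogenetic_points)
  grid <- tidyr::expand_grid(
    blasts = c(1, 3, 7, 15), hb = c(7, 9, 11), plt = c(30, 70, 150),
    anc = c(0.5, 1.5))
  for (g in cyto) {
    scores <- purrr::pmap_dbl(grid, function(blasts, hb, plt, anc) {
      risk_score("ipssr",
                 clinical_input("MDS", bm_blasts = blasts, hemoglobin = hb,
                                platelets = plt, anc = anc), g)$score
    })
    df <- dplyr::mutate(grid, score = scores)
    # worsening one component with the rest fixed never lowers the score
    worse <- df |>
      dplyr::group_by(hb, plt, anc) |>
      dplyr::summarise(ok = all(diff(score[order(blasts)]) >= 0),
                       .groups = "drop")
    expect_true(all(worse$ok))
    worse_hb <- df |>
      dplyr::group_by(blasts, plt, anc) |>
      dplyr::summarise(ok = all(diff(score[order(-hb)]) >= 0),
                       .groups = "drop")
    expect_true(all(worse_hb$ok))
  }
  # worsening the cytogenetic group alone
  cl <- clinical_input("MDS", bm_blasts = 3, hemoglobin = 10,
                       platelets = 100, anc = 1)
  cyto_scores <- vapply(cyto, function(g) risk_score("ipssr", cl, g)$score,
                        numeric(1))
  expect_true(all(diff(cyto_scores) >= 0))
})

test_that("category bins partition the score range without gaps", {
  cfg <- risk_config()
  for (model in c("ipssr", "ipssrm", "cpss", "cpss_mol")) {
    bins <- cfg[[model]]$categories
    maxes <- vapply(bins, `[[`, numeric(1), "max")
    expect_true(all(diff(maxes) > 0))
    # every score in a fine sweep maps to exactly one category
    for (sc in seq(0, maxes[length(maxes)], by = 0.25)) {
      expect_length(onekaryo:::category_of(sc, bins), 1)
    }
  }
})

test_that("classification comparison builds the transition matrix", {
  a <- tibble::tibble(patient_id = paste0("p", 1:6),
                      category = c("Low", "Low", "High", "Very Low",
                                   "Intermediate", "Low"))
  ident <- compare_classifications(a, a)
  expect_true(all(ident$per_patient$direction == "confirmed"))
  off <- ident$transitions[ident$transitions$from != ident$transitions$to, ]
  expect_true(all(off$n == 0))

  b <- a
  b$category[2] <- "High"
  cmp <- compare_classifications(a, b)
  expect_equal(sum(cmp$per_patient$direction == "upstage"), 1)
  # row sums equal patient counts per original category
  rows <- cmp$transitions |>
    dplyr::group_by(from) |>
    dplyr::summarise(n = sum(n))
  expect_equal(rows$n[rows$from == "Low"], 3)
  expect_equal(sum(rows$n), 6)
  # unpaired patients are listed, not silently dropped
  cmp2 <- compare_classifications(a[1:4, ], a[3:6, ])
  expect_setequal(cmp2$unpaired, c("p1", "p2", "p5", "p6"))
})
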