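# Prognostic scoring tables (editable, versioned data).
# Component points and category bins are transcriptions/approximations of the
# published IPSS-R and CPSS systems and of their molecular extensions; the
# molecular gene adjustments in particular are approximations and should be
# recalibrated before any clinical use.
ipssr:
  cytogenetic_points: {Very Good: 0, Good: 1, Intermediate: 2, Poor: 3, Very Poor: 4}
  blasts:        # bone-marrow blast %
    - {max: 2, points: 0}
    - {max: 4.99, points: 1}
    - {max: 10, points: 2}
    - {max: 100, points: 3}
  hemoglobin:    # g/dL, lower is worse
    - {min: 10, points: 0}
    - {min: 8, points: 1}
    - {min: 0, points: 1.5}
  platelets:     # x10^9/L
    - {min: 100, points: 0}
    - {min: 50, points: 0.5}
    - {min: 0, points: 1}
  anc:           # x10^9/L
    - {min: 0.8, points: 0}
    - {min: 0, points: 0.5}
  categories:
    - {max: 1.5, label: Very Low}
    - {max: 3, label: Low}
    - {max: 4.5, label: Intermediate}
    - {max: 6, label: High}
    - {max: 100, label: Very High}
ipssrm:
  # additive gene adjustments on the IPSS-R score (approximation)
  gene_points: {EZH2: 1.0, TP53: 1.0, SF3B1: -0.5}
  categories:
    - {max: 1.5, label: Low}
    - {max: 3, label: Intermediate-1}
    - {max: 4.5, label: Intermediate-2}
    - {max: 6, label: High}
    - {max: 100, label: Very High}
cpss:
  cytogenetic_points: {Low: 0, Intermediate: 1, High: 2}
  wbc_high_threshold: 13      # x10^9/L; myeloproliferative CMML
  blasts_who_threshold: 10    # CMML-2
  categories:
    - {max: 0, label: Low}
    - {max: 1, label: Intermediate-1}
    - {max: 3, label: Intermediate-2}
    - {max: 10, label: High}
cpss_mol:
  gene_points: {ASXL1: 1, NRAS: 1, SETBP1: 1, RUNX1: 2}
  genetic_group_max: 3        # genetic score capped into 0-3 group points
  blasts_threshold: 5
  categories:
    - {max: 0, label: Low}
    - {max: 1, label: Intermediate-1}
    - {max: 3, label: Intermediate-2}
    - {max: 10, label: High}
cytogenetic_groups:
  ipssr: [Very Good, Good, Intermediate, Poor, Very Poor]
  cpss: [Low, Intermediate, High]
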