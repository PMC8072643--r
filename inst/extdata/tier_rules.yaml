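# Pathogenicity tiering rules (editable data, not code).
# The defaults below approximate published myeloid-panel guideline logic:
# named hotspot protein changes and database-pathogenic hits tier as
# pathogenic; truncating variants in the listed tumor suppressors as likely
# pathogenic; everything else as VUS. Treat these lists as a starting point
# and curate per laboratory policy.
hotspots:
  SF3B1: [K700E, K666N, H662Q, E622D, R625C]
  SRSF2: [P95H, P95L, P95R, P95_103del, P95delinsRP]
  JAK2: [V617F]
  IDH1: [R132H, R132C]
  IDH2: [R140Q, R172K]
  NPM1: [W288fs]
  KRAS: [G12D, G12V, G13D]
  NRAS: [G12D, G12V, Q61K]
  U2AF1: [S34F, S34Y, Q157P, Q157R]
  TP53: [R175H, R248Q, R248W, R273H, R273C]
tumor_suppressors:
  [TP53, TET2, ASXL1, EZH2, RUNX1, BCOR, BCORL1, ZRSR2, STAG2, PHF6, WT1,
   NF1, CUX1, ETV6, DDX41, GATA2]
truncating_consequences:
  [stop_gained, frameshift, splice_acceptor, splice_donor]
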