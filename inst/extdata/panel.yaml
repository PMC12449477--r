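# Marker/panel configuration schema (worked example).
#
# cell_types: ordered rules; the FIRST rule a cell satisfies assigns its
#   label (cells matching none become "U.C."). A rule matches when
#   - mode "any" (default): at least one positive marker has count >= tau
#   - mode "all": every positive marker has count >= tau
#   and every negative_marker has count exactly 0 (a count of 1 is
#   indeterminate: neither positive nor negative).
# tumour_rule: grid-level mask rule — positive markers need aggregated
#   count >= 1 per grid cell, negative markers exactly 0.
# hotcold_gene: basis gene of the hot (>= 2) / cold (<= 1) rule.
cell_types:
  - label: epithelial
    positive_markers: [CDH1, KRT5, KRT8, EPCAM]
    mode: any
  - label: CAF
    positive_markers: [COL1A1]
  - label: myeloid
    positive_markers: [CD68, CD163]
    mode: any
  - label: LYM
    positive_markers: [PTPRC, CD3E, CD8A]
    mode: any
  - label: plasma
    positive_markers: [POU2AF1]
tumour_rule:
  positive: [CDH1, SFTPB, SFTPC]
  negative: [SFTPD]
hotcold_gene: CD274
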