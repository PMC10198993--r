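# Column-name mapping from each predictor's export dialect onto the
# package's canonical prediction-record schema. Edit the right-hand side to
# match a different export version; no code change needed.
diana:
  mirna: mirna
  gene: gene_name
  mitg_score: mitg_score
mirdb:
  mirna: mirna_name
  gene: gene_symbol
  prediction_score: target_score
targetscan:
  mirna: mirna
  gene: gene_symbol
  site_start: utr_start
  site_end: utr_end
  context_plus: context_plus_score
  pct: pct
rna22:
  mirna: mirna
  gene: gene
  site_start: site_start
  site_end: site_end
  p_value: p_value
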