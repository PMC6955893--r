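{
  "required": {
    "package_version": "string",
    "seed": "number",
    "input": {
      "n_samples": "number",
      "n_taxa": "number",
      "depth": "number",
      "groups": "object"
    },
    "niche": {
      "n_generalist": "number",
      "n_specialist": "number",
      "n_non_significant": "number",
      "generalist_seq_fraction": "number",
      "specialist_seq_fraction": "number",
      "n_perm": "number",
      "alpha": "number"
    },
    "indval": {
      "n_tested": "number",
      "n_selected": "number",
      "selected_by_group": "object",
      "gates": "object"
    },
    "multivariate_tests": "object",
    "environment_selection": {
      "vif_retained": "object",
      "vif_dropped": "object",
      "n_pcnm": "number",
      "forward_selected_env": "object",
      "forward_selected_spat": "object"
    },
    "variation_partitioning": "object",
    "beta_null": "object",
    "neutral_model": "object",
    "cross_partition": "object",
    "flags": "object"
  }
}
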