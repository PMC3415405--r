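{
  "sim": {
    "n_genes": 10000,
    "extra_probe_fraction": 0.15,
    "group_sizes": {"2N": 12, "CHD-": 22, "AVSD": 7, "ASD": 8, "VSD": 6},
    "trisomy_chrom": "chr21",
    "dosage_fraction": 0.3,
    "n_de_per_contrast": {"AVSD": 400, "ASD+VSD": 450},
    "de_log2fc_range": [0.3, 1.0],
    "planted_cluster": {"chromosome": "chr21", "start": 40, "k": 3, "contrast": "AVSD"},
    "noise_sd": [0.1, 0.3],
    "low_expr_fraction": 0.1,
    "seed": 1
  },
  "alpha_detect": 0.01,
  "min_arrays": 4,
  "alpha_merge": 0.01,
  "alpha_de": 0.05,
  "equality_mode": "pvalue",
  "equality_band": [0.95, 1.05],
  "collapse": "max-mean",
  "k_values": [2, 3],
  "cluster_method": "exact",
  "n_genesets": 50,
  "geneset_size_range": [5, 100],
  "seed": 1
}
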