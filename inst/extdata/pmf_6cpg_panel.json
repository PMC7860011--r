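{
  "name": "published_pmf_fibrotic_progression_6cpg_panel",
  "description": "Published six-CpG linear discriminant panel separating fibrotic progression from stable disease in prefibrotic primary myelofibrosis. Coefficients are opaque reference values: the training cohort (GEO GSE152519) is not bundled, so they cannot be re-derived here and are shipped for serialization and lookup tests only.",
  "coefficient_units": "per beta unit, linear discriminant model",
  "probes": [
    {"probe_id": "cg03983220", "chr": "chr16", "island_relation": "OpenSea", "gene": "", "ld_coefficient": -7.431161},
    {"probe_id": "cg11628316", "chr": "chr10", "island_relation": "Island", "gene": "MXI1", "ld_coefficient": -44.910325},
    {"probe_id": "cg08880875", "chr": "chr2", "island_relation": "N_Shore", "gene": "M1AP", "ld_coefficient": -11.469252},
    {"probe_id": "cg21459486", "chr": "chr13", "island_relation": "OpenSea", "gene": "", "ld_coefficient": -9.140643},
    {"probe_id": "cg05972185", "chr": "chr16", "island_relation": "OpenSea", "gene": "ZFHX3", "ld_coefficient": 6.017707},
    {"probe_id": "cg18376352", "chr": "chr19", "island_relation": "Island", "gene": "CRLF1", "ld_coefficient": 12.946803}
  ]
}
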