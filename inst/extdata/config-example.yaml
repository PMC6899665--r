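# Example dietmerge pipeline configuration
markers:
  18S:
    min_len: 94
    max_len: 153
  IN16STK:
    min_len: 72
    max_len: 119
  ZBJ:
    min_len: 155
    max_len: 159
  trnL:
    min_len: 30
    max_len: 93
    rel_abundance_floor: 0.01
exclusion:
  allowed_kingdoms: [Plantae, Animalia]
  excluded_clades:
    - Plantae;Bryophyta
    - Plantae;Marchantiophyta
    - Plantae;Anthocerotophyta
    - Animalia;Chordata;Aves
    - Animalia;Chordata;Mammalia
    - Animalia;Nematoda
    - Animalia;Arthropoda;Insecta;Coleoptera;Tenebrionidae
lca_tolerance: 1.0
lineage_sep: ";"
seed: 1
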