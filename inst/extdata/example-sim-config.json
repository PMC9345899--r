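{
  "sim": {
    "n_promoters": 60,
    "total_tags_per_sample": 8000,
    "genome": {"chr1": 300000, "chr2": 300000},
    "n_genes": 40,
    "n_tra": 10,
    "n_housekeeping": 10
  },
  "seed": 5,
  "outdir": "simout"
}
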