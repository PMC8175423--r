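{
  "seed": 20,
  "scenario": {
    "n_species": 16,
    "n_replicates": 3,
    "n_ptr_compounds": 60,
    "n_gc_compounds": 24
  },
  "clustering": { "k": 12 },
  "dapc": { "labels": ["trophic_mode", "phylum"], "n_rep": 5, "grid": [4, 8, 16, 24, 32] },
  "pi": { "n_null": 300 },
  "biomarkers": {
    "tasks": ["trophic_mode"],
    "platforms": ["PTR"],
    "ntree": 150,
    "subset_grid": [5, 10, 15, 30, 60]
  }
}
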