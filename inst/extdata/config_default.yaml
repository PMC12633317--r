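# Default synthetic end-to-end run: five clones spanning the EMT axis.
output: emtscape_run
seed: 1
n_clones: 5
n_tumor_cells: 500
n_immune_cells: 2000
n_panel_samples: 81
qc_preset_tumor: total
qc_preset_immune: cd45
scale: 10000
log2fc_threshold: 1.5
min_gene_overlap: 50
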