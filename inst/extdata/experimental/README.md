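# Experimental Cell-Index curves (not shipped)

Place the averaged experimental Cell-Index curves of the real-time
transwell assays here, one CSV per condition with the export layout
`time_h,ci_mean,ci_sd`, to enable the experimental-agreement checks:

- `sarc_migration_2e4.csv`   — chondrosarcoma, 2e4 cells/well, serum gradient
- `ht1080_basal_2e4.csv`     — fibrosarcoma, 2e4 cells/well, serum-free
- `a375_migration_2e4.csv`   — melanoma, 2e4 cells/well, serum gradient
- `sarc_migration_3e4.csv`   — chondrosarcoma, 3e4 cells/well, serum gradient

Each curve should be the average of the independent replicate experiments
(see `average_replicates()`); `read_rtca_table()` also accepts the raw
per-experiment XLSX sheets, which can be averaged and exported with
`write_rtca_table()`. These files are distributed with the assay study's
supplementary material and are not redistributed here.
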