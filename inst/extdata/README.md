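# External data drop-in

The published per-tumor supplementary model-data workbook (features, NLR,
abscopal labels, and optionally a recorded train/validation split) is not
redistributed with this package. To reproduce the published AUC panel from
it, place the file here as `s1_model_data.xlsx` (or a CSV export as
`s1_model_data.csv`) and run `reproduce_published_aucs()`; see
`?read_s1_table` for the column-mapping options.
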