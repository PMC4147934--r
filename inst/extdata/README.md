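# Bundled data

`reference_subtypes_synthetic.tsv` — a SYNTHETIC example of a reference
subtype signature matrix (subtypes x gene sets, values in [-1, 1]).
Published reference profiles of this kind are digitized by eye from
heatmap figures and are not reproduced here; this file is an editable
template whose values are invented for illustration and tests of the file
format only. Replace it with your own digitization before using
`read_reference_matrix()` for real analyses.
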