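# Packaged five-lesion worked example (synthetic emulation of a patient
# with three fibroadenomas, one benign and one malignant phyllodes tumor).
genome_build: hg19
mutations: mutations_synthetic.tsv
segments: segments_synthetic.seg
purity: purity_synthetic.tsv
frequency_table: cohort_A
reference_sim:
  n: 22
  seed: 7
alpha: 0.05
clonal_threshold: 0.9
tolerance: 1000000
cutoff_method: normal_ci
cutoff_level: 0.95
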