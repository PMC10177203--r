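# Example histocad run configuration: synthesize a small labelled archive,
# then evaluate stub features + a linear SVM under grouped nested CV.
schema_version: 1
master_seed: 424
dataset:
  layout: synthetic
  synthetic:
    n_cases_per_class: 20
    images_per_case: 8
    image_size: [96, 96]
    nucleus_rate: {benign: 20, malignant: 120}
    stain_shift_sd: 8
backbone:
  name: stub
  input_size: 96
  widths: [8, 16, 32]
  seed: 1
augmentation:
  strategy: base
  target_size: 96
  resize_edge: 96
  repeats: 1
classifier:
  family: linear_svm
evaluation:
  k: 5
  k_inner: 5
  n_search_iter: 10
  test_strategy: ten_crop
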