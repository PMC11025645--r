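# Example pipeline configuration: a reduced run for quick exploration.
# Unset fields fall back to default_config(); see the methods vignette
# for what each parameter controls.
seed: 1
synth:
  vocab: 20
  embedding_dim: 24
  k: 4
  n_words_train: 900
  n_words_test: 500
  n_reps: 9
  rep_dims: 24
bold:
  n_voxels: 24
  n_test_repeats: 3
generality:
  max_epochs: 60
  n_train_tokens: 500
  n_test_tokens: 300
compare:
  k: 8
  n_iter: 500
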