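# Shared shortcut: generate fixtures, split 80/20 and assemble the full
# descriptor matrices for both partitions.
fixture_feature_split <- function(n_pos, n_neg, signal, seed,
                                  train_fraction = 0.8) {
  fix <- generate_fixtures(fixture_config(n_pos, n_neg,
                                          signal_strength = signal,
                                          seed = seed))
  parts <- split_dataset(fix$dataset, train_fraction, seed = seed)
  list(train = assemble_features(parts$train, fix$ss, fix$pssm),
       test = assemble_features(parts$test, fix$ss, fix$pssm),
       fixtures = fix)
}
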