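# Shared smoke-scale study data: the 15 simulator cases, noise-augmented to
# 10 dB, decomposed and labeled once and cached for every test that needs
# them. Sizes (20 s records at 250 Hz, classifier input 1250, 5 epochs, one
# seed) are the package's reduced smoke configuration of the full protocol
# (60 s at 1000 Hz, 60 epochs, 3 seeds).
.smoke_cache <- new.env(parent = emptyenv())

smoke_fs <- 250
smoke_duration <- 20

smoke_cases <- function() {
  if (is.null(.smoke_cache$cases)) {
    .smoke_cache$cases <- lapply(1:15, function(cid) {
      rec <- synth_clean_aecg(table1_cases()[cid, ], smoke_duration, smoke_fs,
                              seed = 100 + cid)
      add_noise(rec, noise_spec(seed = 200 + cid))
    })
  }
  .smoke_cache$cases
}

smoke_dataset <- function() {
  if (is.null(.smoke_cache$dataset))
    .smoke_cache$dataset <- build_labeled_dataset(smoke_cases(),
                                                  eemd_config(seed = 11))
  .smoke_cache$dataset
}

smoke_spec <- function() classifier_spec(input_len = 1250L)

smoke_cv <- function() {
  if (is.null(.smoke_cache$cv))
    .smoke_cache$cv <- loso_cv(smoke_dataset(), smoke_spec(),
                               train_config(epochs = 5, seeds = 1L))
  .smoke_cache$cv
}
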