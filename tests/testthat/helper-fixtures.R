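# Shared fixtures, built once per test run and memoized.  The trained-model
# set is the expensive one (four SmallCNN training runs); everything that
# needs trained networks shares it.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

fixture_dataset <- function() {
  memo("dataset", function() {
    generate_image_dataset(K = 4, n_train = 50, n_test = 10, canvas = 64,
                           seed = 1)
  })
}

# clean-trained vs noise-trained twins (same init), plus the single-low-SSNR
# and clean+low-SSNR mixes used for the training-protocol contrasts
fixture_models <- function() {
  memo("models", function() {
    ds <- fixture_dataset()
    init <- small_cnn(4, seed = 11)
    cfg <- train_config(epochs = 20, augment = TRUE, seed = 2)
    list(
      clean = train_model(init, ds, noise_mix("clean", prop = 1), cfg),
      noise = train_model(init, ds,
                          noise_mix(c("clean", "gaussian"),
                                    lo = c(NA, 0.2), hi = c(NA, 0.99),
                                    prop = c(0.5, 0.5)), cfg),
      low_only = train_model(init, ds,
                             noise_mix("gaussian", lo = 0.2, hi = 0.2,
                                       prop = 1), cfg),
      mixed_low = train_model(init, ds,
                              noise_mix(c("clean", "gaussian"),
                                        lo = c(NA, 0.2), hi = c(NA, 0.2),
                                        prop = c(0.5, 0.5)), cfg))
  })
}

fixture_accuracy_curves <- function() {
  memo("curves", function() {
    ds <- fixture_dataset()
    te <- dataset_split(ds, "test")
    mods <- fixture_models()
    lapply(mods, function(m) {
      accuracy_by_ssnr(m, te$images, te$labels, "gaussian",
                       levels = seq(0.05, 1, by = 0.05), n_noise = 3,
                       seed = 9)
    })
  })
}

# tiny bias-free dense network assembled by hand, for relevance-propagation
# oracles: input 4 -> hidden 3 (relu) -> output 2
toy_dense_model <- function(seed = 5) {
  set.seed(seed)
  W1 <- matrix(rnorm(12), 4, 3)
  W2 <- matrix(rnorm(6), 3, 2)
  list(W1 = W1, W2 = W2)
}

clean_test_accuracy <- function(model, ds) {
  te <- dataset_split(ds, "test")
  mean(vapply(seq_along(te$images),
              function(i) predict_class(model, te$images[[i]]) ==
                te$labels[i], NA))
}
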