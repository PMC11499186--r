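# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small mixed cohort on a 24^3 grid.
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(cohort_config(n_healthy = 30, n_ms = 8,
                                  grid_shape = c(24, 24, 24), seed = 11))
  })
}

# Random-weight micro model matched to a micro input grid (no training
# needed for contract tests: determinism, shapes, gradients).
micro_model <- function(dims = c(12, 12, 12)) {
  fixture(paste0("micro_model_", paste(dims, collapse = "x")), function() {
    m <- build_model(model_spec(c(3, 4), post_block_filters = 5,
                                dropout_rate = 0), dims, seed = 7)
    # non-trivial running stats so inference-mode BN is exercised
    set.seed(8)
    m$params$bn_mean <- lapply(m$params$bn_mean,
                               function(v) v + rnorm(length(v), 0, 0.2))
    m$params$bn_var <- lapply(m$params$bn_var,
                              function(v) v * runif(length(v), 0.5, 2))
    class(m) <- c("trained_model", "bag_model")
    m
  })
}

# Noiseless phantom volumes whose only signal is age, plus a quick trained
# micro model on them (used by training/prediction/saliency tests).
trained_micro <- function() {
  fixture("trained_micro", function() {
    set.seed(21)
    ages <- runif(36, 20, 85)
    vols <- lapply(ages, function(a)
      phantom_intensity(phantom_labels(morphology_params(a), c(20, 20, 20)),
                        morphology_params(a)))
    vols <- lapply(vols, function(v) {
      x <- v
      m <- x != 0
      x[m] <- x[m] - mean(x[m])
      x
    })
    spec <- model_spec(c(4, 6), post_block_filters = 6)
    model <- build_model(spec, c(20, 20, 20), seed = 5)
    tm <- train_model(model, vols[1:28], ages[1:28], vols[29:36],
                      ages[29:36],
                      train_config(epochs = 15, learning_rate = 0.003,
                                   max_shift = 1, seed = 13))
    list(model = tm, vols = vols, ages = ages)
  })
}
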