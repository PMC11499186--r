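# Age model: architecture arithmetic, splitting, augmentation, the
# training loop's bookkeeping and determinism, prediction contracts, and a
# finite-difference oracle for the whole backward pass.

test_that("pooled grid and parameter count follow the layer arithmetic", {
  # five floor-halvings: 162->5, 198->6, 164->5
  expect_identical(pooled_shape(c(162, 198, 164), 5), c(5L, 6L, 5L))
  expect_identical(pooled_shape(c(32, 32, 32), 4), c(2L, 2L, 2L))

  # hand-computed parameter count for the default spec
  f <- c(32, 64, 128, 256, 256); cin <- c(1, f[-5])
  hand <- sum(27 * cin * f) + sum(f) + 2 * sum(f) +  # conv blocks + bn
    256 * 64 + 64 + 2 * 64 +                         # 1x1x1 block + bn
    64 + 1                                           # head
  expect_identical(n_parameters(model_spec()), as.integer(hand))
  # and for the tiny preset
  f <- c(8, 8, 16, 16); cin <- c(1, f[-4])
  hand <- sum(27 * cin * f) + 3 * sum(f) + 16 * 16 + 3 * 16 + 17
  expect_identical(n_parameters(model_preset("tiny")$spec), as.integer(hand))

  expect_error(model_spec(integer(0)), "conv block")
  expect_error(build_model(model_spec(c(4, 4, 4, 4, 4)), c(16, 16, 16)),
               "too small")
})

test_that("stratified split honors fractions with largest-remainder ties", {
  set.seed(1)
  # 10 balanced strata of 40 -> exactly 300/90/10
  rec <- data.frame(subject_id = sprintf("s%03d", 1:400),
                    age = rep(seq(22, 67, by = 5), each = 40),
                    sex = rep(c("M", "F"), 200))
  sp <- stratified_split(rec, seed = 3)
  counts <- table(sp$split)[c("train", "validation", "test")]
  expect_identical(as.integer(counts), c(300L, 90L, 10L))
  expect_setequal(sp$subject_id, rec$subject_id)
  expect_false(any(duplicated(sp$subject_id)))

  # determinism and seed sensitivity with identical per-stratum counts
  sp2 <- stratified_split(rec, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(rec, seed = 4)
  expect_false(identical(sp$split, sp3$split))
  expect_identical(table(sp$split), table(sp3$split))

  # a singleton stratum lands in the largest fraction (train)
  one <- data.frame(subject_id = "only", age = 33, sex = "F")
  expect_identical(stratified_split(one, seed = 1)$split, "train")

  expect_error(stratified_split(rec, fractions = c(a = 0.6, b = 0.3)),
               "sum to 1")
})

test_that("translation augmentation shifts, zero-fills and is uniform", {
  x <- array(rnorm(6^3), c(6, 6, 6))
  expect_identical(augment_translate(x, shift = c(0, 0, 0)), x)
  s <- augment_translate(x, shift = c(1, -2, 3))
  expect_equal(s[5, 2, 6], x[4, 4, 3])
  expect_true(all(s[1, , ] == 0))  # vacated plane

  # content away from the border is conserved
  y <- array(0, c(8, 8, 8)); y[4:5, 4:5, 4:5] <- 1
  expect_equal(sum(augment_translate(y, shift = c(2, -2, 1)) != 0),
               sum(y != 0))

  set.seed(9)
  draws <- replicate(10000, sample(seq(-5, 5), 3, replace = TRUE))
  freq <- table(factor(draws, levels = -5:5)) / length(draws)
  expect_true(all(abs(freq - 1 / 11) < 0.01))
})

test_that("backward pass matches finite differences everywhere", {
  set.seed(42)
  d <- c(8, 8, 8)
  m <- build_model(model_spec(c(2, 3), post_block_filters = 4,
                              dropout_rate = 0), d, seed = 3)
  N <- 2
  x <- matrix(rnorm(prod(d) * N), prod(d), N)
  tgt <- c(30, 55)
  dropmask <- matrix(1, 4, N)
  res <- cnn_train_batch(x, d, m$params, tgt, "mse", dropmask, 0)
  loss_at <- function(params)
    cnn_train_batch(x, d, params, tgt, "mse", dropmask, 0)$loss
  eps <- 1e-5
  worst <- 0
  probe <- function(nm, j = NULL) {
    p <- if (is.null(j)) m$params[[nm]] else m$params[[nm]][[j]]
    g <- if (is.null(j)) res$grads[[nm]] else res$grads[[nm]][[j]]
    for (i in sample(length(p), min(4, length(p)))) {
      pp <- m$params
      if (is.null(j)) pp[[nm]][i] <- p[i] + eps else pp[[nm]][[j]][i] <- p[i] + eps
      lp <- loss_at(pp)
      if (is.null(j)) pp[[nm]][i] <- p[i] - eps else pp[[nm]][[j]][i] <- p[i] - eps
      lm <- loss_at(pp)
      fd <- (lp - lm) / (2 * eps)
      worst <<- max(worst, abs(fd - g[i]) / max(1e-6, abs(fd) + abs(g[i])))
    }
  }
  for (j in 1:2) { probe("conv_W", j); probe("conv_b", j) }
  for (j in 1:3) { probe("bn_gamma", j); probe("bn_beta", j) }
  probe("proj_W"); probe("proj_b"); probe("head_w"); probe("head_b")
  expect_lt(worst, 1e-5)

  # input gradient (saliency path) against finite differences
  mm <- micro_model(d)
  ig <- cnn_infer(x, d, mm$params, TRUE)
  for (i in sample(prod(d), 4)) {
    xp <- x; xp[i, 1] <- xp[i, 1] + eps
    xm <- x; xm[i, 1] <- xm[i, 1] - eps
    fd <- (cnn_infer(xp, d, mm$params, FALSE)$pred[1] -
             cnn_infer(xm, d, mm$params, FALSE)$pred[1]) / (2 * eps)
    expect_equal(ig$input_grad[i, 1], fd, tolerance = 1e-4)
  }
})

test_that("training bookkeeping, checkpointing and determinism hold", {
  tm <- trained_micro()$model
  cfg <- tm$train_config
  expect_identical(nrow(tm$history), cfg$epochs)
  expect_equal(tm$best_val_mae, min(tm$history$val_mae))
  expect_identical(tm$epoch_of_best,
                   which.min(tm$history$val_mae))

  # beats the no-information baseline on the age-encoding phantoms
  fx <- trained_micro()
  baseline <- mean(abs(mean(fx$ages[1:28]) - fx$ages[29:36]))
  expect_lt(tm$best_val_mae, baseline)

  # checkpoint reload reproduces the recorded validation MAE
  path <- tempfile(fileext = ".rds")
  save_checkpoint(tm, path)
  back <- load_checkpoint(path)
  val_pred <- predict_ages(back, fx$vols[29:36])
  expect_equal(mean(abs(val_pred - fx$ages[29:36])), tm$best_val_mae,
               tolerance = 1e-4)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$best_val_mae, tm$best_val_mae, tolerance = 1e-12)
  unlink(c(path, paste0(path, ".json")))

  # identical seeds -> identical result; empty sets refused
  fx2 <- trained_micro()
  m0 <- build_model(tm$spec, tm$input_shape, seed = 5)
  re <- train_model(m0, fx2$vols[1:10], fx2$ages[1:10], fx2$vols[29:32],
                    fx2$ages[29:32],
                    train_config(epochs = 2, seed = 13, max_shift = 1))
  re2 <- train_model(m0, fx2$vols[1:10], fx2$ages[1:10], fx2$vols[29:32],
                     fx2$ages[29:32],
                     train_config(epochs = 2, seed = 13, max_shift = 1))
  expect_identical(re$best_val_mae, re2$best_val_mae)
  expect_identical(re$params, re2$params)
  expect_error(train_model(m0, list(), numeric(0), fx2$vols[1:2],
                           fx2$ages[1:2], train_config(epochs = 1)),
               "non-empty")
})

test_that("prediction is aligned, batch-invariant and deterministic", {
  fx <- trained_micro()
  tm <- fx$model
  vols <- fx$vols[29:36]
  rec <- predict_records(tm, vols,
                         data.frame(subject_id = sprintf("s%d", 1:8),
                                    age = fx$ages[29:36]))
  expect_identical(nrow(rec), 8L)
  expect_equal(rec$bag, rec$predicted_age - rec$age)

  single <- predict_ages(tm, vols[3])
  expect_equal(single, predict_ages(tm, vols)[3], tolerance = 1e-4)
  dup <- predict_ages(tm, list(vols[[1]], vols[[1]]))
  expect_identical(dup[1], dup[2])

  expect_error(predict_ages(tm, list(array(0, c(9, 9, 9)))), "shape")
})
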