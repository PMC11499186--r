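# 3D CNN age regressor: specification, initialization, stratified
# splitting, translation augmentation, Adam training with best-validation
# checkpointing, and inference. The numeric engine lives in src/cnn3d.cpp;
# everything random (init, shuffling, augmentation, dropout) is drawn on
# the R side from the configured seeds.

#' Model architecture specification
#'
#' The default mirrors the reference architecture: five
#' conv(3x3x3)-batchnorm-maxpool(2x2x2)-ReLU blocks with
#' 32/64/128/256/256 filters, a 1x1x1 conv-batchnorm-ReLU block with 64
#' filters, then global average pooling, dropout 0.5 and a linear head
#' emitting the scalar age.
#'
#' @param conv_block_filters integer vector, one entry per conv-pool block.
#' @param post_block_filters filters of the 1x1x1 block.
#' @param dropout_rate dropout fraction in `[0, 1)` before the head.
#' @return a `model_spec` object.
#' @export
model_spec <- function(conv_block_filters = c(32, 64, 128, 256, 256),
                       post_block_filters = 64,
                       dropout_rate = 0.5) {
  if (length(conv_block_filters) < 1) stop("need at least one conv block")
  if (any(conv_block_filters <= 0) || post_block_filters <= 0)
    stop("filter counts must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(conv_block_filters = as.integer(conv_block_filters),
                 post_block_filters = as.integer(post_block_filters),
                 dropout_rate = dropout_rate),
            class = "model_spec")
}

#' Training configuration
#'
#' Defaults are the reference protocol: 300 epochs, Adam with learning rate
#' 0.001, weight decay 0.0003 (decoupled, on conv/dense weights only),
#' batch size 8, translation augmentation of up to 5 voxels applied to 50%
#' of training samples, re-drawn every epoch. Loss is mean absolute error
#' (matching the MAE model-selection criterion); `"mse"` is available.
#'
#' @param epochs,learning_rate,weight_decay,batch_size optimizer settings.
#' @param augment_prob probability a training sample is shifted, per epoch.
#' @param max_shift maximum absolute translation per axis, voxels.
#' @param seed integer seed governing init, shuffling, dropout, shifts.
#' @param loss `"mae"` or `"mse"`.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 300, learning_rate = 0.001,
                         weight_decay = 0.0003, batch_size = 8,
                         augment_prob = 0.5, max_shift = 5,
                         seed = 1, loss = c("mae", "mse")) {
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0,
            batch_size >= 1, augment_prob >= 0, augment_prob <= 1,
            max_shift >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 augment_prob = augment_prob, max_shift = as.integer(max_shift),
                 seed = as.integer(seed), loss = match.arg(loss)),
            class = "train_config")
}

#' Desk-scale and full-scale presets
#'
#' `"tiny"` is the desk-scale protocol (32^3 grid, filters 8/8/16/16 with a
#' 16-filter 1x1x1 block, 40 epochs, max shift 2 voxels so shifted brains
#' stay in-frame on the small grid, and learning rate 0.003 -- chosen from
#' a convergence check on the small model; see the vignette); `"paper"` is
#' the full-scale default.
#'
#' @param name `"tiny"` or `"paper"`.
#' @return list with `spec` ([model_spec()]) and `train` ([train_config()]).
#' @export
model_preset <- function(name = c("tiny", "paper")) {
  name <- match.arg(name)
  if (name == "tiny")
    list(spec = model_spec(c(8, 8, 16, 16), post_block_filters = 16),
         train = train_config(epochs = 40, max_shift = 2,
                              learning_rate = 0.003))
  else
    list(spec = model_spec(), train = train_config())
}

#' Build (initialize) a model for a given input shape
#'
#' He-normal initialization for conv weights; batch-norm gamma/beta at 1/0;
#' the head bias is re-initialized to the mean training age by [train_model()].
#'
#' @param spec a [model_spec()].
#' @param input_shape integer length-3 voxel grid; every axis must be at
#'   least `2^length(conv_block_filters)` so all poolings are defined.
#' @param seed integer seed for the weight initialization.
#' @return a `bag_model` object (untrained).
#' @export
build_model <- function(spec, input_shape, seed = 1) {
  stopifnot(inherits(spec, "model_spec"), length(input_shape) == 3L)
  nb <- length(spec$conv_block_filters)
  if (any(input_shape < 2^nb))
    stop("input shape ", paste(input_shape, collapse = "x"),
         " too small for ", nb, " pooling layers (need >= ", 2^nb, " per axis)")
  set.seed(seed)
  f <- spec$conv_block_filters
  cin <- c(1L, f[-length(f)])
  params <- list(
    conv_W = lapply(seq_len(nb), function(b)
      matrix(rnorm(27 * cin[b] * f[b], 0, sqrt(2 / (27 * cin[b]))),
             27 * cin[b], f[b])),
    conv_b = lapply(f, function(k) numeric(k)),
    bn_gamma = lapply(c(f, spec$post_block_filters), function(k) rep(1, k)),
    bn_beta = lapply(c(f, spec$post_block_filters), function(k) numeric(k)),
    bn_mean = lapply(c(f, spec$post_block_filters), function(k) numeric(k)),
    bn_var = lapply(c(f, spec$post_block_filters), function(k) rep(1, k)),
    proj_W = matrix(rnorm(f[nb] * spec$post_block_filters, 0,
                          sqrt(2 / f[nb])), f[nb], spec$post_block_filters),
    proj_b = numeric(spec$post_block_filters),
    head_w = rnorm(spec$post_block_filters, 0,
                   sqrt(1 / spec$post_block_filters)),
    head_b = 0)
  structure(list(spec = spec, input_shape = as.integer(input_shape),
                 params = params),
            class = "bag_model")
}

#' Spatial grid entering the global average pool
#'
#' Each of the `B` conv-pool blocks floor-halves every axis.
#'
#' @param input_shape integer length-3.
#' @param n_blocks number of conv-pool blocks.
#' @return integer length-3.
#' @export
pooled_shape <- function(input_shape, n_blocks) {
  d <- as.integer(input_shape)
  for (i in seq_len(n_blocks)) d <- d %/% 2L
  d
}

#' Trainable parameter count, computed layer by layer
#'
#' @param spec a [model_spec()].
#' @return integer count (conv weights + biases, batch-norm gamma/beta,
#'   1x1x1 block, linear head; running statistics are not trainable).
#' @export
n_parameters <- function(spec) {
  f <- spec$conv_block_filters
  cin <- c(1L, f[-length(f)])
  conv <- sum(27 * cin * f + f + 2 * f)
  proj <- f[length(f)] * spec$post_block_filters + spec$post_block_filters +
    2 * spec$post_block_filters
  head <- spec$post_block_filters + 1
  as.integer(conv + proj + head)
}

#' Stratified train/validation/test split
#'
#' Subjects are stratified by (age bin x sex); within each stratum the
#' fractions are honored by largest-remainder rounding (ties go to the
#' larger fraction, so a singleton stratum lands in training) and the
#' stratum members are shuffled with the given seed before assignment.
#'
#' @param records data.frame with `subject_id`, `age`, `sex`.
#' @param fractions named numeric summing to 1 (default 75/22.5/2.5).
#' @param age_bin_width stratification bin width in years.
#' @param seed integer seed.
#' @return data.frame with `subject_id` and `split`.
#' @export
stratified_split <- function(records,
                             fractions = c(train = 0.75, validation = 0.225,
                                           test = 0.025),
                             age_bin_width = 10, seed = 1) {
  stopifnot(all(c("subject_id", "age", "sex") %in% names(records)))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  bins <- floor(records$age / age_bin_width)
  strata <- paste(bins, records$sex, sep = "/")
  set.seed(seed)
  out <- character(nrow(records))
  for (st in sort(unique(strata))) {
    idx <- which(strata == st)
    n_s <- length(idx)
    quota <- n_s * fractions
    base <- floor(quota)
    rem <- n_s - sum(base)
    if (rem > 0) {
      pri <- order(-(quota - base), -fractions)  # largest remainder, then fraction
      base[pri[seq_len(rem)]] <- base[pri[seq_len(rem)]] + 1
    }
    idx <- idx[sample.int(n_s)]
    out[idx] <- rep(names(fractions), base)
  }
  data.frame(subject_id = records$subject_id, split = out,
             stringsAsFactors = FALSE)
}

#' Integer translation augmentation
#'
#' Shifts the volume by an integer offset per axis (sampled uniformly from
#' `[-max_shift, max_shift]` when `shift` is not given); vacated voxels are
#' zero-filled.
#'
#' @param vol an [image_volume()] or 3D array.
#' @param max_shift maximum absolute shift per axis.
#' @param shift optional explicit integer length-3 shift.
#' @return shifted object of the same type.
#' @export
augment_translate <- function(vol, max_shift = 5, shift = NULL) {
  x <- if (inherits(vol, "image_volume")) vol$data else vol
  if (is.null(shift))
    shift <- sample(seq(-max_shift, max_shift), 3, replace = TRUE)
  shift <- as.integer(shift)
  d <- dim(x)
  out <- array(0, d)
  dst <- lapply(1:3, function(a) max(1, 1 + shift[a]):min(d[a], d[a] + shift[a]))
  src <- lapply(1:3, function(a) dst[[a]] - shift[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  if (inherits(vol, "image_volume"))
    image_volume(out, spacing = vol$spacing, space = vol$space)
  else out
}

vols_to_matrix <- function(vols) {
  get_arr <- function(v) if (inherits(v, "image_volume")) v$data else v
  d <- dim(get_arr(vols[[1]]))
  m <- matrix(0, prod(d), length(vols))
  for (i in seq_along(vols)) {
    a <- get_arr(vols[[i]])
    if (!identical(dim(a), d)) stop("volumes differ in shape")
    m[, i] <- as.numeric(a)
  }
  list(m = m, dims = d)
}

# Adam with decoupled weight decay over the nested parameter tree.
adam_tree <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8,
                      wd = 0) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_tree(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps, wd)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
  list(p = p, m = m, v = v)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

TRAINABLE <- c("conv_W", "conv_b", "bn_gamma", "bn_beta",
               "proj_W", "proj_b", "head_w", "head_b")
DECAYED <- c("conv_W", "proj_W", "head_w")

#' Train the age regressor
#'
#' Mini-batch Adam on preprocessed healthy volumes; per-epoch validation
#' MAE is recorded and the returned checkpoint is the epoch with the
#' minimum validation MAE. Fully reproducible given `cfg$seed`.
#'
#' @param model a [build_model()] result.
#' @param train_vols,val_vols lists of volumes (or 3D arrays) already
#'   rescaled and cropped; shapes must equal `model$input_shape`.
#' @param train_ages,val_ages numeric ages in years.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return a `trained_model`: best parameters, `history` (epoch,
#'   train_loss, val_mae), `best_val_mae`, `epoch_of_best`.
#' @export
train_model <- function(model, train_vols, train_ages, val_vols, val_ages,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "bag_model"), inherits(cfg, "train_config"))
  if (length(train_vols) == 0 || length(val_vols) == 0)
    stop("train and validation sets must be non-empty")
  stopifnot(length(train_vols) == length(train_ages),
            length(val_vols) == length(val_ages))
  tr <- vols_to_matrix(train_vols)
  va <- vols_to_matrix(val_vols)
  if (!identical(as.integer(tr$dims), model$input_shape))
    stop("training volume shape does not match model input shape")
  params <- model$params
  params$head_b <- mean(train_ages)  # start predictions at the prior mean

  set.seed(cfg$seed)
  n <- length(train_vols)
  C <- model$spec$post_block_filters
  state_m <- lapply(params[TRAINABLE], zeros_like)
  state_v <- lapply(params[TRAINABLE], zeros_like)
  t_step <- 0
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_mae = numeric())
  best <- list(mae = Inf, params = params, epoch = 0L)
  keep <- 1 - model$spec$dropout_rate

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- tr$m[, idx, drop = FALSE]
      if (cfg$max_shift > 0 && cfg$augment_prob > 0) {
        for (j in seq_along(idx)) {
          if (runif(1) < cfg$augment_prob) {
            arr <- array(xb[, j], tr$dims)
            xb[, j] <- as.numeric(augment_translate(arr, cfg$max_shift))
          }
        }
      }
      dropmask <- if (keep < 1)
        matrix(rbinom(C * length(idx), 1, keep) / keep, C, length(idx))
      else matrix(1, C, length(idx))
      res <- cnn_train_batch(xb, model$input_shape, params,
                             train_ages[idx], cfg$loss, dropmask, 0.1)
      params$bn_mean <- res$bn_mean
      params$bn_var <- res$bn_var
      t_step <- t_step + 1
      for (nm in TRAINABLE) {
        r <- adam_tree(params[[nm]], res$grads[[nm]], state_m[[nm]],
                       state_v[[nm]], cfg$learning_rate, t_step,
                       wd = if (nm %in% DECAYED) cfg$weight_decay else 0)
        params[[nm]] <- r$p; state_m[[nm]] <- r$m; state_v[[nm]] <- r$v
      }
      ep_loss <- ep_loss + res$loss
      nb <- nb + 1
    }
    val_pred <- infer_matrix(va$m, model$input_shape, params)
    val_mae <- mean(abs(val_pred - val_ages))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_mae = val_mae))
    if (val_mae < best$mae)
      best <- list(mae = val_mae, params = params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train_loss %.3f  val_mae %.3f%s",
                      epoch, ep_loss / nb, val_mae,
                      if (best$epoch == epoch) " *" else ""))
  }
  structure(list(spec = model$spec, input_shape = model$input_shape,
                 params = best$params, train_config = cfg,
                 history = history, best_val_mae = best$mae,
                 epoch_of_best = best$epoch),
            class = c("trained_model", "bag_model"))
}

infer_matrix <- function(m, dims, params, batch_size = 32) {
  n <- ncol(m)
  pred <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    pred[idx] <- cnn_infer(m[, idx, drop = FALSE], dims, params,
                           input_grad = FALSE)$pred
  }
  pred
}

#' Predict ages for a set of volumes
#'
#' Inference mode: dropout off, batch-norm on running statistics, so
#' predictions are deterministic and independent of batch composition.
#'
#' @param model a `trained_model` (or any `bag_model`).
#' @param vols list of volumes preprocessed like the training inputs.
#' @return numeric vector of predicted ages, input order preserved.
#' @export
predict_ages <- function(model, vols) {
  stopifnot(inherits(model, "bag_model"))
  x <- vols_to_matrix(vols)
  if (!identical(as.integer(x$dims), model$input_shape))
    stop("volume shape ", paste(x$dims, collapse = "x"),
         " does not match model input shape ",
         paste(model$input_shape, collapse = "x"))
  infer_matrix(x$m, model$input_shape, model$params)
}

#' Build per-subject prediction records with the brain age gap
#'
#' @param model a `trained_model`.
#' @param vols list of preprocessed volumes.
#' @param manifest data.frame with `subject_id` and `age` aligned to `vols`.
#' @return data.frame with `subject_id`, `age`, `predicted_age`, `bag`.
#' @export
predict_records <- function(model, vols, manifest) {
  stopifnot(nrow(manifest) == length(vols))
  pred <- predict_ages(model, vols)
  data.frame(subject_id = manifest$subject_id, age = manifest$age,
             predicted_age = pred, bag = bag(pred, manifest$age),
             stringsAsFactors = FALSE)
}

#' Save / load a trained model checkpoint
#'
#' Weights go to `path`; architecture, training configuration and training
#' summary go to a human-readable JSON sidecar `<path>.json`.
#'
#' @param model a `trained_model`.
#' @param path checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "bag_model"))
  saveRDS(model, path)
  meta <- list(conv_block_filters = model$spec$conv_block_filters,
               post_block_filters = model$spec$post_block_filters,
               dropout_rate = model$spec$dropout_rate,
               input_shape = model$input_shape,
               best_val_mae = model$best_val_mae,
               epoch_of_best = model$epoch_of_best,
               train_config = unclass(model$train_config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
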