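# Orchestration: a single structured configuration drives the six stages
# (generate -> preprocess -> split/train -> predict -> stats -> saliency).
# `run_study()` is the in-memory engine; `run_pipeline()` adds file I/O and
# a JSON run manifest. Per-stage seeds are derived from the global seed by
# fixed offsets so stages can be re-run independently.

PIPELINE_STAGES <- c("generate", "preprocess", "train", "predict",
                     "stats", "saliency")

stage_seed <- function(seed, stage) {
  offs <- c(generate = 11L, split = 23L, train = 37L, saliency = 53L,
            groups = 71L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Study configuration
#'
#' Bundles all stage configurations. The `"tiny"` preset is the desk-scale
#' protocol: 300 healthy phantoms (ages 20-89), 60 disease phantoms (ages
#' 20-60) with a brain-age offset drawn from Normal(8, 2) truncated at
#' zero, a 32^3 grid, filters 8/8/16/16, 40 epochs, and sex-balanced
#' saliency groups of 5 per sex. The `"paper"` preset carries the
#' full-scale architecture and training defaults.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param seed global integer seed; stage seeds are derived from it.
#' @param ... named overrides for individual sections (`phantom`, `split`,
#'   `model`, `train`, `stats`, `saliency`): each a list of fields to
#'   replace.
#' @return a `study_config` list.
#' @export
study_config <- function(preset = c("tiny", "paper"), seed = 1, ...) {
  preset <- match.arg(preset)
  mp <- model_preset(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    phantom = list(n_healthy = if (preset == "tiny") 300 else 5294,
                   n_ms = if (preset == "tiny") 60 else 195,
                   age_range = c(20, 89), ms_age_range = c(20, 60),
                   grid_shape = if (preset == "tiny") c(32, 32, 32)
                                else c(182, 218, 182),
                   ms_offset_mean = 8, ms_offset_sd = 2, noise_sd = 7),
    preprocess = list(scale_unit_sd = FALSE),
    split = list(fractions = c(train = 0.75, validation = 0.225,
                               test = 0.025),
                 age_bin_width = 10),
    model = list(conv_block_filters = mp$spec$conv_block_filters,
                 post_block_filters = mp$spec$post_block_filters,
                 dropout_rate = mp$spec$dropout_rate),
    train = unclass(mp$train),
    stats = list(alpha = 0.05, comparison_age_range = NULL),
    saliency = list(n_samples = 25, noise_fraction = 0.10, threshold_pct = 5,
                    threshold_mode = "range",
                    n_per_sex = if (preset == "tiny") 5 else NULL))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "study_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

band_counts <- function(manifest, cohort, band) {
  rng <- AGE_BANDS[[band]]
  pool <- manifest[manifest$cohort == cohort & manifest$age >= rng[1] &
                     manifest$age < rng[2], ]
  c(M = sum(pool$sex == "M"), F = sum(pool$sex == "F"))
}

#' Run the full brain-age-gap study in memory
#'
#' Executes generate -> preprocess (zero-mean rescale, population crop with
#' bounds frozen on the healthy training split) -> stratified split ->
#' train -> predict -> BAG statistics -> saliency analysis, and returns all
#' intermediate objects. Deterministic given the configuration.
#'
#' Saliency maps are computed for held-out healthy subjects
#' (validation + test) and all disease subjects; group-averaged band maps
#' additionally draw healthy members from the whole healthy cohort so that
#' small cohorts can fill sex-balanced bands. If a band cannot supply the
#' configured members per sex, the band uses the largest balanced size
#' available (minimum 2 per sex).
#'
#' @param cfg a [study_config()].
#' @param verbose print progress.
#' @param upto last stage to execute (`"generate"`, `"preprocess"`,
#'   `"train"`, `"predict"`, `"stats"` or `"saliency"`); later components
#'   of the result are absent.
#' @return a `bag_study` list; see the vignette for the components.
#' @export
run_study <- function(cfg, verbose = FALSE, upto = "saliency") {
  stopifnot(inherits(cfg, "study_config"))
  upto_n <- match(match.arg(upto, PIPELINE_STAGES), PIPELINE_STAGES)
  say <- function(...) if (verbose) message(sprintf(...))
  partial <- function(...) {
    structure(c(list(config = cfg), list(...)), class = "bag_study")
  }

  # -- generate ---------------------------------------------------------
  pcfg <- do.call(cohort_config, c(cfg$phantom,
                                   list(seed = stage_seed(cfg$seed, "generate"))))
  say("generating %d + %d phantoms on a %s grid",
      pcfg$n_healthy, pcfg$n_ms, paste(pcfg$grid_shape, collapse = "x"))
  ds <- generate_cohort(pcfg)
  excl <- apply_exclusions(ds$manifest, character())
  manifest <- excl$manifest
  if (upto_n < 2) return(partial(dataset = ds, manifest = manifest))

  # -- split ------------------------------------------------------------
  healthy <- manifest[manifest$cohort == "healthy", ]
  split <- stratified_split(healthy, fractions = cfg$split$fractions,
                            age_bin_width = cfg$split$age_bin_width,
                            seed = stage_seed(cfg$seed, "split"))
  manifest$split <- split$split[match(manifest$subject_id, split$subject_id)]
  manifest$split[manifest$cohort == "MS"] <- "ms"

  # -- preprocess -------------------------------------------------------
  say("preprocessing (zero-mean rescale + population crop)")
  vols <- lapply(ds$volumes, rescale_zero_mean,
                 scale_unit_sd = isTRUE(cfg$preprocess$scale_unit_sd))
  train_idx <- which(manifest$split == "train")
  bounds <- population_crop(vols[train_idx])$bounds
  vols <- population_crop(vols, bounds = bounds)$volumes
  parc_grid <- ds$parcellation$label_grid[
    (bounds$low[1] + 1):bounds$high[1], (bounds$low[2] + 1):bounds$high[2],
    (bounds$low[3] + 1):bounds$high[3], drop = FALSE]
  parc <- parcellation(parc_grid, ds$parcellation$regions)
  if (upto_n < 3)
    return(partial(dataset = ds, manifest = manifest, split = split,
                   bounds = bounds, parcellation = parc, volumes = vols))

  # -- train ------------------------------------------------------------
  spec <- model_spec(cfg$model$conv_block_filters,
                     cfg$model$post_block_filters, cfg$model$dropout_rate)
  tcfg <- do.call(train_config,
                  c(cfg$train[setdiff(names(cfg$train), "seed")],
                    list(seed = stage_seed(cfg$seed, "train"))))
  input_shape <- dim(vols[[1]]$data)
  model <- build_model(spec, input_shape,
                       seed = stage_seed(cfg$seed, "train"))
  vi <- which(manifest$split == "validation")
  say("training %d epochs on %d subjects (%d validation)",
      tcfg$epochs, length(train_idx), length(vi))
  model <- train_model(model, vols[train_idx], manifest$age[train_idx],
                       vols[vi], manifest$age[vi], tcfg, verbose = verbose)
  say("best validation MAE %.2f y at epoch %d", model$best_val_mae,
      model$epoch_of_best)
  if (upto_n < 4)
    return(partial(dataset = ds, manifest = manifest, split = split,
                   bounds = bounds, parcellation = parc, volumes = vols,
                   model = model))

  # -- predict ----------------------------------------------------------
  eval_idx <- which(manifest$split %in% c("validation", "test", "ms"))
  predictions <- predict_records(model, vols[eval_idx],
                                 manifest[eval_idx, ])
  predictions$cohort <- manifest$cohort[eval_idx]
  predictions$split <- manifest$split[eval_idx]
  if (upto_n < 5)
    return(partial(dataset = ds, manifest = manifest, split = split,
                   bounds = bounds, parcellation = parc, volumes = vols,
                   model = model, predictions = predictions))

  # -- stats ------------------------------------------------------------
  test_rec <- predictions[predictions$split == "test", ]
  ms_rec <- predictions[predictions$split == "ms", ]
  stats_out <- list(
    healthy_test = list(mae = mae(test_rec), bag = mean_bag(test_rec),
                        n = nrow(test_rec)),
    ms = list(mae = mae(ms_rec), bag = mean_bag(ms_rec), n = nrow(ms_rec)),
    ms_vs_healthy = mann_whitney_u(ms_rec$bag, test_rec$bag,
                                   mode = "normal_approx"),
    bland_altman_healthy = bland_altman(test_rec),
    bland_altman_ms = bland_altman(ms_rec))
  ms_manifest <- merge(ms_rec, manifest, by = c("subject_id", "age"))
  if (nrow(ms_manifest) >= 8 && any(ms_manifest$bag < 0) &&
      any(ms_manifest$bag >= 0)) {
    stats_out$clinical <- compare_groups(
      ms_manifest, ms_manifest$bag < 0,
      variables = c("age", "age_at_onset", "edss", "disease_duration",
                    "lesion_volume", "bpf"),
      covariate_sets = list(age_at_onset = "sex", age = "sex"))
  }
  if (upto_n < 6)
    return(partial(dataset = ds, manifest = manifest, split = split,
                   bounds = bounds, parcellation = parc, volumes = vols,
                   model = model, predictions = predictions,
                   stats = stats_out))

  # -- saliency ---------------------------------------------------------
  # Maps are computed for (a) held-out healthy + all disease subjects (the
  # localization and score analyses), (b) every healthy subject inside the
  # disease chronological-age window (the regional score comparison, which
  # mirrors the reference protocol's restriction of the healthy group to
  # the patients' age range), and (c) healthy subjects needed to fill the
  # group-averaged age bands.
  scfg <- cfg$saliency
  scope <- scfg$scope %||% "full"
  cmp_range <- cfg$stats$comparison_age_range %||% cfg$phantom$ms_age_range
  healthy_cmp <- manifest$cohort == "healthy" &
    manifest$age >= cmp_range[1] & manifest$age < cmp_range[2]
  band_need <- manifest$cohort == "healthy" &
    manifest$age < max(vapply(AGE_BANDS, `[`, 0, 2))
  sal_idx <- if (scope == "bands")
    which(band_need | manifest$split == "ms")  # group-map analysis only
  else
    which(manifest$split %in% c("validation", "test", "ms") |
            healthy_cmp | band_need)
  say("saliency for %d subjects", length(sal_idx))
  sal <- saliency_pipeline(model, vols[sal_idx], manifest[sal_idx, ], parc,
                           n_samples = scfg$n_samples,
                           noise_fraction = scfg$noise_fraction,
                           threshold_pct = scfg$threshold_pct,
                           threshold_mode = scfg$threshold_mode %||% "range",
                           subject_seeds =
                             stage_seed(cfg$seed, "saliency") + sal_idx)
  heldout_h <- manifest$subject_id[manifest$split %in% c("validation", "test")]
  ms_ids <- manifest$subject_id[manifest$split == "ms"]
  region_comparison <- NULL
  vent_rank <- NULL
  if (scope == "full") {
    region_comparison <- compare_region_scores(
      sal$scores[manifest$subject_id[healthy_cmp]],
      sal$scores[ms_ids], alpha = cfg$stats$alpha)
    # ventricle localization: best lateral-ventricle rank per held-out map
    vent_rank <- vapply(sal$scores[heldout_h], function(tb) {
      ord <- order(-tb$weighted_score)
      min(match(c(1L, 2L), tb$region_id[ord]))
    }, 0)
  }

  say("group-averaged band maps")
  group_maps <- list()
  for (co in c("healthy", "MS")) for (b in names(AGE_BANDS)) {
    have <- band_counts(manifest[manifest$subject_id %in% names(sal$maps), ],
                        co, b)
    nps <- scfg$n_per_sex %||% if (b == "<30") 5L else 10L
    nps <- min(nps, have)
    if (nps < 2) next  # band not fillable in this cohort
    group_maps[[paste(co, b)]] <-
      group_average_map(sal$maps, manifest, co, b,
                        seed = stage_seed(cfg$seed, "groups"),
                        n_per_sex = nps)
  }
  dice_table <- NULL
  ms_bands <- grep("^MS ", names(group_maps), value = TRUE)
  h_bands <- grep("^healthy ", names(group_maps), value = TRUE)
  if (length(ms_bands) && length(h_bands)) {
    dice_table <- expand.grid(ms_band = sub("^MS ", "", ms_bands),
                              healthy_band = sub("^healthy ", "", h_bands),
                              stringsAsFactors = FALSE)
    dice_table$dice <- mapply(function(mb, hb)
      dice(group_maps[[paste("MS", mb)]], group_maps[[paste("healthy", hb)]]),
      dice_table$ms_band, dice_table$healthy_band)
  }

  structure(list(config = cfg, dataset = ds, manifest = manifest,
                 split = split, bounds = bounds, parcellation = parc,
                 volumes = vols, model = model, predictions = predictions,
                 stats = stats_out, saliency = sal,
                 region_comparison = region_comparison,
                 ventricle_rank = vent_rank, group_maps = group_maps,
                 dice_table = dice_table),
            class = "bag_study")
}

#' @export
print.bag_study <- function(x, ...) {
  if (is.null(x$stats)) {
    cat(sprintf("<bag_study preset=%s seed=%d (partial run)>\n",
                x$config$preset, x$config$seed))
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "<bag_study preset=%s seed=%d>\n",
    "  healthy test: MAE %.2f y, mean BAG %.2f (SD %.2f), n=%d\n",
    "  disease:      MAE %.2f y, mean BAG %.2f (SD %.2f), n=%d\n",
    "  MS vs healthy BAG Mann-Whitney p = %.3g\n"),
    x$config$preset, x$config$seed,
    x$stats$healthy_test$mae, x$stats$healthy_test$bag$mean,
    x$stats$healthy_test$bag$sd, x$stats$healthy_test$n,
    x$stats$ms$mae, x$stats$ms$bag$mean, x$stats$ms$bag$sd, x$stats$ms$n,
    x$stats$ms_vs_healthy$p_value))
  invisible(x)
}

#' Run the pipeline with file outputs and a run manifest
#'
#' Executes the requested stages of [run_study()] and writes the standard
#' artifacts (dataset, split/bounds, checkpoint + history, predictions,
#' statistics tables, saliency scores/comparison/Dice tables) under
#' `out_dir`, plus `run_manifest.json` with the config hash, seeds, output
#' paths and summary metrics. Because later stages consume in-memory
#' results, requesting a later stage without its predecessors requires the
#' predecessors' outputs to exist from a previous run with identical
#' configuration; otherwise a dependency error is raised.
#'
#' @param cfg a [study_config()] or path to a JSON file of one.
#' @param out_dir output directory.
#' @param stages subset of `c("generate", "preprocess", "train",
#'   "predict", "stats", "saliency")` (contiguous from the start, or the
#'   full run's artifacts must already exist).
#' @param verbose print progress.
#' @return invisibly, the run manifest list.
#' @export
run_pipeline <- function(cfg, out_dir, stages = PIPELINE_STAGES,
                         verbose = FALSE) {
  if (is.character(cfg)) {
    if (!file.exists(cfg)) stop("missing config file: ", cfg)
    raw <- jsonlite::read_json(cfg, simplifyVector = TRUE)
    if (!is.null(raw$split$fractions)) {
      fr <- unlist(raw$split$fractions)
      if (is.null(names(fr)) && length(fr) == 3)
        names(fr) <- c("train", "validation", "test")  # JSON drops names
      raw$split$fractions <- fr
    }
    sections <- intersect(names(raw),
                          c("phantom", "preprocess", "split", "model",
                            "train", "stats", "saliency"))
    cfg <- do.call(study_config,
                   c(list(preset = raw$preset %||% "tiny",
                          seed = raw$seed %||% 1),
                     raw[sections]))
  }
  stopifnot(inherits(cfg, "study_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  # stage dependency check against prior artifacts
  need_before <- setdiff(PIPELINE_STAGES[seq_len(match(stages[1],
                                                       PIPELINE_STAGES)) - 1],
                         stages)
  if (length(need_before) > 0 &&
      !file.exists(file.path(out_dir, "run_manifest.json")))
    stop("stage dependency unmet: missing artifacts of earlier stages (",
         paste(need_before, collapse = ", "), ") under ", out_dir)

  # the engine always runs from the top (cheap at desk scale,
  # deterministic) but stops after the last requested stage; stage
  # selection controls which artifacts are (re)written.
  study <- run_study(cfg, verbose = verbose,
                     upto = stages[length(stages)])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  wtsv <- function(df, f) {
    utils::write.table(df, file.path(out_dir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    outputs[[f]] <<- f
  }

  if ("generate" %in% stages) {
    write_dataset(study$dataset, file.path(out_dir, "dataset"), force = TRUE)
    outputs[["dataset"]] <- "dataset/manifest.tsv"
  }
  if ("preprocess" %in% stages) {
    wtsv(study$manifest, "manifest.tsv")
    wtsv(study$split, "split.tsv")
    write_crop_bounds(study$bounds, file.path(out_dir, "crop_bounds.json"))
    outputs[["crop_bounds"]] <- "crop_bounds.json"
  }
  if ("train" %in% stages) {
    save_checkpoint(study$model, file.path(out_dir, "checkpoint.rds"))
    outputs[["checkpoint"]] <- "checkpoint.rds"
    wtsv(study$model$history, "history.tsv")
  }
  if ("predict" %in% stages) wtsv(study$predictions, "predictions.tsv")
  if ("stats" %in% stages) {
    s <- study$stats
    summary <- list(
      healthy_test = list(mae = s$healthy_test$mae,
                          mean_bag = s$healthy_test$bag$mean,
                          sd_bag = s$healthy_test$bag$sd,
                          n = s$healthy_test$n),
      ms = list(mae = s$ms$mae, mean_bag = s$ms$bag$mean,
                sd_bag = s$ms$bag$sd, n = s$ms$n),
      ms_vs_healthy_p = s$ms_vs_healthy$p_value,
      bland_altman_healthy = s$bland_altman_healthy[
        c("mean_diff", "sd_diff", "lower_limit", "upper_limit")],
      bland_altman_ms = s$bland_altman_ms[
        c("mean_diff", "sd_diff", "lower_limit", "upper_limit")])
    jsonlite::write_json(summary, file.path(out_dir, "stats_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs[["stats_summary"]] <- "stats_summary.json"
    if (!is.null(s$clinical)) {
      wtsv(s$clinical$group_table, "clinical_group_table.tsv")
      wtsv(s$clinical$correlation_table, "clinical_correlation_table.tsv")
    }
  }
  if ("saliency" %in% stages) {
    scores_long <- do.call(rbind, lapply(names(study$saliency$scores),
                                         function(id) {
      tb <- study$saliency$scores[[id]]
      tb$subject_id <- id
      tb
    }))
    wtsv(scores_long, "region_scores.tsv")
    if (!is.null(study$region_comparison))
      wtsv(study$region_comparison, "region_comparison.tsv")
    if (!is.null(study$dice_table)) wtsv(study$dice_table, "dice.tsv")
    jsonlite::write_json(lapply(study$group_maps, function(g)
      list(cohort = g$cohort, age_band = g$age_band,
           member_ids = g$member_ids)),
      file.path(out_dir, "group_members.json"), auto_unbox = TRUE)
    outputs[["group_members"]] <- "group_members.json"
  }

  run_manifest <- list(
    config_hash = config_hash(study$config),
    seed = study$config$seed,
    stage_seeds = list(generate = stage_seed(cfg$seed, "generate"),
                       split = stage_seed(cfg$seed, "split"),
                       train = stage_seed(cfg$seed, "train"),
                       saliency = stage_seed(cfg$seed, "saliency")),
    stages = stages, outputs = outputs,
    metrics = Filter(Negate(is.null),
                     list(best_val_mae = study$model$best_val_mae,
                          healthy_test_mean_bag =
                            study$stats$healthy_test$bag$mean,
                          ms_mean_bag = study$stats$ms$bag$mean)))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run_manifest)
}

# NULL-or-empty fallback (JSON round trips turn NULL into empty lists)
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
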