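# SmoothGrad saliency and regional saliency scoring: noise-averaged input
# gradients, [0, 255] linear mapping, bottom-percentile denoising, weighted
# regional saliency scores against a parcellation, sex-balanced group
# averaging with binarization, Dice overlap, and the per-region group
# comparison with Bonferroni correction.

#' SmoothGrad saliency map
#'
#' Mean over `n_samples` of the absolute input gradient
#' `|d(predicted age)/d(voxel)|`, each evaluated at the volume plus i.i.d.
#' Gaussian noise with sd `noise_fraction * (max - min)` of the volume.
#' Deterministic given `seed`. `n_samples = 1, noise_fraction = 0` is the
#' plain gradient-magnitude map.
#'
#' @param model a `trained_model`; inference mode is used.
#' @param vol volume preprocessed identically to the training inputs.
#' @param n_samples number of noisy draws (>= 1; default 25).
#' @param noise_fraction noise sd as a fraction of the intensity range
#'   (default 0.10).
#' @param seed integer seed.
#' @param subject_id optional id carried in the result.
#' @return a `saliency_map`: non-negative 3D `data` plus provenance fields.
#' @export
smoothgrad <- function(model, vol, n_samples = 25, noise_fraction = 0.10,
                       seed = 1, subject_id = NA_character_) {
  stopifnot(inherits(model, "bag_model"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  x <- if (inherits(vol, "image_volume")) vol$data else vol
  d <- dim(x)
  if (!identical(as.integer(d), model$input_shape))
    stop("volume shape does not match model input shape")
  set.seed(seed)
  sigma <- noise_fraction * (max(x) - min(x))
  v0 <- as.numeric(x)
  acc <- numeric(length(v0))
  batch <- 8L
  done <- 0L
  while (done < n_samples) {
    nb <- min(batch, n_samples - done)
    xb <- matrix(v0, length(v0), nb)
    if (sigma > 0)
      xb <- xb + matrix(rnorm(length(v0) * nb, 0, sigma), length(v0), nb)
    res <- cnn_infer(xb, model$input_shape, model$params, input_grad = TRUE)
    acc <- acc + rowSums(abs(res$input_grad))
    done <- done + nb
  }
  structure(list(data = array(acc / n_samples, d), subject_id = subject_id,
                 n_samples = as.integer(n_samples),
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "saliency_map")
}

map_data <- function(map) {
  if (inherits(map, c("saliency_map", "group_map"))) map$data else map
}

with_map_data <- function(map, data) {
  if (inherits(map, "saliency_map")) { map$data <- data; map } else data
}

#' Linear [0, 255] intensity mapping
#'
#' Affine map sending the minimum to 0 and the maximum to 255; a constant
#' map becomes all zeros (degenerate-case rule). Invariant under positive
#' affine transforms of the input.
#'
#' @param map a `saliency_map` or 3D array.
#' @return same type, values in `[0, 255]`.
#' @export
rescale_0_255 <- function(map) {
  x <- map_data(map)
  rng <- range(x)
  y <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) * 255 else x * 0
  with_map_data(map, y)
}

#' Threshold out the lowest saliency values
#'
#' Removes the "bottom `pct`%" of a (non-negative) saliency map. Two
#' readings of that rule are implemented:
#' \describe{
#'   \item{`"range"` (default)}{voxels below `pct`% of the intensity range
#'     (e.g. below 12.75 on a `[0, 255]` map) are set to 0. Gradient maps
#'     are heavy-tailed, so this removes the large mass of near-zero
#'     voxels and leaves the sparse salient support that group-level
#'     overlap analysis needs; dense maps would otherwise binarize to the
#'     whole brain and saturate every Dice comparison (see the vignette).}
#'   \item{`"percentile"`}{voxels at or below the `pct`-th percentile of
#'     the positive voxel values are set to 0 (exactly the `pct`% lowest
#'     positive voxels for an all-distinct map).}
#' }
#' Both are invariant under positive rescaling of the map. `pct = 0` keeps
#' all positive voxels, `pct = 100` clears the map.
#'
#' @param map a `saliency_map` or 3D array.
#' @param pct percentage in `[0, 100]` (default 5).
#' @param mode `"range"` or `"percentile"`.
#' @return same type, denoised.
#' @export
denoise_threshold <- function(map, pct = 5, mode = c("range", "percentile")) {
  if (pct < 0 || pct > 100) stop("pct must be in [0, 100]")
  mode <- match.arg(mode)
  x <- map_data(map)
  pos <- x[x > 0]
  if (length(pos) == 0) return(map)
  if (pct == 0) return(with_map_data(map, x))
  if (pct == 100) return(with_map_data(map, x * 0))
  if (mode == "range") {
    rng <- range(x)
    thr <- rng[1] + pct / 100 * (rng[2] - rng[1])
    x[x < thr] <- 0
  } else {
    thr <- stats::quantile(pos, pct / 100, type = 7, names = FALSE)
    x[x <= thr] <- 0
  }
  with_map_data(map, x)
}

#' Weighted regional saliency scores
#'
#' Per region: `coverage_pct` = percentage of voxels in the region with
#' non-zero saliency; `mean_intensity` = mean saliency over the region;
#' `weight` = min-max scaling of the region means to `[0, 1]`;
#' `weighted_score = coverage_pct * weight`. If all region means are equal
#' the min-max scaling is degenerate and every weight is set to 1 (so
#' coverage information is preserved). Scores are invariant to positive
#' rescaling of the map.
#'
#' @param map a `saliency_map` or 3D array (typically already denoised).
#' @param parc a [parcellation()] on the same grid.
#' @return data.frame: `region_id`, `name`, `coverage_pct`,
#'   `mean_intensity`, `weight`, `weighted_score`.
#' @export
region_scores <- function(map, parc) {
  stopifnot(inherits(parc, "parcellation"))
  x <- map_data(map)
  if (!identical(dim(x), dim(parc$label_grid)))
    stop("map shape does not match parcellation shape")
  if (nrow(parc$regions) < 2) stop("need >= 2 regions for min-max weighting")
  ids <- parc$regions$region_id
  cov <- numeric(length(ids)); mi <- numeric(length(ids))
  for (i in seq_along(ids)) {
    vox <- x[parc$label_grid == ids[i]]
    if (length(vox) == 0)
      stop("region has no voxels in the label grid: ", parc$regions$name[i])
    cov[i] <- 100 * mean(vox != 0)
    mi[i] <- mean(vox)
  }
  rng <- range(mi)
  w <- if (rng[2] > rng[1]) (mi - rng[1]) / (rng[2] - rng[1]) else rep(1, length(mi))
  data.frame(region_id = ids, name = parc$regions$name, coverage_pct = cov,
             mean_intensity = mi, weight = w, weighted_score = cov * w,
             stringsAsFactors = FALSE)
}

# Age bands used for group-averaged maps.
AGE_BANDS <- list("<30" = c(-Inf, 30), "30-39" = c(30, 40),
                  "40-49" = c(40, 50), "50-59" = c(50, 60))

age_band_of <- function(age) {
  for (nm in names(AGE_BANDS))
    if (age >= AGE_BANDS[[nm]][1] && age < AGE_BANDS[[nm]][2]) return(nm)
  NA_character_
}

#' Sex-balanced group-averaged binary saliency map
#'
#' Draws a sex-balanced random sample of subjects of one cohort within one
#' age band (default: 10 per sex, except 5 per sex for the `<30` band),
#' averages their (thresholded) saliency maps voxel-wise, and binarizes the
#' average (any non-zero voxel becomes 1).
#'
#' @param maps named list of `saliency_map`s (names = subject ids) or a
#'   list alongside `manifest` row order.
#' @param manifest data.frame with `subject_id`, `age`, `sex`, `cohort`.
#' @param cohort cohort to sample from.
#' @param age_band one of `"<30"`, `"30-39"`, `"40-49"`, `"50-59"`.
#' @param seed integer seed for the member draw.
#' @param n_per_sex members per sex; `NULL` uses the defaults above.
#' @return a `group_map`: binary `data`, `member_ids`, `cohort`,
#'   `age_band`, `sex_composition`.
#' @export
group_average_map <- function(maps, manifest, cohort, age_band, seed = 1,
                              n_per_sex = NULL) {
  if (!age_band %in% names(AGE_BANDS)) stop("unknown age band: ", age_band)
  if (is.null(n_per_sex)) n_per_sex <- if (age_band == "<30") 5L else 10L
  if (is.null(names(maps))) names(maps) <- manifest$subject_id
  rng <- AGE_BANDS[[age_band]]
  pool <- manifest[manifest$cohort == cohort & manifest$age >= rng[1] &
                     manifest$age < rng[2], , drop = FALSE]
  set.seed(seed)
  members <- character(0)
  for (sx in c("M", "F")) {
    ids <- pool$subject_id[pool$sex == sx]
    ids <- intersect(ids, names(maps))
    if (length(ids) < n_per_sex)
      stop(sprintf("insufficient %s subjects in %s band %s: have %d, need %d",
                   sx, cohort, age_band, length(ids), n_per_sex))
    members <- c(members, sample(ids, n_per_sex))
  }
  d <- dim(map_data(maps[[members[1]]]))
  acc <- array(0, d)
  for (id in members) acc <- acc + map_data(maps[[id]])
  avg <- acc / length(members)
  structure(list(data = array(as.integer(avg > 0), d), cohort = cohort,
                 age_band = age_band, member_ids = members,
                 sex_composition = c(M = n_per_sex, F = n_per_sex)),
            class = "group_map")
}

#' Dice similarity coefficient of two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`; both maps empty is undefined and
#' raises an error.
#'
#' @param a,b `group_map`s or binary 3D arrays of one shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  xa <- map_data(a) != 0
  xb <- map_data(b) != 0
  if (!identical(dim(xa), dim(xb))) stop("maps must share one shape")
  na <- sum(xa); nb <- sum(xb)
  if (na + nb == 0) stop("both maps are empty: Dice undefined")
  2 * sum(xa & xb) / (na + nb)
}

#' Per-region comparison of weighted saliency scores between groups
#'
#' Two-sided Mann-Whitney U per region on the per-subject weighted scores,
#' against the Bonferroni threshold `alpha / n_regions`; regions are ranked
#' by the mean weighted score of the healthy group (most important first).
#'
#' @param healthy_tables,ms_tables lists of [region_scores()] tables (one
#'   per subject, >= 2 per group, identical region sets).
#' @param alpha family-wise error rate (default 0.05).
#' @param mw_mode Mann-Whitney mode (default normal approximation).
#' @return data.frame ranked by healthy-group importance: `region_id`,
#'   `name`, `mean_score_healthy`, `mean_score_ms`, `p_value`,
#'   `corrected_alpha`, `significant`.
#' @export
compare_region_scores <- function(healthy_tables, ms_tables, alpha = 0.05,
                                  mw_mode = "normal_approx") {
  stopifnot(length(healthy_tables) >= 2, length(ms_tables) >= 2)
  ref <- healthy_tables[[1]][, c("region_id", "name")]
  score_matrix <- function(tables) {
    vapply(tables, function(tb) {
      if (!identical(tb$region_id, ref$region_id))
        stop("region sets differ between score tables")
      tb$weighted_score
    }, numeric(nrow(ref)))
  }
  H <- score_matrix(healthy_tables)
  M <- score_matrix(ms_tables)
  thr <- bonferroni(alpha, nrow(ref))
  p <- vapply(seq_len(nrow(ref)), function(i)
    mann_whitney_u(H[i, ], M[i, ], mode = mw_mode)$p_value, 0)
  out <- data.frame(region_id = ref$region_id, name = ref$name,
                    mean_score_healthy = rowMeans(H),
                    mean_score_ms = rowMeans(M),
                    p_value = p, corrected_alpha = thr,
                    significant = p < thr, stringsAsFactors = FALSE)
  out[order(-out$mean_score_healthy), ]
}

#' Per-subject saliency pipeline
#'
#' Convenience wrapper: SmoothGrad, [0, 255] mapping, bottom-percentile
#' denoising, regional scores. The order (threshold each subject map, then
#' group-average, then binarize) follows the package default; see
#' [group_average_map()].
#'
#' @param model a `trained_model`.
#' @param vols list of preprocessed volumes.
#' @param manifest data.frame aligned with `vols` (needs `subject_id`).
#' @param parc a [parcellation()] on the model input grid.
#' @param n_samples,noise_fraction,threshold_pct,threshold_mode
#'   SmoothGrad/denoise settings.
#' @param seed integer seed; per-subject seeds are derived from it.
#' @param subject_seeds optional explicit per-subject seeds (overrides
#'   `seed + i`), so maps are reproducible regardless of subject subsets.
#' @return list with `maps` (named list of denoised `saliency_map`s) and
#'   `scores` (named list of [region_scores()] tables).
#' @export
saliency_pipeline <- function(model, vols, manifest, parc, n_samples = 25,
                              noise_fraction = 0.10, threshold_pct = 5,
                              threshold_mode = "range", seed = 1,
                              subject_seeds = NULL) {
  stopifnot(length(vols) == nrow(manifest))
  maps <- list(); scores <- list()
  for (i in seq_along(vols)) {
    id <- manifest$subject_id[i]
    sm <- smoothgrad(model, vols[[i]], n_samples = n_samples,
                     noise_fraction = noise_fraction,
                     seed = if (is.null(subject_seeds)) seed + i
                            else subject_seeds[i],
                     subject_id = id)
    sm <- denoise_threshold(rescale_0_255(sm), pct = threshold_pct,
                            mode = threshold_mode)
    maps[[id]] <- sm
    scores[[id]] <- region_scores(sm, parc)
  }
  list(maps = maps, scores = scores)
}
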