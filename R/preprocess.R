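# Numeric preprocessing applied after registration: zero-mean intensity
# rescaling, population-wide background cropping, QC exclusion bookkeeping.
# Crop bounds are 0-based half-open everywhere.

#' Rescale a volume to zero mean over the brain mask
#'
#' Subtracts the mean intensity over the mask (default: non-zero voxels of
#' the skull-stripped volume) from the masked voxels; background stays 0.
#' Idempotent, and equivariant to adding a constant on the mask. Only the
#' mean is removed; set `scale_unit_sd = TRUE` to additionally divide by
#' the masked standard deviation (off by default: the reference protocol
#' rescales to zero mean only).
#'
#' @param vol an [image_volume()].
#' @param scale_unit_sd also scale masked voxels to unit sd.
#' @return the rescaled [image_volume()] (mask recorded in `brain_mask`).
#' @export
rescale_zero_mean <- function(vol, scale_unit_sd = FALSE) {
  stopifnot(inherits(vol, "image_volume"))
  mask <- if (is.null(vol$brain_mask)) vol$data != 0 else vol$brain_mask
  if (!any(mask)) stop("empty brain mask: cannot rescale")
  x <- vol$data
  vals <- x[mask] - mean(x[mask])
  if (scale_unit_sd) {
    s <- stats::sd(vals)
    if (s > 0) vals <- vals / s
  }
  x[mask] <- vals
  x[!mask] <- 0
  image_volume(x, spacing = vol$spacing, space = vol$space, brain_mask = mask)
}

#' Crop bounds: per-axis 0-based half-open voxel index ranges
#'
#' @param low,high integer length-3 vectors, `low < high` per axis.
#' @return a `crop_bounds` object.
#' @export
crop_bounds <- function(low, high) {
  low <- as.integer(low); high <- as.integer(high)
  stopifnot(length(low) == 3L, length(high) == 3L)
  if (any(low < 0) || any(low >= high)) stop("invalid crop bounds")
  structure(list(low = low, high = high), class = "crop_bounds")
}

#' @export
print.crop_bounds <- function(x, ...) {
  cat(sprintf("<crop_bounds [%s) x [%s) x [%s)>\n",
              paste(c(x$low[1], x$high[1]), collapse = ", "),
              paste(c(x$low[2], x$high[2]), collapse = ", "),
              paste(c(x$low[3], x$high[3]), collapse = ", ")))
  invisible(x)
}

#' Compute the tightest population-wide crop
#'
#' Bounds are the smallest box containing the union of all non-zero voxels
#' across the population; one common bound is applied to every volume, so
#' no subject loses brain information. Compute bounds on the training
#' population and apply them frozen to validation/test/disease volumes.
#'
#' @param vols list of [image_volume()] on one shared grid.
#' @param bounds optionally, frozen [crop_bounds()] to apply instead of
#'   computing new ones.
#' @return list with `bounds` and `volumes` (cropped).
#' @export
population_crop <- function(vols, bounds = NULL) {
  stopifnot(length(vols) >= 1)
  d <- dim(vols[[1]]$data)
  for (v in vols)
    if (!identical(dim(v$data), d)) stop("all volumes must share one grid shape")
  if (is.null(bounds)) {
    nz <- array(FALSE, d)
    for (v in vols) nz <- nz | (v$data != 0)
    if (!any(nz)) stop("all volumes are identically zero")
    idx <- which(nz, arr.ind = TRUE)
    bounds <- crop_bounds(apply(idx, 2, min) - 1L, apply(idx, 2, max))
  }
  if (any(bounds$high > d)) stop("crop bounds exceed grid")
  lo <- bounds$low; hi <- bounds$high
  cropped <- lapply(vols, function(v) {
    image_volume(v$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3],
                        drop = FALSE],
                 spacing = v$spacing, space = v$space,
                 brain_mask = if (is.null(v$brain_mask)) NULL else
                   v$brain_mask[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                                (lo[3] + 1):hi[3], drop = FALSE])
  })
  list(bounds = bounds, volumes = cropped)
}

#' Serialize / restore crop bounds as JSON
#'
#' @param bounds a [crop_bounds()].
#' @param path JSON file path.
#' @return `path` (write) or a [crop_bounds()] (read).
#' @export
write_crop_bounds <- function(bounds, path) {
  jsonlite::write_json(list(low = bounds$low, high = bounds$high), path)
  invisible(path)
}

#' @rdname write_crop_bounds
#' @export
read_crop_bounds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  crop_bounds(x$low, x$high)
}

#' Apply QC exclusions to a manifest
#'
#' Removes the listed subjects and reports per-cohort before/after counts.
#' Unknown ids raise a warning (not an error) and are ignored.
#'
#' @param manifest data.frame with `subject_id` and `cohort`.
#' @param exclusion_ids character vector of subject ids to drop.
#' @return list with `manifest` (retained rows) and `report` (data.frame
#'   with cohort, n_input, n_excluded, n_retained).
#' @export
apply_exclusions <- function(manifest, exclusion_ids = character()) {
  stopifnot(all(c("subject_id", "cohort") %in% names(manifest)))
  unknown <- setdiff(exclusion_ids, manifest$subject_id)
  if (length(unknown))
    warning("unknown subject ids in exclusion list: ",
            paste(unknown, collapse = ", "))
  drop <- manifest$subject_id %in% exclusion_ids
  kept <- manifest[!drop, , drop = FALSE]
  kept$qc_excluded <- FALSE
  cohorts <- unique(manifest$cohort)
  report <- data.frame(
    cohort = cohorts,
    n_input = vapply(cohorts, function(ch) sum(manifest$cohort == ch), 0L),
    n_excluded = vapply(cohorts, function(ch) sum(drop & manifest$cohort == ch), 0L),
    stringsAsFactors = FALSE)
  report$n_retained <- report$n_input - report$n_excluded
  list(manifest = kept, report = report)
}
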