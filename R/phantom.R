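# Synthetic brain-phantom generator.
#
# Phantoms are nested geometric shapes in template space: an outer brain
# ellipsoid with a cortical ribbon, bilateral lateral-ventricle ellipsoids,
# midline third/fourth ventricles, bilateral subcortical nuclei, and (for
# the disease condition) focal white-matter lesions rendered at CSF-like
# intensity ("black holes"). All morphology is driven by a single
# effective age = chronological age + ms_offset, so the brain-age offset a
# model should recover is known exactly by construction. T1-like contrast:
# CSF < GM < WM.

# Label codes used by both subject rendering and the parcellation.
PHANTOM_REGIONS <- data.frame(
  region_id  = 1:10,
  name       = c("lateral_ventricle_L", "lateral_ventricle_R",
                 "third_ventricle", "fourth_ventricle",
                 "subcortical_L", "subcortical_R",
                 "cortex_L", "cortex_R",
                 "white_matter_L", "white_matter_R"),
  hemisphere = c("L", "R", "midline", "midline", "L", "R", "L", "R", "L", "R"),
  stringsAsFactors = FALSE)

#' Morphology parameters for a phantom at a given (effective) age
#'
#' Deterministic map from age and disease offset to phantom geometry. All
#' shared (atrophy) fields depend only on `age + ms_offset`; lesion fields
#' depend only on `ms_offset`. Radii/thicknesses are in voxels of the
#' 32-voxel reference grid and are rescaled for other grid sizes.
#'
#' @param age chronological age in years (>= 0).
#' @param ms_offset disease-related brain-age offset in years (`age +
#'   ms_offset` must be >= 0; 0 for healthy subjects).
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(age, ms_offset = 0) {
  if (!is.finite(age) || age < 0) stop("age must be >= 0")
  eage <- age + ms_offset
  if (!is.finite(eage) || eage < 0) stop("effective age must be >= 0")
  structure(list(
    effective_age      = eage,
    ventricle_radius   = 2.0 + 0.04 * eage,
    cortical_thickness = max(3.2 - 0.02 * eage, 0.8),
    gm_intensity       = 100,
    wm_intensity       = 140,
    csf_intensity      = 40,
    lesion_count       = if (ms_offset > 0) as.integer(round(0.75 * ms_offset)) else 0L,
    lesion_radius      = if (ms_offset > 0) 1.3 else 0
  ), class = "morphology_params")
}

# Squared normalized distance to an ellipsoid: <= 1 means inside.
ellipsoid_rho2 <- function(d, center, semi) {
  semi <- pmax(semi, 0.75)  # thin structures stay resolvable on small grids
  t1 <- ((seq_len(d[1]) - center[1]) / semi[1])^2
  t2 <- ((seq_len(d[2]) - center[2]) / semi[2])^2
  t3 <- ((seq_len(d[3]) - center[3]) / semi[3])^2
  outer(outer(t1, t2, "+"), t3, "+")
}

#' Render the phantom geometry as an integer label grid
#'
#' Geometry is expressed in reference units (1 unit = min(grid)/32 voxels)
#' and rendered with fixed structure priorities (ventricles overwrite white
#' matter, etc.). This is the per-subject ground truth; counting ventricle
#' labels here gives the exact morphological aging signal.
#'
#' @param params a [morphology_params()].
#' @param grid_shape integer length-3, >= 16 per axis.
#' @param lesion_centers optional matrix of voxel coordinates (rows) for
#'   focal lesions; lesions only overwrite white matter and are coded -1.
#' @return 3D integer array (0 = background, -1 = lesion, 1..10 = regions
#'   as in the package parcellation).
#' @export
phantom_labels <- function(params, grid_shape,
                           lesion_centers = NULL) {
  d <- as.integer(grid_shape)
  if (length(d) != 3L || any(d < 16L)) stop("grid_shape must be >= 16 per axis")
  u <- min(d) / 32
  ctr <- (d + 1) / 2
  brain_semi <- c(0.42, 0.44, 0.40) * d
  if (params$ventricle_radius * 1.4 * u >= min(brain_semi))
    stop("ventricle radius does not fit inside the grid")

  rho2 <- ellipsoid_rho2(d, ctr, brain_semi)
  lab <- array(0L, d)
  left <- slice.index(lab, 1) < ctr[1]

  inside <- rho2 <= 1
  tau <- params$cortical_thickness * u / mean(brain_semi)
  cortex <- inside & rho2 > (1 - tau)^2
  wm <- inside & !cortex
  lab[wm & left] <- 9L
  lab[wm & !left] <- 10L
  lab[cortex & left] <- 7L
  lab[cortex & !left] <- 8L

  sub_semi <- rep(2.2 * u, 3)
  subL <- ellipsoid_rho2(d, ctr + c(-8, 1.5, 0) * u, sub_semi) <= 1
  subR <- ellipsoid_rho2(d, ctr + c(+8, 1.5, 0) * u, sub_semi) <= 1
  lab[subL & inside] <- 5L
  lab[subR & inside] <- 6L

  rv <- params$ventricle_radius * u
  vsemi <- c(0.5, 1.4, 0.75) * rv
  vL <- ellipsoid_rho2(d, ctr + c(-4, 0.5, 0.5) * u, vsemi) <= 1
  vR <- ellipsoid_rho2(d, ctr + c(+4, 0.5, 0.5) * u, vsemi) <= 1
  eage <- params$effective_age
  v3 <- ellipsoid_rho2(d, ctr, c(0.9, 2.0 + 0.015 * eage, 1.6) * u) <= 1
  v4 <- ellipsoid_rho2(d, ctr + c(0, -4.5, -4.5) * u,
                       rep((1.3 + 0.008 * eage) * u, 3)) <= 1
  lab[v3 & inside] <- 3L
  lab[v4 & inside] <- 4L
  lab[vL & inside] <- 1L
  lab[vR & inside] <- 2L

  if (!is.null(lesion_centers) && nrow(lesion_centers) > 0) {
    lr <- params$lesion_radius * u
    lesion <- array(FALSE, d)
    for (i in seq_len(nrow(lesion_centers)))
      lesion <- lesion |
        ellipsoid_rho2(d, as.numeric(lesion_centers[i, ]), rep(lr, 3)) <= 1
    # lesions live in white matter only; mark with the negative WM code
    lab[lesion & lab %in% c(9L, 10L)] <- -1L
  }
  lab
}

#' T1-like intensity rendering of a phantom label grid
#'
#' CSF < GM < WM contrast; lesions (-1) render at CSF-like intensity
#' ("black holes").
#'
#' @param lab label grid from [phantom_labels()].
#' @param params the matching [morphology_params()].
#' @return 3D numeric array of noiseless intensities.
#' @export
phantom_intensity <- function(lab, params) {
  lut <- c(params$csf_intensity,                      # -1 lesion
           0,                                         # 0 background
           params$csf_intensity, params$csf_intensity,
           params$csf_intensity, params$csf_intensity,
           110, 110,                                  # subcortical nuclei
           params$gm_intensity, params$gm_intensity,
           params$wm_intensity, params$wm_intensity)
  array(lut[lab + 2L], dim(lab))
}

#' Cohort configuration for the phantom generator
#'
#' Defaults state the emulated world: healthy ages spanning adulthood
#' (20-89, uniform), a disease cohort restricted to ages 20-60 as in a
#' relapsing-remitting MS population, a brain-age offset drawn from
#' Normal(`ms_offset_mean`, `ms_offset_sd`) truncated at zero, and additive
#' Gaussian intensity noise with sd equal to 5% of the white-matter
#' intensity.
#'
#' @param n_healthy,n_ms cohort sizes (>= 0).
#' @param age_range healthy age range in years, `c(min, max)`.
#' @param ms_age_range disease-cohort age range; defaults to
#'   `age_range` clipped to 20-60.
#' @param grid_shape voxel grid, >= 16 per axis.
#' @param ms_offset_mean,ms_offset_sd offset distribution in years.
#' @param noise_sd intensity noise sd (arbitrary units).
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_healthy = 100, n_ms = 20,
                          age_range = c(20, 89), ms_age_range = NULL,
                          grid_shape = c(32, 32, 32),
                          ms_offset_mean = 8, ms_offset_sd = 2,
                          noise_sd = 7, seed = 1) {
  if (n_healthy < 0 || n_ms < 0) stop("cohort sizes must be >= 0")
  if (age_range[1] >= age_range[2]) stop("age_range must satisfy min < max")
  if (any(grid_shape < 16)) stop("grid_shape must be >= 16 per axis")
  if (is.null(ms_age_range))
    ms_age_range <- c(max(age_range[1], 20), min(age_range[2], 60))
  structure(list(n_healthy = n_healthy, n_ms = n_ms, age_range = age_range,
                 ms_age_range = ms_age_range,
                 grid_shape = as.integer(grid_shape),
                 ms_offset_mean = ms_offset_mean, ms_offset_sd = ms_offset_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort of brain phantoms
#'
#' Produces one volume per subject on a shared grid, a manifest with
#' demographics, ground-truth offsets and clinical covariates, and a shared
#' parcellation. Bit-identical output for identical configuration.
#'
#' @param cfg a [cohort_config()].
#' @return a list with elements `volumes` (list of [image_volume()]),
#'   `labels` (list of subject-specific integer label grids, ground truth),
#'   `manifest` (data.frame of subject records), and `parcellation`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_healthy + cfg$n_ms
  set.seed(cfg$seed)
  cohorts <- rep(c("healthy", "MS"), c(cfg$n_healthy, cfg$n_ms))
  ages <- numeric(n)
  ages[cohorts == "healthy"] <- runif(cfg$n_healthy, cfg$age_range[1], cfg$age_range[2])
  ages[cohorts == "MS"] <- runif(cfg$n_ms, cfg$ms_age_range[1], cfg$ms_age_range[2])
  # alternate sexes within each cohort so age bands stay sex-balanced
  sexes <- unlist(lapply(c(cfg$n_healthy, cfg$n_ms), function(k)
    rep_len(c("M", "F"), k)), use.names = FALSE)
  offsets <- numeric(n)
  if (cfg$n_ms > 0 && (cfg$ms_offset_mean != 0 || cfg$ms_offset_sd != 0)) {
    draw_trunc <- function(k) {
      out <- numeric(k)
      for (i in seq_len(k)) {
        repeat {
          x <- rnorm(1, cfg$ms_offset_mean, cfg$ms_offset_sd)
          if (x >= 0) break
        }
        out[i] <- x
      }
      out
    }
    offsets[cohorts == "MS"] <- draw_trunc(cfg$n_ms)
  }
  subject_seeds <- sample.int(.Machine$integer.max, n)

  manifest <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = ages, sex = sexes, cohort = cohorts, ms_offset = offsets,
    qc_excluded = FALSE, stringsAsFactors = FALSE)
  manifest <- fill_covariates(manifest, seed = subject_seeds[1])

  volumes <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seeds[i])
    p <- morphology_params(ages[i], offsets[i])
    centers <- NULL
    if (p$lesion_count > 0) {
      base <- phantom_labels(p, cfg$grid_shape)
      wm_idx <- which(base %in% c(9L, 10L))
      pick <- wm_idx[sample.int(length(wm_idx), min(p$lesion_count, length(wm_idx)))]
      centers <- arrayInd(pick, dim(base))
    }
    lab <- phantom_labels(p, cfg$grid_shape, lesion_centers = centers)
    vol <- phantom_intensity(lab, p)
    if (cfg$noise_sd > 0) {
      inside <- lab != 0L
      vol[inside] <- vol[inside] + rnorm(sum(inside), 0, cfg$noise_sd)
    }
    volumes[[i]] <- image_volume(vol, spacing = c(1, 1, 1), space = "template")
    labels[[i]] <- lab
  }

  list(volumes = volumes, labels = labels, manifest = manifest,
       parcellation = build_parcellation(cfg$grid_shape))
}

#' Reference parcellation for the phantom template
#'
#' Region extents are chosen so that every subject's structures nest inside
#' their parcel across the modeled age range: ventricular parcels use the
#' oldest (effective age 90) geometry, the cortical ribbon the youngest
#' (age 20). Label 0 is background; labels partition the grid.
#'
#' @param grid_shape voxel grid.
#' @return a [parcellation()].
#' @export
build_parcellation <- function(grid_shape) {
  old <- morphology_params(90, 0)
  young <- morphology_params(20, 0)
  ref <- old
  ref$cortical_thickness <- young$cortical_thickness
  lab <- phantom_labels(ref, grid_shape)
  parcellation(lab, PHANTOM_REGIONS)
}

#' Fill clinical covariates with a known correlation structure
#'
#' Generative equations (MS subjects; `eage = age + ms_offset`):
#' \itemize{
#'   \item `lesion_volume = exp(-1.6 + 0.28 ms_offset + N(0, 0.45))` ml,
#'     increasing in the offset; healthy subjects get 0.
#'   \item `bpf = 0.82 - 0.002 eage - 0.006 ms_offset + N(0, 0.015)`,
#'     clamped to (0.4, 0.95): decreasing in effective age.
#'   \item `edss = 0.25 ms_offset + N(0, 0.8)`, clamped to [0, 10], rounded
#'     to half points: noisily increasing in the offset.
#'   \item `disease_duration = 0.3 + 1.1 ms_offset + N(0, 2.5)`, clamped to
#'     [0.3, age - 18]; `age_at_onset = age - disease_duration` (<= age).
#' }
#' Healthy subjects get `NA` for the disease-specific fields.
#'
#' @param manifest data.frame with `age`, `cohort`, `ms_offset`.
#' @param seed integer seed.
#' @return the manifest with covariate columns filled.
#' @export
fill_covariates <- function(manifest, seed = 1) {
  stopifnot(all(c("age", "cohort", "ms_offset") %in% names(manifest)))
  set.seed(seed)
  n <- nrow(manifest)
  eage <- manifest$age + manifest$ms_offset
  ms <- manifest$cohort == "MS"
  bpf <- 0.82 - 0.002 * eage - 0.006 * manifest$ms_offset + rnorm(n, 0, 0.015)
  manifest$bpf <- pmin(pmax(bpf, 0.4), 0.95)
  manifest$lesion_volume <- 0
  manifest$edss <- NA_real_
  manifest$disease_duration <- NA_real_
  manifest$age_at_onset <- NA_real_
  if (any(ms)) {
    k <- sum(ms)
    off <- manifest$ms_offset[ms]
    manifest$lesion_volume[ms] <-
      round(exp(-1.6 + 0.28 * off + rnorm(k, 0, 0.45)), 4)
    manifest$edss[ms] <-
      round(pmin(pmax(0.25 * off + rnorm(k, 0, 0.8), 0), 10) * 2) / 2
    dur <- 0.3 + 1.1 * off + rnorm(k, 0, 2.5)
    dur <- pmin(pmax(dur, 0.3), manifest$age[ms] - 18)
    manifest$disease_duration[ms] <- round(dur, 2)
    manifest$age_at_onset[ms] <- round(manifest$age[ms] - dur, 2)
  }
  manifest
}

#' Single-record covariate sampler
#'
#' Record-level wrapper around [fill_covariates()].
#'
#' @param record one-row data.frame (or list) with `age`, `cohort`,
#'   `ms_offset`.
#' @param seed integer seed.
#' @return the record with covariates filled.
#' @export
sample_covariates <- function(record, seed = 1) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 1)
  fill_covariates(df, seed = seed)
}

#' Write a generated dataset to disk
#'
#' One NIfTI per subject, the parcellation NIfTI, a region table TSV and a
#' manifest TSV with every subject-record field.
#'
#' @param dataset result of [generate_cohort()].
#' @param out_dir output directory.
#' @param force overwrite an existing dataset (default errors).
#' @return path of the written manifest, invisibly.
#' @export
write_dataset <- function(dataset, out_dir, force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (file.exists(manifest_path) && !force)
    stop("dataset already exists at ", out_dir, " (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$volume_file <- sprintf("%s.nii.gz", man$subject_id)
  for (i in seq_len(nrow(man)))
    write_nifti(dataset$volumes[[i]], file.path(out_dir, man$volume_file[i]))
  write_nifti(dataset$parcellation, file.path(out_dir, "parcellation.nii.gz"))
  utils::write.table(dataset$parcellation$regions,
                     file.path(out_dir, "regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(man, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(manifest_path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `volumes`, `manifest`, `parcellation`.
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) stop("no manifest.tsv under ", dir)
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  vols <- lapply(man$volume_file, function(f) read_nifti(file.path(dir, f)))
  parc_vol <- read_nifti(file.path(dir, "parcellation.nii.gz"))
  regions <- utils::read.delim(file.path(dir, "regions.tsv"),
                               stringsAsFactors = FALSE)
  parc <- parcellation(array(as.integer(round(parc_vol$data)),
                             dim(parc_vol$data)), regions)
  list(volumes = vols, manifest = man, parcellation = parc)
}
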