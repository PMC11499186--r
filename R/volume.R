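#' 3D image volume
#'
#' The unit every pipeline stage consumes and produces: a 3D scalar grid
#' with voxel spacing, a space tag, and an optional brain mask. Volumes are
#' assumed skull-stripped and affinely registered to a common template, so
#' background voxels are exactly zero.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per axis (all > 0).
#' @param space `"template"` or `"native"`.
#' @param brain_mask optional logical array of the same shape.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), space = "template",
                         brain_mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values")
  space <- match.arg(space, c("template", "native"))
  if (!is.null(brain_mask)) {
    if (!identical(dim(brain_mask), dim(data)))
      stop("`brain_mask` shape must equal `data` shape")
    brain_mask <- array(as.logical(brain_mask), dim(data))
  }
  structure(list(data = data, spacing = as.numeric(spacing), space = space,
                 brain_mask = brain_mask),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume %dx%dx%d, spacing %s mm, space=%s%s>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              x$space, if (is.null(x$brain_mask)) "" else ", masked"))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Parcellation: integer label grid plus region table
#'
#' Label 0 is background; every non-zero label must appear in `regions`.
#'
#' @param label_grid 3D integer array of region labels.
#' @param regions data.frame with columns `region_id` (unique, > 0),
#'   `name`, `hemisphere` (`"L"`, `"R"` or `"midline"`).
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(label_grid, regions) {
  if (!is.array(label_grid) || length(dim(label_grid)) != 3L)
    stop("`label_grid` must be a 3D array")
  stopifnot(is.data.frame(regions),
            all(c("region_id", "name", "hemisphere") %in% names(regions)))
  if (anyDuplicated(regions$region_id)) stop("region ids must be unique")
  if (any(regions$region_id <= 0)) stop("region ids must be > 0")
  if (!all(regions$hemisphere %in% c("L", "R", "midline")))
    stop("hemisphere must be L, R or midline")
  labs <- setdiff(unique(as.integer(label_grid)), 0L)
  missing <- setdiff(labs, regions$region_id)
  if (length(missing))
    stop("labels present in grid but absent from region table: ",
         paste(missing, collapse = ", "))
  structure(list(label_grid = array(as.integer(label_grid), dim(label_grid)),
                 regions = regions),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$label_grid)
  cat(sprintf("<parcellation %dx%dx%d, %d regions>\n",
              d[1], d[2], d[3], nrow(x$regions)))
  invisible(x)
}
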