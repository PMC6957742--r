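#' Core CT volume container
#'
#' A `core_volume` bundles a 3D attenuation grid with its voxel spacing, the
#' downcore depth of the first slice, an optional retained-voxel mask and
#' free-form provenance metadata. The array axes are (x, y, z); the z index
#' increases with downcore depth.
#'
#' @param data 3D numeric array, axes (x, y, z).
#' @param spacing_mm numeric length-3, voxel spacing in mm (dx, dy, dz); all
#'   strictly positive. Default 0.351 x 0.351 x 0.5 mm, the usual helical-CT
#'   reconstruction grid for a slabbed sediment core.
#' @param depth_origin_cm downcore depth (cm) of slice z = 1.
#' @param mask optional logical array congruent with `data`: `TRUE` for voxels
#'   retained for analysis. `NULL` means all voxels retained.
#' @param meta named list of provenance (source files, scanner settings, ...).
#' @return An object of class `core_volume`.
#' @export
core_volume <- function(data, spacing_mm = c(0.351, 0.351, 0.5),
                        depth_origin_cm = 0, mask = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (x, y, z)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), dim(data)))
      stop("`mask` must be a logical array congruent with `data`")
  }
  structure(list(data = data, spacing_mm = spacing_mm,
                 depth_origin_cm = as.numeric(depth_origin_cm),
                 mask = mask, meta = meta),
            class = "core_volume")
}

#' @export
print.core_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<core_volume> %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  depth origin %.2f cm, section length %.2f cm, %s\n",
              x$depth_origin_cm, d[3] * x$spacing_mm[3] / 10,
              if (is.null(x$mask)) "no mask" else
                sprintf("%d retained voxels", sum(x$mask))))
  invisible(x)
}

#' Labelled voxel volume
#'
#' Integer labels congruent with a [core_volume()]: 0 = background, k > 0 =
#' burrow component k. After compaction the label set is `{0} U {1..K}`.
#'
#' @param labels 3D integer array.
#' @param spacing_mm voxel spacing in mm, inherited from the parent volume.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_mm) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (is.double(labels)) storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be nonnegative")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers")
  structure(list(labels = labels, spacing_mm = spacing_mm),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("<label_volume> %s voxels, %d component%s\n",
              paste(dim(x$labels), collapse = " x "), k, if (k == 1) "" else "s"))
  invisible(x)
}

n_labels <- function(lv) {
  if (inherits(lv, "label_volume")) max(0L, max(lv$labels)) else max(0L, max(lv))
}

#' Depth of each slice in cm
#'
#' @param volume a [core_volume()] (or any object with `spacing_mm` and
#'   `depth_origin_cm`).
#' @param nz number of slices; taken from the volume if omitted.
#' @return numeric vector of slice-centre depths in cm, increasing with z.
#' @export
slice_depths_cm <- function(volume, nz = dim(volume$data)[3]) {
  volume$depth_origin_cm + ((seq_len(nz) - 0.5) * volume$spacing_mm[3]) / 10
}

# voxel-centre coordinate vectors in mm along each axis
voxel_centres_mm <- function(dims, spacing_mm) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing_mm[a])
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
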