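#' Read a grayscale image stack into a core volume
#'
#' Accepts either one multipage TIFF file or an ordered vector of
#' single-page files. Page order becomes z order. Image stacks carry no
#' spacing metadata, so `spacing_mm` must be supplied explicitly.
#'
#' @param paths one multipage TIFF path or several single-page paths,
#'   already in z order.
#' @param spacing_mm voxel spacing in mm (required, length 3).
#' @param depth_origin_cm downcore depth of the first page.
#' @return A [core_volume()] (integer-valued; 16-bit samples are returned
#'   on their native 0..65535 scale).
#' @export
read_image_stack <- function(paths, spacing_mm, depth_origin_cm = 0) {
  if (missing(spacing_mm))
    stop("image stacks carry no spacing metadata: supply `spacing_mm`")
  pages <- list()
  for (p in paths)
    pages <- c(pages, tiff::readTIFF(p, all = TRUE, as.is = TRUE))
  if (!length(pages)) stop("no pages read")
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3)
      stop("page ", i, " is multi-channel (RGB?): supply single-channel ",
           "grayscale input")
    if (!identical(dim(pages[[i]]), dim(pages[[1]])))
      stop("ragged page shapes: page ", i, " is ",
           paste(dim(pages[[i]]), collapse = "x"), ", page 1 is ",
           paste(dim(pages[[1]]), collapse = "x"))
  }
  d <- dim(pages[[1]])  # (ny, nx): TIFF rows are y
  data <- array(if (is.integer(pages[[1]])) 0L else 0,
                dim = c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) data[, , k] <- t(pages[[k]])
  core_volume(data, spacing_mm = spacing_mm,
              depth_origin_cm = depth_origin_cm,
              meta = list(source = paste(paths, collapse = ";")))
}

#' Write a volume as a multipage TIFF stack
#'
#' Writes 16-bit (default) or 8-bit grayscale pages, one per slice. Data
#' must be integer-valued in `[0, 2^bits - 1]`; integer round trips through
#' [read_image_stack()] are then bit-faithful. Label volumes can be written
#' directly (components fit comfortably in 16 bits).
#'
#' @param x a [core_volume()], [label_volume()] or 3D array.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(x, path, bits = 16L) {
  data <- if (inherits(x, "core_volume")) x$data
  else if (inherits(x, "label_volume")) x$labels else x
  stopifnot(length(dim(data)) == 3, bits %in% c(8L, 16L))
  top <- 2^bits - 1
  if (max(abs(data - round(data))) > 1e-9 || min(data) < 0 || max(data) > top)
    stop(sprintf("data must be integer-valued in [0, %d] for %d-bit output",
                 top, bits))
  pages <- lapply(seq_len(dim(data)[3]),
                  function(k) t(data[, , k]) / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Export burrow and profile tables
#'
#' Writes the burrow morphometrics table and the per-slice profile table as
#' comma-separated text with header rows, re-readable losslessly at full
#' numeric precision.
#'
#' @param burrow_table data frame from [parameterise_components()].
#' @param slice_profiles data frame from [slice_profiles()].
#' @param path_prefix output path prefix; `<prefix>_burrows.csv` and
#'   `<prefix>_profiles.csv` are written.
#' @return Invisibly, the written paths.
#' @export
write_tables <- function(burrow_table, slice_profiles, path_prefix) {
  paths <- paste0(path_prefix, c("_burrows.csv", "_profiles.csv"))
  utils::write.csv(burrow_table, paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(slice_profiles), paths[2], row.names = FALSE)
  invisible(paths)
}

#' Read a depth-binned 2D-image ichnology table
#'
#' Consumes the Bioturbation-Index log derived from high-resolution
#' core-surface images: a delimited table with columns `top_cm`, `base_cm`,
#' `bi` (integer 0-6) and optionally `taxa` (free text) and `disjoint_flag`
#' (logical: the 2D structures are disjoint from the CT-segmented fills).
#'
#' A small synthetic example ships with the package:
#' `system.file("extdata", "synthetic_image2d_bi.csv", package = "ichnoCT")`.
#'
#' @param path CSV file path.
#' @return Data frame with the columns above (`disjoint_flag` defaults to
#'   `FALSE`, `taxa` to `""`).
#' @export
read_image2d_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("top_cm", "base_cm", "bi")
  if (!all(need %in% names(tab)))
    stop("image2d table must have columns ", paste(need, collapse = ", "))
  if (any(tab$bi < 0 | tab$bi > 6)) stop("bi grades must be in 0..6")
  if (any(tab$top_cm >= tab$base_cm)) stop("need top_cm < base_cm")
  if (is.null(tab$taxa)) tab$taxa <- ""
  if (is.null(tab$disjoint_flag)) tab$disjoint_flag <- FALSE
  tab$disjoint_flag <- as.logical(tab$disjoint_flag)
  tab
}

#' Serialise / deserialise a scene spec as YAML
#'
#' @param spec a [scene_spec()].
#' @param path YAML file path.
#' @return `write_scene_spec` returns `path` invisibly; `read_scene_spec`
#'   returns the reconstructed [scene_spec()].
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  x$burrows <- lapply(spec$burrows, unclass)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- yaml::read_yaml(path)
  burrows <- lapply(x$burrows, function(b)
    burrow_spec(b$kind, b$diameter_mm, b$length_mm, b$z_angle_deg,
                b$azimuth_deg, unlist(b$anchor_mm), b$contrast,
                b$modulation_amplitude, b$n_branches))
  scene_spec(unlist(x$shape_voxels), unlist(x$spacing_mm), x$core_radius_mm,
             x$rim_mm, x$host_mean, x$host_sigma, x$liner_thickness_mm,
             x$liner_contrast, burrows, x$seed)
}
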