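#' Segmentation parameters
#'
#' Marker thresholds and watershed options for isolating dense burrow
#' fills. All thresholds are derived from the retained (masked) voxels
#' only, so behaviour is scale-free in attenuation units.
#'
#' @param marker_nsigma_fg fill-marker threshold in robust host-noise
#'   standard deviations (MAD-based) above the host median (default 4.5).
#'   Thresholding against the host background keeps marker selection
#'   independent of how abundant the fills are, so densely bioturbated
#'   intervals are treated the same as barren ones.
#' @param marker_quantile_bg intensity quantile of retained voxels below
#'   which voxels become host (background) markers (default 0.5).
#' @param min_equiv_diameter_mm minimum cylinder-equivalent diameter of a
#'   component to keep (default 1, matching the practical CT resolution
#'   limit for pyritised fills).
#' @param min_marker_voxels minimum size (voxels, 26-connected) of a fill
#'   marker cluster (default 8). Genuine marker regions from threshold
#'   segmentation span at least the cross-section of the smallest
#'   segmentable burrow; smaller clusters are noise specks and are
#'   discarded. Set to 1 to keep every above-threshold voxel.
#' @param flood_on flooding surface: `"gradient"` (gradient magnitude,
#'   default) or `"inverted_intensity"`.
#' @param connectivity 6 (face) or 26 (face+edge+corner) neighbourhood.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(marker_nsigma_fg = 4.5,
                                marker_quantile_bg = 0.5,
                                min_equiv_diameter_mm = 1.0,
                                min_marker_voxels = 8L,
                                flood_on = c("gradient", "inverted_intensity"),
                                connectivity = 6L) {
  flood_on <- match.arg(flood_on)
  stopifnot(marker_nsigma_fg > 0,
            marker_quantile_bg > 0, marker_quantile_bg < 1,
            min_equiv_diameter_mm >= 0, min_marker_voxels >= 1,
            connectivity %in% c(6L, 26L))
  structure(list(marker_nsigma_fg = marker_nsigma_fg,
                 marker_quantile_bg = marker_quantile_bg,
                 min_equiv_diameter_mm = min_equiv_diameter_mm,
                 min_marker_voxels = as.integer(min_marker_voxels),
                 flood_on = flood_on, connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

retained_mask <- function(volume) {
  if (is.null(volume$mask)) array(TRUE, dim = dim(volume$data)) else volume$mask
}

#' Threshold-based watershed markers
#'
#' Fill markers are retained voxels strictly above
#' `host median + marker_nsigma_fg * sigma`, where `sigma` is the robust
#' (MAD) spread of the retained intensities; host markers are voxels
#' strictly below the background quantile. The two classes are disjoint by
#' construction (the fill threshold always sits above the host median).
#' Fill-marker clusters smaller than `min_marker_voxels` (26-connected)
#' are discarded as noise specks.
#'
#' @param volume a preprocessed [core_volume()] (mask applied).
#' @param params a [segmentation_params()].
#' @return A [label_volume()] with marker classes 1 = fill, 2 = host;
#'   attributes `thr_fg` and `thr_bg` record the absolute thresholds.
#' @export
generate_markers <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "core_volume"))
  mask <- retained_mask(volume)
  vals <- volume$data[mask]
  if (length(vals) == 0) stop("no retained voxels")
  if (diff(range(vals)) == 0)
    stop("all retained voxels have the same value: no contrast to segment")
  med <- stats::median(vals)
  sig <- stats::mad(vals, center = med)
  thr <- c(med + params$marker_nsigma_fg * sig,
           stats::quantile(vals, params$marker_quantile_bg, names = FALSE))
  markers <- array(0L, dim = dim(volume$data))
  fg <- mask & volume$data > thr[1]
  if (params$min_marker_voxels > 1L && any(fg)) {
    cl <- .label_components_cpp(as.vector(fg), dim(fg), 26L)
    sizes <- tabulate(cl, nbins = max(cl))
    small <- which(sizes < params$min_marker_voxels)
    if (length(small)) fg[array(cl %in% small, dim = dim(fg))] <- FALSE
  }
  markers[fg] <- 1L
  markers[mask & volume$data < thr[2]] <- 2L
  out <- label_volume(markers, volume$spacing_mm)
  attr(out, "thr_fg") <- thr[1]
  attr(out, "thr_bg") <- thr[2]
  out
}

# gradient magnitude by central differences (one-sided at edges), per mm
gradient_magnitude <- function(data, spacing) {
  d <- dim(data)
  g2 <- array(0, dim = d)
  for (a in 1:3) {
    hi <- pmin(seq_len(d[a]) + 1L, d[a])
    lo <- pmax(seq_len(d[a]) - 1L, 1L)
    step <- (hi - lo) * spacing[a]
    ix <- function(v) switch(a, data[v, , , drop = FALSE],
                             data[, v, , drop = FALSE],
                             data[, , v, drop = FALSE])
    diffs <- ix(hi) - ix(lo)
    scl <- switch(a, step, rep(step, each = d[1]),
                  rep(step, each = d[1] * d[2]))
    g2 <- g2 + (diffs / scl)^2
  }
  sqrt(g2)
}

#' Marker-based watershed of the fill/host boundary
#'
#' Floods the chosen surface (gradient magnitude by default) from the fill
#' and host markers simultaneously; every retained voxel is assigned to the
#' marker class whose flood reaches it first (priority flooding, FIFO on
#' ties, hence deterministic). The fill mask always contains the fill
#' markers.
#'
#' @param volume a preprocessed [core_volume()].
#' @param markers marker [label_volume()] from [generate_markers()] (1 =
#'   fill, 2 = host), or an equivalent user-supplied marker volume.
#' @param params a [segmentation_params()].
#' @return Logical array: `TRUE` for fill voxels. Attribute `watershed`
#'   carries the full class assignment (1/2, 0 outside the mask).
#' @export
watershed_segment <- function(volume, markers,
                              params = segmentation_params()) {
  stopifnot(inherits(volume, "core_volume"))
  m <- if (inherits(markers, "label_volume")) markers$labels else markers
  stopifnot(identical(dim(m), dim(volume$data)))
  mask <- retained_mask(volume)
  if (!any(m == 1L & mask)) stop("no fill markers inside the retained region")
  if (!any(m == 2L & mask)) stop("no host markers inside the retained region")
  surface <- switch(params$flood_on,
                    gradient = gradient_magnitude(volume$data, volume$spacing_mm),
                    inverted_intensity = -volume$data)
  ws <- .watershed_flood_cpp(as.vector(surface), as.vector(as.integer(m)),
                             as.vector(mask), dim(volume$data),
                             params$connectivity)
  ws <- array(ws, dim = dim(volume$data))
  fill <- ws == 1L
  attr(fill, "watershed") <- ws
  fill
}

#' Separate a fill mask into burrow components
#'
#' Labels maximal connected components of the binary fill mask
#' (6-connectivity by default), numbered 1..K in order of decreasing voxel
#' count; equal-sized components are ordered by the (z, y, x) scan position
#' of their first voxel, so labelling is deterministic.
#'
#' @param fill logical 3D array (fill mask).
#' @param spacing_mm voxel spacing in mm.
#' @param connectivity 6 or 26.
#' @return A [label_volume()].
#' @export
separate_components <- function(fill, spacing_mm, connectivity = 6L) {
  stopifnot(is.logical(fill), length(dim(fill)) == 3)
  raw <- .label_components_cpp(as.vector(fill), dim(fill),
                               as.integer(connectivity))
  k <- max(raw, 0L)
  if (k == 0L)
    return(label_volume(array(0L, dim = dim(fill)), spacing_mm))
  counts <- tabulate(raw, nbins = k)
  # first voxel in (z, y, x) scan order; linear order is x-fastest so take
  # the min over a z-major re-ranking of each component's voxels
  d <- dim(fill)
  idx <- which(raw > 0L)
  ai <- arrayInd(idx, d)
  zyx_rank <- (ai[, 3] - 1) * (d[1] * d[2]) + (ai[, 2] - 1) * d[1] + ai[, 1]
  first <- rep(Inf, k)
  lab <- raw[idx]
  ord_first <- tapply(zyx_rank, lab, min)
  first[as.integer(names(ord_first))] <- ord_first
  perm <- order(-counts, first)
  remap <- integer(k); remap[perm] <- seq_len(k)
  out <- array(0L, dim = d)
  out[idx] <- remap[lab]
  label_volume(out, spacing_mm)
}

#' Remove components below the diameter threshold
#'
#' Drops components whose cylinder-equivalent diameter (see
#' [parameterise_components()]) is below `min_equiv_diameter_mm`, then
#' compacts the labels preserving the original order.
#'
#' @param labels a [label_volume()].
#' @param min_equiv_diameter_mm threshold in mm; 0 keeps everything.
#' @return A [label_volume()] with attribute `components`: the burrow table
#'   of the retained components (labels renumbered).
#' @export
filter_small <- function(labels, min_equiv_diameter_mm = 1.0) {
  stopifnot(inherits(labels, "label_volume"))
  comp <- parameterise_components(labels)
  keep <- comp$equiv_diameter_mm >= min_equiv_diameter_mm
  old <- comp$id[keep]
  k <- n_labels(labels)
  remap <- integer(k)
  remap[old] <- seq_along(old)
  lab <- labels$labels
  nz <- lab != 0L
  lab[nz] <- remap[lab[nz]]
  out <- label_volume(lab, labels$spacing_mm)
  newcomp <- comp[keep, , drop = FALSE]
  if (nrow(newcomp)) newcomp$id <- seq_len(nrow(newcomp))
  rownames(newcomp) <- NULL
  attr(out, "components") <- newcomp
  out
}

#' Full burrow segmentation pipeline
#'
#' Convenience wrapper: markers, watershed, connected components, size
#' filter, morphometrics.
#'
#' @param volume a preprocessed [core_volume()].
#' @param params a [segmentation_params()].
#' @return List: `labels` (a [label_volume()]), `components` (burrow table),
#'   `fill` (binary mask before component filtering), `log` (thresholds and
#'   component counts before/after filtering).
#' @export
segment_burrows <- function(volume, params = segmentation_params()) {
  markers <- generate_markers(volume, params)
  if (!any(markers$labels == 1L)) {
    # nothing above threshold survived the speck filter: no segmentable fills
    labs <- label_volume(array(0L, dim = dim(volume$data)), volume$spacing_mm)
    labs <- filter_small(labs, params$min_equiv_diameter_mm)
    return(list(labels = labs, components = attr(labs, "components"),
                fill = array(FALSE, dim = dim(volume$data)),
                log = list(thr_fg = attr(markers, "thr_fg"),
                           thr_bg = attr(markers, "thr_bg"),
                           n_components_raw = 0L, n_components = 0L)))
  }
  fill <- watershed_segment(volume, markers, params)
  labs <- separate_components(fill, volume$spacing_mm, params$connectivity)
  k_before <- n_labels(labs)
  labs <- filter_small(labs, params$min_equiv_diameter_mm)
  comp <- attr(labs, "components")
  list(labels = labs, components = comp, fill = fill,
       log = list(thr_fg = attr(markers, "thr_fg"),
                  thr_bg = attr(markers, "thr_bg"),
                  n_components_raw = k_before,
                  n_components = n_labels(labs)))
}
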