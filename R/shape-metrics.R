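#' Morphometrics of every burrow component
#'
#' For each labelled component, computes voxel count, volume, centroid, the
#' principal (best-fit) axis as the leading eigenvector of the covariance of
#' voxel-centre coordinates in mm (sign chosen so the z component is
#' nonnegative), the length as the extent of the voxel centres projected on
#' that axis, the cylinder-equivalent diameter
#' `2 * sqrt(volume / (pi * length))`, and the z-orientation angle
#' `asin(|axis_z|)` in degrees (0 = horizontal, 90 = vertical). Size and
#' orientation classes are attached via [classify_size()] and
#' [classify_orientation()].
#'
#' Single-voxel components are degenerate: their length is set to the
#' largest voxel spacing, the z-angle is undefined (`NA`) and they are
#' flagged `degenerate = TRUE` so downstream orientation profiles can
#' exclude them.
#'
#' @param labels a [label_volume()].
#' @param axis_estimator `"eigen"` (best-fit axis, default) or `"chord"`
#'   (direction between the two most distant voxel centres along the eigen
#'   axis ordering -- i.e. the endpoints of the projection).
#' @param tiny_threshold_mm size-class threshold passed to [classify_size()].
#' @param vertical_cutoff_deg passed to [classify_orientation()].
#' @return Data frame with one row per component: id, voxel_count,
#'   volume_mm3, centroid_x/y/z_mm, axis_x/y/z, length_mm,
#'   equiv_diameter_mm, z_angle_deg, degenerate, size_class,
#'   orientation_class.
#' @export
parameterise_components <- function(labels, axis_estimator = c("eigen", "chord"),
                                    tiny_threshold_mm = 5.0,
                                    vertical_cutoff_deg = 45.0) {
  stopifnot(inherits(labels, "label_volume"))
  axis_estimator <- match.arg(axis_estimator)
  sp <- labels$spacing_mm
  d <- dim(labels$labels)
  idx <- which(labels$labels > 0L)
  empty <- data.frame(id = integer(), voxel_count = integer(),
                      volume_mm3 = numeric(), centroid_x_mm = numeric(),
                      centroid_y_mm = numeric(), centroid_z_mm = numeric(),
                      axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
                      length_mm = numeric(), equiv_diameter_mm = numeric(),
                      z_angle_deg = numeric(), degenerate = logical(),
                      size_class = character(), orientation_class = character())
  if (length(idx) == 0) return(empty)
  lab <- labels$labels[idx]
  ai <- arrayInd(idx, d)
  xyz <- sweep(ai - 0.5, 2, sp, "*")  # voxel centres in mm
  voxvol <- prod(sp)
  rows <- lapply(sort(unique(lab)), function(k) {
    P <- xyz[lab == k, , drop = FALSE]
    n <- nrow(P)
    ctr <- colMeans(P)
    if (n == 1) {
      return(data.frame(id = k, voxel_count = 1L, volume_mm3 = voxvol,
                        centroid_x_mm = ctr[1], centroid_y_mm = ctr[2],
                        centroid_z_mm = ctr[3], axis_x = NA_real_,
                        axis_y = NA_real_, axis_z = NA_real_,
                        length_mm = max(sp),
                        equiv_diameter_mm = 2 * sqrt(voxvol / (pi * max(sp))),
                        z_angle_deg = NA_real_, degenerate = TRUE))
    }
    cv <- stats::cov(P)
    ev <- eigen(cv, symmetric = TRUE)
    axis <- ev$vectors[, 1]
    if (axis_estimator == "chord") {
      pr0 <- P %*% axis
      chord <- P[which.max(pr0), ] - P[which.min(pr0), ]
      if (sum(chord^2) > 0) axis <- chord / sqrt(sum(chord^2))
    }
    if (axis[3] < 0 || (axis[3] == 0 && (axis[1] < 0 ||
                                         (axis[1] == 0 && axis[2] < 0))))
      axis <- -axis
    pr <- P %*% axis
    len <- max(pr) - min(pr)
    degen <- len <= 0
    if (degen) len <- max(sp)
    vol <- n * voxvol
    data.frame(id = k, voxel_count = n, volume_mm3 = vol,
               centroid_x_mm = ctr[1], centroid_y_mm = ctr[2],
               centroid_z_mm = ctr[3], axis_x = axis[1], axis_y = axis[2],
               axis_z = axis[3], length_mm = len,
               equiv_diameter_mm = 2 * sqrt(vol / (pi * len)),
               z_angle_deg = if (degen) NA_real_ else
                 asin(min(abs(axis[3]), 1)) * 180 / pi,
               degenerate = degen)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$size_class <- classify_size(out$equiv_diameter_mm, tiny_threshold_mm)
  out$orientation_class <- ifelse(out$degenerate, NA_character_,
                                  classify_orientation(out$z_angle_deg,
                                                       vertical_cutoff_deg,
                                                       .allow_na = TRUE))
  out
}

#' Size class of a burrow
#'
#' Burrows with cylinder-equivalent diameter strictly under the threshold
#' (default 5 mm, i.e. 0.5 cm) are `"tiny"`; all others `"large"`.
#'
#' @param equiv_diameter_mm numeric vector of equivalent diameters (mm).
#' @param tiny_threshold_mm threshold in mm (default 5).
#' @return Character vector, `"tiny"` or `"large"`.
#' @export
classify_size <- function(equiv_diameter_mm, tiny_threshold_mm = 5.0) {
  ifelse(equiv_diameter_mm < tiny_threshold_mm, "tiny", "large")
}

#' Orientation class of a burrow
#'
#' Burrows whose z-angle is at or above the cutoff (default 45 degrees) are
#' `"sub_vertical"`, otherwise `"sub_horizontal"`.
#'
#' @param z_angle_deg numeric vector of z-angles in degrees.
#' @param vertical_cutoff_deg cutoff in degrees (default 45).
#' @param .allow_na internal: return `NA` for `NA` angles instead of
#'   erroring.
#' @return Character vector, `"sub_vertical"` or `"sub_horizontal"`.
#' @export
classify_orientation <- function(z_angle_deg, vertical_cutoff_deg = 45.0,
                                 .allow_na = FALSE) {
  if (any(is.na(z_angle_deg)) && !.allow_na)
    stop("z-angle undefined (degenerate component): exclude it before ",
         "orientation classification")
  ifelse(z_angle_deg >= vertical_cutoff_deg, "sub_vertical", "sub_horizontal")
}
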