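#' Fitted half-core geometry
#'
#' Position of the core's cylinder axis in the x-y plane, its radius, and the
#' outward normal of the slab (cut) face. The face plane passes through the
#' axis; sediment lies on the side opposite `face_normal`.
#'
#' @param axis_center_mm numeric length-2 (x, y) of the axis in mm.
#' @param radius_mm core radius in mm (> 0).
#' @param face_normal numeric length-2 unit vector pointing from the sediment
#'   across the slab face.
#' @return An object of class `core_geometry`.
#' @export
core_geometry <- function(axis_center_mm, radius_mm, face_normal) {
  stopifnot(length(axis_center_mm) == 2, radius_mm > 0,
            length(face_normal) == 2)
  face_normal <- face_normal / sqrt(sum(face_normal^2))
  structure(list(axis_center_mm = as.numeric(axis_center_mm),
                 radius_mm = radius_mm, face_normal = face_normal),
            class = "core_geometry")
}

#' @export
print.core_geometry <- function(x, ...) {
  cat(sprintf(
    "<core_geometry> axis (%.2f, %.2f) mm, radius %.2f mm, face normal (%.2f, %.2f)\n",
    x$axis_center_mm[1], x$axis_center_mm[2], x$radius_mm,
    x$face_normal[1], x$face_normal[2]))
  invisible(x)
}

# algebraic (Kasa) circle fit: returns c(cx, cy, r)
kasa_circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  c(sol[1], sol[2], sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

#' Locate the half-core in a scan
#'
#' Separates core material from air by the midpoint of the bimodal intensity
#' histogram (2-means on a voxel sample), projects occupancy to the x-y
#' plane, and fits a circle to the cross-section boundary. Points on the
#' flat slab face are iteratively trimmed (they fall well inside the fitted
#' circle) so only the curved arc constrains centre and radius; the face
#' normal points from the fitted centre towards the mean of the trimmed
#' (face) boundary points, i.e. away from the sediment bulk.
#'
#' Because the plastic liner attenuates like the sediment, the detected
#' outer boundary is the liner's outer wall; the known liner wall thickness
#' is subtracted to report the core (sediment) radius, mirroring the manual
#' geometric deletion of liners in practice.
#'
#' @param volume a [core_volume()].
#' @param liner_thickness_mm known liner wall thickness in mm, subtracted
#'   from the fitted outer radius (default 1.5, the simulator's liner).
#' @return A [core_geometry()].
#' @export
fit_core_geometry <- function(volume, liner_thickness_mm = 1.5) {
  stopifnot(inherits(volume, "core_volume"))
  dims <- dim(volume$data); sp <- volume$spacing_mm
  vals <- as.vector(volume$data)
  samp <- vals[unique(round(seq(1, length(vals),
                                length.out = min(length(vals), 2e5))))]
  if (diff(range(samp)) == 0)
    stop("no bimodal core/air histogram found (is the scan empty?)")
  km <- stats::kmeans(samp, centers = matrix(range(samp), 2, 1))
  ctrs <- sort(km$centers[, 1])
  wvar <- tapply(samp, km$cluster, stats::var)
  pooled_sd <- sqrt(mean(wvar, na.rm = TRUE))
  if (!is.finite(pooled_sd)) pooled_sd <- 0
  if (diff(ctrs) < 4 * max(pooled_sd, 1e-12))
    stop("no bimodal core/air histogram found (is the scan empty?)")
  thr <- mean(ctrs)

  occ <- apply(volume$data > thr, c(1, 2), mean) > 0.5
  if (!any(occ)) stop("no core material above the air threshold")
  # boundary pixels: occupied with at least one 4-neighbour unoccupied/edge
  pad <- matrix(FALSE, nrow(occ) + 2, ncol(occ) + 2)
  pad[2:(nrow(occ) + 1), 2:(ncol(occ) + 1)] <- occ
  inner <- pad[2:(nrow(occ) + 1), 2:(ncol(occ) + 1)] &
    pad[1:nrow(occ), 2:(ncol(occ) + 1)] & pad[3:(nrow(occ) + 2), 2:(ncol(occ) + 1)] &
    pad[2:(nrow(occ) + 1), 1:ncol(occ)] & pad[2:(nrow(occ) + 1), 3:(ncol(occ) + 2)]
  bnd <- which(occ & !inner, arr.ind = TRUE)
  bx <- (bnd[, 1] - 0.5) * sp[1]; by <- (bnd[, 2] - 0.5) * sp[2]

  # The boundary mixes the curved arc with the flat slab-face chord; a
  # single least-squares circle is dragged towards the chord. A consensus
  # search (circumcircles of point triples, scored by inlier count) finds
  # the arc; the final circle is a least-squares refit on the arc inliers.
  tol <- 2 * max(sp[1:2])
  fit <- with_seed(20260101L, {
    best <- NULL; best_n <- -1L
    n <- length(bx)
    for (it in 1:300) {
      i <- sample.int(n, 3)
      x1 <- bx[i[1]]; y1 <- by[i[1]]; x2 <- bx[i[2]]; y2 <- by[i[2]]
      x3 <- bx[i[3]]; y3 <- by[i[3]]
      den <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
      if (abs(den) < 1e-9) next
      ux <- ((x1^2 + y1^2) * (y2 - y3) + (x2^2 + y2^2) * (y3 - y1) +
               (x3^2 + y3^2) * (y1 - y2)) / den
      uy <- ((x1^2 + y1^2) * (x3 - x2) + (x2^2 + y2^2) * (x1 - x3) +
               (x3^2 + y3^2) * (x2 - x1)) / den
      r <- sqrt((x1 - ux)^2 + (y1 - uy)^2)
      if (r < 5 || r > max(dims[1] * sp[1], dims[2] * sp[2])) next
      n_in <- sum(abs(sqrt((bx - ux)^2 + (by - uy)^2) - r) < tol)
      if (n_in > best_n) { best_n <- n_in; best <- c(ux, uy, r) }
    }
    if (is.null(best)) stop("could not fit the core cross-section boundary")
    best
  })
  for (k in 1:2) {  # refine on inliers
    keep <- abs(sqrt((bx - fit[1])^2 + (by - fit[2])^2) - fit[3]) < tol
    if (sum(keep) < 10) break
    fit <- kasa_circle_fit(bx[keep], by[keep])
  }
  # the half-disc centroid sits 4R/(3*pi) behind the face plane, so the
  # outward face normal points from the occupied centroid through the axis
  occ_idx <- which(occ, arr.ind = TRUE)
  normal <- c(fit[1] - mean((occ_idx[, 1] - 0.5) * sp[1]),
              fit[2] - mean((occ_idx[, 2] - 0.5) * sp[2]))
  core_geometry(fit[1:2], max(fit[3] - liner_thickness_mm, 1e-6), normal)
}

#' Delete liner and artefact rim
#'
#' Marks as excluded every voxel that is outside the half-core, within
#' `rim_mm` of the curved core surface (radially from the fitted axis), or
#' -- when `trim_face` is `TRUE` -- within `rim_mm` of the slab face
#' (perpendicular distance). Exclusion is carried by the volume's logical
#' mask; attenuation values are never altered, so interior statistics remain
#' uncontaminated. Downstream operations ignore excluded voxels.
#'
#' @param volume a [core_volume()].
#' @param geometry a [core_geometry()], e.g. from [fit_core_geometry()].
#' @param rim_mm rim width to delete, in mm (>= 0); default 2, the usual
#'   allowance for drilling disturbance along the core edge.
#' @param trim_face also trim `rim_mm` below the slab face.
#' @return The input `core_volume` with its `mask` set (combined with any
#'   pre-existing mask by AND).
#' @export
remove_liner_and_rim <- function(volume, geometry, rim_mm = 2,
                                 trim_face = TRUE) {
  stopifnot(inherits(volume, "core_volume"), inherits(geometry, "core_geometry"),
            rim_mm >= 0)
  if (rim_mm >= geometry$radius_mm)
    stop("rim_mm >= core radius: nothing would remain")
  dims <- dim(volume$data); sp <- volume$spacing_mm
  cc <- voxel_centres_mm(dims, sp)
  dx <- cc[[1]] - geometry$axis_center_mm[1]
  dy <- cc[[2]] - geometry$axis_center_mm[2]
  r2d <- sqrt(outer(dx^2, dy^2, "+"))
  keep2d <- r2d <= geometry$radius_mm - rim_mm
  # signed distance along the face normal; sediment side is negative
  sdist <- outer(dx * geometry$face_normal[1], dy * geometry$face_normal[2], "+")
  keep2d <- keep2d & (sdist <= if (trim_face) -rim_mm else 0)
  mask <- array(keep2d, dim = dims)
  if (!is.null(volume$mask)) mask <- mask & volume$mask
  volume$mask <- mask
  volume$meta$rim_mm <- rim_mm
  volume
}
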