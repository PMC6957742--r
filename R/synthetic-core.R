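#' Specification of one synthetic burrow
#'
#' Describes a single burrow fill to be rasterised into a synthetic core
#' volume: either a straight cylindrical tube or a branched pinch-and-swell
#' network (a random-walk trunk with side branches and a sinusoidally
#' modulated radius).
#'
#' @param kind `"straight_tube"` or `"branched_network"`.
#' @param diameter_mm tube diameter in mm (> 0); for modulated tubes this is
#'   the mean diameter.
#' @param length_mm axial length in mm (> 0).
#' @param z_angle_deg angle of the axis above the horizontal plane, in
#'   degrees: 0 = horizontal, 90 = vertical.
#' @param azimuth_deg compass direction of the horizontal component of the
#'   axis, degrees in \[0, 360).
#' @param anchor_mm numeric length-3, axis start point in mm (x, y, z).
#' @param contrast attenuation offset of the fill above the host-sediment
#'   mean, in units of the host noise standard deviation. May be 0 for an
#'   invisible burrow (negative control).
#' @param modulation_amplitude relative amplitude in \[0, 1) of the
#'   sinusoidal radius modulation along the axis (pinch-and-swell); 0 gives a
#'   constant radius.
#' @param n_branches number of side branches (`branched_network` only).
#' @return An object of class `burrow_spec`.
#' @export
burrow_spec <- function(kind = c("straight_tube", "branched_network"),
                        diameter_mm, length_mm, z_angle_deg, azimuth_deg = 0,
                        anchor_mm, contrast = 8,
                        modulation_amplitude = 0, n_branches = 0L) {
  kind <- match.arg(kind)
  stopifnot(diameter_mm > 0, length_mm > 0,
            z_angle_deg >= 0, z_angle_deg <= 90,
            modulation_amplitude >= 0, modulation_amplitude < 1,
            n_branches >= 0, length(anchor_mm) == 3)
  structure(list(kind = kind, diameter_mm = diameter_mm,
                 length_mm = length_mm, z_angle_deg = z_angle_deg,
                 azimuth_deg = azimuth_deg %% 360,
                 anchor_mm = as.numeric(anchor_mm), contrast = contrast,
                 modulation_amplitude = modulation_amplitude,
                 n_branches = as.integer(n_branches)),
            class = "burrow_spec")
}

#' Specification of a synthetic core scene
#'
#' Fully determines one synthetic half-core CT volume: geometry (semicircular
#' cross-section of an archive half, plastic liner shell, downcore z axis),
#' host-sediment attenuation statistics, and a list of burrows. Together with
#' `seed` the spec determines the generated volume bit for bit.
#'
#' Geometry convention: the cylinder axis is parallel to z at the x-y centre
#' of the grid; the half-core occupies the side `y <= cy` of the slab face
#' plane, the liner wraps the curved surface only (the slab face is open),
#' and air fills the rest of the grid at `host_mean - 10 * host_sigma`.
#'
#' @param shape_voxels integer length-3 grid size (nx, ny, nz).
#' @param spacing_mm voxel spacing in mm; default 0.351 x 0.351 x 0.5.
#' @param core_radius_mm core radius in mm; default 31 (6.2 cm archive half).
#' @param rim_mm nominal artefact rim width in mm recorded for downstream
#'   trimming (default 2).
#' @param host_mean,host_sigma mean and standard deviation of the host
#'   sediment attenuation (arbitrary CT units).
#' @param liner_thickness_mm thickness of the liner shell in mm.
#' @param liner_contrast attenuation offset of the liner relative to
#'   `host_mean`; default 0 (liner nearly indistinguishable from sediment).
#' @param burrows list of [burrow_spec()] objects.
#' @param seed integer seed controlling noise and branched-network geometry.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape_voxels, spacing_mm = c(0.351, 0.351, 0.5),
                       core_radius_mm = 31, rim_mm = 2,
                       host_mean = 1000, host_sigma = 25,
                       liner_thickness_mm = 1.5, liner_contrast = 0,
                       burrows = list(), seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(shape_voxels) == 3, all(shape_voxels > 0),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            core_radius_mm > 0, rim_mm >= 0, host_sigma > 0,
            liner_thickness_mm >= 0)
  ext <- shape_voxels[1:2] * spacing_mm[1:2]
  rtot <- core_radius_mm + liner_thickness_mm
  if (2 * rtot > ext[1] || rtot > ext[2])
    stop(sprintf(paste0("core (radius %.1f mm + liner) does not fit the ",
                        "%.1f x %.1f mm x-y footprint"), core_radius_mm,
                 ext[1], ext[2]))
  for (b in burrows)
    if (!inherits(b, "burrow_spec")) stop("`burrows` must be burrow_spec objects")
  structure(list(shape_voxels = shape_voxels, spacing_mm = spacing_mm,
                 core_radius_mm = core_radius_mm, rim_mm = rim_mm,
                 host_mean = host_mean, host_sigma = host_sigma,
                 liner_thickness_mm = liner_thickness_mm,
                 liner_contrast = liner_contrast,
                 burrows = burrows, seed = as.integer(seed)),
            class = "scene_spec")
}

# axis centre of the scene's half-core, in mm
scene_axis_centre <- function(spec) {
  ext <- spec$shape_voxels[1:2] * spec$spacing_mm[1:2]
  rtot <- spec$core_radius_mm + spec$liner_thickness_mm
  c(ext[1] / 2, (ext[2] + rtot) / 2)
}

# unit direction vector from (z_angle, azimuth) in degrees
direction_from_angles <- function(z_angle_deg, azimuth_deg) {
  za <- z_angle_deg * pi / 180; az <- azimuth_deg * pi / 180
  c(cos(za) * cos(az), cos(za) * sin(az), sin(za))
}

# Linear voxel indices whose centres lie within radius r(t) of the segment
# p0 -> p1. `radius_fun(s)` gives the local radius at arc position arc0 + s.
rasterise_segment <- function(dims, spacing, p0, p1, radius_fun, arc0 = 0,
                              rmax = NULL) {
  d <- p1 - p0; L <- sqrt(sum(d^2))
  if (L == 0) return(integer(0))
  d <- d / L
  if (is.null(rmax)) rmax <- max(radius_fun(seq(0, L, length.out = 64)))
  lo <- pmax(1L, ceiling((pmin(p0, p1) - rmax) / spacing + 0.5))
  hi <- pmin(dims, floor((pmax(p0, p1) + rmax) / spacing + 0.5))
  if (any(lo > hi)) return(integer(0))
  ax <- lapply(1:3, function(a) (seq(lo[a], hi[a]) - 0.5) * spacing[a] - p0[a])
  t3 <- outer(outer(d[1] * ax[[1]], d[2] * ax[[2]], "+"), d[3] * ax[[3]], "+")
  w2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  perp2 <- pmax(w2 - t3^2, 0)
  inside <- t3 >= 0 & t3 <= L & perp2 <= radius_fun(t3)^2
  if (!any(inside)) return(integer(0))
  lin <- outer(outer(seq(lo[1], hi[1]),
                     (seq(lo[2], hi[2]) - 1L) * dims[1], "+"),
               (seq(lo[3], hi[3]) - 1L) * dims[1] * dims[2], "+")
  lin[inside]
}

# polyline for one burrow (matrix of vertices); straight tubes are 2 vertices
burrow_polylines <- function(b, rng_seed) {
  d0 <- direction_from_angles(b$z_angle_deg, b$azimuth_deg)
  if (b$kind == "straight_tube")
    return(list(rbind(b$anchor_mm, b$anchor_mm + b$length_mm * d0)))
  with_seed(rng_seed, {
    step <- 1.5
    walk <- function(p, d, len) {
      n <- max(2L, ceiling(len / step))
      pts <- matrix(0, n + 1, 3); pts[1, ] <- p
      for (i in seq_len(n)) {
        d <- d + rnorm(3, 0, 0.22); d <- d / sqrt(sum(d^2))
        pts[i + 1, ] <- pts[i, ] + step * d
      }
      pts
    }
    trunk <- walk(b$anchor_mm, d0, b$length_mm)
    out <- list(trunk)
    if (b$n_branches > 0) {
      at <- sample(seq_len(nrow(trunk) - 1), b$n_branches, replace = TRUE)
      for (i in at) {
        dd <- trunk[i + 1, ] - trunk[i, ]; dd <- dd / sqrt(sum(dd^2))
        dd <- dd + rnorm(3, 0, 0.9); dd <- dd / sqrt(sum(dd^2))
        out[[length(out) + 1]] <-
          walk(trunk[i, ], dd, runif(1, 0.15, 0.35) * b$length_mm)
      }
    }
    out
  })
}

# rasterise one burrow; returns sorted unique linear indices
rasterise_burrow <- function(b, dims, spacing, rng_seed) {
  r0 <- b$diameter_mm / 2
  lambda <- max(8 * r0, 2.5)  # pinch-and-swell wavelength
  polys <- burrow_polylines(b, rng_seed)
  idx <- integer(0)
  for (pl in polys) {
    arc <- c(0, cumsum(sqrt(rowSums(diff(pl)^2))))
    for (i in seq_len(nrow(pl) - 1)) {
      a0 <- arc[i]
      rf <- if (b$modulation_amplitude > 0)
        function(s) r0 * (1 + b$modulation_amplitude * sin(2 * pi * (a0 + s) / lambda))
      else function(s) rep(r0, length(s))
      idx <- c(idx, rasterise_segment(dims, spacing, pl[i, ], pl[i + 1, ],
                                      rf, rmax = r0 * (1 + b$modulation_amplitude)))
    }
  }
  sort(unique(idx))
}

#' Generate a synthetic core CT volume with ground truth
#'
#' Rasterises a [scene_spec()] into an attenuation volume and a ground-truth
#' label volume. The half-core interior is `host_mean` plus i.i.d. Gaussian
#' noise of sd `host_sigma`; the liner shell sits at
#' `host_mean + liner_contrast` (plus the same noise); air is constant at
#' `host_mean - 10 * host_sigma`. Each burrow's voxels (centre-in-tube
#' rasterisation) are set to `host_mean + contrast * host_sigma` before noise
#' is added. The same spec and seed always reproduce the identical volume.
#'
#' Burrows extending outside the half-core are clipped to it with a warning;
#' a burrow with no voxels left after clipping is an error. Overlaps between
#' burrows are resolved in favour of the earlier-listed burrow.
#'
#' @param spec a [scene_spec()].
#' @return A list with elements `volume` (a [core_volume()]) and `truth`,
#'   itself a list of `label_volume` (one label per burrow, in listed order)
#'   and `table` (data frame of true per-burrow volume_mm3, voxel_count,
#'   z_angle_deg, diameter_mm, length_mm, contrast, clipped).
#' @export
generate_core <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  dims <- spec$shape_voxels; sp <- spec$spacing_mm
  ctr <- scene_axis_centre(spec)
  cc <- voxel_centres_mm(dims, sp)
  r2d <- sqrt(outer((cc[[1]] - ctr[1])^2, (cc[[2]] - ctr[2])^2, "+"))
  side <- outer(rep(TRUE, dims[1]), cc[[2]] <= ctr[2], "&")
  core2d <- r2d <= spec$core_radius_mm & side
  liner2d <- r2d > spec$core_radius_mm &
    r2d <= spec$core_radius_mm + spec$liner_thickness_mm & side
  if (!any(core2d)) stop("core cross-section is empty")

  base2d <- matrix(spec$host_mean - 10 * spec$host_sigma, dims[1], dims[2])
  base2d[core2d] <- spec$host_mean
  base2d[liner2d] <- spec$host_mean + spec$liner_contrast
  data <- array(base2d, dim = dims)

  incore3d_idx <- which(array(core2d | liner2d, dim = dims))
  noise <- with_seed(spec$seed, rnorm(length(incore3d_idx), 0, spec$host_sigma))

  labels <- array(0L, dim = dims)
  core3d <- array(core2d, dim = dims)
  tab <- vector("list", length(spec$burrows))
  for (i in seq_along(spec$burrows)) {
    b <- spec$burrows[[i]]
    idx <- rasterise_burrow(b, dims, sp,
                            (spec$seed %% 1000000L) + 7919L * i)
    n_raw <- length(idx)
    idx <- idx[core3d[idx]]
    if (length(idx) < n_raw)
      warning(sprintf("burrow %d clipped to the core (%d of %d voxels kept)",
                      i, length(idx), n_raw))
    if (length(idx) == 0)
      stop(sprintf("burrow %d has no voxels inside the core after clipping", i))
    free <- labels[idx] == 0L
    labels[idx[free]] <- i
    data[idx[free]] <- spec$host_mean + b$contrast * spec$host_sigma
    nvox <- sum(free)
    tab[[i]] <- data.frame(
      id = i, kind = b$kind, voxel_count = nvox,
      volume_mm3 = nvox * prod(sp),
      z_angle_deg = b$z_angle_deg, diameter_mm = b$diameter_mm,
      length_mm = b$length_mm, contrast = b$contrast,
      clipped = length(idx) < n_raw)
  }
  data[incore3d_idx] <- data[incore3d_idx] + noise

  truth_table <- if (length(tab)) do.call(rbind, tab) else
    data.frame(id = integer(), kind = character(), voxel_count = integer(),
               volume_mm3 = numeric(), z_angle_deg = numeric(),
               diameter_mm = numeric(), length_mm = numeric(),
               contrast = numeric(), clipped = logical())
  list(volume = core_volume(data, sp,
                            meta = list(source = "ichnoCT simulator",
                                        seed = spec$seed,
                                        core_radius_mm = spec$core_radius_mm,
                                        axis_centre_mm = ctr)),
       truth = list(label_volume = label_volume(labels, sp),
                    table = truth_table))
}

# minimum distance between segments p0-p1 and q0-q1 (Eberly's algorithm)
segment_distance <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0; d2 <- q1 - q0; r <- p0 - q0
  a <- sum(d1^2); e <- sum(d2^2); f <- sum(d2 * r)
  if (a == 0 && e == 0) return(sqrt(sum(r^2)))
  if (a == 0) { s <- 0; t <- min(max(f / e, 0), 1) }
  else {
    cc <- sum(d1 * r)
    if (e == 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
    else {
      b <- sum(d1 * d2); den <- a * e - b^2
      s <- if (den != 0) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  sqrt(sum((p0 + s * d1 - (q0 + t * d2))^2))
}

# Sample disjoint straight tubes inside the trimmed half-core.
# All geometric quantities in mm. Returns a list of burrow_spec.
place_disjoint_tubes <- function(n, diameter_range, length_range,
                                 z_angle_range, contrast_range,
                                 spec_shape, spacing, core_radius, rim,
                                 liner_thickness, z_band_mm = NULL,
                                 max_tries = 8000) {
  ext <- spec_shape[1:2] * spacing[1:2]
  rtot <- core_radius + liner_thickness
  ctr <- c(ext[1] / 2, (ext[2] + rtot) / 2)
  zmax <- spec_shape[3] * spacing[3]
  zlim <- if (is.null(z_band_mm)) c(0, zmax) else z_band_mm
  margin <- 2 * max(spacing)
  segs <- list(); specs <- list()
  ok_point <- function(p, r) {
    rad <- sqrt(sum((p[1:2] - ctr)^2))
    rad + r <= core_radius - rim - margin &&
      p[2] + r <= ctr[2] - rim - margin &&
      p[3] - r >= zlim[1] + margin && p[3] + r <= zlim[2] - margin
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      dia <- runif(1, diameter_range[1], diameter_range[2])
      len <- runif(1, length_range[1], length_range[2])
      za <- runif(1, z_angle_range[1], z_angle_range[2])
      az <- runif(1, 0, 360)
      d <- direction_from_angles(za, az)
      p0 <- c(ctr[1] + runif(1, -core_radius, core_radius),
              ctr[2] + runif(1, -core_radius, 0),
              runif(1, zlim[1], zlim[2]))
      p1 <- p0 + len * d
      r <- dia / 2
      if (!ok_point(p0, r) || !ok_point(p1, r) ||
          !ok_point((p0 + p1) / 2, r)) next
      clash <- FALSE
      for (j in seq_along(segs)) {
        s <- segs[[j]]
        if (segment_distance(p0, p1, s$p0, s$p1) <
            r + s$r + 2 * max(spacing)) { clash <- TRUE; break }
      }
      if (clash) next
      segs[[length(segs) + 1]] <- list(p0 = p0, p1 = p1, r = r)
      specs[[length(specs) + 1]] <- burrow_spec(
        "straight_tube", diameter_mm = dia, length_mm = len,
        z_angle_deg = za, azimuth_deg = az, anchor_mm = p0,
        contrast = runif(1, contrast_range[1], contrast_range[2]))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place burrow %d after %d tries", i, max_tries))
  }
  specs
}

#' Named preset scenes
#'
#' Ready-made [scene_spec()]s emulating characteristic downcore ichnofabrics:
#' \describe{
#'   \item{tiny_vertical}{sub-millimetre steeply inclined tubes
#'     (Trichichnus-like): diameters 0.5-1 mm, z-angles >= 75 deg.}
#'   \item{thick_horizontal}{large sub-horizontal tubes (> 0.5 cm diameter,
#'     Thalassinoides-like).}
#'   \item{mixed}{four 10-cm depth bands alternating between
#'     vertical-dominated and horizontal-dominated burrow populations; the
#'     true band classes are attached as `attr(spec, "bands")`.}
#'   \item{branched}{pinch-and-swell branched networks of sub-millimetre
#'     tunnels (Virgaichnus-like).}
#' }
#'
#' @param name preset name.
#' @param seed integer seed; the same name and seed always return the
#'   identical spec.
#' @return A [scene_spec()] (for `"mixed"` with a `bands` attribute: a data
#'   frame of top_cm, base_cm, klass).
#' @export
preset_scene <- function(name = c("tiny_vertical", "thick_horizontal",
                                  "mixed", "branched"), seed = 1L) {
  if (!is.character(name) || !name[1] %in%
      c("tiny_vertical", "thick_horizontal", "mixed", "branched"))
    stop('unknown preset; available: "tiny_vertical", "thick_horizontal", ',
         '"mixed", "branched"')
  name <- name[1]
  seed <- as.integer(seed)
  sp <- c(0.351, 0.351, 0.5)
  shape <- c(192L, 112L, if (name == "mixed") 800L else 300L)
  R <- 31; rim <- 2; lt <- 1.5
  burrows <- with_seed(seed, switch(name,
    tiny_vertical = place_disjoint_tubes(
      25, c(0.5, 1.0), c(60, 130), c(75, 90), c(8, 8),
      shape, sp, R, rim, lt),
    thick_horizontal = place_disjoint_tubes(
      8, c(6, 8), c(25, 40), c(0, 10), c(8, 8),
      shape, sp, R, rim, lt),
    branched = {
      anchors <- place_disjoint_tubes(6, c(6, 6), c(45, 55), c(30, 70),
                                      c(8, 8), shape, sp, R, rim, lt)
      lapply(anchors, function(a) burrow_spec(
        "branched_network", diameter_mm = 0.8, length_mm = a$length_mm,
        z_angle_deg = a$z_angle_deg, azimuth_deg = a$azimuth_deg,
        anchor_mm = a$anchor_mm, contrast = 8,
        modulation_amplitude = 0.35, n_branches = 8L))
    },
    mixed = {
      band_mm <- 100
      out <- list()
      for (k in 0:3) {
        zb <- c(k * band_mm, (k + 1) * band_mm)
        out <- c(out, if (k %% 2 == 0)
          place_disjoint_tubes(10, c(2, 3), c(65, 80), c(80, 90), c(8, 8),
                               shape, sp, R, rim, lt, z_band_mm = zb)
        else
          place_disjoint_tubes(12, c(4, 5.5), c(22, 35), c(0, 8), c(8, 8),
                               shape, sp, R, rim, lt, z_band_mm = zb))
      }
      out
    }))
  spec <- scene_spec(shape, sp, core_radius_mm = R, rim_mm = rim,
                     liner_thickness_mm = lt, burrows = burrows, seed = seed)
  if (name == "mixed")
    attr(spec, "bands") <- data.frame(
      top_cm = c(0, 10, 20, 30), base_cm = c(10, 20, 30, 40),
      klass = c("V", "H", "V", "H"))
  spec
}

#' Random disjoint-tube scene
#'
#' Draws a scene of disjoint straight tubes with uniformly random
#' orientations, for segmentation- and orientation-recovery experiments.
#' Defaults correspond to clearly resolvable pyritised fills: diameters of
#' several voxels and strong attenuation contrast.
#'
#' @param seed integer seed (determines burrow placement and, downstream,
#'   the noise realisation).
#' @param n_burrows number of tubes; default drawn uniformly from 10..30.
#' @param contrast_range per-burrow contrast range in host-noise sigma units.
#' @param diameter_range_mm,length_range_mm tube size ranges.
#' @param z_angle_range_deg orientation range (degrees above horizontal).
#' @param shape_voxels grid size.
#' @return A [scene_spec()].
#' @export
random_scene <- function(seed, n_burrows = NULL, contrast_range = c(6, 10),
                         diameter_range_mm = c(1.5, 3),
                         length_range_mm = c(15, 60),
                         z_angle_range_deg = c(0, 90),
                         shape_voxels = c(256L, 128L, 400L)) {
  seed <- as.integer(seed)
  sp <- c(0.351, 0.351, 0.5); R <- 31; rim <- 2; lt <- 1.5
  burrows <- with_seed(seed, {
    n <- if (is.null(n_burrows)) sample(10:30, 1) else n_burrows
    place_disjoint_tubes(n, diameter_range_mm, length_range_mm,
                         z_angle_range_deg, contrast_range,
                         shape_voxels, sp, R, rim, lt)
  })
  scene_spec(shape_voxels, sp, core_radius_mm = R, rim_mm = rim,
             liner_thickness_mm = lt, burrows = burrows, seed = seed)
}
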