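# Shared fixtures and independent oracles for the test suite.
# Small scenes: 96 x 56 x nz grid, 14 mm core radius, 1.5 mm liner.

SMALL_SP <- c(0.351, 0.351, 0.5)

small_scene <- function(burrows, seed = 1L, nz = 80L, host_sigma = 25) {
  scene_spec(c(96L, 56L, nz), SMALL_SP, core_radius_mm = 14, rim_mm = 2,
             host_sigma = host_sigma, liner_thickness_mm = 1.5,
             burrows = burrows, seed = seed)
}

# axis centre of the small scene's half-core (mm)
small_centre <- function(nz = 80L) {
  ext <- c(96, 56) * SMALL_SP[1:2]
  c(ext[1] / 2, (ext[2] + 14 + 1.5) / 2)
}

# a tube through the small core's interior at a given orientation
small_tube <- function(z_angle_deg, azimuth_deg = 0, diameter_mm = 2,
                       length_mm = 20, contrast = 8, nz = 80L,
                       anchor = NULL) {
  ctr <- small_centre(nz)
  d <- ichnoCT:::direction_from_angles(z_angle_deg, azimuth_deg)
  if (is.null(anchor))
    anchor <- c(ctr[1], ctr[2] - 7, nz * SMALL_SP[3] / 2) - d * length_mm / 2
  burrow_spec("straight_tube", diameter_mm = diameter_mm,
              length_mm = length_mm, z_angle_deg = z_angle_deg,
              azimuth_deg = azimuth_deg, anchor_mm = anchor,
              contrast = contrast)
}

# generate + preprocess in one go
prep_scene <- function(spec, rim_mm = 2) {
  sc <- generate_core(spec)
  geom <- fit_core_geometry(sc$volume)
  vol <- remove_liner_and_rim(sc$volume, geom, rim_mm)
  list(volume = vol, truth = sc$truth, geometry = geom)
}

# independent oracle: count voxel centres inside the analytic cylinder
# p0 + t*d (t in [0, L]), radius r; plain loops over the whole grid
brute_cylinder_count <- function(p0, d, L, r, dims, spacing) {
  cnt <- 0L
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      w <- c((i - 0.5) * spacing[1], (j - 0.5) * spacing[2],
             (k - 0.5) * spacing[3]) - p0
      t <- sum(w * d)
      if (t < 0 || t > L) next
      if (sum(w^2) - t^2 <= r^2) cnt <- cnt + 1L
    }
  cnt
}

# independent oracle: connected-component labelling by BFS in plain R
brute_flood_fill <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, ]
  labels <- array(0L, dim = d)
  nxt <- 0L
  for (s in which(mask & labels == 0L)) {
    if (labels[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    labels[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ai <- arrayInd(v, d)
      for (o in seq_len(nrow(off))) {
        p <- ai + unlist(off[o, ])
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# are two labelings identical up to a relabelling (bijection of labels)?
labels_match_up_to_permutation <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  nz <- a > 0L
  pairs <- unique(cbind(a[nz], b[nz]))
  !any(duplicated(pairs[, 1])) && !any(duplicated(pairs[, 2]))
}

# match each recovered component to the truth label with maximal overlap;
# returns data.frame(recovered, truth, overlap_voxels)
match_components <- function(recovered_labels, truth_labels) {
  rl <- if (inherits(recovered_labels, "label_volume"))
    recovered_labels$labels else recovered_labels
  tl <- if (inherits(truth_labels, "label_volume"))
    truth_labels$labels else truth_labels
  idx <- which(rl > 0L)
  if (!length(idx))
    return(data.frame(recovered = integer(), truth = integer(),
                      overlap_voxels = integer()))
  tab <- table(recovered = rl[idx], truth = tl[idx])
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  tab <- tab[tab$truth != "0" & tab$Freq > 0, ]
  out <- do.call(rbind, lapply(split(tab, tab$recovered), function(g)
    g[which.max(g$Freq), ]))
  data.frame(recovered = as.integer(out$recovered),
             truth = as.integer(out$truth),
             overlap_voxels = out$Freq)
}
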