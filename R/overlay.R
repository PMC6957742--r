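#' Overlay rendering style
#'
#' @param color_mode colour burrows `"by_component"`, `"by_orientation"` or
#'   `"by_size"`.
#' @param alpha blend opacity of the burrow colours in (0, 1].
#' @param projection `"slab_face"` (project along the face normal, i.e. the
#'   y axis, matching archive-half photographs) or
#'   `"max_intensity_lateral"` (along x).
#' @return An object of class `overlay_style`.
#' @export
overlay_style <- function(color_mode = c("by_component", "by_orientation",
                                         "by_size"),
                          alpha = 0.8,
                          projection = c("slab_face",
                                         "max_intensity_lateral")) {
  color_mode <- match.arg(color_mode)
  projection <- match.arg(projection)
  stopifnot(alpha > 0, alpha <= 1)
  structure(list(color_mode = color_mode, alpha = alpha,
                 projection = projection), class = "overlay_style")
}

# fixed categorical palette, cycled deterministically over component ids
OVERLAY_PALETTE <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
                     "#FFFF33", "#A65628", "#F781BF", "#66C2A5", "#FC8D62",
                     "#8DA0CB", "#E78AC3")

#' Project segmented burrows over the core image
#'
#' Projects the labelled burrow voxels along the chosen axis onto the core
#' face (nearest-to-face label wins where components overlap in
#' projection), alpha-blends their colours over the projected grayscale
#' core image and returns the blended raster. Rendering is a pure function
#' of its inputs.
#'
#' @param volume a [core_volume()].
#' @param labels a congruent [label_volume()].
#' @param components burrow table (needed for `by_orientation` /
#'   `by_size` colour modes).
#' @param style an [overlay_style()].
#' @param file optional PNG path; if given, the raster is written with a
#'   depth axis in cm and a colour legend.
#' @return RGB raster array of dimension (n_depth, n_across, 3) in
#'   \[0, 1\], depth increasing down the rows; attribute `legend` maps
#'   colours to components/classes.
#' @export
render_overlay <- function(volume, labels, components = NULL,
                           style = overlay_style(), file = NULL) {
  stopifnot(inherits(volume, "core_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(labels$labels), dim(volume$data)))
    stop("labels and volume shapes differ")
  axis <- if (style$projection == "slab_face") 2L else 1L
  keep <- c(setdiff(1:2, axis), 3L)
  mask <- retained_mask(volume)
  vals <- volume$data
  vals[!mask] <- NA
  base <- apply(vals, keep, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  rng <- range(base, na.rm = TRUE)
  base01 <- (base - rng[1]) / max(diff(rng), 1e-12)
  base01[is.na(base01)] <- 0

  proj <- matrix(0L, nrow = dim(base)[1], ncol = dim(base)[2])
  for (j in seq_len(dim(labels$labels)[axis])) {
    sl <- if (axis == 2L) labels$labels[, j, ] else labels$labels[j, , ]
    nz <- sl > 0L
    proj[nz] <- sl[nz]
  }

  k <- n_labels(labels)
  comp_col <- function(ids) {
    switch(style$color_mode,
      by_component = OVERLAY_PALETTE[(ids - 1L) %% length(OVERLAY_PALETTE) + 1L],
      by_orientation = {
        if (is.null(components)) stop("components table needed for by_orientation")
        cls <- components$orientation_class[match(ids, components$id)]
        ifelse(is.na(cls), "#999999",
               ifelse(cls == "sub_vertical", "#D7191C", "#2C7BB6"))
      },
      by_size = {
        if (is.null(components)) stop("components table needed for by_size")
        cls <- components$size_class[match(ids, components$id)]
        ifelse(cls == "tiny", "#FDAE61", "#5E3C99")
      })
  }
  out <- array(rep(base01, 3), dim = c(dim(base01), 3))
  legend <- NULL
  if (k > 0 && any(proj > 0)) {
    ids <- sort(unique(proj[proj > 0]))
    cols <- comp_col(ids)
    rgbm <- t(grDevices::col2rgb(cols)) / 255
    a <- style$alpha
    for (i in seq_along(ids)) {
      sel <- proj == ids[i]
      for (ch in 1:3)
        out[, , ch][sel] <- (1 - a) * base01[sel] + a * rgbm[i, ch]
    }
    legend <- data.frame(id = ids, colour = cols)
  }
  # orient: rows = depth (z), columns = across-core
  img <- aperm(out, c(2, 1, 3))
  attr(img, "legend") <- legend
  if (!is.null(file)) {
    png::writePNG(pmin(pmax(img, 0), 1), file)
    return(invisible(img))
  }
  img
}

#' Downcore orientation strip chart
#'
#' Depth-aligned curves of the per-slice vertical and horizontal volume
#' percentages with the H / V / V-H interval bands behind them.
#'
#' @param profiles a [slice_profiles()] data frame.
#' @param intervals interval table from [classify_intervals()] (optional).
#' @param file optional PNG path (written via [ggplot2::ggsave()]).
#' @return A ggplot object.
#' @export
orientation_strip <- function(profiles, intervals = NULL, file = NULL) {
  p <- ggplot2::ggplot()
  if (nrow(profiles) == 0) {
    p <- p + ggplot2::annotate("text", x = 50, y = 0, label = "no data") +
      ggplot2::labs(x = "volume-%", y = "depth (cm)")
  } else {
    if (!is.null(intervals) && nrow(intervals))
      p <- p + ggplot2::geom_rect(
        data = intervals,
        ggplot2::aes(ymin = top_cm, ymax = base_cm,
                     fill = klass),
        xmin = -Inf, xmax = Inf, alpha = 0.25) +
        ggplot2::scale_fill_manual(
          values = c(H = "#2C7BB6", V = "#D7191C", `V/H` = "#BDBDBD"),
          name = "interval")
    nonempty <- profiles[profiles$fill_voxels > 0, ]
    p <- p +
      ggplot2::geom_path(data = nonempty,
                         ggplot2::aes(x = pct_vertical,
                                      y = depth_cm,
                                      linetype = "vertical")) +
      ggplot2::geom_path(data = nonempty,
                         ggplot2::aes(x = pct_horizontal,
                                      y = depth_cm,
                                      linetype = "horizontal")) +
      ggplot2::scale_linetype_manual(
        values = c(vertical = "solid", horizontal = "22"),
        name = "orientation") +
      ggplot2::xlim(0, 100)
  }
  p <- p + ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "volume-% of segmented fills", y = "depth (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(file))
    ggplot2::ggsave(file, p, width = 4, height = 8, dpi = 150)
  p
}
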