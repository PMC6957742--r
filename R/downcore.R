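#' Per-slice orientation and bioturbation profile
#'
#' For every CT slice, tallies the segmented fill voxels by the orientation
#' class of the component they belong to and expresses them as volume
#' percentages of all (classed) fill voxels in that slice, plus the
#' bioturbated fraction `100 * fill_voxels / retained_voxels`. Degenerate
#' components (undefined z-angle) are excluded from the orientation
#' percentages.
#'
#' @param labels a [label_volume()] of burrow components.
#' @param components burrow table from [parameterise_components()]; every
#'   nonzero label must have a row.
#' @param volume the matching [core_volume()]; its mask defines the
#'   retained voxels per slice.
#' @return Data frame of class `slice_profiles`: slice_index, depth_cm,
#'   pct_vertical, pct_horizontal, fill_voxels, vertical_voxels,
#'   horizontal_voxels, retained_voxels, bioturbated_pct.
#' @export
slice_profiles <- function(labels, components, volume) {
  stopifnot(inherits(labels, "label_volume"), inherits(volume, "core_volume"),
            identical(dim(labels$labels), dim(volume$data)))
  d <- dim(labels$labels)
  k <- n_labels(labels)
  present <- sort(unique(as.vector(labels$labels)))
  present <- present[present > 0]
  missing <- setdiff(present, components$id)
  if (length(missing))
    stop("label(s) without a component record: ",
         paste(missing, collapse = ", "))
  is_vert <- is_horiz <- rep(FALSE, max(k, 1))
  if (k > 0 && nrow(components)) {
    cls <- components$orientation_class[match(seq_len(k), components$id)]
    is_vert[which(cls == "sub_vertical")] <- TRUE
    is_horiz[which(cls == "sub_horizontal")] <- TRUE
  }
  mask <- retained_mask(volume)
  nz <- d[3]
  fill <- vert <- horiz <- ret <- integer(nz)
  for (z in seq_len(nz)) {
    sl <- labels$labels[, , z]
    cnt <- tabulate(sl, nbins = max(k, 1))
    fill[z] <- sum(cnt)
    vert[z] <- sum(cnt[is_vert])
    horiz[z] <- sum(cnt[is_horiz])
    ret[z] <- sum(mask[, , z])
  }
  classed <- vert + horiz
  out <- data.frame(
    slice_index = seq_len(nz),
    depth_cm = slice_depths_cm(volume, nz),
    pct_vertical = ifelse(classed > 0, 100 * vert / classed, 0),
    pct_horizontal = ifelse(classed > 0, 100 * horiz / classed, 0),
    fill_voxels = fill, vertical_voxels = vert, horizontal_voxels = horiz,
    retained_voxels = ret,
    bioturbated_pct = ifelse(ret > 0, 100 * fill / ret, 0))
  class(out) <- c("slice_profiles", class(out))
  out
}

# windowed moving sum with shrinking windows at the section ends
moving_window_sum <- function(x, half_n) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half_n, 1L)
  hi <- pmin(seq_len(n) + half_n, n)
  cs[hi + 1] - cs[lo]
}

#' Classify H / V / V-H intervals downcore
#'
#' Smooths the orientation profile with a centred moving window of width
#' `window_cm` (volume-weighted: ratio of windowed vertical-voxel and
#' classed-voxel sums), calls each depth `V` when the smoothed vertical
#' share is at least `dominance` percent, `H` when at most `100 -
#' dominance`, and `V/H` otherwise; slices whose window holds no fill
#' inherit the nearest preceding class (or the following one at the section
#' top). Runs of equal class are merged into intervals that tile the
#' section exactly.
#'
#' @param profiles a [slice_profiles()] data frame, ordered by depth.
#' @param window_cm smoothing window in cm (default 2); must be at least
#'   one slice spacing.
#' @param dominance dominance threshold in percent (default 60).
#' @return Data frame of intervals: top_cm, base_cm, klass (`"H"`, `"V"` or
#'   `"V/H"`).
#' @export
classify_intervals <- function(profiles, window_cm = 2.0, dominance = 60.0) {
  stopifnot(nrow(profiles) > 0, !is.unsorted(profiles$depth_cm))
  dz_cm <- if (nrow(profiles) > 1) stats::median(diff(profiles$depth_cm)) else
    window_cm
  if (window_cm < dz_cm)
    stop(sprintf("window_cm (%.3g) is below the slice spacing (%.3g cm)",
                 window_cm, dz_cm))
  half_n <- max(1L, floor(window_cm / dz_cm / 2))
  wv <- moving_window_sum(profiles$vertical_voxels, half_n)
  wc <- moving_window_sum(profiles$vertical_voxels +
                            profiles$horizontal_voxels, half_n)
  sm <- ifelse(wc > 0, 100 * wv / wc, NA_real_)
  klass <- ifelse(is.na(sm), NA_character_,
                  ifelse(sm >= dominance, "V",
                         ifelse(sm <= 100 - dominance, "H", "V/H")))
  if (all(is.na(klass))) klass[] <- "V/H"
  # inherit: carry the last class forward, then backward over a leading gap
  for (i in seq_along(klass))
    if (is.na(klass[i]) && i > 1) klass[i] <- klass[i - 1]
  for (i in rev(seq_along(klass)))
    if (is.na(klass[i]) && i < length(klass)) klass[i] <- klass[i + 1]
  edges_cm <- c(profiles$depth_cm - dz_cm / 2,
                profiles$depth_cm[nrow(profiles)] + dz_cm / 2)
  runs <- rle(klass)
  stops <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  data.frame(top_cm = edges_cm[starts], base_cm = edges_cm[stops + 1L],
             klass = runs$values)
}

#' Default bioturbated-percent to BI grade bands
#'
#' Monotone mapping from the bioturbated volume percentage to the 0-6
#' Bioturbation Index: 0% is grade 0 (no bioturbation); (0, 4\%\] grade 1;
#' (4, 30\%\] grade 2; (30, 60\%\] grade 3; (60, 90\%\] grade 4;
#' (90, 99.9\%\] grade 5; above 99.9% grade 6 (completely bioturbated).
#'
#' @return Data frame with columns `bi` (0:6) and `max_pct` (upper band
#'   edges).
#' @export
bi_bands <- function() {
  data.frame(bi = 0:6, max_pct = c(0, 4, 30, 60, 90, 99.9, 100))
}

bi_grade <- function(pct, bands) {
  if (any(diff(bands$max_pct) <= 0) || any(diff(bands$bi) <= 0))
    stop("BI bands must be strictly monotone")
  vapply(pct, function(p) {
    if (p <= bands$max_pct[1]) return(bands$bi[1])
    bands$bi[which(p <= bands$max_pct)[1]]
  }, numeric(1))
}

#' Bioturbation Index log from CT profiles
#'
#' Averages the per-slice bioturbated percentage over consecutive depth
#' bins of `bin_cm` and maps the bin means through the grade bands to the
#' 0-6 Bioturbation Index.
#'
#' @param profiles a [slice_profiles()] data frame.
#' @param bin_cm depth bin size in cm (default 2).
#' @param bands monotone percent-to-grade table, see [bi_bands()].
#' @return Data frame of BI records: top_cm, base_cm, mean_pct, bi,
#'   source = `"ct"`.
#' @export
bioturbation_index <- function(profiles, bin_cm = 2.0, bands = bi_bands()) {
  stopifnot(nrow(profiles) > 0, bin_cm > 0)
  top0 <- min(profiles$depth_cm)
  bin <- pmax(1L, 1L + floor((profiles$depth_cm - top0) / bin_cm + 1e-9))
  ub <- sort(unique(bin))
  bin_f <- factor(bin, levels = ub)
  mean_pct <- as.numeric(tapply(profiles$bioturbated_pct, bin_f, mean))
  data.frame(top_cm = top0 + (ub - 1) * bin_cm,
             base_cm = top0 + ub * bin_cm,
             mean_pct = mean_pct,
             bi = bi_grade(mean_pct, bands),
             source = "ct", stringsAsFactors = FALSE)
}

# piecewise-constant resample of a BI log onto new bin boundaries;
# a bin takes the grade of the record covering its midpoint
rebin_bi <- function(log, edges) {
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  i <- findInterval(mids, log$top_cm)
  i[i < 1] <- 1
  out <- log$bi[pmin(i, nrow(log))]
  out[mids < min(log$top_cm) | mids > max(log$base_cm)] <- NA
  out
}

#' Combine CT-derived and 2D-image-derived BI logs
#'
#' Rebins both logs onto the intersection of their depth coverage (bin
#' edges from the union of both logs' boundaries) and takes the per-bin
#' maximum of the two grades; where both grades are at least 1 and the 2D
#' table flags its structures as disjoint from the CT fills, one extra
#' grade is added (capped at 6). The combined grade is never below either
#' input.
#'
#' @param ct BI log from [bioturbation_index()].
#' @param image2d 2D-image ichnology BI log, e.g. from
#'   [read_image2d_table()]: columns top_cm, base_cm, bi and optionally
#'   disjoint_flag.
#' @return Data frame: top_cm, base_cm, bi_ct, bi_image2d, bi,
#'   source = `"combined"`.
#' @export
combine_bi <- function(ct, image2d) {
  stopifnot(all(c("top_cm", "base_cm", "bi") %in% names(ct)),
            all(c("top_cm", "base_cm", "bi") %in% names(image2d)))
  lo <- max(min(ct$top_cm), min(image2d$top_cm))
  hi <- min(max(ct$base_cm), max(image2d$base_cm))
  if (lo >= hi) stop("BI logs have no overlapping depth coverage")
  edges <- sort(unique(c(ct$top_cm, ct$base_cm, image2d$top_cm,
                         image2d$base_cm)))
  edges <- edges[edges >= lo & edges <= hi]
  if (length(edges) < 2) edges <- c(lo, hi)
  b_ct <- rebin_bi(ct, edges)
  b_2d <- rebin_bi(image2d, edges)
  disj <- if ("disjoint_flag" %in% names(image2d)) {
    mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
    i <- pmin(pmax(findInterval(mids, image2d$top_cm), 1), nrow(image2d))
    as.logical(image2d$disjoint_flag[i])
  } else rep(FALSE, length(edges) - 1)
  bi <- pmax(b_ct, b_2d)
  bonus <- !is.na(bi) & b_ct >= 1 & b_2d >= 1 & disj
  bi[bonus] <- pmin(bi[bonus] + 1, 6)
  data.frame(top_cm = utils::head(edges, -1), base_cm = utils::tail(edges, -1),
             bi_ct = b_ct, bi_image2d = b_2d, bi = bi, source = "combined",
             stringsAsFactors = FALSE)
}

#' Downcore analysis of a segmented core
#'
#' Runs [slice_profiles()], [classify_intervals()] and
#' [bioturbation_index()] in one call.
#'
#' @param volume preprocessed [core_volume()].
#' @param segmentation result of [segment_burrows()].
#' @param window_cm,dominance see [classify_intervals()].
#' @param bin_cm,bands see [bioturbation_index()].
#' @return List: `profiles`, `intervals`, `bi`.
#' @export
analyse_downcore <- function(volume, segmentation, window_cm = 2.0,
                             dominance = 60.0, bin_cm = 2.0,
                             bands = bi_bands()) {
  prof <- slice_profiles(segmentation$labels, segmentation$components, volume)
  list(profiles = prof,
       intervals = classify_intervals(prof, window_cm, dominance),
       bi = bioturbation_index(prof, bin_cm, bands))
}
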