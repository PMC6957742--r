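# Minimal DICOM Part-10 support: enough to read a single-frame CT series
# (explicit or implicit VR, little endian) and to write small test series.
# Only the tags the pipeline needs are interpreted; everything else is
# skipped by its declared length. Sequences (SQ) of undefined length are
# not supported.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# VRs we need when parsing implicit-VR files
DCM_TAG_VR <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0020,000D" = "UI",
  "0020,000E" = "UI", "0020,0013" = "IS", "0020,0032" = "DS",
  "0020,1041" = "DS", "0018,0050" = "DS", "0018,0088" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0010" = "US",
  "0028,0011" = "US", "0028,0030" = "DS", "0028,0100" = "US",
  "0028,0101" = "US", "0028,0102" = "US", "0028,0103" = "US",
  "0028,1052" = "DS", "0028,1053" = "DS", "7FE0,0010" = "OW")

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])
}
dcm_u32 <- function(raw, pos) {
  sum(as.numeric(raw[pos:(pos + 3)]) * c(1, 256, 65536, 16777216))
}

# parse one dataset starting at byte offset `pos` (1-based); returns a named
# list of raw values keyed by "GGGG,EEEE" plus their VRs
dcm_parse <- function(raw, pos, explicit, file, stop_group = NULL) {
  out <- list(); vrs <- character()
  n <- length(raw)
  while (pos + 7 <= n + 1 && pos <= n) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2)
    if (!is.null(stop_group) && group != stop_group) break
    pos <- pos + 4
    key <- dcm_tag_key(group, elem)
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1)]); pos <- pos + 2
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- dcm_u32(raw, pos + 2); pos <- pos + 6
      } else {
        len <- dcm_u16(raw, pos); pos <- pos + 2
      }
    } else {
      vr <- if (key %in% names(DCM_TAG_VR)) DCM_TAG_VR[[key]] else "UN"
      len <- dcm_u32(raw, pos); pos <- pos + 4
    }
    if (len >= 4294967295)
      stop(sprintf("%s: undefined-length element %s is not supported",
                   file, key))
    if (len > 0 && pos + len - 1 > n)
      stop(sprintf("%s: element %s overruns the file", file, key))
    out[[key]] <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
    vrs[key] <- vr
    pos <- pos + len
  }
  attr(out, "vrs") <- vrs
  attr(out, "end") <- pos
  out
}

dcm_string <- function(val) {
  if (is.null(val) || length(val) == 0) return(NA_character_)
  sub(" +$", "", rawToChar(val[val != as.raw(0)]))
}
dcm_numbers <- function(val) {
  s <- dcm_string(val)
  if (is.na(s)) return(numeric(0))
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(val) {
  if (is.null(val)) return(NA_integer_)
  readBin(val, "integer", length(val) / 2, size = 2, signed = FALSE,
          endian = "little")
}

dcm_read_file <- function(file) {
  raw <- readBin(file, "raw", file.size(file))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("%s: not a DICOM Part-10 file (missing DICM magic)", file))
  meta <- dcm_parse(raw, 133, explicit = TRUE, file = file, stop_group = 2L)
  ts <- dcm_string(meta[["0002,0010"]])
  if (is.na(ts)) stop(sprintf("%s: missing transfer syntax (0002,0010)", file))
  if (!ts %in% c(DCM_EXPLICIT_LE, DCM_IMPLICIT_LE))
    stop(sprintf("%s: unsupported transfer syntax %s", file, ts))
  ds <- dcm_parse(raw, attr(meta, "end"), explicit = ts == DCM_EXPLICIT_LE,
                  file = file)
  need <- function(key, what) {
    if (is.null(ds[[key]]))
      stop(sprintf("%s: missing required tag (%s) %s", file, key, what))
    ds[[key]]
  }
  rows <- dcm_us(need("0028,0010", "Rows"))[1]
  cols <- dcm_us(need("0028,0011", "Columns"))[1]
  bits <- dcm_us(need("0028,0100", "BitsAllocated"))[1]
  if (bits != 16L)
    stop(sprintf("%s: only 16-bit pixel data is supported (BitsAllocated %d)",
                 file, bits))
  signed <- identical(dcm_us(ds[["0028,0103"]])[1], 1L)
  px_raw <- need("7FE0,0010", "PixelData")
  px <- readBin(px_raw, "integer", rows * cols, size = 2, signed = signed,
                endian = "little")
  slope <- dcm_numbers(ds[["0028,1053"]]); if (!length(slope)) slope <- 1
  icpt <- dcm_numbers(ds[["0028,1052"]]); if (!length(icpt)) icpt <- 0
  ipp <- dcm_numbers(ds[["0020,0032"]])
  list(file = file,
       series_uid = dcm_string(ds[["0020,000E"]]),
       instance = suppressWarnings(as.integer(dcm_string(ds[["0020,0013"]]))),
       pixel_spacing = dcm_numbers(ds[["0028,0030"]]),
       slice_spacing = c(dcm_numbers(ds[["0018,0088"]]),
                         dcm_numbers(ds[["0018,0050"]]))[1],
       z_pos = if (length(ipp) >= 3) ipp[3] else
         dcm_numbers(ds[["0020,1041"]])[1],
       rows = rows, cols = cols,
       # stream is x-fastest within each row: matrix with nrow = cols is (x, y)
       pixels = matrix(px * slope[1] + icpt[1], nrow = cols))
}

#' Read a DICOM series into a core volume
#'
#' Reads every `.dcm` file in a directory (one single-frame slice each),
#' checks they belong to one series with congruent shapes, sorts them by
#' slice position into ascending z, applies the rescale slope/intercept and
#' takes the voxel spacing from the pixel-spacing and slice-position tags.
#' Explicit- and implicit-VR little-endian transfer syntaxes are supported.
#'
#' @param directory path containing the series.
#' @param depth_origin_cm downcore depth of the first (shallowest) slice.
#' @return A [core_volume()].
#' @export
read_dicom_series <- function(directory, depth_origin_cm = 0) {
  files <- list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files)) stop("no .dcm files in ", directory)
  slices <- lapply(sort(files), dcm_read_file)
  uids <- vapply(slices, function(s) s$series_uid, character(1))
  if (length(unique(uids)) != 1)
    stop("directory mixes several series UIDs: ",
         paste(unique(uids), collapse = ", "))
  shp <- vapply(slices, function(s) c(s$rows, s$cols), integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent slice shapes in series (first offender: ",
         slices[[which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]]]$file,
         ")")
  ps <- slices[[1]]$pixel_spacing
  if (length(ps) < 2 || any(is.na(ps)))
    stop(sprintf("%s: missing PixelSpacing tag (0028,0030)",
                 slices[[1]]$file))
  zpos <- vapply(slices, function(s) s$z_pos, numeric(1))
  ord <- if (!any(is.na(zpos))) order(zpos) else
    order(vapply(slices, function(s) s$instance, integer(1)))
  slices <- slices[ord]; zpos <- zpos[ord]
  dz <- if (length(slices) > 1 && !any(is.na(zpos)))
    stats::median(diff(zpos)) else slices[[1]]$slice_spacing
  if (is.na(dz) || !length(dz) || dz <= 0)
    stop(sprintf("%s: cannot determine slice spacing ", slices[[1]]$file),
         "(need ImagePositionPatient, SliceLocation or SpacingBetweenSlices)")
  data <- array(0, dim = c(slices[[1]]$cols, slices[[1]]$rows,
                           length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$pixels
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  core_volume(data, spacing_mm = c(ps[2], ps[1], dz),
              depth_origin_cm = depth_origin_cm,
              meta = list(source = directory,
                          series_uid = slices[[1]]$series_uid))
}

dcm_pad <- function(x, pad = as.raw(0)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}
dcm_elem <- function(group, elem, vr, value) {
  tag <- writeBin(as.integer(c(group, elem)), raw(), size = 2,
                  endian = "little")
  if (vr %in% c("OB", "OW")) {
    c(tag, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(length(value)), raw(), size = 4, endian = "little"),
      value)
  } else {
    c(tag, charToRaw(vr),
      writeBin(as.integer(length(value)), raw(), size = 2, endian = "little"),
      value)
  }
}
dcm_str_elem <- function(group, elem, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
  dcm_elem(group, elem, vr, dcm_pad(charToRaw(s), pad))
}
dcm_us_elem <- function(group, elem, v) {
  dcm_elem(group, elem, "US", writeBin(as.integer(v), raw(), size = 2,
                                       endian = "little"))
}

#' Write a core volume as a DICOM series (test fixtures)
#'
#' Writes one explicit-VR little-endian single-frame file per slice, with
#' 16-bit signed pixels. Data must be integer-valued within the int16
#' range; the rescale slope/intercept are written as 1/0.
#'
#' @param volume a [core_volume()] with integer-valued data.
#' @param directory output directory (created if needed).
#' @param series_uid series instance UID; fixed default so fixtures are
#'   deterministic.
#' @return Invisibly, the written file paths.
#' @export
write_dicom_series <- function(volume, directory,
                               series_uid = "2.25.424242.1") {
  stopifnot(inherits(volume, "core_volume"))
  vals <- volume$data
  if (max(abs(vals - round(vals))) > 1e-6 ||
      min(vals) < -32768 || max(vals) > 32767)
    stop("DICOM writer requires integer-valued data within the int16 range")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vals); sp <- volume$spacing_mm
  sop_class <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    sop_uid <- paste0(series_uid, ".", k)
    meta_body <- c(
      dcm_str_elem(2L, 2L, "UI", sop_class),
      dcm_str_elem(2L, 3L, "UI", sop_uid),
      dcm_str_elem(2L, 16L, "UI", DCM_EXPLICIT_LE),
      dcm_str_elem(2L, 18L, "UI", "2.25.424242.0.1"))
    meta <- c(dcm_elem(2L, 0L, "UL",
                       writeBin(as.integer(length(meta_body)), raw(),
                                size = 4, endian = "little")),
              meta_body)
    px <- writeBin(as.integer(round(vals[, , k])), raw(), size = 2,
                   endian = "little")
    zmm <- volume$depth_origin_cm * 10 + (k - 1) * sp[3]
    ds <- c(
      dcm_str_elem(8L, 22L, "UI", sop_class),          # (0008,0016)
      dcm_str_elem(8L, 24L, "UI", sop_uid),            # (0008,0018)
      dcm_str_elem(32L, 13L, "UI", paste0(series_uid, ".s")),  # (0020,000D)
      dcm_str_elem(32L, 14L, "UI", series_uid),        # (0020,000E)
      dcm_str_elem(32L, 19L, "IS", as.character(k)),   # (0020,0013)
      dcm_str_elem(32L, 50L, "DS",
                   sprintf("0\\0\\%.6g", zmm)),        # (0020,0032)
      dcm_str_elem(32L, 4161L, "DS", sprintf("%.6g", zmm)),  # (0020,1041)
      dcm_str_elem(24L, 80L, "DS", sprintf("%.6g", sp[3])),  # (0018,0050)
      dcm_str_elem(24L, 136L, "DS", sprintf("%.6g", sp[3])), # (0018,0088)
      dcm_us_elem(40L, 2L, 1L),                        # SamplesPerPixel
      dcm_str_elem(40L, 4L, "CS", "MONOCHROME2"),
      dcm_us_elem(40L, 16L, d[2]),                     # Rows = ny
      dcm_us_elem(40L, 17L, d[1]),                     # Columns = nx
      dcm_str_elem(40L, 48L, "DS",
                   sprintf("%.6g\\%.6g", sp[2], sp[1])),  # PixelSpacing dy\dx
      dcm_us_elem(40L, 256L, 16L), dcm_us_elem(40L, 257L, 16L),
      dcm_us_elem(40L, 258L, 15L), dcm_us_elem(40L, 259L, 1L),
      dcm_str_elem(40L, 4178L, "DS", "0"),             # RescaleIntercept
      dcm_str_elem(40L, 4179L, "DS", "1"),             # RescaleSlope
      dcm_elem(32736L, 16L, "OW", px))
    files[k] <- file.path(directory, sprintf("slice_%04d.dcm", k))
    con <- file(files[k], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(files)
}
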