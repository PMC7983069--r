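#' Two-channel well time series
#'
#' Container for one imaging well: ordered pairs of NAD(P)H and FAD
#' wide-field fluorescence frames with acquisition times and a treatment
#' label. All frames must share dimensions; times must be strictly
#' increasing. Intensities are in arbitrary camera units and must be
#' nonnegative.
#'
#' @param nadh list of numeric matrices, one NAD(P)H frame per time point.
#' @param fad list of numeric matrices, one FAD frame per time point.
#' @param times_h numeric vector of acquisition times in hours.
#' @param treatment treatment-group label (single string).
#' @param well_id well identifier.
#' @return An object of class `well_series`.
#' @export
well_series <- function(nadh, fad, times_h, treatment = "control",
                        well_id = "W1") {
  if (length(nadh) != length(fad) || length(nadh) != length(times_h))
    stop_orx("nadh, fad and times_h must have equal length",
             class = "orx_validation_error")
  if (is.unsorted(times_h, strictly = TRUE))
    stop_orx("times_h must be strictly increasing",
             class = "orx_validation_error")
  for (i in seq_along(nadh)) {
    assert_matrix_image(nadh[[i]], sprintf("NADH frame %d", i))
    assert_matrix_image(fad[[i]], sprintf("FAD frame %d", i))
    assert_same_dim(nadh[[i]], fad[[i]],
                    sprintf("channels of frame %d", i))
    if (i > 1) assert_same_dim(nadh[[i]], nadh[[1]], "frames")
  }
  structure(list(nadh = nadh, fad = fad, times_h = as.numeric(times_h),
                 treatment = as.character(treatment)[1],
                 well_id = as.character(well_id)[1]),
            class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  d <- if (length(x$nadh)) dim(x$nadh[[1]]) else c(0, 0)
  cat(sprintf("well_series '%s' (%s): %d frames of %dx%d, t = %s h\n",
              x$well_id, x$treatment, length(x$nadh), d[1], d[2],
              paste(x$times_h, collapse = ", ")))
  invisible(x)
}

#' @export
length.well_series <- function(x) length(x$nadh)

#' Read a well time series from a manifest
#'
#' The manifest is a CSV file (or data frame) with columns
#' `well`, `time_h`, `channel` (`NADH` or `FAD`), `path` and optionally
#' `treatment`. Every time point must have exactly one frame per channel;
#' frames are returned sorted by time regardless of row order. TIFF files
#' are read with their stored integer range preserved.
#'
#' @param manifest path to a manifest CSV, or a data frame with the columns
#'   above.
#' @param well which well to load (default: the only well present).
#' @return A [well_series].
#' @export
read_well_series <- function(manifest, well = NULL) {
  m <- if (is.data.frame(manifest)) manifest
       else utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("well", "time_h", "channel", "path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_orx("manifest lacks column(s): %s", paste(miss, collapse = ", "),
             class = "orx_io_error")
  wells <- unique(m$well)
  if (is.null(well)) {
    if (length(wells) > 1)
      stop_orx("manifest contains %d wells; pass `well=`", length(wells),
               class = "orx_io_error")
    well <- wells[1]
  }
  m <- m[m$well == well, , drop = FALSE]
  if (!nrow(m)) stop_orx("well '%s' not found in manifest", well,
                         class = "orx_io_error")
  m$channel <- toupper(m$channel)
  key <- paste(m$well, m$time_h, m$channel)
  if (anyDuplicated(key))
    stop_orx("duplicate (well,time,channel) row: %s", key[duplicated(key)][1],
             class = "orx_io_error")
  times <- sort(unique(m$time_h))
  nadh <- vector("list", length(times)); fad <- nadh
  for (i in seq_along(times)) {
    for (ch in c("NADH", "FAD")) {
      row <- m[m$time_h == times[i] & m$channel == ch, , drop = FALSE]
      if (nrow(row) != 1)
        stop_orx("missing %s frame for well %s at t=%g h", ch, well, times[i],
                 class = "orx_io_error")
      if (!file.exists(row$path))
        stop_orx("file not found: %s (well %s, t=%g, %s)", row$path, well,
                 times[i], ch, class = "orx_io_error")
      img <- read_intensity_tiff(row$path)
      if (ch == "NADH") nadh[[i]] <- img else fad[[i]] <- img
    }
  }
  trt <- if ("treatment" %in% names(m)) m$treatment[1] else "unknown"
  well_series(nadh, fad, times, treatment = trt, well_id = well)
}

# TIFF helpers: frames are stored as 16-bit grayscale; the tiff package
# returns [0,1]-scaled data for integer TIFFs, so rescale back to counts.
read_intensity_tiff <- function(path) {
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  storage.mode(x) <- "double"
  x
}

write_intensity_tiff <- function(img, path, bits = 16L) {
  maxv <- 2^bits - 1
  img <- pmin(pmax(round(img), 0), maxv)
  tiff::writeTIFF(img / maxv, path, bits.per.sample = bits)
  invisible(path)
}

#' Write an ORR image as a 32-bit float TIFF
#'
#' TIFF float samples are clamped to `[0, 1]` by the reader, so ORR values
#' are stored with the lossless affine encoding `orr * 0.5 + 0.25`
#' (occupying `[0.25, 0.75]`) and undefined pixels (both channels zero) as
#' the sentinel 0. [read_orr_tiff] inverts the encoding and restores
#' undefined pixels to `NaN`.
#'
#' @param orr numeric ORR matrix (values in `[0,1]`, `NaN` = undefined).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_orr_tiff <- function(orr, path) {
  enc <- orr * 0.5 + 0.25
  enc[is.na(orr)] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_orr_tiff
#' @export
read_orr_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  out <- (x - 0.25) * 2
  out[x == 0] <- NaN
  out
}

#' Write a well series to per-channel TIFF files plus a manifest
#'
#' Frames are written as 16-bit single-plane grayscale TIFFs named
#' `{well}_t{###}_{NADH|FAD}.tif` and indexed by a `manifest.csv` that
#' [read_well_series] can load back.
#'
#' @param series a [well_series].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_well_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(series$nadh)) {
    for (ch in c("NADH", "FAD")) {
      fn <- sprintf("%s_t%03d_%s.tif", series$well_id, i, ch)
      img <- if (ch == "NADH") series$nadh[[i]] else series$fad[[i]]
      write_intensity_tiff(img, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        well = series$well_id, time_h = series$times_h[i], channel = ch,
        path = file.path(dir, fn), treatment = series$treatment,
        stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}
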