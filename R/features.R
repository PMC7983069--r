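# Per-organoid quantification: 12 metabolic + 12 morphological variables.

metabolic_vars <- c("orr_mean", "orr_min", "orr_max", "orr_sd",
                    "nadh_mean", "nadh_min", "nadh_max", "nadh_sd",
                    "fad_mean", "fad_min", "fad_max", "fad_sd")
morphological_vars <- c("area", "perimeter", "solidity", "extent",
                        "eccentricity", "circularity", "feret_min",
                        "feret_max", "axis_minor", "axis_major",
                        "convex_area", "equiv_diameter")

#' Names of the 24 quantified variables
#'
#' @return list with `metabolic` (12) and `morphological` (12) variable
#'   names in their stable output order.
#' @export
feature_variables <- function() {
  list(metabolic = metabolic_vars, morphological = morphological_vars)
}

stat4 <- function(v, prefix) {
  v <- v[!is.na(v)]
  if (!length(v)) {
    out <- rep(NA_real_, 4)
  } else {
    out <- c(mean(v), min(v), max(v), if (length(v) > 1) stats::sd(v) else 0)
  }
  names(out) <- paste0(prefix, c("_mean", "_min", "_max", "_sd"))
  out
}

#' Quantify one organoid region
#'
#' Computes the 24 variables for a single labeled region: mean, minimum,
#' maximum and standard deviation of the ORR, NAD(P)H intensity and FAD
#' intensity over the raw registered pixel values inside the mask (no
#' background subtraction, no smoothing; undefined ORR pixels are excluded
#' from the ORR statistics), plus the 12 morphological descriptors of
#' [region_properties].
#'
#' @param region_mask logical/numeric matrix selecting the region.
#' @param nadh,fad,orr registered, co-cropped images.
#' @return one-row data frame with 24 feature columns plus
#'   `border_touching`, `centroid_y`, `centroid_x`.
#' @export
quantify_organoid <- function(region_mask, nadh, fad, orr) {
  sel <- region_mask != 0
  if (!any(sel))
    stop_orx("empty region", class = "orx_validation_error")
  assert_same_dim(region_mask, nadh, "mask and image")
  rp <- region_properties(matrix(as.integer(sel), nrow(sel), ncol(sel)))
  met <- c(stat4(orr[sel][!is.nan(orr[sel])], "orr"),
           stat4(nadh[sel], "nadh"), stat4(fad[sel], "fad"))
  out <- cbind(as.data.frame(t(met)),
               rp[, morphological_vars, drop = FALSE],
               rp[, c("border_touching", "centroid_y", "centroid_x")])
  rownames(out) <- NULL
  out
}

#' Assemble the long-format feature table
#'
#' One row per (track, frame-with-detection): the 24 variables of
#' [quantify_organoid] keyed by organoid id, well, treatment and time.
#' Track gap frames have no row.
#'
#' @param tracks data frame from [link_tracks].
#' @param masks list of per-frame label matrices.
#' @param series the registered [well_series] the masks were computed on.
#' @param orr_images optional list of precomputed ORR images (computed on
#'   the fly when `NULL`).
#' @return data frame (`feature_table`): keys `organoid_id`, `well`,
#'   `treatment`, `time_h`, `frame`, then 24 feature columns and
#'   `border_touching`.
#' @export
build_feature_table <- function(tracks, masks, series, orr_images = NULL) {
  stopifnot(inherits(series, "well_series"))
  if (is.null(orr_images))
    orr_images <- Map(compute_orr, series$nadh, series$fad)
  rows <- list()
  for (i in seq_len(nrow(tracks))) {
    f <- tracks$frame[i]
    lab <- tracks$label[i]
    mask <- masks[[f]]
    if (!any(mask == lab))
      stop_orx("track %d references missing label %d in frame %d",
               tracks$track_id[i], lab, f, class = "orx_integrity_error")
    q <- quantify_organoid(mask == lab, series$nadh[[f]], series$fad[[f]],
                           orr_images[[f]])
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(organoid_id = tracks$track_id[i], well = series$well_id,
                 treatment = series$treatment, time_h = tracks$time_h[i],
                 frame = f), q)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_feature_table()
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

empty_feature_table <- function() {
  cols <- c("organoid_id", "well", "treatment", "time_h", "frame",
            metabolic_vars, morphological_vars, "border_touching",
            "centroid_y", "centroid_x")
  out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
  names(out) <- cols
  out
}

#' Drop tracks that ever touch the image border
#'
#' Organoids connected to the (post-registration crop) image border are
#' excluded from statistical analysis. The rule is applied per track: if a
#' track's region touches the border at any time point the entire track is
#' dropped, keeping every retained organoid's longitudinal series complete.
#'
#' @param table a feature table from [build_feature_table].
#' @return the filtered table; dropped ids in `attr(,"dropped_tracks")`.
#' @export
exclude_border_tracks <- function(table) {
  if (!nrow(table)) {
    attr(table, "dropped_tracks") <- integer(0)
    return(table)
  }
  bad <- unique(table$organoid_id[table$border_touching > 0])
  out <- table[!(table$organoid_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_tracks") <- bad
  out
}
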