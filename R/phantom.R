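# Synthetic two-channel organoid phantoms with full ground truth.
#
# The generator emulates wide-field one-photon autofluorescence frames:
# blobby organoids (disks with a low-order radial Fourier perturbation so
# circularity stays above the retained-population threshold) on a flat
# medium background, summed-channel signal-to-background ratio drawn from
# [2, 3], solid and hollow phenotypes with opposite core/rim redox
# contrast, per-frame global stage drift, and treatment-dependent growth
# and redox-ratio trajectories over {0, 0.33, 12, 24, 36, 48} h.

#' Treatment trajectory models
#'
#' Per-treatment relative trajectories of mean organoid ORR and area over
#' the imaging schedule, anchored to the reported qualitative course of
#' each agent: untreated controls keep their ORR (multiplier 1 throughout)
#' and grow to +10% area at 48 h; cyanide shows a sharp ORR rise at 20 min
#' (electron-transport-chain inhibition) followed by a decline below
#' baseline, with growth arrest from 12 h; 2-deoxy-glucose declines in both
#' ORR and growth from 12-36 h; cisplatin responds late (48 h); paclitaxel
#' keeps growing until 24 h and falls below control afterwards.
#'
#' @param treatment one of `"control"`, `"cyanide"`, `"2DG"`,
#'   `"cisplatin"`, `"paclitaxel"`.
#' @param times_h time points (hours); multipliers are interpolated
#'   linearly if other times are requested.
#' @return data frame with columns `time_h`, `orr_mult`, `area_mult`.
#' @export
treatment_trajectories <- function(treatment, times_h = c(0, 0.33, 12, 24, 36, 48)) {
  base_t <- c(0, 0.33, 12, 24, 36, 48)
  traj <- switch(treatment,
    control = list(orr = c(1, 1, 1, 1, 1, 1),
                   area = c(1, 1.001, 1.025, 1.05, 1.075, 1.10)),
    cyanide = list(orr = c(1, 1.25, 1.05, 0.95, 0.85, 0.80),
                   area = c(1, 1.001, 1.000, 0.995, 0.99, 0.985)),
    "2DG" = list(orr = c(1, 1.00, 0.99, 0.95, 0.91, 0.89),
                 area = c(1, 1.001, 1.005, 1.00, 0.995, 0.99)),
    cisplatin = list(orr = c(1, 1.00, 1.00, 0.99, 0.96, 0.92),
                     area = c(1, 1.001, 1.02, 1.04, 1.03, 1.005)),
    paclitaxel = list(orr = c(1, 1.00, 0.94, 0.90, 0.87, 0.84),
                      area = c(1, 1.001, 1.02, 1.05, 1.005, 0.97)),
    stop_orx("unknown treatment '%s'", treatment,
             class = "orx_config_error"))
  data.frame(time_h = times_h,
             orr_mult = stats::approx(base_t, traj$orr, times_h)$y,
             area_mult = stats::approx(base_t, traj$area, times_h)$y)
}

#' Phantom configuration
#'
#' Study-condition defaults: 512x512 working-scale frames, 6 time points at
#' {0, 0.33, 12, 24, 36, 48} h, 8 organoids of base radius 25-60 px,
#' summed-channel signal-to-background ratio drawn uniformly from [2, 3],
#' 19% hollow phenotype fraction, solid organoids with an FAD-elevated
#' (ORR-depressed) core and hollow organoids the reverse, global stage
#' drift of 2 px per frame, and Gaussian read noise plus an
#' intensity-proportional shot-noise term.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param times_h acquisition times (hours, strictly increasing).
#' @param n_organoids number of organoids.
#' @param treatment treatment label (see [treatment_trajectories]).
#' @param frac_hollow fraction of hollow-phenotype organoids.
#' @param radius_range base radius range (px); the default 25-60 px at the
#'   512 px working scale is scaled with the frame size. Radii below 18 px
#'   are rejected so every organoid exceeds the 1000 px retention area.
#' @param sbr_range summed-channel signal-to-background ratio range.
#' @param orr solid/hollow rim and core mean ORR levels (unitless).
#' @param background per-channel background intensity (arbitrary units).
#' @param noise `read_sd` (Gaussian, counts) and `shot_scale`
#'   (variance per unit intensity).
#' @param drift_px global `(dy, dx)` translation added per frame step.
#' @param min_gap_px minimum gap between organoid rims at placement.
#' @param margin_px extra placement margin from the frame border.
#' @param seed integer seed; the same config + seed reproduces bit-identical
#'   frames and truth.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(512, 512),
                           times_h = c(0, 0.33, 12, 24, 36, 48),
                           n_organoids = 8,
                           treatment = "control",
                           frac_hollow = 0.19,
                           radius_range = NULL,
                           sbr_range = c(2, 3),
                           orr = list(solid_rim = 0.70, solid_core = 0.52,
                                      hollow_rim = 0.62, hollow_core = 0.80),
                           background = c(nadh = 400, fad = 400),
                           noise = list(read_sd = 25, shot_scale = 1),
                           drift_px = c(2, 2),
                           min_gap_px = 4,
                           margin_px = 10,
                           seed = 1) {
  if (is.null(radius_range))
    radius_range <- pmax(c(25, 60) * min(image_size) / 512, 18)
  if (any(sbr_range <= 1))
    stop_orx("signal-to-background ratio must exceed 1",
             class = "orx_validation_error")
  if (any(radius_range < 18))
    stop_orx("radius_range below 18 px cannot yield area > 1000 px",
             class = "orx_validation_error")
  if (is.unsorted(times_h, strictly = TRUE))
    stop_orx("times_h must be strictly increasing",
             class = "orx_validation_error")
  traj <- treatment_trajectories(treatment, times_h)  # validates treatment
  if (any(traj$orr_mult <= 0) || any(traj$area_mult <= 0))
    stop_orx("trajectory multipliers must be positive",
             class = "orx_validation_error")
  structure(list(image_size = as.integer(image_size), times_h = times_h,
                 n_organoids = as.integer(n_organoids),
                 treatment = treatment, frac_hollow = frac_hollow,
                 radius_range = radius_range, sbr_range = sbr_range,
                 orr = orr, background = background, noise = noise,
                 drift_px = drift_px, min_gap_px = min_gap_px,
                 margin_px = margin_px, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Read a phantom configuration from a YAML file
#'
#' The YAML keys mirror the [phantom_config] arguments; unknown keys are
#' rejected. `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return a [phantom_config].
#' @export
phantom_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(phantom_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop_orx("unknown phantom config key(s): %s", paste(bad, collapse = ", "),
             class = "orx_config_error")
  if (is.null(y$seed))
    stop_orx("phantom config requires a seed", class = "orx_config_error")
  if (!is.null(y$background)) y$background <- unlist(y$background)
  do.call(phantom_config, y)
}

#' Render one organoid as noise-free channel patches
#'
#' Draws a perturbed disk (radius modulated by a low-order Fourier series
#' in polar angle) with distinct core and rim mean ORR. Solid organoids
#' have an FAD-elevated, NAD(P)H-depressed core, so core ORR is below rim
#' ORR; hollow organoids the reverse. The summed-channel intensity is flat
#' across the organoid with a ~1 px anti-aliased edge; the returned patches
#' contain only the organoid's contribution (background is added at frame
#' level).
#'
#' @param center `(y, x)` center in frame coordinates.
#' @param radius mean radius (px), must be >= 5.
#' @param phenotype `"solid"` or `"hollow"`.
#' @param intensities list: `total` (summed-channel organoid intensity,
#'   positive), `rim_orr`, `core_orr` in (0, 1).
#' @param shape optional list with Fourier amplitudes `amp` and phases
#'   `phase` (defaults: regular disk).
#' @param orr_mult multiplier applied to rim/core ORR (treatment effect),
#'   results clipped to (0.02, 0.98).
#' @return list: `mask` (logical), `nadh`, `fad` (numeric patches), and
#'   `origin` (`(y0, x0)` frame position of patch element [1,1]).
#' @export
render_organoid <- function(center, radius, phenotype = c("solid", "hollow"),
                            intensities, shape = NULL, orr_mult = 1) {
  phenotype <- match.arg(phenotype)
  if (radius < 5) stop_orx("radius must be >= 5 px",
                           class = "orx_validation_error")
  if (intensities$total <= 0)
    stop_orx("intensities must be positive", class = "orx_validation_error")
  amp <- if (is.null(shape)) numeric(0) else shape$amp
  phase <- if (is.null(shape)) numeric(0) else shape$phase
  rmax <- radius * (1 + sum(abs(amp))) + 2
  half <- ceiling(rmax)
  y0 <- floor(center[1]) - half; x0 <- floor(center[2]) - half
  n <- 2 * half + 1
  yy <- (y0:(y0 + n - 1)) - center[1]
  xx <- (x0:(x0 + n - 1)) - center[2]
  dy <- matrix(yy, n, n); dx <- matrix(xx, n, n, byrow = TRUE)
  rr <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  pert <- 0
  for (k in seq_along(amp))
    pert <- pert + amp[k] * cos((k + 1) * th + phase[k])
  rloc <- radius * (1 + pert)
  cov <- pmin(pmax(rloc - rr + 0.5, 0), 1)   # ~1 px anti-aliased edge
  mask <- cov >= 0.5
  # core/rim ORR with a smooth transition at 55% of the local radius
  core_frac <- 0.55
  w <- 1 / (1 + exp((rr - core_frac * rloc) / 1.5))  # 1 in core, 0 at rim
  ro <- intensities$rim_orr * orr_mult
  co <- intensities$core_orr * orr_mult
  orr_px <- pmin(pmax(co * w + ro * (1 - w), 0.02), 0.98)
  total <- intensities$total * cov
  list(mask = mask, nadh = orr_px * total, fad = (1 - orr_px) * total,
       origin = c(y0, x0))
}

#' Generate a phantom well time series with ground truth
#'
#' Places organoids without overlap (bounded rejection sampling), renders
#' every time point with the treatment's growth and ORR trajectory, applies
#' cumulative global drift, and adds read + shot noise. Identical config
#' and seed give bit-identical output.
#'
#' @param config a [phantom_config].
#' @return list with `series` (a [well_series]) and `truth` (list:
#'   `masks` per-frame ground-truth label matrices, `tracks` data frame of
#'   true centroids, `per_organoid` data frame of true area / mean ORR /
#'   phenotype per organoid and time point, `sbr` configured ratio).
#' @export
generate_phantom_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  nt <- length(cfg$times_h)
  n <- cfg$n_organoids
  traj <- treatment_trajectories(cfg$treatment, cfg$times_h)
  growth <- sqrt(traj$area_mult)          # radius scale per frame
  drift <- cbind((seq_len(nt) - 1) * cfg$drift_px[1],
                 (seq_len(nt) - 1) * cfg$drift_px[2])
  # organoid draws
  sbr <- stats::runif(1, cfg$sbr_range[1], cfg$sbr_range[2])
  bg_total <- sum(cfg$background)
  if (n > 0) {
    # place largest organoids first so dense fields remain packable
    radius <- sort(stats::runif(n, cfg$radius_range[1], cfg$radius_range[2]),
                   decreasing = TRUE)
    hollow <- stats::runif(n) < cfg$frac_hollow
    shapes <- lapply(seq_len(n), function(i) {
      k <- 3
      amp0 <- if (hollow[i]) 0.02 else 0.06   # hollow organoids are rounder
      list(amp = stats::runif(k, 0, amp0),
           phase = stats::runif(k, 0, 2 * pi))
    })
    # placement: keep organoids inside the frame at maximal growth + drift
    # (exact per-organoid bound: growth scaling plus shape perturbation)
    pert_max <- vapply(shapes, function(s) sum(s$amp), numeric(1))
    rmax_t <- radius * max(growth) * (1 + pert_max) + 2
    margin <- rmax_t + cfg$margin_px +
      max(abs(drift[, 1]), abs(drift[, 2]))
    if (any(margin * 2 > min(H, W)))
      stop_orx("frame too small to place organoid of radius %.0f",
               max(radius), class = "orx_placement_error")
    cy <- cx <- numeric(n)
    done <- FALSE
    for (restart in 1:200) {         # bounded rejection sampling w/ restarts
      ok <- TRUE
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in 1:500) {
          py <- stats::runif(1, 1 + margin[i], H - margin[i])
          px <- stats::runif(1, 1 + margin[i], W - margin[i])
          if (i == 1 || all(sqrt((py - cy[seq_len(i - 1)])^2 +
                                 (px - cx[seq_len(i - 1)])^2) >
                            rmax_t[i] + rmax_t[seq_len(i - 1)] +
                              cfg$min_gap_px)) {
            cy[i] <- py; cx[i] <- px; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) { done <- TRUE; break }
    }
    if (!done)
      stop_orx("failed to place %d organoids after 200 restarts", n,
               class = "orx_placement_error")
  }
  nadh_frames <- fad_frames <- masks <- vector("list", nt)
  tracks <- list(); per_org <- list()
  for (f in seq_len(nt)) {
    nadh <- matrix(cfg$background["nadh"], H, W)
    fad <- matrix(cfg$background["fad"], H, W)
    lab <- matrix(0L, H, W)
    if (n > 0) {
      for (i in seq_len(n)) {
        ph <- if (hollow[i]) "hollow" else "solid"
        # additive organoid signal on top of the flat background; hollow
        # organoids carry more NAD(P)H, hence brighter summed signal
        amp_total <- (sbr - 1) * bg_total * (if (hollow[i]) 1.25 else 1)
        ints <- list(total = amp_total,
                     rim_orr = if (hollow[i]) cfg$orr$hollow_rim else cfg$orr$solid_rim,
                     core_orr = if (hollow[i]) cfg$orr$hollow_core else cfg$orr$solid_core)
        ctr <- c(cy[i] + drift[f, 1], cx[i] + drift[f, 2])
        org <- render_organoid(ctr, radius[i] * growth[f], ph, ints,
                               shape = shapes[[i]],
                               orr_mult = traj$orr_mult[f])
        ys <- org$origin[1]:(org$origin[1] + nrow(org$mask) - 1)
        xs <- org$origin[2]:(org$origin[2] + ncol(org$mask) - 1)
        sely <- ys >= 1 & ys <= H; selx <- xs >= 1 & xs <= W
        nadh[ys[sely], xs[selx]] <- nadh[ys[sely], xs[selx]] +
          org$nadh[sely, selx]
        fad[ys[sely], xs[selx]] <- fad[ys[sely], xs[selx]] +
          org$fad[sely, selx]
        sub <- lab[ys[sely], xs[selx]]
        sub[org$mask[sely, selx]] <- i
        lab[ys[sely], xs[selx]] <- sub
        # noise-free truth from the rendered frame (organoid + background
        # light, as a wide-field measurement integrates) via the ORR formula
        msel <- org$mask[sely, selx]
        nad_m <- org$nadh[sely, selx][msel] + cfg$background["nadh"]
        fad_m <- org$fad[sely, selx][msel] + cfg$background["fad"]
        tru_orr <- mean(nad_m / (nad_m + fad_m))
        midx <- which(msel)
        myy <- ((midx - 1) %% sum(sely)) + min(ys[sely])
        mxx <- ((midx - 1) %/% sum(sely)) + min(xs[selx])
        tracks[[length(tracks) + 1L]] <- data.frame(
          track_id = i, frame = f, time_h = cfg$times_h[f],
          y = mean(myy), x = mean(mxx))
        per_org[[length(per_org) + 1L]] <- data.frame(
          organoid = i, time_h = cfg$times_h[f], frame = f,
          area_px = sum(msel), mean_orr = tru_orr, phenotype = ph,
          radius_px = radius[i] * growth[f])
      }
    }
    # read noise + intensity-proportional shot term, then 16-bit rounding
    for (ch in c("nadh", "fad")) {
      img <- if (ch == "nadh") nadh else fad
      sdpx <- sqrt(cfg$noise$read_sd^2 + cfg$noise$shot_scale * img)
      img <- img + stats::rnorm(length(img), 0, 1) * sdpx
      img <- pmin(pmax(round(img), 0), 65535)
      if (ch == "nadh") nadh <- img else fad <- img
    }
    nadh_frames[[f]] <- nadh; fad_frames[[f]] <- fad; masks[[f]] <- lab
  }
  series <- well_series(nadh_frames, fad_frames, cfg$times_h,
                        treatment = cfg$treatment,
                        well_id = sprintf("PH%02d", cfg$seed %% 100))
  truth <- list(masks = masks,
                tracks = if (length(tracks)) do.call(rbind, tracks)
                         else data.frame(track_id = integer(0),
                                         frame = integer(0),
                                         time_h = numeric(0),
                                         y = numeric(0), x = numeric(0)),
                per_organoid = if (length(per_org)) do.call(rbind, per_org)
                               else data.frame(organoid = integer(0),
                                               time_h = numeric(0),
                                               frame = integer(0),
                                               area_px = numeric(0),
                                               mean_orr = numeric(0),
                                               phenotype = character(0),
                                               radius_px = numeric(0)),
                sbr = sbr)
  list(series = series, truth = truth)
}

#' Write phantom frames and ground truth to disk
#'
#' Frames go out as 16-bit per-channel TIFFs with a manifest (see
#' [write_well_series]); truth label masks as 16-bit TIFFs and the truth
#' tables as CSV.
#'
#' @param phantom result of [generate_phantom_series].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_well_series(phantom$series, dir)
  for (f in seq_along(phantom$truth$masks)) {
    write_intensity_tiff(phantom$truth$masks[[f]],
                         file.path(dir, sprintf("truth_mask_t%03d.tif", f)))
  }
  utils::write.csv(phantom$truth$tracks,
                   file.path(dir, "truth_tracks.csv"), row.names = FALSE)
  utils::write.csv(phantom$truth$per_organoid,
                   file.path(dir, "truth_per_organoid.csv"), row.names = FALSE)
  invisible(dir)
}
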