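# End-to-end orchestration: phantom or TIFF input -> registration -> ORR ->
# segmentation -> tracking -> features -> longitudinal stats -> PCA.

#' Pipeline configuration
#'
#' Either `phantoms` (a list of [phantom_config], one well each) or
#' `manifest` (CSV path with one or more wells) must be given.
#'
#' @param phantoms list of [phantom_config] objects.
#' @param manifest manifest CSV path (see [read_well_series]).
#' @param out_dir output directory for stage artifacts.
#' @param segmentation a [segmentation_params] or `NULL` (auto-scaled).
#' @param tracking a [tracking_params].
#' @param stats_variable variable analysed by the longitudinal stage.
#' @param normalization `"organoid"` or `"well"`.
#' @param run_stats,run_pca stage switches.
#' @param seed seed recorded in the run log (phantom configs carry their
#'   own seeds).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantoms = NULL, manifest = NULL,
                            out_dir = tempfile("orgredox_run_"),
                            segmentation = NULL,
                            tracking = tracking_params(),
                            stats_variable = "orr_mean",
                            normalization = "organoid",
                            run_stats = TRUE, run_pca = TRUE,
                            seed = 1) {
  if (is.null(phantoms) && is.null(manifest))
    stop_orx("either phantoms or manifest must be given",
             class = "orx_config_error")
  structure(list(phantoms = phantoms, manifest = manifest,
                 out_dir = out_dir, segmentation = segmentation,
                 tracking = tracking, stats_variable = stats_variable,
                 normalization = normalization, run_stats = run_stats,
                 run_pca = run_pca, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_event <- function(log_path, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Stages per well: load or generate the two-channel series, register all
#' frames to the pretreatment frame (NAD(P)H-derived shifts applied to
#' both channels), compute ORR images, segment every frame independently,
#' link organoids into tracks, quantify the 24 variables, and drop
#' border-touching tracks. If more than one treatment group is present
#' (and `run_stats`), the longitudinal mixed-model stage and contrasts
#' run; with a single group the stage is skipped with an explicit log
#' entry. The PCA stage runs on the pooled pretreatment feature table.
#' All tabular artifacts are CSV; a JSON-lines run log records parameters,
#' per-stage results and every exclusion with a reason. Re-running the
#' same configuration reproduces identical CSVs.
#'
#' @param config a [pipeline_config].
#' @return list: `features` (combined feature table), `tracks`, `shifts`,
#'   `normalized`, `contrasts` (or `NULL`), `pca` (or `NULL`),
#'   `out_dir`, `artifacts` (file manifest with MD5 checksums).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  log_event(log_path, "start", seed = config$seed,
            variable = config$stats_variable,
            normalization = config$normalization)
  # --- assemble wells ---
  wells <- list()
  truths <- list()
  if (!is.null(config$phantoms)) {
    for (pc in config$phantoms) {
      ph <- generate_phantom_series(pc)
      wells[[ph$series$well_id]] <- ph$series
      truths[[ph$series$well_id]] <- ph$truth
    }
  } else {
    man <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    for (w in unique(man$well))
      wells[[w]] <- read_well_series(man, well = w)
  }
  all_feats <- list(); all_tracks <- list(); all_shifts <- list()
  for (w in names(wells)) {
    series <- wells[[w]]
    reg <- tryCatch(register_series(series), error = function(e)
      stop_orx("registration failed for well %s: %s", w,
               conditionMessage(e), class = "orx_stage_error"))
    log_event(log_path, "register", well = w,
              shifts_dy = reg$shifts$dy, shifts_dx = reg$shifts$dx,
              common_region = reg$common_region)
    rs <- reg$series
    segp <- if (is.null(config$segmentation))
      segmentation_params(image_size = dim(rs$nadh[[1]]))
    else config$segmentation
    masks <- lapply(rs$nadh, segment_frame, params = segp)
    log_event(log_path, "segment", well = w,
              n_regions = vapply(masks, max, numeric(1)),
              background_kernel = segp$background_kernel,
              scaled = segp$scaled)
    cents <- lapply(masks, extract_centroids)
    tracks <- link_tracks(cents, config$tracking, times_h = rs$times_h)
    log_event(log_path, "track", well = w,
              n_tracks = length(unique(tracks$track_id)))
    orr <- Map(compute_orr, rs$nadh, rs$fad)
    feats <- build_feature_table(tracks, masks, rs, orr)
    kept <- exclude_border_tracks(feats)
    log_event(log_path, "features", well = w, n_rows = nrow(kept),
              dropped_border_tracks = attr(kept, "dropped_tracks"),
              reason = "track touches common-crop border")
    kept$organoid_id <- paste(w, kept$organoid_id, sep = ":")
    tracks$track_id <- paste(w, tracks$track_id, sep = ":")
    all_feats[[w]] <- kept; all_tracks[[w]] <- tracks
    all_shifts[[w]] <- cbind(well = w, reg$shifts)
  }
  features <- do.call(rbind, all_feats)
  rownames(features) <- NULL
  tracks <- do.call(rbind, all_tracks); rownames(tracks) <- NULL
  shifts <- do.call(rbind, all_shifts); rownames(shifts) <- NULL
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(tracks, file.path(config$out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(shifts, file.path(config$out_dir, "shifts.csv"),
                   row.names = FALSE)
  # --- longitudinal stats ---
  normalized <- contrasts <- NULL
  if (config$run_stats && nrow(features)) {
    normalized <- normalize_series(features, config$stats_variable,
                                   mode = config$normalization)
    for (msg in attr(normalized, "dropped"))
      log_event(log_path, "normalize", dropped = msg)
    utils::write.csv(normalized, file.path(config$out_dir, "normalized.csv"),
                     row.names = FALSE)
    if (length(unique(features$treatment)) >= 2) {
      model <- if (config$normalization == "organoid") fit_lmm(normalized)
               else fit_pooled(normalized)
      contrasts <- lsmeans_contrasts(model)
      utils::write.csv(contrasts, file.path(config$out_dir, "contrasts.csv"),
                       row.names = FALSE)
      log_event(log_path, "stats", rho = model$rho, sigma = model$sigma,
                intercept_sd = model$intercept_sd)
    } else {
      log_event(log_path, "stats", skipped = TRUE,
                reason = "single treatment group: pairwise contrasts undefined")
    }
  }
  # --- PCA ---
  pca_out <- NULL
  if (config$run_pca && nrow(features)) {
    pre <- features[features$time_h == min(features$time_h), ]
    if (nrow(pre) >= 3) {
      std <- standardize_within_time(pre)
      model <- fit_pca(std)
      scores <- pca_project(model, std)
      utils::write.csv(data.frame(std$meta, scores[, 1:2]),
                       file.path(config$out_dir, "pca_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(variable = rownames(model$loadings),
                                  model$loadings[, 1:2]),
                       file.path(config$out_dir, "pca_loadings.csv"),
                       row.names = FALSE)
      pca_out <- list(model = model, scores = scores,
                      top = top_loadings(model, min(12, nrow(model$loadings))))
      log_event(log_path, "pca", explained_pc1 = model$explained[1],
                explained_pc2 = model$explained[2])
    } else {
      log_event(log_path, "pca", skipped = TRUE,
                reason = "fewer than 3 pretreatment organoids")
    }
  }
  csvs <- list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE)
  artifacts <- data.frame(file = basename(csvs),
                          md5 = unname(tools::md5sum(csvs)))
  utils::write.csv(artifacts, file.path(config$out_dir, "artifact_manifest.csv"),
                   row.names = FALSE)
  log_event(log_path, "done", n_artifacts = nrow(artifacts))
  list(features = features, tracks = tracks, shifts = shifts,
       normalized = normalized, contrasts = contrasts, pca = pca_out,
       truths = if (length(truths)) truths else NULL,
       out_dir = config$out_dir, artifacts = artifacts)
}
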