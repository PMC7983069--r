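# Feature quantification: closed-form fixtures, schema, border exclusion,
# invariants and recovery against phantom truth.

test_that("a constant 10x10 square reproduces every closed form", {
  m <- matrix(0, 30, 30); m[6:15, 6:15] <- 1
  nadh <- matrix(200, 30, 30); fad <- matrix(200, 30, 30)
  q <- quantify_organoid(m, nadh, fad, compute_orr(nadh, fad))
  expect_equal(q$orr_mean, 0.5)
  expect_equal(q$orr_min, 0.5)
  expect_equal(q$orr_max, 0.5)
  expect_equal(q$orr_sd, 0)
  expect_equal(q$nadh_mean, 200)
  expect_equal(q$area, 100)
  expect_equal(q$extent, 1.0)
  expect_equal(q$solidity, 1.0)
  expect_equal(q$perimeter, 40)
  expect_equal(q$circularity, pi / 4, tolerance = 1e-8)
  expect_equal(q$equiv_diameter, sqrt(400 / pi), tolerance = 1e-8)
  expect_false(q$border_touching)
})

test_that("a rasterized disk has near-zero eccentricity and ~80 px calipers", {
  m <- disk_mask(c(121, 121), 61, 61, 40)
  img <- matrix(100, 121, 121)
  q <- quantify_organoid(m, img, img, compute_orr(img, img))
  expect_lt(q$eccentricity, 0.05)
  expect_equal(q$feret_min, 80, tolerance = 1.5)
  expect_equal(q$feret_max, 80, tolerance = 1.5)
  expect_equal(q$axis_major, 80, tolerance = 1)
  expect_equal(q$axis_minor, 80, tolerance = 1)
})

test_that("a 20x5 rectangle matches the rotating-calipers diagonal", {
  m <- matrix(0, 30, 40); m[6:10, 6:25] <- 1
  img <- matrix(50, 30, 40)
  q <- quantify_organoid(m, img, img, compute_orr(img, img))
  expect_equal(q$extent, 1.0)
  expect_equal(q$feret_max, sqrt(20^2 + 5^2), tolerance = 0.05)
  expect_equal(q$feret_min, 5, tolerance = 0.05)
  expect_gt(q$axis_major, q$axis_minor)
})

test_that("exactly 24 variables are emitted, split 12 metabolic / 12 morphological", {
  v <- feature_variables()
  expect_length(v$metabolic, 12)
  expect_length(v$morphological, 12)
  expect_length(intersect(v$metabolic, v$morphological), 0)
  m <- matrix(0, 20, 20); m[5:14, 5:14] <- 1
  img <- matrix(10, 20, 20)
  q <- quantify_organoid(m, img, img, compute_orr(img, img))
  expect_true(all(c(v$metabolic, v$morphological) %in% names(q)))
})

test_that("feature table has one row per (track, detected frame)", {
  ph <- small_phantom(2)
  masks <- ph$truth$masks
  cs <- lapply(masks, extract_centroids)
  tracks <- link_tracks(cs, tracking_params(), times_h = ph$series$times_h)
  ft <- build_feature_table(tracks, masks, ph$series)
  expect_equal(nrow(ft), 4 * 6)
  v <- feature_variables()
  expect_true(all(c(v$metabolic, v$morphological) %in% names(ft)))
  # a gap frame removes exactly one row
  tracks2 <- tracks[!(tracks$track_id == 1 & tracks$frame == 3), ]
  ft2 <- build_feature_table(tracks2, masks, ph$series)
  expect_equal(nrow(ft2), 23)
  # referencing a label that does not exist is an integrity error
  bad <- tracks; bad$label[1] <- 99L
  expect_error(build_feature_table(bad, masks, ph$series), "missing label")
})

test_that("feature invariants hold on phantom-derived regions", {
  ph <- small_phantom(5)
  masks <- ph$truth$masks
  cs <- lapply(masks, extract_centroids)
  tracks <- link_tracks(cs, tracking_params(), times_h = ph$series$times_h)
  ft <- build_feature_table(tracks, masks, ph$series)
  expect_true(all(ft$orr_min <= ft$orr_mean & ft$orr_mean <= ft$orr_max))
  expect_true(all(ft$nadh_min <= ft$nadh_mean & ft$nadh_mean <= ft$nadh_max))
  expect_true(all(ft$fad_min <= ft$fad_mean & ft$fad_mean <= ft$fad_max))
  expect_true(all(ft$orr_sd >= 0 & ft$nadh_sd >= 0 & ft$fad_sd >= 0))
  expect_true(all(ft$solidity > 0 & ft$solidity <= 1))
  expect_true(all(ft$extent > 0 & ft$extent <= 1))
  expect_true(all(ft$eccentricity >= 0 & ft$eccentricity < 1))
  expect_true(all(ft$axis_minor <= ft$axis_major + 1e-9))
  expect_true(all(ft$feret_min <= ft$feret_max + 1e-9))
  expect_true(all(ft$area <= ft$convex_area))
  # pixel-count conservation
  for (i in c(1, 10, 24)) {
    f <- ft$frame[i]
    expect_equal(ft$area[i],
                 sum(masks[[f]] == tracks$label[tracks$track_id ==
                       ft$organoid_id[i] & tracks$frame == f]))
  }
})

test_that("segmentation-derived features recover phantom truth", {
  cfg <- small_phantom_config(21, noise = list(read_sd = 0, shot_scale = 0),
                              drift_px = c(0, 0))
  ph <- generate_phantom_series(cfg)
  lab <- segment_frame(ph$series$nadh[[1]])
  rp <- region_properties(lab)
  tr <- ph$truth$per_organoid[ph$truth$per_organoid$frame == 1, ]
  tt <- ph$truth$tracks[ph$truth$tracks$frame == 1, ]
  expect_equal(nrow(rp), nrow(tr))
  orr <- compute_orr(ph$series$nadh[[1]], ph$series$fad[[1]])
  for (i in seq_len(nrow(rp))) {
    k <- which.min((tt$y - rp$centroid_y[i])^2 + (tt$x - rp$centroid_x[i])^2)
    expect_lt(abs(rp$area[i] - tr$area_px[k]) / tr$area_px[k], 0.05)
    measured_orr <- mean(orr[lab == rp$label[i]], na.rm = TRUE)
    expect_lt(abs(measured_orr - tr$mean_orr[k]), 0.02)
  }
})

test_that("tracks touching the border at any frame are dropped whole", {
  ph <- small_phantom(2)
  masks <- ph$truth$masks
  cs <- lapply(masks, extract_centroids)
  tracks <- link_tracks(cs, tracking_params(), times_h = ph$series$times_h)
  ft <- build_feature_table(tracks, masks, ph$series)
  # mark organoid 1 as border-touching at the last frame only
  ft$border_touching[ft$organoid_id == 1 & ft$frame == 6] <- TRUE
  kept <- exclude_border_tracks(ft)
  expect_false(1 %in% kept$organoid_id)
  expect_equal(attr(kept, "dropped_tracks"), 1)
  expect_equal(nrow(kept), 18)  # 3 remaining tracks x 6 frames
  # fully interior organoids are retained
  expect_true(all(2:4 %in% kept$organoid_id))
  empty <- exclude_border_tracks(ft[0, ])
  expect_equal(nrow(empty), 0)
})
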