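# Phantom generator: rendering contracts, trajectories, reproducibility.

test_that("rendered organoids have the phenotype-specific core/rim redox contrast", {
  ints <- list(total = 1000, rim_orr = 0.7, core_orr = 0.5)
  solid <- render_organoid(c(60, 60), 40, "solid", ints)
  orr <- compute_orr(solid$nadh + 1e-9, solid$fad)  # avoid 0/0 outside
  inside <- solid$mask
  expect_true(all(orr[inside] >= 0.5 - 1e-6 & orr[inside] <= 0.7 + 1e-6))
  # core mean below rim mean for solid
  n <- nrow(solid$mask)
  rr <- sqrt((row(solid$mask) - (60 - solid$origin[1] + 1))^2 +
             (col(solid$mask) - (60 - solid$origin[2] + 1))^2)
  core <- inside & rr < 0.4 * 40
  rim <- inside & rr > 0.8 * 40
  expect_lt(mean(orr[core]), mean(orr[rim]))

  hollow <- render_organoid(c(60, 60), 40, "hollow",
                            list(total = 1000, rim_orr = 0.5, core_orr = 0.7))
  orr_h <- compute_orr(hollow$nadh + 1e-9, hollow$fad)
  expect_gt(mean(orr_h[core]), mean(orr_h[rim]))
})

test_that("degenerate render parameters are rejected", {
  ints <- list(total = 1000, rim_orr = 0.7, core_orr = 0.5)
  expect_error(render_organoid(c(50, 50), 0, "solid", ints), "radius")
  expect_error(render_organoid(c(50, 50), 40, "solid",
                               list(total = -5, rim_orr = 0.7,
                                    core_orr = 0.5)), "positive")
})

test_that("identical config and seed give bit-identical phantoms", {
  a <- generate_phantom_series(small_phantom_config(7))
  b <- generate_phantom_series(small_phantom_config(7))
  expect_identical(a$series$nadh, b$series$nadh)
  expect_identical(a$series$fad, b$series$fad)
  expect_identical(a$truth$masks, b$truth$masks)
  expect_identical(a$truth$per_organoid, b$truth$per_organoid)
})

test_that("an organoid-free config renders pure background", {
  ph <- generate_phantom_series(small_phantom_config(3, n_organoids = 0))
  expect_equal(nrow(ph$truth$per_organoid), 0)
  expect_true(all(ph$truth$masks[[1]] == 0))
  expect_length(ph$series$nadh, 6)
})

test_that("control phantoms hit the configured +10% growth at 48 h", {
  ph <- small_phantom(11)
  tr <- ph$truth$per_organoid
  a0 <- tr$area_px[tr$time_h == 0]
  a48 <- tr$area_px[tr$time_h == 48]
  ratio <- a48 / a0
  expect_true(all(abs(ratio - 1.10) < 0.02 * 1.10))
})

test_that("measured signal-to-background ratio tracks the configured value", {
  for (s in c(2, 5)) {
    ph <- small_phantom(s)
    m <- ph$truth$masks[[1]] > 0
    tot <- ph$series$nadh[[1]] + ph$series$fad[[1]]
    sbr_meas <- mean(tot[m]) / mean(tot[!m])
    expect_lt(abs(sbr_meas - ph$truth$sbr) / ph$truth$sbr, 0.10)
  }
})

test_that("noise-free rendering reproduces the truth table mean ORR", {
  cfg <- small_phantom_config(4, noise = list(read_sd = 0, shot_scale = 0))
  ph <- generate_phantom_series(cfg)
  for (f in c(1, 6)) {
    orr <- compute_orr(ph$series$nadh[[f]], ph$series$fad[[f]])
    tr <- ph$truth$per_organoid[ph$truth$per_organoid$frame == f, ]
    for (i in seq_len(nrow(tr))) {
      sel <- ph$truth$masks[[f]] == tr$organoid[i]
      expect_lt(abs(mean(orr[sel]) - tr$mean_orr[i]), 0.01)
    }
  }
})

test_that("truth masks and truth tracks agree on centroids", {
  ph <- small_phantom(2)
  for (f in c(1, 4)) {
    cs <- extract_centroids(ph$truth$masks[[f]])
    tt <- ph$truth$tracks[ph$truth$tracks$frame == f, ]
    tt <- tt[order(tt$track_id), ]
    expect_equal(cs$y, tt$y, tolerance = 1e-8)
    expect_equal(cs$x, tt$x, tolerance = 1e-8)
  }
})

test_that("treatment trajectories obey the pharmacological contracts", {
  ctrl <- treatment_trajectories("control")
  expect_true(all(ctrl$orr_mult == 1))
  cy <- treatment_trajectories("cyanide")
  expect_gt(cy$orr_mult[cy$time_h == 0.33], 1)   # acute ETC-inhibition rise
  expect_lt(cy$orr_mult[cy$time_h == 36], 1)     # later decline
  expect_lt(cy$orr_mult[cy$time_h == 48], 1)
  for (trt in c("cyanide", "2DG", "cisplatin", "paclitaxel")) {
    tj <- treatment_trajectories(trt)
    expect_lte(tj$area_mult[tj$time_h == 48],
               ctrl$area_mult[ctrl$time_h == 48])
  }
  pac <- treatment_trajectories("paclitaxel")
  expect_lt(pac$area_mult[pac$time_h == 48], ctrl$area_mult[ctrl$time_h == 48])
  expect_error(treatment_trajectories("nonsense"), "unknown treatment")
})

test_that("phantom frames round-trip through TIFF and the manifest reader", {
  ph <- small_phantom(2)
  dir <- withr::local_tempdir()
  man <- write_well_series(ph$series, dir)
  back <- read_well_series(man)
  expect_equal(back$times_h, ph$series$times_h)
  expect_equal(back$nadh[[1]], ph$series$nadh[[1]], ignore_attr = TRUE)
  expect_equal(back$fad[[6]], ph$series$fad[[6]], ignore_attr = TRUE)
})

test_that("phantom configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "n_organoids: 3", "treatment: cyanide",
               "image_size: [256, 256]"), f)
  cfg <- phantom_config_from_yaml(f)
  expect_equal(cfg$seed, 5L)
  expect_equal(cfg$n_organoids, 3L)
  expect_equal(cfg$treatment, "cyanide")
  writeLines(c("seed: 5", "bogus_key: 1"), f)
  expect_error(phantom_config_from_yaml(f), "unknown phantom config key")
  writeLines("n_organoids: 3", f)
  expect_error(phantom_config_from_yaml(f), "requires a seed")
})
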