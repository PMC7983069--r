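# 12-step segmentation, watershed splitting, Dice and circularity.

test_that("circularity matches closed forms on geometric fixtures", {
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 1
  expect_equal(circularity(sq), pi / 4, tolerance = 1e-8)  # P = 40 exactly
  bar <- matrix(0, 10, 60); bar[5:6, 6:55] <- 1
  expect_lt(circularity(bar), 0.4)                         # filtered shape
  expect_equal(circularity(bar), 4 * pi * 100 / 104^2, tolerance = 1e-6)
  disk <- disk_mask(c(121, 121), 61, 61, 50)
  expect_gte(circularity(disk), 0.95)                      # converges to 1
  expect_error(circularity(matrix(0, 5, 5)), "empty")
})

test_that("Dice coefficient satisfies its defining identities", {
  a <- disk_mask(c(50, 50), 25, 25, 10)
  expect_equal(dice(a, a), 1)
  b <- disk_mask(c(50, 50), 25, 25, 0.5)  # single pixel, inside a
  expect_equal(dice(a, !a), 0)
  m1 <- matrix(0, 10, 20); m1[1:10, 1:10] <- 1
  m2 <- matrix(0, 10, 20); m2[1:10, 6:15] <- 1
  expect_equal(dice(m1, m2), 0.5)                 # |A|=|B|=100, overlap 50
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice(matrix(0, 3, 3), matrix(0, 4, 4)), "dimension")
})

test_that("watershed splitting separates touching disks near the midline", {
  m <- matrix(0, 80, 130)
  m <- disk_mask(c(80, 130), 40, 45, 30) | disk_mask(c(80, 130), 40, 95, 30)
  lab <- split_touching(m, hmin_depth = 5)
  expect_equal(max(lab), 2)
  # conservation: labels partition the foreground exactly
  expect_true(all((lab > 0) == m))
  # boundary between labels within 3 px of the equidistant chord x = 70
  l1 <- unique(lab[disk_mask(c(80, 130), 40, 45, 20)])
  l2 <- unique(lab[disk_mask(c(80, 130), 40, 95, 20)])
  xs <- col(lab)
  expect_true(all(xs[lab == l1] <= 73))
  expect_true(all(xs[lab == l2] >= 67))
})

test_that("near-coincident disks stay one region after h-suppression", {
  m <- disk_mask(c(80, 80), 40, 38, 30) | disk_mask(c(80, 80), 40, 43, 30)
  lab <- split_touching(m, hmin_depth = 5)
  expect_equal(max(lab), 1)
  expect_true(all((lab > 0) == m))
})

test_that("a single disk passes the splitter untouched", {
  m <- disk_mask(c(80, 80), 40, 40, 30)
  lab <- split_touching(m, hmin_depth = 5)
  expect_equal(max(lab), 1)
  expect_true(all((lab > 0) == m))
})

test_that("a background-only frame yields an empty mask", {
  ph <- generate_phantom_series(small_phantom_config(9, n_organoids = 0))
  lab <- segment_frame(ph$series$nadh[[1]])
  expect_equal(max(lab), 0)
})

test_that("a solid organoid at SBR ~2.5 is recovered with Dice >= 0.9", {
  cfg <- phantom_config(image_size = c(256, 256), n_organoids = 1,
                        radius_range = c(40, 40), sbr_range = c(2.5, 2.5),
                        drift_px = c(0, 0), seed = 31)
  ph <- generate_phantom_series(cfg)
  lab <- segment_frame(ph$series$nadh[[1]])
  expect_equal(max(lab), 1)
  expect_gte(dice(lab > 0, ph$truth$masks[[1]] > 0), 0.9)
})

test_that("segmentation is deterministic and obeys the morphology filter", {
  ph <- small_phantom(12)
  p <- segmentation_params(image_size = c(256, 256))
  lab1 <- segment_frame(ph$series$nadh[[1]], p)
  lab2 <- segment_frame(ph$series$nadh[[1]], p)
  expect_identical(lab1, lab2)
  rp <- region_properties(lab1)
  expect_true(all(rp$area > p$min_area))
  expect_true(all(rp$circularity > p$min_circularity))
})

test_that("sub-threshold regions are absent from the final mask", {
  # one organoid of true area ~500 px (radius 12.6): below the 1000 px cut
  cfg <- phantom_config(image_size = c(256, 256), n_organoids = 1,
                        radius_range = c(40, 40), sbr_range = c(2.5, 2.5),
                        drift_px = c(0, 0), seed = 13)
  ph <- generate_phantom_series(cfg)
  frame <- ph$series$nadh[[1]]
  small <- render_organoid(c(60, 60), 12.6, "solid",
                           list(total = 1000, rim_orr = 0.7, core_orr = 0.5))
  ys <- small$origin[1]:(small$origin[1] + nrow(small$mask) - 1)
  xs <- small$origin[2]:(small$origin[2] + ncol(small$mask) - 1)
  frame[ys, xs] <- frame[ys, xs] + small$nadh
  expect_lt(sum(small$mask), 600)
  lab <- segment_frame(frame)
  # the large organoid is kept, the ~500 px one is filtered out
  expect_equal(max(lab), 1)
  expect_equal(sum(lab[ys, xs][small$mask] > 0), 0)
})

test_that("strict mode refuses undersized frames; scaled mode flags itself", {
  expect_error(segmentation_params(image_size = c(256, 256), strict = TRUE),
               "strict")
  p <- segmentation_params(image_size = c(256, 256))
  expect_true(p$scaled)
  expect_lt(p$background_kernel, 450)
  p2 <- segmentation_params(image_size = c(2048, 2048))
  expect_false(p2$scaled)
  expect_equal(p2$background_kernel, 451)  # odd-size normalization of 450
})
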