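# Longitudinal statistics: normalization, mixed and pooled models,
# estimated-marginal-means contrasts, bivariate fits, correlation matrix.

fake_table <- function(values, times = c(0, 12, 48), wells = "W1",
                       treatment = "control") {
  # values: matrix organoids x times
  n <- nrow(values)
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(organoid_id = i, well = wells, treatment = treatment,
               time_h = times, orr_mean = values[i, ], area = values[i, ])))
  out
}

test_that("organoid- and well-level normalization follow their formulas", {
  tab <- fake_table(rbind(c(0.5, 0.55, 0.6), c(0.3, 0.3, 0.36)))
  org <- normalize_series(tab, "orr_mean", mode = "organoid")
  expect_equal(org$Y[org$organoid_id == 1 & org$time_h == 48], 1.2)
  expect_equal(org$Y[org$organoid_id == 2 & org$time_h == 48], 1.2)
  expect_true(all(org$Y[org$pretreatment] == 1))
  # well level: denominator is the well pretreatment mean 0.4
  wl <- normalize_series(tab, "orr_mean", mode = "well")
  expect_equal(wl$Y[wl$organoid_id == 1 & wl$time_h == 48], 0.6 / 0.4)
  expect_equal(wl$Y[wl$organoid_id == 2 & wl$time_h == 48], 0.36 / 0.4)
  # normalization idempotence: renormalizing returns the same series
  renorm <- tab
  renorm$orr_mean <- org$Y[match(paste(renorm$organoid_id, renorm$time_h),
                                 paste(org$organoid_id, org$time_h))]
  again <- normalize_series(renorm, "orr_mean", mode = "organoid")
  expect_equal(again$Y, org$Y)
})

test_that("organoids without a pretreatment denominator are dropped and logged", {
  tab <- fake_table(rbind(c(0.5, 0.55, 0.6), c(0.3, 0.3, 0.36)))
  tab <- tab[!(tab$organoid_id == 2 & tab$time_h == 0), ]
  org <- normalize_series(tab, "orr_mean", mode = "organoid")
  expect_false(2 %in% org$organoid_id)
  expect_match(attr(org, "dropped"), "organoid 2")
})

test_that("with no heterogeneity and rho = 0 the LMM reduces to OLS", {
  s <- simulate_normalized_series(n_per_group = 12, intercept_sd = 0,
                                  rho = 0, sigma = 0.05,
                                  effect = rbind(0, c(0, -0.1, -0.1, -0.1, -0.1)),
                                  seed = 5)
  f <- fit_lmm(s)
  d <- f$data
  ols <- stats::lm(Y ~ time_f * treatment, data = d)
  # balanced saturated design: fixed effects are cell means under any
  # within-organoid covariance, so the two fits agree
  expect_equal(unname(nlme::fixef(f$fit)), unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("lsmeans equal raw cell means in a balanced design", {
  s <- simulate_normalized_series(n_per_group = 10, intercept_sd = 0.05,
                                  rho = 0.3, sigma = 0.05, seed = 8,
                                  treatments = c("A", "B", "C", "D", "E"),
                                  effect = matrix(0, 5, 5))
  f <- fit_lmm(s)
  ct <- lsmeans_contrasts(f)
  expect_equal(nrow(ct), choose(5, 2) * 5)  # 10 pairs x 5 time points
  # contrast estimate equals the difference of cell means (balanced design)
  d <- f$data
  cm <- tapply(d$Y, list(d$treatment, d$time_f), mean)
  for (i in sample(nrow(ct), 10)) {
    expect_equal(ct$estimate[i],
                 cm[ct$group1[i], as.character(ct$time_h[i])] -
                   cm[ct$group2[i], as.character(ct$time_h[i])],
                 tolerance = 1e-8)
  }
  # antisymmetry follows: difference(A,B) = -difference(B,A)
  expect_true(all(ct$p_adj >= ct$p_unadj - 1e-12))
})

test_that("mixed and pooled fits decompose variance as expected", {
  s <- simulate_normalized_series(n_per_group = 20, intercept_sd = 0.15,
                                  rho = 0.3, sigma = 0.05, seed = 11)
  f <- fit_lmm(s)
  p <- fit_pooled(s)
  # organoid heterogeneity inflates the pooled residual variance
  expect_gt(p$sigma, f$sigma)
  expect_gt(f$intercept_sd, 0.08)
})

test_that("bivariate regression returns exact values on a noiseless line", {
  tab <- data.frame(organoid_id = 1:10, area = 1:10, orr_mean = 2 * (1:10))
  # summary.lm warns on an exactly perfect fit; that is the fixture's point
  fit <- suppressWarnings(bivariate_fit(tab, "area", "orr_mean"))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)
  expect_lt(fit$p, 1e-10)
  tab$area <- 5
  expect_error(bivariate_fit(tab, "area", "orr_mean"), "zero variance")
  expect_error(bivariate_fit(tab[1:2, ], "organoid_id", "orr_mean"), ">= 3")
})

test_that("independent variables rarely show strong correlation", {
  set.seed(21)
  hits <- 0
  for (r in 1:20) {
    tab <- data.frame(a = rnorm(1000), b = rnorm(1000))
    if (abs(bivariate_fit(tab, "a", "b")$r) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("the 24x24 correlation matrix is symmetric with unit diagonal", {
  ph <- small_phantom(2)
  masks <- ph$truth$masks
  cs <- lapply(masks, extract_centroids)
  tracks <- link_tracks(cs, tracking_params(), times_h = ph$series$times_h)
  ft <- build_feature_table(tracks, masks, ph$series)
  cm <- correlation_matrix(ft, time_h = 0)
  expect_equal(dim(cm$r), c(24, 24))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(diag(cm$r)[!is.na(diag(cm$r))] == 1))
  # area and convex area are near-proportional by construction
  expect_gt(cm$r["area", "convex_area"], 0.9)
  expect_true(cm$significant["area", "convex_area"])
  # constant columns are masked and logged
  ft2 <- ft; ft2$extent <- 1
  cm2 <- correlation_matrix(ft2, time_h = 0)
  expect_true("extent" %in% cm2$dropped)
  expect_true(all(is.na(cm2$r["extent", ])))
})

test_that("variance components are recovered at n = 50 organoids per group", {
  s <- simulate_normalized_series(n_per_group = 50, intercept_sd = 0.1,
                                  rho = 0.5, sigma = 0.05, seed = 99,
                                  effect = rbind(0, c(0, -0.2, -0.2, -0.2, -0.2)))
  f <- fit_lmm(s)
  expect_lt(abs(f$rho - 0.5) / 0.5, 0.2)
  expect_lt(abs(f$intercept_sd - 0.1) / 0.1, 0.2)
  expect_lt(abs(f$sigma - 0.05) / 0.05, 0.2)
})
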