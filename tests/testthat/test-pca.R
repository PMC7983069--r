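# PCA protocol: standardization, eigenvector agreement, projection,
# coverage ellipses, top loadings, subpopulation recovery.

pca_table <- function(x, time_h = 0) {
  vars <- paste0("v", seq_len(ncol(x)))
  colnames(x) <- vars
  cbind(data.frame(organoid_id = seq_len(nrow(x)), well = "W1",
                   treatment = "control", time_h = time_h), as.data.frame(x))
}

test_that("standardization gives mean 0 / sd 1 within every time point", {
  set.seed(1)
  tab <- rbind(pca_table(matrix(rnorm(60, 5, 3), 20, 3), 0),
               pca_table(matrix(rnorm(60, -2, 0.5), 20, 3), 24))
  std <- standardize_within_time(tab, paste0("v", 1:3))
  for (t in c(0, 24)) {
    sel <- std$meta$time_h == t
    expect_equal(colMeans(std$x[sel, ]), c(v1 = 0, v2 = 0, v3 = 0),
                 tolerance = 1e-12)
    expect_equal(apply(std$x[sel, ], 2, sd), c(v1 = 1, v2 = 1, v3 = 1),
                 tolerance = 1e-12)
  }
  # constant column dropped with log
  tab$v2 <- 7
  std2 <- standardize_within_time(tab, paste0("v", 1:3))
  expect_true("v2" %in% std2$dropped)
})

test_that("loadings agree with an independent eigendecomposition", {
  set.seed(2)
  # correlated pair: analytic eigenvectors are (1,1)/sqrt(2), (1,-1)/sqrt(2)
  n <- 2000; r <- 0.6
  z <- matrix(rnorm(2 * n), n, 2)
  x <- cbind(z[, 1], r * z[, 1] + sqrt(1 - r^2) * z[, 2])
  tab <- pca_table(x)
  std <- standardize_within_time(tab, c("v1", "v2"))
  model <- fit_pca(std)
  # independent oracle: eigen() of the sample correlation matrix
  ev <- eigen(stats::cor(x))$vectors
  for (j in 1:2) {
    cosine <- abs(sum(model$loadings[, j] * ev[, j]))
    expect_gt(cosine, 0.999)
  }
  expect_equal(model$explained[1], (1 + abs(cor(std$x)[1, 2])) / 2,
               tolerance = 0.01)
  # orthonormality
  G <- t(model$loadings) %*% model$loadings
  expect_equal(G, diag(ncol(G)), tolerance = 1e-10, ignore_attr = TRUE)
  # deterministic sign convention
  for (j in 1:2) expect_gt(max(model$loadings[, j]), 0)
})

test_that("projection is consistent, linear, and schema-checked", {
  set.seed(3)
  x <- matrix(rnorm(200), 40, 5)
  std <- standardize_within_time(pca_table(x), paste0("v", 1:5))
  model <- fit_pca(std)
  sc <- pca_project(model, std)
  # projecting the fit data reproduces the fit scores (svd consistency)
  pc <- stats::prcomp(std$x, center = FALSE)
  expect_equal(abs(sc), abs(pc$x[, 1:ncol(sc)]), tolerance = 1e-8,
               ignore_attr = TRUE)
  # score covariance of fit data is diagonal
  cv <- stats::cov(sc)
  expect_equal(cv[upper.tri(cv)], rep(0, sum(upper.tri(cv))),
               tolerance = 1e-8)
  # linearity
  a <- std$x[1, , drop = FALSE]; b <- std$x[2, , drop = FALSE]
  expect_equal(pca_project(model, 2 * a + 3 * b),
               2 * pca_project(model, a) + 3 * pca_project(model, b),
               tolerance = 1e-10)
  # schema error on variable mismatch
  bad <- std; bad$variables <- paste0("w", 1:5)
  expect_error(pca_project(model, bad), "variable set")
})

test_that("95% ellipse has the advertised coverage on bivariate normals", {
  set.seed(4)
  sc <- cbind(rnorm(10000), rnorm(10000) * 2 + 1)
  e <- ellipse_95(sc)
  cov_emp <- mean(ellipse_contains(e, sc))
  expect_lt(abs(cov_emp - 0.95), 0.015)
  # isotropic data give near-equal axes
  iso <- cbind(rnorm(5000), rnorm(5000))
  ei <- ellipse_95(iso)
  lam <- eigen(ei$cov)$values
  expect_lt(lam[1] / lam[2], 1.1)
  # tiny groups are skipped
  expect_message(expect_null(ellipse_95(sc[1:2, ])), "skipped")
})

test_that("top_loadings ranks by PC1-PC2 norm with stable ties", {
  set.seed(5)
  x <- matrix(rnorm(600), 50, 12)
  colnames(x) <- c(feature_variables()$metabolic)
  std <- list(x = scale(x), variables = colnames(x))
  model <- fit_pca(std)
  tl <- top_loadings(model, 12)
  expect_equal(nrow(tl), 12)
  expect_true(all(diff(tl$norm) <= 1e-12))
  expect_true(all(tl$class == "metabolic"))
  expect_warning(tl2 <- top_loadings(model, 40), "clipped")
  expect_equal(nrow(tl2), 12)
  tl24 <- top_loadings(model, 5)
  expect_equal(nrow(tl24), 5)
})

test_that("solid and hollow phantom subpopulations separate on PC1-PC2", {
  # pool pretreatment organoids from several phantom wells; a balanced
  # phenotype mix keeps both groups populated at this small n
  feats <- list()
  for (s in 1:5) {
    ph <- generate_phantom_series(small_phantom_config(100 + s,
                                                       frac_hollow = 0.5))
    masks <- ph$truth$masks[1]
    cs <- lapply(masks, extract_centroids)
    tr <- data.frame(track_id = cs[[1]]$label, frame = 1, time_h = 0,
                     label = cs[[1]]$label, y = cs[[1]]$y, x = cs[[1]]$x)
    ft <- build_feature_table(tr, masks, ph$series)
    ft$phenotype <- ph$truth$per_organoid$phenotype[
      ph$truth$per_organoid$frame == 1]
    ft$organoid_id <- paste(s, ft$organoid_id)
    feats[[s]] <- ft
  }
  ft <- do.call(rbind, feats)
  expect_gte(sum(ft$phenotype == "hollow"), 3)
  std <- standardize_within_time(ft)
  model <- fit_pca(std)
  sc <- pca_project(model, std)
  sil <- silhouette_mean(sc[, 1:2], ft$phenotype)
  expect_gt(sil, 0.2)
  # centroid separation exceeds within-group spread on PC1-PC2
  mu_h <- colMeans(sc[ft$phenotype == "hollow", 1:2, drop = FALSE])
  mu_s <- colMeans(sc[ft$phenotype == "solid", 1:2, drop = FALSE])
  spread <- mean(c(apply(sc[ft$phenotype == "solid", 1:2], 2, sd)))
  expect_gt(sqrt(sum((mu_h - mu_s)^2)), spread)
})
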