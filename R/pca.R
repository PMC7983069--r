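# Multivariate subpopulation analysis: within-timepoint standardization,
# PCA loadings learned on pretreatment data, out-of-sample projection of
# later time points, top-loading report and 95% coverage ellipses.

#' Standardize feature variables within each time point
#'
#' Each variable is z-scored (mean 0, SD 1) separately at every time point,
#' removing scale differences between the 24 variables before PCA.
#' Variables that are constant at a time point are dropped for that
#' standardization (logged in `attr(,"dropped")`).
#'
#' @param table a feature table.
#' @param variables variable names (default: all 24).
#' @return list: `x` (standardized matrix, rows = organoid-times),
#'   `meta` (key columns), `center`/`scale` per time point, `dropped`.
#' @export
standardize_within_time <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- c(metabolic_vars, morphological_vars)
  miss <- setdiff(variables, names(table))
  if (length(miss))
    stop_orx("missing variable column(s): %s", paste(miss, collapse = ", "),
             class = "orx_schema_error")
  times <- sort(unique(table$time_h))
  x <- as.matrix(table[, variables])
  center <- scale_ <- list()
  dropped <- character(0)
  for (t in times) {
    sel <- table$time_h == t
    if (sum(sel) < 2)
      stop_orx("need >= 2 organoids at time %g", t,
               class = "orx_validation_error")
    mu <- colMeans(x[sel, , drop = FALSE])
    sd_ <- apply(x[sel, , drop = FALSE], 2, stats::sd)
    bad <- sd_ == 0 | is.na(sd_)
    if (any(bad)) {
      dropped <- union(dropped, variables[bad])
      sd_[bad] <- 1
    }
    x[sel, ] <- sweep(sweep(x[sel, , drop = FALSE], 2, mu), 2, sd_, "/")
    key <- as.character(t)
    center[[key]] <- mu; scale_[[key]] <- sd_
  }
  list(x = x,
       meta = table[, intersect(c("organoid_id", "well", "treatment",
                                  "time_h", "frame"), names(table))],
       center = center, scale = scale_, variables = variables,
       dropped = dropped)
}

#' Fit the pretreatment PCA model
#'
#' Principal components of the standardized pretreatment data via singular
#' value decomposition. Loadings use a deterministic sign convention: the
#' entry of largest magnitude in each component is positive. Retained
#' components: `min(rows - 1, n variables)`.
#'
#' @param std a [standardize_within_time] result (or a plain standardized
#'   matrix), pretreatment rows only.
#' @return object of class `orx_pca`: `loadings` (variables x components),
#'   `sdev`, `explained` (variance fractions), `variables`.
#' @export
fit_pca <- function(std) {
  x <- if (is.list(std)) std$x else std
  vars <- if (is.list(std)) std$variables else colnames(x)
  if (nrow(x) < 3)
    stop_orx("need >= 3 rows to fit a PCA", class = "orx_validation_error")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(nrow(x) - 1, ncol(x))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  ev <- pc$sdev[seq_len(k)]^2
  structure(list(loadings = load, sdev = sqrt(ev),
                 explained = ev / sum(pc$sdev^2),
                 variables = vars),
            class = "orx_pca")
}

#' @export
print.orx_pca <- function(x, ...) {
  cat(sprintf("PCA on %d variables, %d components; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$loadings), ncol(x$loadings),
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Project standardized data onto the pretreatment PC basis
#'
#' Data at any time point are standardized within their own time point and
#' multiplied by the pretreatment loading matrix, so posttreatment
#' organoids are expressed in the pretreatment component space.
#'
#' @param model an `orx_pca` from [fit_pca].
#' @param std a [standardize_within_time] result or standardized matrix
#'   with the same variable set as the fit.
#' @return matrix of scores (rows x components).
#' @export
pca_project <- function(model, std) {
  x <- if (is.list(std)) std$x else std
  vars <- if (is.list(std)) std$variables else colnames(x)
  if (!identical(vars, model$variables))
    stop_orx("variable set does not match the fitted model",
             class = "orx_schema_error")
  x %*% model$loadings
}

#' Biplot display scaling factor
#'
#' Scores are scaled to fit inside the loadings interval:
#' `max|loading| / max|score|` over the first two components.
#'
#' @param model an `orx_pca`.
#' @param scores score matrix from [pca_project].
#' @return scalar scale factor.
#' @export
biplot_scale <- function(model, scores) {
  ms <- max(abs(scores[, 1:2]))
  if (ms == 0) return(1)
  max(abs(model$loadings[, 1:2])) / ms
}

#' 95% bivariate-normal coverage ellipse of a score cloud
#'
#' Mean and covariance of the group's (PC1, PC2) scores with the
#' chi-squared(2 df) 0.95 quantile radius, i.e. the ellipse that contains
#' 95% of the points under a bivariate normal model.
#'
#' @param scores matrix of scores (>= 2 columns).
#' @param group optional logical/index vector selecting the group's rows.
#' @param level coverage level (default 0.95).
#' @return list of class `orx_ellipse`: `center`, `cov`, `radius2`
#'   (squared Mahalanobis radius), `level`, `n`; or `NULL` (with a
#'   message) for groups of fewer than 3 points.
#' @export
ellipse_95 <- function(scores, group = NULL, level = 0.95) {
  s <- scores[, 1:2, drop = FALSE]
  if (!is.null(group)) s <- s[group, , drop = FALSE]
  if (nrow(s) < 3) {
    message("ellipse skipped: fewer than 3 points")
    return(NULL)
  }
  structure(list(center = colMeans(s), cov = stats::cov(s),
                 radius2 = stats::qchisq(level, df = 2), level = level,
                 n = nrow(s)),
            class = "orx_ellipse")
}

#' Does the ellipse contain each point?
#'
#' @param ellipse an `orx_ellipse`.
#' @param scores 2-column matrix of points.
#' @return logical vector.
#' @export
ellipse_contains <- function(ellipse, scores) {
  d <- sweep(scores[, 1:2, drop = FALSE], 2, ellipse$center)
  m2 <- rowSums((d %*% solve(ellipse$cov)) * d)
  m2 <= ellipse$radius2
}

#' Top variables loading on PC1 and PC2
#'
#' Variables ranked by the Euclidean norm of their (PC1, PC2) loadings;
#' the display convention keeps the `k` strongest contributors. Ties are
#' broken by variable name for determinism.
#'
#' @param model an `orx_pca`.
#' @param k how many variables (default 12; clipped with a warning).
#' @return data frame: `variable`, `norm`, `pc1`, `pc2`, `class`
#'   (metabolic/morphological), ranked.
#' @export
top_loadings <- function(model, k = 12) {
  L <- model$loadings
  if (k > nrow(L)) {
    warning("k clipped to the number of variables")
    k <- nrow(L)
  }
  nrm <- sqrt(L[, 1]^2 + L[, 2]^2)
  ord <- order(-nrm, rownames(L))
  sel <- ord[seq_len(k)]
  data.frame(variable = rownames(L)[sel], norm = nrm[sel],
             pc1 = L[sel, 1], pc2 = L[sel, 2],
             class = ifelse(rownames(L)[sel] %in% metabolic_vars,
                            "metabolic", "morphological"),
             row.names = NULL)
}
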