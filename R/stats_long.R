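# Longitudinal statistics: pretreatment normalization, random-intercept
# mixed-effect model with AR(1) residual correlation, pooled fixed-effects
# comparison, estimated-marginal-means Tukey contrasts, bivariate
# regressions, and the 24x24 pretreatment correlation matrix.

#' Pretreatment normalization of a longitudinal variable
#'
#' Organoid-level mode divides each organoid's posttreatment values by that
#' organoid's own pretreatment value (single-organoid tracking);
#' well-level mode divides by the well's pretreatment mean (pooled
#' analysis, mimicking data without tracking). Pretreatment rows are
#' flagged excluded (their normalized value is 1 by construction at
#' organoid level); organoids (or wells) with a zero, missing or absent
#' pretreatment denominator are dropped with a logged reason.
#'
#' @param table a feature table ([build_feature_table]).
#' @param variable which variable to normalize (e.g. `"orr_mean"` or
#'   `"area"`).
#' @param mode `"organoid"` or `"well"`.
#' @param pre_time_h the pretreatment time point (default 0).
#' @return data frame with `organoid_id`, `well`, `treatment`, `time_h`,
#'   `tindex` (1-based posttreatment time index), `Y` (normalized value)
#'   and `pretreatment` flag; dropped units in `attr(,"dropped")`.
#' @export
normalize_series <- function(table, variable = "orr_mean",
                             mode = c("organoid", "well"), pre_time_h = 0) {
  mode <- match.arg(mode)
  if (!variable %in% names(table))
    stop_orx("variable '%s' not in table", variable,
             class = "orx_validation_error")
  d <- data.frame(organoid_id = table$organoid_id, well = table$well,
                  treatment = table$treatment, time_h = table$time_h,
                  value = table[[variable]])
  pre <- d[d$time_h == pre_time_h, ]
  dropped <- character(0)
  if (mode == "organoid") {
    den <- stats::setNames(pre$value, pre$organoid_id)
    keyed <- den[as.character(d$organoid_id)]
    bad <- unique(d$organoid_id[is.na(keyed) | keyed <= 0])
    if (length(bad))
      dropped <- sprintf("organoid %s: missing or non-positive pretreatment %s",
                         bad, variable)
    d <- d[!(d$organoid_id %in% bad), , drop = FALSE]
    d$Y <- d$value / den[as.character(d$organoid_id)]
  } else {
    wm <- tapply(pre$value, pre$well, mean, na.rm = TRUE)
    keyed <- wm[as.character(d$well)]
    badw <- unique(d$well[is.na(keyed) | keyed <= 0])
    if (length(badw))
      dropped <- sprintf("well %s: missing or non-positive pretreatment mean %s",
                         badw, variable)
    d <- d[!(d$well %in% badw), , drop = FALSE]
    d$Y <- d$value / wm[as.character(d$well)]
  }
  d$pretreatment <- d$time_h == pre_time_h
  post_times <- sort(unique(d$time_h[!d$pretreatment]))
  d$tindex <- match(d$time_h, post_times)  # NA for pretreatment rows
  out <- d[, c("organoid_id", "well", "treatment", "time_h", "tindex",
               "Y", "pretreatment")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "mode") <- mode
  out
}

model_frame <- function(series) {
  d <- series[!series$pretreatment & !is.na(series$Y), , drop = FALSE]
  d$time_f <- factor(d$time_h, levels = sort(unique(d$time_h)))
  d$treatment <- factor(d$treatment)
  d$organoid <- factor(paste(d$well, d$organoid_id, sep = ":"))
  d
}

check_design <- function(d) {
  tab <- table(d$treatment, d$time_f)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop_orx("empty design cell: treatment '%s' at time %s",
             rownames(tab)[empty[1]], colnames(tab)[empty[2]],
             class = "orx_design_error")
  }
}

#' Random-intercept mixed model with AR(1) residual correlation
#'
#' Fits `Y ~ time + treatment + treatment:time` with time as a categorical
#' factor (no linearity assumption), a random intercept per organoid to
#' absorb organoid-level heterogeneity, and a first-order autoregressive
#' correlation of the within-organoid residuals over the ordered
#' posttreatment time index. Estimation is REML (`nlme::lme`), with an ML
#' fallback on convergence failure (warned).
#'
#' @param series output of [normalize_series] (organoid mode).
#' @return object of class `orx_lmm`: the `nlme` fit plus extracted
#'   random-intercept SD, AR(1) rho, residual SD and the model frame.
#' @export
fit_lmm <- function(series) {
  d <- model_frame(series)
  if (nlevels(d$time_f) < 2)
    stop_orx("need >= 2 posttreatment time points",
             class = "orx_design_error")
  check_design(d)
  fixed <- if (nlevels(d$treatment) > 1) Y ~ time_f * treatment else Y ~ time_f
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | organoid,
              correlation = nlme::corAR1(form = ~ tindex | organoid),
              data = d, method = "REML",
              control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                         msMaxIter = 100, tolerance = 1e-8)),
    error = function(e) {
      warning("REML fit failed (", conditionMessage(e),
              "); falling back to ML")
      nlme::lme(fixed, random = ~ 1 | organoid,
                correlation = nlme::corAR1(form = ~ tindex | organoid),
                data = d, method = "ML",
                control = nlme::lmeControl(opt = "optim", maxIter = 100,
                                           msMaxIter = 100))
    })
  vc <- nlme::VarCorr(fit)
  structure(list(fit = fit, data = d,
                 intercept_sd = suppressWarnings(
                   as.numeric(vc["(Intercept)", "StdDev"])),
                 rho = ar1_rho(fit),
                 sigma = fit$sigma,
                 logLik = as.numeric(stats::logLik(fit)),
                 pooled = FALSE),
            class = "orx_lmm")
}

#' Pooled fixed-effects model (no random intercept)
#'
#' The pooled counterpart of [fit_lmm]: `Y ~ time + treatment +
#' treatment:time` by generalized least squares with the same AR(1)
#' within-organoid residual correlation but no organoid random effect,
#' for well-level-normalized data.
#'
#' @param series output of [normalize_series] (well mode).
#' @return object of class `orx_lmm` with `pooled = TRUE`.
#' @export
fit_pooled <- function(series) {
  d <- model_frame(series)
  if (nlevels(d$time_f) < 2)
    stop_orx("need >= 2 posttreatment time points",
             class = "orx_design_error")
  check_design(d)
  fixed <- if (nlevels(d$treatment) > 1) Y ~ time_f * treatment else Y ~ time_f
  fit <- nlme::gls(fixed,
                   correlation = nlme::corAR1(form = ~ tindex | organoid),
                   data = d, method = "REML",
                   control = nlme::glsControl(maxIter = 100, msMaxIter = 100))
  structure(list(fit = fit, data = d, intercept_sd = 0,
                 rho = ar1_rho(fit), sigma = fit$sigma,
                 logLik = as.numeric(stats::logLik(fit)), pooled = TRUE),
            class = "orx_lmm")
}

ar1_rho <- function(fit) {
  cs <- fit$modelStruct$corStruct
  if (is.null(cs)) return(NA_real_)
  unname(stats::coef(cs, unconstrained = FALSE)["Phi"])
}

#' @export
print.orx_lmm <- function(x, ...) {
  cat(sprintf("%s model: %d obs, %d organoids | AR(1) rho = %.3f, sigma = %.4f",
              if (x$pooled) "pooled GLS" else "random-intercept LME",
              nrow(x$data), nlevels(x$data$organoid), x$rho, x$sigma))
  if (!x$pooled) cat(sprintf(", intercept SD = %.4f", x$intercept_sd))
  cat("\n")
  invisible(x)
}

#' Pairwise treatment contrasts at each time point
#'
#' Estimated marginal means (least-squares means) per treatment and time
#' point, with all pairwise treatment differences within each time point
#' and Tukey-adjusted p values (the multiplicity family is the set of
#' pairs within one time point).
#'
#' @param model an `orx_lmm` from [fit_lmm] or [fit_pooled].
#' @return data frame: `time_h`, `group1`, `group2`, `estimate` (group1 -
#'   group2 on the normalized scale), `percent_diff` (`estimate * 100`),
#'   `SE`, `df`, `p_adj`, `p_unadj`, `significant` (p_adj < 0.05).
#' @export
lsmeans_contrasts <- function(model) {
  stopifnot(inherits(model, "orx_lmm"))
  d <- model$data
  if (nlevels(d$treatment) < 2)
    stop_orx("contrasts need >= 2 treatment groups",
             class = "orx_design_error")
  em <- if (inherits(model$fit, "lme"))
    emmeans::emmeans(model$fit, ~ treatment | time_f, data = d,
                     mode = "containment")
  else emmeans::emmeans(model$fit, ~ treatment | time_f, data = d,
                        mode = "df.error")
  tuk <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  raw <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  pair <- strsplit(as.character(tuk$contrast), " - ", fixed = TRUE)
  out <- data.frame(
    time_h = as.numeric(as.character(tuk$time_f)),
    group1 = vapply(pair, `[`, "", 1),
    group2 = vapply(pair, `[`, "", 2),
    estimate = tuk$estimate,
    percent_diff = 100 * tuk$estimate,
    SE = tuk$SE, df = tuk$df,
    p_adj = tuk$p.value, p_unadj = raw$p.value)
  out$significant <- out$p_adj < 0.05
  out
}

#' Bivariate linear regression between two organoid variables
#'
#' Ordinary least squares of `y` on `x` with the Pearson correlation and
#' the two-sided p value of the slope.
#'
#' @param table a feature table (typically pretreatment rows).
#' @param x,y variable names.
#' @return list: `slope`, `intercept`, `r`, `p`, `n`.
#' @export
bivariate_fit <- function(table, x, y) {
  xv <- table[[x]]; yv <- table[[y]]
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3)
    stop_orx("need >= 3 paired observations", class = "orx_validation_error")
  if (stats::sd(xv) == 0)
    stop_orx("x has zero variance", class = "orx_validation_error")
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(xv, yv),
       p = sm$coefficients[2, 4],
       n = length(xv))
}

#' Pairwise correlation matrix of the 24 variables
#'
#' Pearson correlations between all 24 variables on (by default)
#' pretreatment rows, with a significance mask at p < 0.05 (unadjusted).
#' Constant variables are masked `NA` and logged.
#'
#' @param table a feature table.
#' @param time_h which time point to use (default 0 = pretreatment);
#'   `NULL` uses all rows.
#' @return list: `r` (24x24), `p`, `significant` (logical mask),
#'   `dropped` (constant variables).
#' @export
correlation_matrix <- function(table, time_h = 0) {
  vars <- c(metabolic_vars, morphological_vars)
  d <- if (is.null(time_h)) table else table[table$time_h == time_h, ]
  if (nrow(d) < 4)
    stop_orx("need >= 4 organoids", class = "orx_validation_error")
  m <- as.matrix(d[, vars])
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  dropped <- vars[is.na(sds) | sds == 0]
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  n <- nrow(m)
  tstat <- r * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  r[dropped, ] <- NA; r[, dropped] <- NA
  p[dropped, ] <- NA; p[, dropped] <- NA
  diag(r)[!(vars %in% dropped)] <- 1
  list(r = r, p = p, significant = !is.na(p) & p < 0.05, dropped = dropped)
}

#' Simulate organoid-level normalized longitudinal data
#'
#' Generates data from the random-intercept AR(1) model used by
#' [fit_lmm]: `Y = 1 + b_organoid + effect(treatment, time) + e`, with
#' `b ~ N(0, intercept_sd^2)` and AR(1) errors of marginal SD `sigma` and
#' lag-1 correlation `rho` over the time index. Used for parameter and
#' power recovery studies.
#'
#' @param n_per_group organoids per treatment group.
#' @param times_h posttreatment time points.
#' @param treatments treatment labels; the first is the reference.
#' @param effect matrix `length(treatments) x length(times_h)` of additive
#'   treatment effects (reference row usually 0).
#' @param intercept_sd,rho,sigma variance components.
#' @param seed integer seed.
#' @return data frame shaped like [normalize_series] output (posttreatment
#'   rows only).
#' @export
simulate_normalized_series <- function(n_per_group = 15,
                                       times_h = c(0.33, 12, 24, 36, 48),
                                       treatments = c("control", "treated"),
                                       effect = NULL,
                                       intercept_sd = 0.1, rho = 0.5,
                                       sigma = 0.05, seed = 1) {
  ng <- length(treatments); K <- length(times_h)
  if (is.null(effect)) effect <- matrix(0, ng, K)
  stopifnot(nrow(effect) == ng, ncol(effect) == K)
  with_seed(seed, {
    rows <- list()
    org_id <- 0
    for (g in seq_len(ng)) {
      for (i in seq_len(n_per_group)) {
        org_id <- org_id + 1
        b <- stats::rnorm(1, 0, intercept_sd)
        e <- numeric(K)
        e[1] <- stats::rnorm(1, 0, sigma)
        for (k in seq_len(K - 1))
          e[k + 1] <- rho * e[k] + stats::rnorm(1, 0, sigma * sqrt(1 - rho^2))
        rows[[org_id]] <- data.frame(
          organoid_id = org_id, well = treatments[g],
          treatment = treatments[g], time_h = times_h,
          tindex = seq_len(K),
          Y = 1 + b + effect[g, ] + e,
          pretreatment = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "mode") <- "organoid"
    out
  })
}
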