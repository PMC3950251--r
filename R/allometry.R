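#' Log-log allometric calibration by ordinary least squares
#'
#' Fits `log10(M_b) = a + b * log10(vol_CH)` by OLS, the Type-I model of
#' choice when the curve will be used predictively. Confidence intervals use
#' the t distribution with n - 2 degrees of freedom; `MSE = RSS / (n - 2)`
#' is the regression mean square error on the log10 scale and drives the
#' back-transformation correction factor; AIC is the Gaussian
#' maximum-likelihood criterion with k = 3 estimated parameters (intercept,
#' slope, residual variance).
#'
#' @param dataset a `calibration_dataset` with at least 3 rows.
#' @return An object of class `ols_fit`: `a`, `b`, `ci_a`, `ci_b` (95%),
#'   `se_a`, `se_b`, `r2`, `mse`, `aic`, `lnl`, `n`, `residuals` (log10),
#'   plus internals used for prediction intervals (`xbar`, `sxx`,
#'   `vol_range`).
#' @examples
#' tab <- load_calibration_table("packaged")
#' fit_ols_loglog(tab[tab$group == "non-primate mammal", ])
#' @export
fit_ols_loglog <- function(dataset) {
  dataset <- .as_cd(dataset)
  n <- nrow(dataset)
  if (n < 3L) stop("need at least 3 records to fit a calibration curve, got ", n)
  x <- log10(dataset$vol_CH_m3)
  y <- log10(dataset$M_b_kg)
  if (var(x) <= 0) stop("singular design: zero variance in log10(vol_CH)")
  m <- lm(y ~ x)
  .ols_from_lm(m, x, y, n, vol_range = range(dataset$vol_CH_m3))
}

.ols_from_lm <- function(m, x, y, n, vol_range) {
  rss <- sum(resid(m)^2)
  tss <- sum((y - mean(y))^2)
  s2_ml <- rss / n
  lnl <- -n / 2 * (log(2 * pi * s2_ml) + 1)
  ci <- confint(m, level = 0.95)
  sm <- summary(m)
  structure(list(
    a = unname(coef(m)[1]), b = unname(coef(m)[2]),
    ci_a = unname(ci[1, ]), ci_b = unname(ci[2, ]),
    se_a = sm$coefficients[1, 2], se_b = sm$coefficients[2, 2],
    r2 = 1 - rss / tss,
    mse = rss / (n - 2),
    lnl = lnl,
    aic = -2 * lnl + 2 * 3,
    n = n,
    residuals = unname(resid(m)),
    xbar = mean(x), sxx = sum((x - mean(x))^2),
    vol_range = vol_range), class = "ols_fit")
}

.as_cd <- function(dataset) {
  if (inherits(dataset, "calibration_dataset")) return(dataset)
  as_calibration_dataset(as.data.frame(dataset))
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "<OLS log10-log10 fit> n=%d\n  a = %.4f [%.4f, %.4f]\n  b = %.4f [%.4f, %.4f]\n  r2 = %.4f  MSE = %.5f  AIC = %.2f\n",
    x$n, x$a, x$ci_a[1], x$ci_a[2], x$b, x$ci_b[1], x$ci_b[2],
    x$r2, x$mse, x$aic))
  invisible(x)
}

#' Back-transformation correction factor
#'
#' Predictions back-transformed from a log10 regression are geometric means;
#' multiplying by `CF = exp(MSE * ln(10)^2 / 2)` (the base-10 Baskerville
#' smearing correction) converts them to arithmetic means under log-normal
#' residuals.
#'
#' @param mse mean square error of the log10 regression (>= 0).
#' @return The correction factor, a number >= 1; exactly 1 when `mse` is 0.
#' @examples
#' correction_factor(0.0052)
#' @export
correction_factor <- function(mse) {
  if (!is.numeric(mse) || any(mse < 0)) stop("MSE must be >= 0")
  exp(mse * log(10)^2 / 2)
}

#' A calibration curve packaged for prediction
#'
#' Bundles an OLS fit with its correction factor and a group label, giving
#' the power-law predictive equation `M = CF * 10^a * V^b`.
#'
#' @param fit an `ols_fit`.
#' @param group_label label of the calibration group.
#' @return Object of class `predictive_equation`.
#' @export
predictive_equation <- function(fit, group_label = "") {
  stopifnot(inherits(fit, "ols_fit"))
  structure(list(fit = fit, CF = correction_factor(fit$mse),
                 group_label = group_label), class = "predictive_equation")
}

#' Predict body mass from a convex-hull volume
#'
#' Point estimate `10^(a + b log10 V)`, optionally multiplied by the
#' correction factor, with a 95% prediction interval computed on the log10
#' scale (standard new-observation variance) and back-transformed. The
#' interval brackets the uncorrected geometric-mean prediction. A warning is
#' raised when `vol` falls outside the calibration volume range, since
#' extrapolated log-log predictions are the main hazard of applying these
#' curves to fossils.
#'
#' @param vol convex-hull volume(s) in m^3, > 0.
#' @param eq a [predictive_equation()] (or an `ols_fit`, CF computed on the
#'   fly).
#' @param apply_cf multiply the point estimate by the correction factor?
#' @return data.frame with `vol`, `mass` (kg), `mass_cf`, `lwr`, `upr`,
#'   `extrapolated`.
#' @export
predict_mass <- function(vol, eq, apply_cf = TRUE) {
  if (inherits(eq, "ols_fit")) eq <- predictive_equation(eq)
  stopifnot(inherits(eq, "predictive_equation"))
  if (any(!is.finite(vol)) || any(vol <= 0)) stop("volumes must be > 0")
  f <- eq$fit
  lx <- log10(vol)
  ly <- f$a + f$b * lx
  se_pred <- sqrt(f$mse * (1 + 1 / f$n + (lx - f$xbar)^2 / f$sxx))
  tq <- qt(0.975, f$n - 2)
  extrap <- vol < f$vol_range[1] | vol > f$vol_range[2]
  if (any(extrap))
    warning(sprintf(
      "%d volume(s) outside the calibration range [%.3g, %.3g] m^3: extrapolated",
      sum(extrap), f$vol_range[1], f$vol_range[2]))
  data.frame(vol = vol,
             mass = 10^ly * if (apply_cf) eq$CF else 1,
             mass_cf = 10^ly * eq$CF,
             lwr = 10^(ly - tq * se_pred),
             upr = 10^(ly + tq * se_pred),
             extrapolated = extrap)
}

#' Mean percentage prediction error
#'
#' In-sample prediction quality of a calibration curve on the arithmetic
#' scale: for each record, `PE = 100 * |M_obs - M_pred| / M_pred`, with
#' `M_pred` the back-transformed OLS prediction without correction factor
#' (the mass-estimation convention); the mean and its t-based 95% confidence
#' interval are reported. Set `denominator = "observed"` for the
#' alternative `|M_obs - M_pred| / M_obs` convention.
#'
#' @param dataset the `calibration_dataset` the fit was computed from.
#' @param fit the corresponding `ols_fit`.
#' @param denominator `"predicted"` (default) or `"observed"`.
#' @return List with `mean_PE` (percent), `ci_PE`, `per_record_PE`.
#' @export
percent_prediction_error <- function(dataset, fit,
                                     denominator = c("predicted", "observed")) {
  dataset <- .as_cd(dataset)
  stopifnot(inherits(fit, "ols_fit"))
  denominator <- match.arg(denominator)
  if (nrow(dataset) != fit$n)
    stop("dataset has ", nrow(dataset), " rows but the fit used ", fit$n)
  pred <- 10^(fit$a + fit$b * log10(dataset$vol_CH_m3))
  obs <- dataset$M_b_kg
  pe <- 100 * abs(obs - pred) / if (denominator == "predicted") pred else obs
  n <- length(pe)
  half <- qt(0.975, n - 1) * sd(pe) / sqrt(n)
  list(mean_PE = mean(pe),
       ci_PE = c(mean(pe) - half, mean(pe) + half),
       per_record_PE = pe)
}

#' Apparent density of convex-hulled skeletons
#'
#' `rho_CH = M_b / vol_CH` (kg/m^3) per specimen. Because all soft tissue
#' outside the skeletal hull is excluded from the volume, apparent densities
#' sit well above whole-carcass densities; their group means and scaling
#' with mass diagnose how "missing mass" varies across taxa.
#'
#' @param dataset a `calibration_dataset`.
#' @return List with `records` (data.frame `species, group, rho_CH, M_b_kg`)
#'   and `group_means` (named numeric, arithmetic means).
#' @export
apparent_density <- function(dataset) {
  dataset <- .as_cd(dataset)
  rec <- data.frame(species = dataset$species, group = dataset$group,
                    rho_CH = dataset$M_b_kg / dataset$vol_CH_m3,
                    M_b_kg = dataset$M_b_kg)
  list(records = rec,
       group_means = tapply(rec$rho_CH, rec$group, mean))
}

#' Regression of apparent density on log10 body mass
#'
#' OLS of density (linear scale, kg/m^3) on log10 mass; a non-zero slope
#' indicates that hull volume scales allometrically with mass in the group.
#'
#' @param records data.frame with columns `rho_CH` and `M_b_kg` (as returned
#'   in `apparent_density()$records`), n >= 3.
#' @return List with `a` (intercept), `b` (slope per log10 kg), `r2`,
#'   `p_slope`, `n`.
#' @export
density_mass_regression <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 records, got ", nrow(records))
  if (var(records$rho_CH) <= .Machine$double.eps * mean(records$rho_CH)^2) {
    # constant density: nothing to explain
    return(list(a = mean(records$rho_CH), b = 0, r2 = 0, p_slope = 1,
                n = nrow(records)))
  }
  m <- lm(rho_CH ~ log10(M_b_kg), data = records)
  sm <- summary(m)
  list(a = unname(coef(m)[1]), b = unname(coef(m)[2]),
       r2 = sm$r.squared,
       p_slope = unname(sm$coefficients[2, 4]),
       n = nrow(records))
}

#' ANCOVA comparison of group calibration slopes
#'
#' Tests whether the log10-log10 calibration slopes differ between groups.
#' The slope-heterogeneity F compares the separate-lines model (per-group
#' intercepts and slopes) with the common-slope model, i.e. the
#' group-by-log10(volume) interaction, on `(g - 1, N - 2g)` degrees of
#' freedom. Pairwise slope differences are then assessed with Tukey's HSD
#' using the studentized range on `N - 2g` df. The adjusted-means F (group
#' main effect at the centred covariate, the other row a classical ANCOVA
#' table prints) is reported alongside.
#'
#' @param datasets a single `calibration_dataset` with >= 2 group labels, or
#'   a list of datasets (list names become group labels).
#' @return List with `F` (interaction), `df`, `p`, `adjusted_means_F`,
#'   `adjusted_means_p`, `slopes` (per-group estimate and SE) and `tukey`
#'   (data.frame of pairwise slope contrasts with adjusted p-values).
#' @export
compare_slopes_ancova <- function(datasets) {
  df <- .stack_groups(datasets)
  g <- length(unique(df$group))
  if (g < 2L) stop("need at least 2 groups")
  tab <- table(df$group)
  if (any(tab < 3L))
    stop("every group needs n >= 3; too small: ",
         paste(names(tab)[tab < 3], collapse = ", "))
  df$group <- factor(df$group)
  df$lx <- log10(df$vol_CH_m3)
  df$ly <- log10(df$M_b_kg)
  full <- lm(ly ~ group * lx, data = df)
  common <- lm(ly ~ group + lx, data = df)
  an <- anova(common, full)
  N <- nrow(df)
  df2 <- N - 2 * g
  # adjusted-means F: group main effect with the covariate centred
  df$lxc <- df$lx - mean(df$lx)
  fullc <- lm(ly ~ group * lxc, data = df, contrasts = list(group = "contr.sum"))
  X <- model.matrix(fullc)
  grp_cols <- grep("^group\\d+$", colnames(X))
  bb <- coef(fullc)[grp_cols]
  V <- vcov(fullc)[grp_cols, grp_cols]
  F_adj <- drop(t(bb) %*% solve(V, bb)) / length(bb)
  p_adj_means <- pf(F_adj, g - 1, df2, lower.tail = FALSE)

  # per-group slopes and pairwise Tukey HSD on the slope estimates
  sep <- lm(ly ~ group / lx - 1, data = df)
  sl_idx <- grep(":lx$", names(coef(sep)))
  slopes <- coef(sep)[sl_idx]
  names(slopes) <- sub("^group(.*):lx$", "\\1", names(slopes))
  Vs <- vcov(sep)[sl_idx, sl_idx]
  pairs <- utils::combn(seq_along(slopes), 2)
  tk <- do.call(rbind, apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- slopes[i] - slopes[j]
    se <- sqrt(Vs[i, i] + Vs[j, j])  # independent slope estimates
    q <- abs(d) * sqrt(2) / se
    data.frame(pair = paste(names(slopes)[i], "-", names(slopes)[j]),
               diff = unname(d), se = se,
               p_adj = ptukey(q, nmeans = length(slopes), df = df2,
                              lower.tail = FALSE))
  }))
  tk$significant <- tk$p_adj < 0.05
  rownames(tk) <- NULL
  list(F = an$F[2], df = c(g - 1, df2), p = an$`Pr(>F)`[2],
       adjusted_means_F = F_adj, adjusted_means_p = p_adj_means,
       slopes = data.frame(group = names(slopes), b = unname(slopes),
                           se = sqrt(diag(Vs))),
       tukey = tk)
}

.stack_groups <- function(datasets) {
  if (inherits(datasets, "calibration_dataset") || is.data.frame(datasets))
    return(as.data.frame(.as_cd(datasets)))
  stopifnot(is.list(datasets))
  parts <- lapply(seq_along(datasets), function(i) {
    d <- as.data.frame(.as_cd(datasets[[i]]))
    if (!is.null(names(datasets)) && nzchar(names(datasets)[i]))
      d$group <- names(datasets)[i]
    d
  })
  do.call(rbind, parts)
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA of a response across group labels (used for
#' comparing mean apparent densities between taxonomic groups).
#'
#' @param values numeric response vector.
#' @param group group label per value (>= 2 groups, each n >= 2).
#' @return List with `F`, `df`, `p`.
#' @export
oneway_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs n >= 2")
  a <- anova(aov(values ~ group))
  list(F = a$`F value`[1], df = c(a$Df[1], a$Df[2]), p = a$`Pr(>F)`[1])
}

#' Regression assumption checks
#'
#' Shapiro-Wilk normality and Breusch-Pagan homoscedasticity tests on the
#' residuals of the mass-volume regression under the requested transform.
#' When the raw-scale fit fails either test at alpha = 0.05 the report
#' recommends the log10 transform, mirroring the standard workflow for
#' allometric data.
#'
#' @param dataset a `calibration_dataset` with n >= 4.
#' @param transform `"raw"` (mass on volume) or `"log10"` (default).
#' @return List with `shapiro` (statistic, p), `breusch_pagan`
#'   (statistic, p), `transform`, `recommend_log10`.
#' @export
assumption_checks <- function(dataset, transform = c("log10", "raw")) {
  dataset <- .as_cd(dataset)
  transform <- match.arg(transform)
  if (nrow(dataset) < 4L)
    stop("need at least 4 records for assumption checks, got ", nrow(dataset))
  m <- if (transform == "raw") {
    lm(M_b_kg ~ vol_CH_m3, data = dataset)
  } else {
    lm(log10(M_b_kg) ~ log10(vol_CH_m3), data = dataset)
  }
  sw <- shapiro.test(resid(m))
  bp <- lmtest::bptest(m)
  list(shapiro = list(statistic = unname(sw$statistic), p = sw$p.value),
       breusch_pagan = list(statistic = unname(bp$statistic), p = bp$p.value),
       transform = transform,
       recommend_log10 = transform == "raw" &&
         (sw$p.value < 0.05 || bp$p.value < 0.05))
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test (df = n - 1), as used to compare trunk hull
#' volumes before and after point-cloud down-sampling.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) != 0)
      stop("zero variance of differences with nonzero mean: t undefined")
    return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}
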