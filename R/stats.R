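#' Major-axis (model II) regression
#'
#' Ordinary least squares assumes the x variable is error-free; when both
#' variables carry errors of similar magnitude (two independent
#' measurement methods of the same flux) the major axis — the first
#' principal axis of the bivariate scatter — is the appropriate line.
#' The slope is the closed-form principal-axis solution
#' \deqn{b = (S_{yy} - S_{xx} + \sqrt{(S_{yy}-S_{xx})^2 + 4 S_{xy}^2}) / (2 S_{xy})}
#' and the intercept passes through the centroid. The confidence interval
#' for the slope is the classical F-based (Jolicoeur-type) interval on the
#' axis angle, \eqn{|\sin 2(\theta - \hat\theta)| \le \sqrt{H}} with
#' \eqn{H = 4 F_{\alpha;1,n-2} \lambda_1 \lambda_2 / ((n-2)(\lambda_1-\lambda_2)^2)}
#' (eigenvalues of the covariance matrix); when that interval is undefined
#' (H >= 1, the axis direction indistinguishable from vertical) a
#' percentile bootstrap of the slope is reported instead and flagged.
#' R-squared is the squared Pearson correlation and the p-value is the
#' correlation test (axis direction uninformative when r = 0).
#'
#' @param x,y numeric vectors (EC on x, BM on y by convention)
#' @param conf confidence level for the slope interval
#' @param nboot bootstrap resamples for the fallback interval
#' @param boot_seed seed for the bootstrap fallback (local RNG state)
#' @return object of class `regression_result`: slope, intercept,
#'   slope_ci95, r_squared, p_value, n, heteroskedastic (NA here),
#'   inference_method ("standard" or "bootstrap")
#' @export
ma_regression <- function(x, y, conf = 0.95, nboot = 2000, boot_seed = 71) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ma_regression() needs at least 3 complete pairs")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx + syy == 0) stop("ma_regression(): degenerate data (no variance)")
  if (sxy == 0) {
    if (sxx == syy) stop("ma_regression(): major axis undefined ",
                         "(circular scatter, Sxy = 0, Sxx = Syy)")
    if (syy > sxx) stop("ma_regression(): major axis vertical, ",
                        "slope undefined")
    slope <- 0
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  intercept <- mean(y) - slope * mean(x)

  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)$values
  l1 <- ev[1]; l2 <- max(ev[2], 0)
  Fv <- stats::qf(conf, 1, n - 2)
  H <- if (l1 == l2) Inf else 4 * Fv * l1 * l2 / ((n - 2) * (l1 - l2)^2)
  method <- "standard"
  if (H < 1) {
    half <- 0.5 * asin(sqrt(H))
    theta <- atan(slope)
    ci <- sort(tan(c(theta - half, theta + half)))
  } else {
    method <- "bootstrap"
    ci <- local({
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(boot_seed)
      bs <- replicate(nboot, {
        i <- sample.int(n, n, replace = TRUE)
        xv <- stats::var(x[i]); yv <- stats::var(y[i])
        xyv <- stats::cov(x[i], y[i])
        if (xyv == 0) NA_real_
        else (yv - xv + sqrt((yv - xv)^2 + 4 * xyv^2)) / (2 * xyv)
      })
      stats::quantile(bs, c((1 - conf) / 2, (1 + conf) / 2), na.rm = TRUE,
                      names = FALSE)
    })
  }

  if (sxx == 0 || syy == 0) {
    r <- NA_real_; pv <- NA_real_   # one margin constant: r undefined
  } else {
    r <- stats::cor(x, y)
    pv <- if (abs(r) == 1) 0 else stats::cor.test(x, y)$p.value
  }
  structure(list(
    slope = slope, intercept = intercept, slope_ci95 = ci,
    r_squared = r^2, p_value = pv, n = n,
    heteroskedastic = NA, inference_method = method),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "slope %.3f (CI95 %.3f-%.3f), intercept %.1f, R2 %.2f, P %.3g, n %d [%s]\n",
    x$slope, x$slope_ci95[1], x$slope_ci95[2],
    if (is.null(x$intercept) || is.na(x$intercept)) NA else x$intercept,
    x$r_squared, x$p_value, x$n, x$inference_method))
  invisible(x)
}

#' Normality-gated paired comparison
#'
#' Tests whether two paired series differ: a two-sided paired t-test when
#' the pair differences pass a Shapiro-Wilk normality check at
#' `alpha_gate`, otherwise a two-sided Wilcoxon signed-rank test (exact
#' distribution up to 25 non-zero differences without ties, normal
#' approximation with continuity correction beyond; zero differences
#' dropped, tied ranks averaged).
#'
#' @param a,b equal-length numeric vectors
#' @param alpha_gate normality-gate significance level
#' @return list of class `paired_compare`: mean_difference (a - b), sem,
#'   shapiro_p, test_used, p_value, n
#' @export
paired_compare <- function(a, b, alpha_gate = 0.05) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("paired_compare() needs at least 3 complete pairs")
  d <- a - b
  md <- mean(d)
  sem <- stats::sd(d) / sqrt(n)
  if (stats::sd(d) == 0) {
    return(structure(list(
      mean_difference = md, sem = 0, shapiro_p = NA_real_,
      test_used = "degenerate",
      p_value = if (md == 0) 1 else 0, n = n), class = "paired_compare"))
  }
  sh <- stats::shapiro.test(d)$p.value
  if (sh >= alpha_gate) {
    test <- "paired_t"
    p <- stats::t.test(d)$p.value
  } else {
    test <- "wilcoxon_signed_rank"
    dz <- d[d != 0]
    exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
    p <- suppressWarnings(
      stats::wilcox.test(dz, exact = exact, correct = TRUE)$p.value)
  }
  structure(list(mean_difference = md, sem = sem, shapiro_p = sh,
                 test_used = test, p_value = p, n = n),
            class = "paired_compare")
}

#' @export
print.paired_compare <- function(x, ...) {
  cat(sprintf("mean difference %.1f +/- %.1f, P %.4g (%s, n %d)\n",
              x$mean_difference, x$sem, x$p_value, x$test_used, x$n))
  invisible(x)
}

#' Two-sample comparison of group means
#'
#' Welch two-sample t-test (two-sided). When a group is (near) constant
#' the t-test is undefined and an exact permutation test on the difference
#' of means is used instead.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2
#' @return list: mean_a, sem_a, mean_b, sem_b, p_value, test_used, n_a, n_b
#' @export
group_compare <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("group_compare() needs n >= 2 per group")
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    p <- 1; test <- "degenerate"
  } else if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    test <- "permutation"
    pool <- c(a, b); na <- length(a)
    obs <- abs(mean(a) - mean(b))
    idx <- utils::combn(length(pool), na)
    stat <- apply(idx, 2, function(j) {
      abs(mean(pool[j]) - mean(pool[-j]))
    })
    p <- mean(stat >= obs - 1e-12)
  } else {
    test <- "welch_t"
    p <- stats::t.test(a, b)$p.value
  }
  list(mean_a = mean(a), sem_a = sem(a), mean_b = mean(b), sem_b = sem(b),
       p_value = p, test_used = test, n_a = length(a), n_b = length(b))
}

#' Inverse-uncertainty weights
#'
#' @param s positive uncertainty half-ranges
#' @param power 1 for weights 1/s (default, weighting by inverse
#'   uncertainty), 2 for inverse-variance weights 1/s^2
#' @return numeric weights
#' @export
inverse_uncertainty_weights <- function(s, power = 1) {
  stopifnot(all(s > 0), power %in% c(1, 2))
  1 / s^power
}

#' Uncertainty-weighted univariate screen
#'
#' Weighted least squares of a response (a between-method flux difference)
#' on one predictor, weighting sites by the inverse of their flux
#' uncertainty so noisier sites count less. Categorical predictors are
#' dummy-coded and tested with an overall F-test. Homoskedasticity of the
#' weighted residuals is checked with the Breusch-Pagan test at
#' `alpha_gate`; on failure, inference switches to the White
#' heteroskedasticity-robust covariance (HC0) and the reported R-squared
#' becomes the squared Pearson correlation between response and fitted
#' values (the weighted-least-squares R-squared is no longer meaningful).
#' Residual normality (Shapiro-Wilk on weighted residuals) is reported for
#' diagnostics.
#'
#' @param response numeric vector
#' @param predictor numeric vector, or factor/character for categories
#' @param weights positive weights (e.g. from
#'   [inverse_uncertainty_weights()]); unit weights give ordinary least
#'   squares
#' @param alpha_gate significance level of the Breusch-Pagan gate
#' @return object of class `regression_result` with slope (single-
#'   coefficient designs; NA for factors with >2 levels), intercept,
#'   slope_ci95, r_squared, p_value (overall predictor test), n,
#'   heteroskedastic, inference_method ("standard" or "white_robust"),
#'   and diagnostics (shapiro_p, bp_p, coefficients)
#' @export
weighted_screen <- function(response, predictor, weights = NULL,
                            alpha_gate = 0.05) {
  if (is.character(predictor)) predictor <- factor(predictor)
  ok <- stats::complete.cases(response, predictor)
  if (is.null(weights)) weights <- rep(1, length(response))
  ok <- ok & !is.na(weights)
  y <- response[ok]; x <- if (is.factor(predictor)) droplevels(predictor[ok])
                          else predictor[ok]
  w <- weights[ok]
  n <- length(y)
  if (any(w <= 0)) stop("weighted_screen(): weights must be > 0")
  k <- if (is.factor(x)) nlevels(x) - 1 else 1
  if (k < 1 || (is.factor(x) && nlevels(x) < 2) ||
      (!is.factor(x) && stats::var(x) == 0)) {
    stop("weighted_screen(): constant predictor (singular design)")
  }
  if (n < k + 2) stop("weighted_screen(): too few observations")

  dat <- data.frame(y = y, x = x)
  fit <- stats::lm(y ~ x, data = dat, weights = w)
  if (any(is.na(stats::coef(fit)))) {
    stop("weighted_screen(): singular design")
  }
  wres <- stats::residuals(fit) * sqrt(w)
  shapiro_p <- if (stats::sd(wres) > 0 && n >= 3 && n <= 5000) {
    stats::shapiro.test(wres)$p.value
  } else NA_real_
  # a (near-)exact fit leaves only numerical noise in the residuals;
  # heteroskedasticity is then meaningless and the gate stays open
  exact_fit <- sum(wres^2) <= 1e-12 * sum((y - mean(y))^2)
  bp_p <- if (exact_fit) NA_real_ else {
    tryCatch(suppressWarnings(lmtest::bptest(fit)$p.value),
             error = function(e) NA_real_)
  }
  hetero <- !is.na(bp_p) && bp_p < alpha_gate

  coefs <- stats::coef(fit)
  if (hetero) {
    vc <- suppressWarnings(sandwich::vcovHC(fit, type = "HC0"))
    wt <- lmtest::waldtest(fit, stats::update(fit, . ~ 1), vcov = vc,
                           test = "F")
    p_overall <- wt$`Pr(>F)`[2]
    r2 <- stats::cor(y, stats::fitted(fit))^2
    method <- "white_robust"
  } else {
    vc <- suppressWarnings(stats::vcov(fit))
    sm <- suppressWarnings(summary(fit))
    fs <- sm$fstatistic
    p_overall <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    r2 <- sm$r.squared
    method <- "standard"
  }

  slope <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (k == 1) {
    slope <- unname(coefs[2])
    se <- sqrt(vc[2, 2])
    tq <- stats::qt(0.975, n - 2)
    ci <- c(slope - tq * se, slope + tq * se)
  }
  structure(list(
    slope = slope, intercept = unname(coefs[1]), slope_ci95 = ci,
    r_squared = unname(r2), p_value = unname(p_overall), n = n,
    heteroskedastic = hetero, inference_method = method,
    shapiro_p = shapiro_p, bp_p = unname(bp_p), coefficients = coefs),
    class = "regression_result")
}

#' Two-way analysis of variance (type II)
#'
#' F-tests for two crossed factors and their interaction, using type-II
#' sums of squares so unbalanced designs are handled sensibly. When the
#' interaction is inestimable (empty factor crossing) its p-value is NA.
#'
#' @param response numeric vector
#' @param factor_a,factor_b factors or character vectors
#' @return list: p_a, p_b, p_interaction, table (the full ANOVA table),
#'   degenerate (TRUE when the response carries no variance)
#' @export
two_way_anova <- function(response, factor_a, factor_b) {
  dat <- data.frame(y = response, A = factor(factor_a), B = factor(factor_b))
  dat <- dat[stats::complete.cases(dat), ]
  dat$A <- droplevels(dat$A); dat$B <- droplevels(dat$B)
  occupied <- sum(table(dat$A, dat$B) > 0)
  if (occupied < 3) stop("two_way_anova() needs at least 3 occupied cells")
  if (stats::sd(dat$y) == 0) {
    return(list(p_a = NA_real_, p_b = NA_real_, p_interaction = NA_real_,
                table = NULL, degenerate = TRUE))
  }
  fit <- stats::lm(y ~ A * B, data = dat)
  tab <- suppressWarnings(car::Anova(fit, type = 2, singular.ok = TRUE))
  p <- tab[["Pr(>F)"]]
  rn <- rownames(tab)
  pick <- function(term) {
    i <- match(term, rn)
    if (is.na(i)) NA_real_ else p[i]
  }
  list(p_a = pick("A"), p_b = pick("B"), p_interaction = pick("A:B"),
       table = tab, degenerate = FALSE)
}

#' Leave-one-out sensitivity of a weighted screen
#'
#' Refits [weighted_screen()] with each site omitted in turn and reports
#' the resulting p-values, flagging sites whose omission moves the overall
#' p-value across the 0.05 or 0.10 significance thresholds — single
#' influential sites that create (or mask) an apparent relationship.
#'
#' @inheritParams weighted_screen
#' @return tibble: index, p_loo, r2_loo, crosses_05, crosses_10; attribute
#'   `p_full` carries the all-sites p-value
#' @export
outlier_sensitivity <- function(response, predictor, weights = NULL,
                                alpha_gate = 0.05) {
  if (is.null(weights)) weights <- rep(1, length(response))
  ok <- stats::complete.cases(response, predictor, weights)
  y <- response[ok]; x <- predictor[ok]; w <- weights[ok]
  n <- length(y)
  if (n < 5) stop("outlier_sensitivity() needs at least 5 observations")
  full <- weighted_screen(y, x, w, alpha_gate)
  res <- purrr::map_dfr(seq_len(n), function(i) {
    fit <- weighted_screen(y[-i], x[-i], w[-i], alpha_gate)
    tibble(index = i, p_loo = fit$p_value, r2_loo = fit$r_squared)
  })
  res$crosses_05 <- (full$p_value < 0.05) != (res$p_loo < 0.05)
  res$crosses_10 <- (full$p_value < 0.10) != (res$p_loo < 0.10)
  attr(res, "p_full") <- full$p_value
  res
}

#' Significance tier marks
#'
#' "**" for p < 0.01, "*" for p < 0.05, "+" for p < 0.10, "" otherwise.
#'
#' @param p numeric vector of p-values
#' @return character vector
#' @export
signif_marks <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.10 ~ "+",
    TRUE ~ ""
  )
}
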