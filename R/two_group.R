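#' Hedges' g standardized mean difference
#'
#' Pooled-SD Cohen's d with the small-sample bias correction
#' `J = 1 - 3 / (4 (n_a + n_b) - 9)`. Sign follows `mean(a) - mean(b)`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Bias-corrected standardized mean difference.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2)
    stop("hedges_g: each group needs n >= 2", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    if (mean(a) == mean(b)) return(0)
    stop("degenerate-data: pooled variance is zero", call. = FALSE)
  }
  J <- 1 - 3 / (4 * (na + nb) - 9)
  J * (mean(a) - mean(b)) / sqrt(sp2)
}

#' Conventional magnitude label for a standardized effect size
#'
#' |g| < 0.2 negligible, < 0.5 small, < 0.8 medium, else large.
#'
#' @param g Effect size (finite).
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
magnitude_label <- function(g) {
  stopifnot(all(is.finite(g)))
  cut(abs(g), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |> as.character()
}

#' Holm-Bonferroni step-down adjustment within one family
#'
#' Sorts the raw p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces the running maximum (monotonicity) and caps at 1;
#' results are returned in the original input order.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) stop("holm_adjust: empty family", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("holm_adjust: p-values must lie in [0, 1]", call. = FALSE)
  o <- order(p)
  adj <- p[o] * (m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Brown-Forsythe (median-centered) Levene test
#'
#' One-way ANOVA on absolute deviations from the group medians; the common
#' robust default for homoscedasticity gating.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (or coercible).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[groups])
  fit <- stats::aov(z ~ groups)
  tab <- summary(fit)[[1]]
  list(statistic = tab$`F value`[1], df = tab$Df, p.value = tab$`Pr(>F)`[1])
}

#' HC4 heteroscedasticity-robust OLS coefficient test
#'
#' Sandwich covariance with per-observation weights
#' `e_i^2 / (1 - h_i)^{delta_i}`, `delta_i = min(4, N h_i / p)` — the HC4
#' estimator, which discounts high-leverage residuals more aggressively than
#' HC0-HC3. Two-sided t-test on one coefficient with `N - p` df.
#'
#' @param x Design matrix (full rank, including intercept).
#' @param y Response vector.
#' @param coef_index Column of `x` whose coefficient is tested.
#' @return List with `estimate`, `se`, `statistic`, `df`, `p.value`,
#'   `vcov` (full HC4 covariance matrix).
#' @export
hc4_ols_p <- function(x, y, coef_index = 2L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (qr(x)$rank < p)
    stop("rank-deficiency: singular design matrix", call. = FALSE)
  xtxi <- solve(crossprod(x))
  beta <- drop(xtxi %*% crossprod(x, y))
  e <- drop(y - x %*% beta)
  h <- stats::hat(x)
  if (any(h >= 1 - 1e-12))
    stop("perfect-leverage: h_i = 1 for some observation", call. = FALSE)
  delta <- pmin(4, n * h / p)
  omega <- e^2 / (1 - h)^delta
  meat <- crossprod(x * omega, x)
  V <- xtxi %*% meat %*% xtxi
  se <- sqrt(diag(V))
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  list(estimate = beta[coef_index], se = se[coef_index],
       statistic = tstat[coef_index], df = n - p,
       p.value = pval[coef_index], vcov = V)
}

#' Assumption-gated two-group test
#'
#' Decision tree for a pairwise comparison of normalized rates:
#' \itemize{
#'   \item Shapiro-Wilk on pooled group-centered residuals (normality gate,
#'     alpha 0.05) and Brown-Forsythe Levene (variance gate, alpha 0.1);
#'   \item both pass: classical OLS/ANOVA F-test (`ols_anova`);
#'   \item normal but heteroscedastic: HC4 robust OLS (`ols_hc4`);
#'   \item non-normal: two-sided Wilcoxon rank-sum (`wilcoxon`), exact for
#'     small tie-free samples, normal approximation with continuity
#'     correction otherwise.
#' }
#' Hedges' g (sign `a - b`) and its magnitude label are always attached.
#'
#' @param a,b Numeric group vectors (n >= 3 each for the gates).
#' @param label Comparison label carried into the result.
#' @param family_id Holm family this comparison belongs to.
#' @param shapiro_alpha,levene_alpha Gate thresholds.
#' @return A `comparison_result` list: `label`, `family_id`, `method`,
#'   `p_raw`, `hedges_g`, `magnitude`, `shapiro_p`, `levene_p`
#'   (`p_holm` is filled in by [adjust_families()]).
#' @export
gated_two_group_test <- function(a, b, label = "a vs b", family_id = "default",
                                 shapiro_alpha = 0.05, levene_alpha = 0.1) {
  if (length(a) < 3 || length(b) < 3)
    stop("gated_two_group_test: need n >= 3 per group for the gates",
         call. = FALSE)
  if (stats::sd(c(a, b)) == 0)
    stop("degenerate-data: constant data in both groups", call. = FALSE)
  resid <- c(a - mean(a), b - mean(b))
  shapiro_p <- if (stats::sd(resid) == 0) 0 else
    stats::shapiro.test(resid)$p.value
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  levene_p <- levene_test(c(a, b), g)$p.value

  if (shapiro_p > shapiro_alpha && levene_p > levene_alpha) {
    method <- "ols_anova"
    fit <- stats::lm(y ~ g, data = data.frame(y = c(a, b), g = g))
    p_raw <- stats::anova(fit)$`Pr(>F)`[1]
  } else if (shapiro_p > shapiro_alpha) {
    method <- "ols_hc4"
    X <- cbind(1, as.numeric(g) - 1)
    p_raw <- hc4_ols_p(X, c(a, b), coef_index = 2L)$p.value
  } else {
    method <- "wilcoxon"
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- length(a) <= 20 && length(b) <= 20 && !ties
    p_raw <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }
  gg <- hedges_g(a, b)
  structure(list(label = label, family_id = family_id, method = method,
                 p_raw = p_raw, p_holm = NA_real_, hedges_g = gg,
                 magnitude = magnitude_label(gg),
                 shapiro_p = shapiro_p, levene_p = levene_p),
            class = "comparison_result")
}

#' Apply Holm adjustment within families of comparison results
#'
#' @param results List of `comparison_result` objects (or a data frame with
#'   `p_raw` and `family_id` columns).
#' @return A data frame, one row per comparison, with the `p_holm` column
#'   filled in per family.
#' @export
adjust_families <- function(results) {
  if (is.data.frame(results)) df <- results
  else df <- do.call(rbind, lapply(results, function(r)
    data.frame(label = r$label, family_id = r$family_id, method = r$method,
               p_raw = r$p_raw, p_holm = NA_real_, hedges_g = r$hedges_g,
               magnitude = r$magnitude, shapiro_p = r$shapiro_p,
               levene_p = r$levene_p, stringsAsFactors = FALSE)))
  for (fam in unique(df$family_id)) {
    i <- df$family_id == fam
    df$p_holm[i] <- holm_adjust(df$p_raw[i])
  }
  df
}
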