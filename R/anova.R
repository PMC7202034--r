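#' Type-III factorial ANOVA under sum-to-zero contrasts
#'
#' Fits the full factorial OLS model with `contr.sum` coding and computes
#' Type-III (marginal) sums of squares for every term — including the
#' intercept — by comparing the residual sum of squares of the full model with
#' the model lacking that term's columns. Under a balanced design these equal
#' the sequential (Type-I) sums of squares.
#'
#' @param data Data frame holding the response and factor columns.
#' @param formula Model formula, e.g.
#'   `normalized ~ genotype * mtdna_species * treatment`.
#' @return Data frame with rows `(Intercept)`, each model term, and
#'   `Residuals`; columns `term`, `sumsq`, `meansq`, `df`, `statistic`,
#'   `p.value`.
#' @export
type3_anova <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  resp <- stats::model.response(mf)
  # sum-to-zero contrasts for every factor term
  for (nm in names(mf)[-1]) if (is.character(mf[[nm]])) mf[[nm]] <- factor(mf[[nm]])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- stats::model.matrix(formula, mf)
  asgn <- attr(X, "assign")
  labs <- c("(Intercept)", attr(stats::terms(formula, data = mf), "term.labels"))
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) {
    # locate the inestimable term for a useful error
    for (k in seq_along(labs)) {
      cols <- which(asgn == k - 1)
      if (qr(X[, cols, drop = FALSE])$rank < length(cols))
        stop("inestimable-term: empty cells make term '", labs[k],
             "' inestimable", call. = FALSE)
    }
    stop("inestimable-term: design matrix is rank deficient", call. = FALSE)
  }
  full <- stats::lm.fit(X, resp)
  rss_full <- sum(full$residuals^2)
  df_res <- n - p
  rows <- lapply(seq_along(labs), function(k) {
    cols <- which(asgn == k - 1)
    Xk <- X[, -cols, drop = FALSE]
    rss_k <- if (ncol(Xk)) sum(stats::lm.fit(Xk, resp)$residuals^2)
             else sum(resp^2)
    ss <- rss_k - rss_full
    df <- length(cols)
    data.frame(term = labs[k], sumsq = ss, meansq = ss / df, df = df,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mse <- rss_full / df_res
  tab$statistic <- tab$meansq / mse
  tab$p.value <- stats::pf(tab$statistic, tab$df, df_res, lower.tail = FALSE)
  rbind(tab,
        data.frame(term = "Residuals", sumsq = rss_full, meansq = mse,
                   df = df_res, statistic = NA_real_, p.value = NA_real_))
}

#' Effect-size and power columns for a Type-III ANOVA table
#'
#' Fills in the six effect-size columns from the `sumsq`/`meansq`/`df`
#' columns. With `T` the total sum of squares over ALL rows (intercept and
#' residuals included — the convention that reproduces published tables of
#' this layout) and `MSe` the residual mean square:
#' \itemize{
#'   \item `etasq = SS / T`
#'   \item `partial.etasq = SS / (SS + SS_res)`
#'   \item `omegasq = (SS - df * MSe) / (T + MSe)`
#'   \item `partial.omegasq = (SS - df * MSe) / (SS + (N - df) * MSe)` with
#'     `N = sum(df) + 1`
#'   \item `cohens.f = sqrt(partial.etasq / (1 - partial.etasq))`
#'   \item `power`: noncentral-F tail beyond the alpha = 0.05 critical value
#'     with `lambda = f^2 * (df + df_res + 1)`.
#' }
#'
#' @param tab Table from [type3_anova()] (or any table with `term`, `sumsq`,
#'   `meansq`, `df` columns including `(Intercept)` and `Residuals` rows).
#' @param N Observation count used in partial omega-squared; defaults to
#'   `sum(df) + 1`.
#' @param alpha Significance level for the power column.
#' @return The table with `etasq`, `partial.etasq`, `omegasq`,
#'   `partial.omegasq`, `cohens.f`, `power` columns appended (NA on the
#'   `Residuals` row).
#' @export
anova_effect_sizes <- function(tab, N = NULL, alpha = 0.05) {
  stopifnot(all(c("term", "sumsq", "df") %in% names(tab)))
  ires <- which(tab$term == "Residuals")
  if (length(ires) != 1L)
    stop("anova_effect_sizes: table must contain exactly one Residuals row",
         call. = FALSE)
  ss_res <- tab$sumsq[ires]
  df_res <- tab$df[ires]
  mse <- ss_res / df_res
  if (is.null(N)) N <- sum(tab$df) + 1
  Tt <- sum(tab$sumsq)
  ss <- tab$sumsq; df <- tab$df
  tab$etasq <- ss / Tt
  tab$partial.etasq <- ss / (ss + ss_res)
  tab$omegasq <- (ss - df * mse) / (Tt + mse)
  tab$partial.omegasq <- (ss - df * mse) / (ss + (N - df) * mse)
  tab$cohens.f <- sqrt(tab$partial.etasq / (1 - tab$partial.etasq))
  lambda <- tab$cohens.f^2 * (df + df_res + 1)
  fcrit <- stats::qf(1 - alpha, df, df_res)
  tab$power <- stats::pf(fcrit, df, df_res, ncp = lambda, lower.tail = FALSE)
  effcols <- c("etasq", "partial.etasq", "omegasq", "partial.omegasq",
               "cohens.f", "power")
  tab[ires, effcols] <- NA_real_
  tab
}
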