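#' Cook's-distance influence filtering
#'
#' Fits the full OLS model and flags observations whose Cook's distance
#' exceeds twice the conventional cutoff `4 / (N - K - 1)`, where `N` is the
#' number of observations and `K` the number of explanatory variables. Flagged
#' observations are listed for removal; nothing is dropped silently.
#'
#' @param x Design matrix (including the intercept column) or a formula.
#' @param y Response vector (ignored when `x` is a formula).
#' @param data Data frame for the formula interface.
#' @param K Number of explanatory variables. Defaults to the number of
#'   non-intercept columns of the design matrix.
#' @param multiplier Multiple of the base cutoff; 2 by default, giving
#'   `8 / (N - K - 1)`.
#' @return An `influence_report` list: `cooks_distances`, `cutoff`,
#'   `removed_indices`, `N`, `K`.
#' @export
cooks_filter <- function(x, y = NULL, data = NULL, K = NULL, multiplier = 2) {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data)
    y <- stats::model.response(mf)
    x <- stats::model.matrix(x, mf)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(K)) K <- p - as.integer(any(apply(x, 2, function(c) all(c == c[1]))))
  if (n <= K + 1)
    stop("cooks_filter: need N > K + 1", call. = FALSE)
  if (qr(x)$rank < p)
    stop("rank-deficiency: singular design matrix", call. = FALSE)
  fit <- stats::lm.fit(x, y)
  e <- unname(fit$residuals)
  h <- stats::hat(x)
  s2 <- sum(e^2) / (n - p)
  d <- e^2 / (p * s2) * h / (1 - h)^2
  cutoff <- multiplier * 4 / (n - K - 1)
  structure(list(cooks_distances = d, cutoff = cutoff,
                 removed_indices = which(d > cutoff), N = n, K = K),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat("Influence report: N =", x$N, " K =", x$K,
      " cutoff =", format(x$cutoff, digits = 6), "\n")
  if (length(x$removed_indices)) {
    cat("Removed", length(x$removed_indices), "observation(s):",
        paste(x$removed_indices, collapse = ", "), "\n")
    cat("Cook's D:", format(x$cooks_distances[x$removed_indices], digits = 4),
        "\n")
  } else cat("No influential observations above the cutoff.\n")
  invisible(x)
}
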