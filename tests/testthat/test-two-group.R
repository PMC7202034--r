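test_that("hedges_g matches hand computation and is antisymmetric", {
  # J = 1 - 3/15 = 0.8, uncorrected d = -1
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 4)), -0.8)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1))
    expect_equal(hedges_g(a, b), -hedges_g(b, a), tolerance = 1e-12)
    # correction factor |J| < 1
    d <- (mean(a) - mean(b)) /
      sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
             (length(a) + length(b) - 2))
    expect_lt(abs(hedges_g(a, b)), abs(d) + 1e-12)
  }
  # J -> 1 with n
  a <- rnorm(5000); b <- rnorm(5000) + 1
  J <- 1 - 3 / (4 * 10000 - 9)
  expect_gt(J, 0.9999)
  expect_error(hedges_g(1, c(1, 2)), "n >= 2")
  expect_error(hedges_g(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})

test_that("magnitude labels follow the conventional thresholds", {
  expect_identical(magnitude_label(0.517), "medium")
  expect_identical(magnitude_label(-1.15), "large")
  expect_identical(magnitude_label(0.197), "negligible")
  expect_identical(magnitude_label(c(0.28, 0.804, -0.368, 0)),
                   c("small", "large", "small", "negligible"))
  # boundary: thresholds are right-open
  expect_identical(magnitude_label(c(0.2, 0.5, 0.8)),
                   c("small", "medium", "large"))
})

test_that("holm_adjust agrees with the step-down oracle and its invariants", {
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # smallest p gets the full Bonferroni factor
    expect_equal(min(adj), min(min(p) * length(p), 1), tolerance = 1e-12)
    # monotone in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm]), adj[perm], tolerance = 1e-15)
  }
  expect_equal(holm_adjust(0.03), 0.03)
  expect_error(holm_adjust(numeric(0)), "empty")
})

test_that("holm_adjust reproduces the published Holm column per family", {
  t1 <- table1_fixture()
  for (fam in unique(t1$family_id)) {
    rows <- t1[t1$family_id == fam, ]
    adj <- holm_adjust(rows$p_raw)
    # published raw p-values are rounded, so allow the induced slack
    expect_true(all(abs(adj - rows$holm_published) <=
                      pmax(0.0015, 0.006 * rows$holm_published)),
                info = fam)
  }
  # the running-maximum carry: raw 0.0536 inherits 0.526 from the 0.0526 entry
  f1 <- t1[t1$family_id == "f1_16", ]
  adj <- holm_adjust(f1$p_raw)
  expect_equal(adj[f1$id == 6], 0.526, tolerance = 1e-9)
  expect_equal(adj[f1$id == 9], 0.000288, tolerance = 1e-9)
})

test_that("HC4 reduces to (a multiple of) classical OLS under equal weights", {
  # balanced two-group design, residuals of equal magnitude, equal leverage
  x <- cbind(1, rep(c(0, 1), each = 4))
  y <- rep(c(0, 2), each = 4) + rep(c(1, -1), 4)
  r <- hc4_ols_p(x, y, 2)
  h <- hat(x)
  expect_equal(diff(range(h)), 0, tolerance = 1e-12)
  V_classical <- solve(crossprod(x))
  ratio <- r$vcov / V_classical
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-9)
  expect_error(hc4_ols_p(cbind(1, c(1, 1, 1)), 1:3), "rank-deficiency")
})

test_that("HC4 tracks classical OLS p-values on homoscedastic data", {
  set.seed(99)
  g <- rep(0:1, each = 100)
  y <- 0.25 * g + rnorm(200)
  x <- cbind(1, g)
  p_hc4 <- hc4_ols_p(x, y, 2)$p.value
  p_cls <- summary(lm(y ~ g))$coefficients[2, 4]
  expect_lt(abs(p_hc4 - p_cls) / p_cls, 0.2)
})

test_that("the gated decision tree routes by the Shapiro/Levene criteria", {
  set.seed(153)
  a <- rnorm(30); b <- rnorm(30)
  r1 <- gated_two_group_test(a, b)
  expect_identical(r1$method, "ols_anova")
  expect_gt(r1$shapiro_p, 0.05)
  expect_gt(r1$levene_p, 0.1)
  # inflate one group's variance: fails Levene, still passes Shapiro
  r2 <- gated_two_group_test(a, b * 5)
  expect_identical(r2$method, "ols_hc4")
  expect_gt(r2$shapiro_p, 0.05)
  expect_lte(r2$levene_p, 0.1)
  # heavy skew: fails Shapiro, Wilcoxon regardless of variances
  set.seed(7)
  r3 <- gated_two_group_test(rlnorm(30, 0, 1.5), rlnorm(30, 0, 1.5))
  expect_identical(r3$method, "wilcoxon")
  expect_lte(r3$shapiro_p, 0.05)
  # result contract
  for (r in list(r1, r2, r3)) {
    expect_true(r$p_raw >= 0 && r$p_raw <= 1)
    expect_identical(r$magnitude, magnitude_label(r$hedges_g))
  }
  expect_error(gated_two_group_test(rep(1, 5), rep(1, 5)), "degenerate")
  expect_error(gated_two_group_test(1:2, 1:5), "n >= 3")
})

test_that("adjust_families fills p_holm per family, preserving order", {
  set.seed(5)
  res <- c(
    lapply(1:4, function(i) gated_two_group_test(rnorm(10), rnorm(10),
                                                 label = paste0("A", i),
                                                 family_id = "famA")),
    lapply(1:3, function(i) gated_two_group_test(rnorm(10), rnorm(10),
                                                 label = paste0("B", i),
                                                 family_id = "famB")))
  df <- adjust_families(res)
  expect_identical(df$label, c(paste0("A", 1:4), paste0("B", 1:3)))
  for (fam in c("famA", "famB")) {
    i <- df$family_id == fam
    expect_equal(df$p_holm[i], holm_adjust(df$p_raw[i]))
    expect_true(all(df$p_holm[i] >= df$p_raw[i] - 1e-15))
  }
})
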