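test_that("VO2, VCO2 and RQ match hand-evaluated closed-flow formulas", {
  # no gas exchange
  g0 <- gas_measurement(FRe = 1, FprimeeO2 = 0.2094, FprimeeCO2 = 0)
  expect_equal(compute_vo2(g0), 0)
  expect_equal(compute_vco2(g0), 0)
  # hand evaluation of the simplified form: (0.0194 - 0.002094)/0.7906
  g1 <- gas_measurement(FRe = 1, FprimeeO2 = 0.19, FprimeeCO2 = 0.01)
  expect_equal(compute_vo2(g1), (0.0194 - 0.2094 * 0.01) / (1 - 0.2094),
               tolerance = 1e-10)
  expect_equal(compute_vo2(g1), 0.021890, tolerance = 1e-4)
  # with CO2 scrubbed VCO2 reduces to FRe * F'eCO2
  expect_equal(compute_vco2(g1), 0.01)
  g2 <- gas_measurement(FRe = 0.5, FprimeeO2 = 0.19, FprimeeCO2 = 0.02)
  expect_equal(compute_vco2(g2), 0.01)
  # RQ
  expect_equal(compute_rq(0.02, 0.02), 1)
  expect_equal(compute_rq(compute_vo2(g1), 0.01), 0.4568, tolerance = 1e-4)
  expect_equal(compute_rq(0.01, 0.007), 0.7)
  expect_error(compute_rq(0, 0.01), "undefined")
})

test_that("rates are homogeneous of degree 1 in FRe and obey the zero-CO2 limit", {
  set.seed(42)
  for (i in 1:25) {
    feo2 <- runif(1, 0.15, 0.2094)
    feco2 <- runif(1, 0, 0.02)
    fre <- runif(1, 0.1, 5)
    k <- runif(1, 0.5, 3)
    g1 <- gas_measurement(FRe = fre, FprimeeO2 = feo2, FprimeeCO2 = feco2)
    gk <- gas_measurement(FRe = k * fre, FprimeeO2 = feo2, FprimeeCO2 = feco2)
    expect_equal(compute_vo2(gk), k * compute_vo2(g1), tolerance = 1e-12)
    expect_equal(compute_vco2(gk), k * compute_vco2(g1), tolerance = 1e-12)
    # closed-form limit with F'eCO2 = FiCO2 = 0
    gz <- gas_measurement(FRe = fre, FprimeeO2 = feo2, FprimeeCO2 = 0)
    expect_equal(compute_vo2(gz), fre * (0.2094 - feo2) / (1 - 0.2094),
                 tolerance = 1e-12)
  }
})

test_that("gas_measurement enforces its invariants", {
  expect_error(gas_measurement(FRe = 0, FprimeeO2 = 0.2, FprimeeCO2 = 0.01),
               "FRe")
  expect_error(gas_measurement(FRe = 1, FprimeeO2 = 1.2, FprimeeCO2 = 0),
               "\\[0, 1\\]")
  expect_error(gas_measurement(FRe = 1, FprimeeO2 = 0.215, FprimeeCO2 = 0),
               "respiring")
  expect_error(gas_measurement(FRe = 1, FiO2 = 1, FprimeiO2 = 1,
                               FprimeeO2 = 0.2, FprimeeCO2 = 0) |>
                 compute_vo2(), "denominator")
})

test_that("per-fly adjustment scales by count and duration", {
  expect_equal(per_fly_rate(3.0, 30, 60), 0.1)
  expect_equal(per_fly_rate(3.0, 30, 80), 0.075)
  expect_equal(per_fly_rate(0, 25, 70), 0)
  expect_error(per_fly_rate(1, 0, 60), "all-flies-lost")
})

test_that("block normalization follows the first-reference-sample rule", {
  d <- data.frame(block_id = "b1", strain = "OreR",
                  genotype = c("w1118", "Sirt4_ko"),
                  treatment = "standard",
                  acquisition_index = 1:2,
                  per_fly_per_hr = c(0.5, 0.6))
  out <- normalize_block(d)
  expect_equal(out$normalized, c(1.0, 1.2))
  # two reference-eligible samples: smallest acquisition_index wins
  d2 <- data.frame(block_id = "b1", strain = "OreR", genotype = "w1118",
                   treatment = "standard", acquisition_index = c(3L, 1L),
                   per_fly_per_hr = c(0.5, 0.25))
  expect_equal(normalize_block(d2)$normalized, c(2, 1))
  # all equal to the reference
  d3 <- d; d3$per_fly_per_hr <- c(0.4, 0.4)
  expect_equal(normalize_block(d3)$normalized, c(1, 1))
  # idempotence on already-normalized data
  out2 <- out; out2$per_fly_per_hr <- out$normalized
  expect_equal(normalize_block(out2)$normalized, out$normalized)
  # errors
  d4 <- d; d4$genotype <- "Sirt4_ko"
  expect_error(normalize_block(d4), "missing-reference.*b1")
  d5 <- d; d5$per_fly_per_hr[1] <- 0
  expect_error(normalize_block(d5), "degenerate-reference")
})

test_that("process_respirometry computes the full per-sample pipeline", {
  tab <- tiny_rates_table()
  out <- process_respirometry(tab)
  expect_true(all(c("Vo2", "Vco2", "RQ", "per_fly_per_hr", "normalized") %in%
                    names(out)))
  # reference sample of each block maps to exactly 1
  ref <- out$genotype == "w1118" & out$treatment == "standard"
  expect_identical(out$normalized[ref & out$acquisition_index == 1],
                   c(1, 1))
  # RQ is invariant under joint block normalization of Vo2 and Vco2
  for (b in unique(out$block_id)) {
    i <- out$block_id == b
    r <- which(i & ref & out$acquisition_index == 1)
    vo2n <- out$Vo2[i] / out$Vo2[r]
    vco2n <- out$Vco2[i] / out$Vco2[r]
    expect_equal(vco2n / vo2n / (out$RQ[r]^-1), out$RQ[i], tolerance = 1e-12)
  }
  # csv round trip
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  out2 <- process_respirometry(f)
  expect_equal(out2$normalized, out$normalized, tolerance = 1e-12)
  # schema validation
  expect_error(process_respirometry(tab[-1]), "missing columns")
  dup <- tab; dup$acquisition_index <- 1L
  expect_error(process_respirometry(dup), "unique within block")
})

test_that("per-strain reference resolution serves wildtype-only designs", {
  tab <- tiny_rates_table()
  tab$strain <- rep(c("OreR", "Zim53"), 3)
  tab$genotype <- "wildtype"
  tab$block_id <- "b1"
  tab$acquisition_index <- 1:6
  tab$treatment <- rep(c("standard", "standard", "rapamycin"), 2)
  out <- process_respirometry(
    tab, reference_predicate(strain = NA, genotype = NA,
                             treatment = "standard"),
    per_strain = TRUE)
  for (s in unique(out$strain)) {
    i <- out$strain == s & out$treatment == "standard"
    first <- which(i)[which.min(out$acquisition_index[i])]
    expect_equal(out$normalized[first], 1)
  }
})
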