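test_that("the respirometry generator is seed-deterministic and well-formed", {
  sc <- respirometry_scenario(n_per_cell = 6, n_blocks = 2, seed = 101)
  d1 <- simulate_respirometry(sc)
  d2 <- simulate_respirometry(sc)
  expect_identical(d1, d2)
  # byte-identical files
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(d1, f1, row.names = FALSE); write.csv(d2, f2, row.names = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # schema and invariants
  expect_true(all(mitonuc:::respirometry_cols %in% names(d1)))
  expect_true(all(d1$n_flies >= 25 & d1$n_flies <= 30))
  expect_true(all(d1$incubation_min >= 60 & d1$incubation_min <= 80))
  expect_false(any(duplicated(d1[c("block_id", "acquisition_index")])))
})

test_that("processing a simulated table recovers the generated rates exactly", {
  sc <- respirometry_scenario(n_per_cell = 6, n_blocks = 2, seed = 7,
                              contamination = 0)
  d <- simulate_respirometry(sc)
  out <- process_respirometry(d)
  # reference sample of every block normalizes to exactly 1
  for (b in unique(out$block_id)) {
    i <- out$block_id == b
    expect_equal(out$normalized[i][out$acquisition_index[i] == 1], 1)
  }
  # the gas-fraction inversion rebuilds the intended per-fly rates:
  # cell means estimated from normalized data track the generated truth
  truth <- attr(d, "truth")$cell_means
  key <- paste(out$strain, out$genotype, out$treatment, sep = ".")
  est <- tapply(out$normalized, key, mean)
  expect_lt(max(abs(est[names(truth)] - truth)), 0.25)
})

test_that("mass correlates with raw rates but not with normalized rates", {
  # raw whole-sample rate and mass share the fly count and the block-level
  # size factor; per-fly + block-reference normalization removes both
  sc <- respirometry_scenario(n_per_cell = 40, n_blocks = 40, seed = 13,
                              contamination = 0)
  d <- simulate_respirometry(sc)
  out <- process_respirometry(d)
  whole_rate <- out$per_fly_per_hr * out$n_flies
  r_raw <- cor(whole_rate, out$mass_mg)
  r_norm <- cor(out$normalized, out$mass_mg)
  expect_gt(r_raw, 0.3)
  expect_lt(abs(r_norm), 0.2)
})

test_that("injected contamination exceeds the Cook's cutoff", {
  sc <- respirometry_scenario(n_per_cell = 12, n_blocks = 2, seed = 23,
                              contamination = 0.04)
  d <- simulate_respirometry(sc)
  expect_gt(length(attr(d, "truth")$outlier_idx), 0)
  out <- process_respirometry(d)
  for (v in c("genotype", "mtdna_species", "treatment"))
    out[[v]] <- factor(out[[v]])
  rep_ <- cooks_filter(normalized ~ genotype * mtdna_species * treatment,
                       data = out, K = 3)
  expect_true(all(attr(d, "truth")$outlier_idx %in% rep_$removed_indices))
})

test_that("a large planted effect is recovered with a 'large' label", {
  # treatment effect planted at Hedges g ~ 1.6 in a 9-per-cell design;
  # a single block keeps the reference division a common factor, so the
  # planted standardized effect carries through to the normalized scale
  sd_cell <- 0.12
  sc <- respirometry_scenario(
    n_per_cell = 9, n_blocks = 1, seed = 29, contamination = 0,
    noise_sdlog = sd_cell,
    cell_means = c("OreR.w1118.rapamycin" = exp(-1.6 * sd_cell)))
  d <- simulate_respirometry(sc)
  out <- process_respirometry(d)
  a <- out$normalized[out$strain == "OreR" & out$genotype == "w1118" &
                        out$treatment == "standard"]
  b <- out$normalized[out$strain == "OreR" & out$genotype == "w1118" &
                        out$treatment == "rapamycin"]
  r <- gated_two_group_test(a, b, "std vs rapa")
  expect_gt(r$hedges_g, 1.1)
  expect_lt(r$hedges_g, 2.1)
  expect_identical(r$magnitude, "large")
})

test_that("codon-pair generator honors its ground-truth contract", {
  # omega = 0: every fixed difference is synonymous, KA is exactly 0
  p0 <- simulate_codon_pair(codon_scenario(100, 2, 0, 0.3, seed = 3))
  expect_identical(p0$n_nonsyn, 0L)
  expect_gt(p0$n_syn, 0L)
  r0 <- ka_ks(p0$seq1, p0$seq2)
  expect_equal(r0$ka, 0, tolerance = 1e-12)
  # translation is preserved codon for codon
  expect_identical(mitonuc:::translate_cds(p0$seq1),
                   mitonuc:::translate_cds(p0$seq2))
  # zero expected divergence: identical sequences
  pz <- simulate_codon_pair(codon_scenario(50, 2, 0.5, 0, seed = 4))
  expect_identical(pz$seq1, pz$seq2)
  # determinism
  pa <- simulate_codon_pair(codon_scenario(60, 2, 0.2, 0.2, seed = 5))
  pb <- simulate_codon_pair(codon_scenario(60, 2, 0.2, 0.2, seed = 5))
  expect_identical(pa, pb)
})

test_that("family simulation respects the tree contract", {
  tr <- ape::read.tree(text = "((a:0.4,b:0.4):0.8,(c:0.4,d:0.4):0.8);")
  fam <- simulate_ortholog_family(codon_scenario(60, 2, 0.5, 0.2, seed = 6),
                                  tr)
  expect_setequal(names(fam$sequences), tr$tip.label)
  expect_true(all(nchar(fam$sequences) == 180))
  # zero branch lengths give identical sequences
  tr0 <- tr; tr0$edge.length[] <- 0
  fam0 <- simulate_ortholog_family(codon_scenario(60, 2, 0.5, 0.2, seed = 6),
                                   tr0)
  expect_identical(length(unique(unname(fam0$sequences))), 1L)
})
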