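# Independent oracles, built from scratch at test time (never via the
# package's own site-classification or adjustment code paths).

# exhaustive degeneracy enumeration straight from the genetic code
oracle_degeneracy_table <- function() {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  sense <- names(code)[code != "*"]
  out <- expand.grid(codon = sense, position = 1:3,
                     stringsAsFactors = FALSE)
  out$class <- mapply(function(cd, p) {
    nt <- strsplit(cd, "")[[1]]
    nsyn <- 0L
    for (b in setdiff(c("A", "C", "G", "T"), nt[p])) {
      alt <- nt; alt[p] <- b
      aa <- code[paste(alt, collapse = "")]
      if (aa != "*" && aa == code[cd]) nsyn <- nsyn + 1L
    }
    if (nsyn == 3L) 4L else if (nsyn >= 1L) 2L else 0L
  }, out$codon, out$position)
  out
}

# published Table 1 / Table 2 fixtures
table1_fixture <- function() {
  utils::read.csv(mitonuc_extdata("table1_comparisons.csv"),
                  stringsAsFactors = FALSE)
}
table2_fixture <- function() {
  utils::read.csv(mitonuc_extdata("table2_anova.csv"),
                  stringsAsFactors = FALSE)
}

# tolerance from the printed representation: k units in the last decimal
printed_tol <- function(x, units = 1) {
  s <- format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  dec <- ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0)
  units * 10^(-dec)
}

# tolerance for an effect-size cell recomputed from a printed sumsq input:
# output ulp slack plus first-order propagation of the input's half-ulp
# (sumsq is printed to 5 decimals; effect sizes scale at most linearly in SS)
table2_tol <- function(printed_out, sumsq_in, units = 2.5) {
  rel_in <- 0.5e-5 / sumsq_in
  printed_tol(printed_out, units) + abs(printed_out) * rel_in
}

# clean regression fixture with bounded design and bounded noise, so no
# observation can be influential under the doubled Cook's cutoff (Gaussian
# noise, by contrast, routinely produces a few points above 8/(N-K-1))
clean_bounded_fixture <- function(n = 200, seed = 12) {
  set.seed(seed)
  x <- cbind(1, runif(n, -1, 1))
  y <- 1 + 0.5 * x[, 2] + runif(n, -0.5, 0.5)
  list(x = x, y = y)
}

# quartet topology by brute force: which pairing minimizes the 4-point sums
oracle_quartet <- function(d) {
  ids <- rownames(d)
  sums <- c(AB_CD = d[1, 2] + d[3, 4],
            AC_BD = d[1, 3] + d[2, 4],
            AD_BC = d[1, 4] + d[2, 3])
  names(which.min(sums))
}

# small respirometry table built by hand (no simulator involvement)
tiny_rates_table <- function() {
  data.frame(
    sample_id = paste0("s", 1:6),
    block_id = rep(c("b1", "b2"), each = 3),
    strain = "OreR", mtdna_species = "D. melanogaster",
    genotype = rep(c("w1118", "w1118", "Sirt4_ko"), 2),
    treatment = rep(c("standard", "rapamycin", "standard"), 2),
    n_flies = c(30L, 28L, 25L, 27L, 30L, 26L),
    incubation_min = c(60, 70, 80, 60, 75, 65),
    mass_mg = c(27, 25, 23, 24, 28, 23),
    FRe = 0.15, FiO2 = 0.2094,
    FeO2 = c(0.200, 0.202, 0.201, 0.199, 0.203, 0.2),
    FiCO2 = 0,
    FeCO2 = c(0.008, 0.006, 0.007, 0.009, 0.005, 0.008),
    acquisition_index = rep(1:3, 2),
    stringsAsFactors = FALSE)
}
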