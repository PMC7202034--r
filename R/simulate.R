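# Synthetic-data generators with stored ground truth: block-structured
# respirometry tables and codon pairs / families evolved under a
# transition-biased, selection-filtered substitution process.

#' Respirometry simulation scenario
#'
#' Describes the world the respirometry generator emulates: a factorial
#' design (strain x genotype x treatment) with target cell means expressed as
#' multiples of the reference cell, per-block multiplicative instrument scale,
#' a block-level fly-size factor inducing the mass-rate correlation, fly-count
#' and incubation jitter, and rare high-leverage outliers.
#'
#' @param strains Named character vector mapping strain label to mtDNA
#'   species.
#' @param genotypes,treatments Factor levels of the design.
#' @param cell_means Named numeric vector of target cell means (multiples of
#'   the reference cell), names `strain.genotype.treatment`; cells not named
#'   default to 1 (no effect).
#' @param n_per_cell Total samples per design cell across all blocks.
#' @param n_blocks Number of experimental blocks (assay days).
#' @param base_rate Reference per-fly rate, mL O2/fly/hr (resting Drosophila
#'   is a few microliters per fly per hour).
#' @param block_scale_sdlog Log-SD of the per-block multiplicative instrument
#'   scale.
#' @param noise_sdlog Log-SD of per-sample biological/technical noise on the
#'   per-fly rate.
#' @param mass_sdlog Log-SD of per-sample mass noise.
#' @param fly_range,incubation_range Ranges for fly counts and incubation
#'   minutes.
#' @param mass_per_fly_mg Mean fly mass, mg.
#' @param mass_cor Target raw mass-rate correlation (achieved through a
#'   shared block-level size factor; reference normalization cancels it).
#' @param contamination Probability a sample is a 5-10x high-leverage
#'   outlier.
#' @param rq Respiratory quotient used when inverting gas fractions.
#' @param chamber_ml Closed-chamber volume, mL.
#' @param seed Master seed.
#' @return A `respirometry_scenario` list.
#' @export
respirometry_scenario <- function(strains = c(OreR = "D. melanogaster",
                                              sm21 = "D. simulans"),
                                  genotypes = c("w1118", "Sirt4_ko"),
                                  treatments = c("standard", "rapamycin"),
                                  cell_means = NULL,
                                  n_per_cell = 33, n_blocks = 6,
                                  base_rate = 0.003,
                                  block_scale_sdlog = 0.08,
                                  noise_sdlog = 0.12,
                                  mass_sdlog = 0.05,
                                  fly_range = c(25L, 30L),
                                  incubation_range = c(60, 80),
                                  mass_per_fly_mg = 0.9,
                                  mass_cor = 0.57,
                                  contamination = 0.015,
                                  rq = 0.9, chamber_ml = 10,
                                  seed = 1L) {
  stopifnot(n_per_cell >= 3, block_scale_sdlog >= 0,
            mass_cor > -1, mass_cor < 1, contamination >= 0,
            contamination < 1)
  sc <- list(strains = strains, genotypes = genotypes,
             treatments = treatments, cell_means = cell_means,
             n_per_cell = n_per_cell, n_blocks = n_blocks,
             base_rate = base_rate, block_scale_sdlog = block_scale_sdlog,
             noise_sdlog = noise_sdlog, mass_sdlog = mass_sdlog,
             fly_range = fly_range, incubation_range = incubation_range,
             mass_per_fly_mg = mass_per_fly_mg, mass_cor = mass_cor,
             contamination = contamination, rq = rq,
             chamber_ml = chamber_ml, seed = seed)
  class(sc) <- "respirometry_scenario"
  sc
}

# Block-level size-factor log-SD achieving the target raw mass-rate
# correlation. The raw (whole-sample) rate and the sample mass share the
# fly-count term and the size factor; everything else is independent, so
# with u the total shared log-variance,
#   rho = u / sqrt((u + var_rate_extra) (u + var_mass_extra)).
size_sdlog_for_cor <- function(rho, var_shared_base, var_rate_extra,
                               var_mass_extra) {
  if (rho <= 0) return(0)
  f <- function(u) u / sqrt((u + var_rate_extra) * (u + var_mass_extra)) - rho
  u <- stats::uniroot(f, c(1e-8, 25))$root
  sqrt(max(u - var_shared_base, 0))
}

#' Simulate a block-structured respirometry samples table
#'
#' Generates one row per sealed-syringe sample with gas fractions obtained by
#' inverting the closed-chamber VO2 model, so that running the table through
#' [process_respirometry()] recovers the generated per-fly rates exactly. The
#' first sample of every block is the reference cell at acquisition index 1.
#'
#' @param sc A [respirometry_scenario()].
#' @return Samples data frame in the respirometry CSV schema, with attribute
#'   `truth`: the cell-mean table, block scales, and outlier row indices.
#' @export
simulate_respirometry <- function(sc = respirometry_scenario()) {
  stopifnot(inherits(sc, "respirometry_scenario"))
  set.seed(sc$seed)
  cells <- expand.grid(strain = names(sc$strains), genotype = sc$genotypes,
                       treatment = sc$treatments, stringsAsFactors = FALSE)
  key <- paste(cells$strain, cells$genotype, cells$treatment, sep = ".")
  mu <- rep(1, nrow(cells)); names(mu) <- key
  if (!is.null(sc$cell_means)) {
    unknown <- setdiff(names(sc$cell_means), key)
    if (length(unknown))
      stop("cell_means names not in design: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    mu[names(sc$cell_means)] <- sc$cell_means
  }
  ref_key <- paste(names(sc$strains)[1], sc$genotypes[1], sc$treatments[1],
                   sep = ".")
  # per-block sample counts per cell (remainder to the earliest blocks)
  per_block <- rep(sc$n_per_cell %/% sc$n_blocks, sc$n_blocks)
  extra <- sc$n_per_cell %% sc$n_blocks
  if (extra) per_block[seq_len(extra)] <- per_block[seq_len(extra)] + 1L

  var_nflies <- stats::var(log(seq(sc$fly_range[1], sc$fly_range[2])))
  size_sd <- size_sdlog_for_cor(
    sc$mass_cor,
    var_shared_base = var_nflies,
    var_rate_extra = sc$noise_sdlog^2 + sc$block_scale_sdlog^2,
    var_mass_extra = sc$mass_sdlog^2)

  rows <- list()
  block_scales <- numeric(sc$n_blocks)
  for (b in seq_len(sc$n_blocks)) {
    scale_b <- stats::rlnorm(1, 0, sc$block_scale_sdlog)
    size_b <- stats::rlnorm(1, 0, size_sd)
    block_scales[b] <- scale_b
    # reference cell first, then the rest of the cells
    ord <- c(which(key == ref_key), which(key != ref_key))
    acq <- 0L
    for (ci in ord) for (s in seq_len(per_block[b])) {
      acq <- acq + 1L
      n_flies <- sample(seq(sc$fly_range[1], sc$fly_range[2]), 1)
      inc <- stats::runif(1, sc$incubation_range[1], sc$incubation_range[2])
      rate <- sc$base_rate * mu[ci] * scale_b * size_b *
        stats::rlnorm(1, 0, sc$noise_sdlog)
      is_out <- (acq > 1) && (stats::runif(1) < sc$contamination)
      if (is_out) rate <- rate * stats::runif(1, 5, 10)
      mass <- n_flies * sc$mass_per_fly_mg * size_b *
        stats::rlnorm(1, 0, sc$mass_sdlog)
      consumed <- rate * n_flies * inc / 60
      feco2 <- sc$rq * consumed / sc$chamber_ml
      feo2 <- 0.2094 - consumed * (1 - 0.2094) / sc$chamber_ml -
        0.2094 * feco2
      if (feo2 <= 0 || feco2 >= 1)
        stop("infeasible-scenario: rate too high for the chamber volume",
             call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("b%02d_s%03d", b, acq),
        block_id = sprintf("block%02d", b),
        strain = cells$strain[ci],
        mtdna_species = unname(sc$strains[cells$strain[ci]]),
        genotype = cells$genotype[ci], treatment = cells$treatment[ci],
        n_flies = n_flies, incubation_min = inc, mass_mg = mass,
        FRe = sc$chamber_ml / inc, FiO2 = 0.2094, FeO2 = feo2,
        FiCO2 = 0, FeCO2 = feco2, acquisition_index = acq,
        outlier = is_out, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  outlier_idx <- which(out$outlier)
  out$outlier <- NULL
  attr(out, "truth") <- list(cell_means = stats::setNames(mu, key),
                             block_scales = block_scales,
                             outlier_idx = outlier_idx,
                             base_rate = sc$base_rate)
  out
}

#' Codon evolution scenario
#'
#' @param n_codons Coding length in codons (>= 30).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Acceptance probability of a nonsynonymous proposal (>= 0);
#'   the simulation ground truth for KA/KS recovery.
#' @param expected_ks Expected synonymous divergence (substitutions per
#'   synonymous site) between the pair, or per unit branch length for
#'   families.
#' @param seed Master seed.
#' @return A `codon_scenario` list.
#' @export
codon_scenario <- function(n_codons = 300, kappa = 2, omega = 0.1,
                           expected_ks = 0.3, seed = 1L) {
  stopifnot(n_codons >= 30, kappa > 0, omega >= 0, expected_ks >= 0)
  structure(list(n_codons = n_codons, kappa = kappa, omega = omega,
                 expected_ks = expected_ks, seed = seed),
            class = "codon_scenario")
}

random_sense_cds <- function(n_codons) {
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# probability that a kappa-weighted random single-nucleotide proposal on this
# sequence is synonymous, and the synonymous (class 2 + class 4) site count
syn_proposal_stats <- function(seq, kappa) {
  code <- genetic_code()
  deg <- degeneracy_table()
  codons <- split_codons(seq)
  w_syn <- w_tot <- 0
  s_sites <- 0
  for (cd in codons) {
    aa <- code[cd]
    nt <- strsplit(cd, "")[[1]]
    for (p in 1:3) {
      cls <- deg[cd, p]
      if (cls > 0) s_sites <- s_sites + 1
      for (b in setdiff(NUCS, nt[p])) {
        w <- if (is_transition(nt[p], b)) kappa else 1
        alt <- nt; alt[p] <- b
        aa2 <- code[paste(alt, collapse = "")]
        w_tot <- w_tot + w
        if (aa2 != "*" && aa2 == aa) w_syn <- w_syn + w
      }
    }
  }
  list(p_syn = w_syn / w_tot, s_sites = s_sites)
}

# one accept/reject substitution sweep: n_prop proposals on seq
evolve_sequence <- function(seq, n_prop, kappa, omega) {
  code <- genetic_code()
  nt <- strsplit(seq, "")[[1]]
  n_syn <- n_nonsyn <- 0L
  L <- length(nt)
  for (k in seq_len(n_prop)) {
    pos <- sample.int(L, 1)
    cur <- nt[pos]
    alts <- setdiff(NUCS, cur)
    w <- ifelse(is_transition(cur, alts), kappa, 1)
    b <- sample(alts, 1, prob = w)
    ci <- (pos - 1) %/% 3
    idx <- ci * 3 + 1:3
    old_codon <- paste(nt[idx], collapse = "")
    new <- nt; new[pos] <- b
    new_codon <- paste(new[idx], collapse = "")
    if (code[new_codon] == "*") next            # reject stops
    if (code[new_codon] == code[old_codon]) {   # synonymous: always fixes
      nt <- new; n_syn <- n_syn + 1L
    } else if (stats::runif(1) < omega) {       # nonsynonymous: filter
      nt <- new; n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(seq = paste(nt, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate a diverged codon pair with known selection ground truth
#'
#' Draws a random sense-codon root, then applies a Poisson number of
#' kappa-biased single-nucleotide proposals; proposals creating stops are
#' rejected, synonymous proposals always fix, nonsynonymous proposals fix
#' with probability omega. The proposal budget is derived analytically from
#' `expected_ks` via the root sequence's synonymous-proposal probability, not
#' tuned post hoc.
#'
#' @param sc A [codon_scenario()].
#' @return List with `seq1` (root), `seq2` (diverged), realized `n_syn` and
#'   `n_nonsyn` accepted events, and the scenario.
#' @export
simulate_codon_pair <- function(sc = codon_scenario()) {
  stopifnot(inherits(sc, "codon_scenario"))
  set.seed(sc$seed)
  root <- random_sense_cds(sc$n_codons)
  st <- syn_proposal_stats(root, sc$kappa)
  lambda <- if (st$p_syn > 0) sc$expected_ks * st$s_sites / st$p_syn else 0
  n_prop <- stats::rpois(1, lambda)
  ev <- evolve_sequence(root, n_prop, sc$kappa, sc$omega)
  list(seq1 = root, seq2 = ev$seq, n_syn = ev$n_syn, n_nonsyn = ev$n_nonsyn,
       scenario = sc)
}

#' Simulate an ortholog family along a tree
#'
#' Evolves a root coding sequence along a `phylo` tree; each edge receives a
#' Poisson proposal budget proportional to its branch length (in expected
#' synonymous substitutions per synonymous site).
#'
#' @param sc A [codon_scenario()] (its `expected_ks` scales unit branch
#'   length).
#' @param tree An `ape::phylo` tree with nonnegative branch lengths.
#' @return List with `sequences` (named by tip label) and `tree` (the true
#'   topology).
#' @export
simulate_ortholog_family <- function(sc, tree) {
  stopifnot(inherits(sc, "codon_scenario"), inherits(tree, "phylo"))
  if (any(tree$edge.length < 0))
    stop("tree must have nonnegative branch lengths", call. = FALSE)
  set.seed(sc$seed)
  root_seq <- random_sense_cds(sc$n_codons)
  ntip <- length(tree$tip.label)
  root_node <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root_node]] <- root_seq
  # preorder traversal
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(ord))) {
    parent <- ord[i, 1]; child <- ord[i, 2]
    elen <- tree$edge.length[which(tree$edge[, 1] == parent &
                                   tree$edge[, 2] == child)]
    pseq <- seqs[[parent]]
    st <- syn_proposal_stats(pseq, sc$kappa)
    lambda <- if (st$p_syn > 0)
      sc$expected_ks * elen * st$s_sites / st$p_syn else 0
    n_prop <- stats::rpois(1, lambda)
    seqs[[child]] <- evolve_sequence(pseq, n_prop, sc$kappa, sc$omega)$seq
  }
  tips <- stats::setNames(unlist(seqs[seq_len(ntip)]), tree$tip.label)
  list(sequences = tips, tree = tree)
}
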