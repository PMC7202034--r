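# End-to-end orchestration: config, comparison plans, the omnibus ANOVA and
# the molecular-evolution stage, with deterministic seeding and plain-text
# artifacts (CSV / FASTA / newick / JSON config).

#' Pipeline configuration
#'
#' Aggregates every tunable of the analysis: the block-reference predicate,
#' assumption-gate thresholds, the Cook's-distance rule, KA/KS options,
#' bootstrap depth and the master seed.
#'
#' @param reference List with `strain`, `genotype`, `treatment` for the block
#'   reference sample.
#' @param per_strain Resolve references per block x strain (wildtype-only
#'   designs).
#' @param shapiro_alpha,levene_alpha Gate thresholds for the two-group
#'   decision tree.
#' @param cooks_multiplier Multiple of `4/(N-K-1)` used as influence cutoff.
#' @param saturation_value Replacement for saturated KA/KS estimates.
#' @param bootstrap_reps Bootstrap replicates for tree support.
#' @param seed Master seed for all stochastic steps.
#' @param comparisons Optional explicit comparison plan (list of entries with
#'   `label`, `family_id`, `filter_a`, `filter_b`); when `NULL` a default
#'   plan is derived from the data.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(reference = list(strain = "OreR",
                                             genotype = "w1118",
                                             treatment = "standard"),
                            per_strain = FALSE,
                            shapiro_alpha = 0.05, levene_alpha = 0.1,
                            cooks_multiplier = 2,
                            saturation_value = 9.999999,
                            bootstrap_reps = 1000,
                            seed = 1L,
                            comparisons = NULL) {
  stopifnot(shapiro_alpha > 0, shapiro_alpha < 1,
            levene_alpha > 0, levene_alpha < 1)
  structure(list(reference = reference, per_strain = per_strain,
                 shapiro_alpha = shapiro_alpha, levene_alpha = levene_alpha,
                 cooks_multiplier = cooks_multiplier,
                 saturation_value = saturation_value,
                 bootstrap_reps = bootstrap_reps, seed = seed,
                 comparisons = comparisons),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path Path to a JSON config; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!length(raw$comparisons)) raw$comparisons <- NULL
  do.call(pipeline_config, raw[intersect(names(raw),
                                         names(formals(pipeline_config)))])
}

#' Semantic hash of a pipeline configuration
#'
#' MD5 over the canonical JSON serialization; changes iff a semantic option
#' changes.
#'
#' @param config A `pipeline_config`.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}

subset_rates <- function(rates, filter) {
  ok <- rep(TRUE, nrow(rates))
  for (nm in names(filter)) ok <- ok & rates[[nm]] %in% filter[[nm]]
  rates$normalized[ok]
}

#' Default pairwise comparison plan for a factorial rates table
#'
#' Mirrors the published table families: within-strain genotype and treatment
#' contrasts form one Holm family per scope ("strain" rows), and mtDNA
#' species-pooled contrasts form a second family.
#'
#' @param rates Processed rates table (from [process_respirometry()]).
#' @param min_n Minimum per-group n for a contrast to be planned.
#' @return List of plan entries (`label`, `family_id`, `filter_a`,
#'   `filter_b`).
#' @export
default_comparison_plan <- function(rates, min_n = 3) {
  plan <- list()
  add <- function(label, family, fa, fb) {
    if (length(subset_rates(rates, fa)) >= min_n &&
        length(subset_rates(rates, fb)) >= min_n)
      plan[[length(plan) + 1L]] <<- list(label = label, family_id = family,
                                         filter_a = fa, filter_b = fb)
  }
  strains <- unique(rates$strain)
  genos <- unique(rates$genotype)
  treats <- unique(rates$treatment)
  for (s in strains) {
    if (length(genos) >= 2)
      for (tr in treats)
        for (i in seq_len(length(genos) - 1)) for (j in seq(i + 1, length(genos)))
          add(sprintf("%s %s: %s vs %s", tr, s, genos[i], genos[j]),
              "strain_contrasts",
              list(strain = s, genotype = genos[i], treatment = tr),
              list(strain = s, genotype = genos[j], treatment = tr))
    for (g in genos)
      for (i in seq_len(length(treats) - 1)) for (j in seq(i + 1, length(treats)))
        add(sprintf("%s %s: %s vs %s", g, s, treats[i], treats[j]),
            "strain_contrasts",
            list(strain = s, genotype = g, treatment = treats[i]),
            list(strain = s, genotype = g, treatment = treats[j]))
  }
  species <- unique(rates$mtdna_species)
  if (length(species) >= 2) {
    for (g in genos) for (tr in treats)
      add(sprintf("%s %s: %s vs %s", tr, g, species[1], species[2]),
          "species_contrasts",
          list(mtdna_species = species[1], genotype = g, treatment = tr),
          list(mtdna_species = species[2], genotype = g, treatment = tr))
    for (g in genos) for (sp in species)
      for (i in seq_len(length(treats) - 1)) for (j in seq(i + 1, length(treats)))
        add(sprintf("%s %s: %s vs %s", g, sp, treats[i], treats[j]),
            "species_contrasts",
            list(mtdna_species = sp, genotype = g, treatment = treats[i]),
            list(mtdna_species = sp, genotype = g, treatment = treats[j]))
  }
  plan
}

#' Run a comparison plan through the gated two-group machinery
#'
#' @param rates Processed rates table with a `normalized` column.
#' @param plan Plan entries as from [default_comparison_plan()].
#' @param shapiro_alpha,levene_alpha Gate thresholds.
#' @return Table-1-shaped data frame: label, family, method, raw and Holm
#'   p-values, Hedges' g and magnitude.
#' @export
run_comparison_plan <- function(rates, plan, shapiro_alpha = 0.05,
                                levene_alpha = 0.1) {
  results <- lapply(plan, function(cm) {
    a <- subset_rates(rates, cm$filter_a)
    b <- subset_rates(rates, cm$filter_b)
    gated_two_group_test(a, b, label = cm$label, family_id = cm$family_id,
                         shapiro_alpha = shapiro_alpha,
                         levene_alpha = levene_alpha)
  })
  adjust_families(results)
}

#' Influence-filtered Type-III omnibus ANOVA with effect sizes
#'
#' Applies the Cook's-distance rule on the full factorial model, drops the
#' flagged observations, and computes the Type-III table with the six
#' effect-size columns.
#'
#' @param rates Processed rates table.
#' @param formula Model formula (default
#'   `normalized ~ genotype * mtdna_species * treatment`).
#' @param cooks_multiplier Cook's cutoff multiplier.
#' @return List with `table` (effect-size-annotated ANOVA table) and
#'   `influence` (the `influence_report`).
#' @export
run_anova <- function(rates,
                      formula = normalized ~ genotype * mtdna_species *
                        treatment,
                      cooks_multiplier = 2) {
  vars <- all.vars(formula)[-1]
  for (v in vars) rates[[v]] <- factor(rates[[v]])
  rep_ <- cooks_filter(formula, data = rates, K = length(vars),
                       multiplier = cooks_multiplier)
  keep <- setdiff(seq_len(nrow(rates)), rep_$removed_indices)
  tab <- type3_anova(rates[keep, , drop = FALSE], formula)
  list(table = anova_effect_sizes(tab), influence = rep_)
}

write_phylip_dist <- function(d, path) {
  ids <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(ids[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Run the full pipeline and write the artifact bundle
#'
#' Stages: respirometry processing, Cook's filtering + comparisons + Type-III
#' ANOVA; independently, protein-guided codon threading, pairwise KA/KS and a
#' bootstrap-supported NJ tree. Every output is a plain-text file stamped (in
#' `run.log`) with the config hash and seed; re-running with identical inputs
#' and config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param samples Respirometry samples (CSV path or data frame); `NULL` skips
#'   the statistics branch.
#' @param cds,protein_aln FASTA paths or named character vectors for the
#'   molecular branch; `NULL` skips it.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the written file paths and in-memory results.
#' @export
run_all <- function(config = pipeline_config(), samples = NULL,
                    cds = NULL, protein_aln = NULL, out_dir = "mitonuc_out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- c(sprintf("mitonuc run  config_hash=%s  seed=%d",
                   config_hash(config), config$seed))
  paths <- list()
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      qdir <- file.path(out_dir, "quarantine")
      dir.create(qdir, showWarnings = FALSE)
      writeLines(c(log, paste0("FAILED at stage ", name, ": ",
                               conditionMessage(e))),
                 file.path(qdir, "run.log"))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  num <- function(df) {  # stable number formatting for byte-identical reruns
    for (nm in names(df)) if (is.numeric(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 15)
    df
  }
  if (!is.null(samples)) {
    rates <- stage("respirometry", {
      ref <- do.call(reference_predicate, config$reference)
      process_respirometry(samples, ref, config$per_strain)
    })
    results$rates <- rates
    paths$rates <- file.path(out_dir, "rates.csv")
    utils::write.csv(num(rates), paths$rates, row.names = FALSE)

    an <- stage("anova", run_anova(rates,
                                   cooks_multiplier = config$cooks_multiplier))
    results$anova <- an
    log <- c(log,
             sprintf("cooks cutoff=%.6f removed=%s", an$influence$cutoff,
                     if (length(an$influence$removed_indices))
                       paste(an$influence$removed_indices, collapse = ",")
                     else "none"),
             sprintf("removed Cook's D: %s",
                     if (length(an$influence$removed_indices))
                       paste(sprintf("%.4f",
                         an$influence$cooks_distances[
                           an$influence$removed_indices]), collapse = ",")
                     else "-"))
    paths$table2 <- file.path(out_dir, "table2.csv")
    utils::write.csv(num(an$table), paths$table2, row.names = FALSE)

    keep <- setdiff(seq_len(nrow(rates)), an$influence$removed_indices)
    filtered <- rates[keep, , drop = FALSE]
    plan <- if (is.null(config$comparisons))
      default_comparison_plan(filtered) else config$comparisons
    tb1 <- stage("comparisons",
                 run_comparison_plan(filtered, plan, config$shapiro_alpha,
                                     config$levene_alpha))
    results$table1 <- tb1
    paths$table1 <- file.path(out_dir, "table1.csv")
    utils::write.csv(num(tb1), paths$table1, row.names = FALSE)
  }
  if (!is.null(cds) && !is.null(protein_aln)) {
    aln <- stage("threading", thread_codon_alignment(protein_aln, cds,
                                                     drop_bad = TRUE))
    kk <- stage("kaks", pairwise_kaks_matrix(aln, config$saturation_value))
    results$kaks <- kk
    paths$kaks <- file.path(out_dir, "kaks.csv")
    utils::write.csv(num(kk$pairs), paths$kaks, row.names = FALSE)
    paths$dist <- file.path(out_dir, "dist.phy")
    write_phylip_dist(k80_distance(unclass(aln)), paths$dist)
    tree <- stage("tree", bootstrap_support(unclass(aln),
                                            n_reps = config$bootstrap_reps,
                                            seed = config$seed))
    results$tree <- tree
    paths$tree <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, paths$tree)
  }
  paths$log <- file.path(out_dir, "run.log")
  writeLines(log, paths$log)
  invisible(list(paths = paths, results = results, log = log))
}

#' Command-line entry point
#'
#' Dispatches `Rscript -e 'mitonuc::mitonuc_cli()'` style invocations (a thin
#' wrapper lives in `inst/cli/mitonuc.R`). Subcommands:
#' `run --config cfg.json --samples s.csv [--cds c.fasta --aln p.fasta]
#' --out dir [--seed n]`,
#' `respiro --in s.csv --out rates.csv [--reference strain,genotype,treatment]`,
#' `kaks --cds c.fasta --aln p.fasta --out kaks.csv`,
#' `simulate-respiro --seed n --out samples.csv`,
#' `simulate-codons --omega w --kappa k --length L --seed n --out pair.fasta`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status: 0 success, 2 validation failure, 3 stage
#'   failure.
#' @export
mitonuc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { message("no subcommand given"); return(2L) }
  cmd <- args[1]
  opt <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      opt[[substring(rest[i], 3)]] <- rest[i + 1L]; i <- i + 2L
    } else i <- i + 1L
  }
  res <- tryCatch({
    switch(cmd,
      run = {
        cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
               else pipeline_config()
        if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
        run_all(cfg, samples = opt$samples, cds = opt$cds,
                protein_aln = opt$aln,
                out_dir = if (is.null(opt$out)) "mitonuc_out" else opt$out)
        0L
      },
      respiro = {
        ref <- if (!is.null(opt$reference)) {
          p <- strsplit(opt$reference, ",")[[1]]
          reference_predicate(p[1], p[2], p[3])
        } else reference_predicate()
        out <- process_respirometry(opt$`in`, ref)
        utils::write.csv(out, opt$out, row.names = FALSE)
        0L
      },
      kaks = {
        aln <- thread_codon_alignment(opt$aln, opt$cds, drop_bad = TRUE)
        kk <- pairwise_kaks_matrix(aln)
        utils::write.csv(kk$pairs, opt$out, row.names = FALSE)
        0L
      },
      `simulate-respiro` = {
        sc <- respirometry_scenario(seed = as.integer(opt$seed %||% 1))
        utils::write.csv(simulate_respirometry(sc), opt$out, row.names = FALSE)
        0L
      },
      `simulate-codons` = {
        sc <- codon_scenario(
          n_codons = as.integer(opt$length %||% 300),
          kappa = as.numeric(opt$kappa %||% 2),
          omega = as.numeric(opt$omega %||% 0.1),
          seed = as.integer(opt$seed %||% 1))
        pr <- simulate_codon_pair(sc)
        write_fasta(c(seq1 = pr$seq1, seq2 = pr$seq2), opt$out)
        0L
      },
      { message("unknown subcommand: ", cmd); 2L })
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("^stage ", conditionMessage(e))) 3L else 2L
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
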