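#' Closed-flow respirometry gas measurement
#'
#' Bundle of fractional gas concentrations and flow rate for one sealed-syringe
#' sample. Defaults assume ambient incurrent air with CO2 and water vapor
#' scrubbed before acquisition: `FiO2 = 0.2094`, `FiCO2 = 0`.
#'
#' @param FRe Excurrent mass flow rate at STP, mL/min. Must be > 0.
#' @param FiO2 Incurrent O2 fraction (dimensionless). Default ambient 0.2094.
#' @param FprimeiO2 Incurrent O2 fraction used in the denominator term;
#'   equals `FiO2` under the standard scrubbing assumption.
#' @param FprimeeO2 Excurrent O2 fraction, water-vapor-free.
#' @param FiCO2 Incurrent CO2 fraction; 0 when scrubbed.
#' @param FprimeeCO2 Excurrent CO2 fraction, water-vapor-free.
#' @param tolerance Slack allowed on the `FprimeeO2 <= FiO2` check for a
#'   respiring sample (instrument noise).
#' @return An object of class `gas_measurement`.
#' @examples
#' g <- gas_measurement(FRe = 1, FprimeeO2 = 0.19, FprimeeCO2 = 0.01)
#' compute_vo2(g)
#' @export
gas_measurement <- function(FRe, FiO2 = 0.2094, FprimeiO2 = FiO2,
                            FprimeeO2, FiCO2 = 0, FprimeeCO2,
                            tolerance = 1e-6) {
  fr <- c(FiO2 = FiO2, FprimeiO2 = FprimeiO2, FprimeeO2 = FprimeeO2,
          FiCO2 = FiCO2, FprimeeCO2 = FprimeeCO2)
  if (any(!is.finite(c(FRe, fr))))
    stop("gas_measurement: all fields must be finite numbers", call. = FALSE)
  if (any(fr < 0 | fr > 1))
    stop("gas_measurement: gas fractions must lie in [0, 1]", call. = FALSE)
  if (FRe <= 0)
    stop("gas_measurement: FRe must be > 0", call. = FALSE)
  if (FprimeeO2 > FiO2 + tolerance)
    stop("gas_measurement: excurrent O2 exceeds incurrent O2 beyond tolerance; ",
         "not a respiring sample", call. = FALSE)
  structure(list(FRe = FRe, FiO2 = FiO2, FprimeiO2 = FprimeiO2,
                 FprimeeO2 = FprimeeO2, FiCO2 = FiCO2,
                 FprimeeCO2 = FprimeeCO2),
            class = "gas_measurement")
}

# vectorized cores shared by the object interface and CSV processing
vo2_rate <- function(FRe, FiO2, FeO2, FeCO2, FiCO2 = 0, FipO2 = FiO2) {
  denom <- 1 - FipO2
  if (any(denom <= 0))
    stop("invalid measurement: denominator 1 - F'iO2 <= 0", call. = FALSE)
  FRe * ((FiO2 - FeO2) - FipO2 * (FeCO2 - FiCO2)) / denom
}

vco2_rate <- function(FRe, FeCO2, FiCO2 = 0, FiO2 = 0.2094, FeO2 = FiO2) {
  FRe * ((FeCO2 - FiCO2) + FiCO2 * (FiO2 - FeO2)) / (1 + FiCO2)
}

#' Volumetric oxygen consumption
#'
#' VO2 (mL/min) from a closed-flow measurement:
#' `FRe * ((FiO2 - F'eO2) - F'iO2 * (F'eCO2 - FiCO2)) / (1 - F'iO2)`.
#' With the ambient defaults (`F'iO2 = 0.2094`, `FiCO2 = 0`) this reduces to
#' the simplified single-term form used for scrubbed systems.
#'
#' @param g A [gas_measurement()].
#' @return Oxygen consumption rate in mL/min.
#' @export
compute_vo2 <- function(g) {
  stopifnot(inherits(g, "gas_measurement"))
  vo2_rate(g$FRe, g$FiO2, g$FprimeeO2, g$FprimeeCO2, g$FiCO2, g$FprimeiO2)
}

#' Volumetric carbon dioxide production
#'
#' VCO2 (mL/min): `FRe * ((F'eCO2 - FiCO2) + FiCO2 * (FiO2 - F'eO2)) / (1 + FiCO2)`.
#' With CO2 scrubbed (`FiCO2 = 0`) this is simply `FRe * F'eCO2`.
#'
#' @inheritParams compute_vo2
#' @return CO2 production rate in mL/min.
#' @export
compute_vco2 <- function(g) {
  stopifnot(inherits(g, "gas_measurement"))
  vco2_rate(g$FRe, g$FprimeeCO2, g$FiCO2, g$FiO2, g$FprimeeO2)
}

#' Respiratory quotient
#'
#' RQ = VCO2 / VO2; indexes the macronutrient class being oxidized
#' (1 for pure carbohydrate, ~0.7 for lipid).
#'
#' @param vo2 Oxygen consumption, mL/min. Must be > 0.
#' @param vco2 CO2 production, mL/min.
#' @return Dimensionless ratio.
#' @export
compute_rq <- function(vo2, vco2) {
  if (any(vo2 <= 0))
    stop("RQ undefined: VO2 must be > 0", call. = FALSE)
  vco2 / vo2
}

#' Per-fly hourly oxygen consumption
#'
#' Adjusts a total volume of O2 consumed over the incubation for the recorded
#' number of flies and the incubation duration.
#'
#' @param vo2_total Total mL O2 consumed over the incubation.
#' @param n_flies Fly count recorded post-assay (>= 1).
#' @param incubation_min Incubation duration in minutes (> 0).
#' @return Rate in mL O2 / fly / hr.
#' @export
per_fly_rate <- function(vo2_total, n_flies, incubation_min) {
  if (any(n_flies < 1))
    stop("all-flies-lost: n_flies must be >= 1 (sample should be flagged, ",
         "not silently dropped)", call. = FALSE)
  if (any(incubation_min <= 0))
    stop("incubation_min must be > 0", call. = FALSE)
  vo2_total / n_flies / (incubation_min / 60)
}

#' Reference predicate for block normalization
#'
#' @param strain Strain label the reference must carry, or `NA` to match any.
#' @param genotype Genotype label, or `NA` to match any.
#' @param treatment Treatment label, or `NA` to match any.
#' @return A predicate specification used by [normalize_block()].
#' @export
reference_predicate <- function(strain = "OreR", genotype = "w1118",
                                treatment = "standard") {
  structure(list(strain = strain, genotype = genotype, treatment = treatment),
            class = "reference_predicate")
}

ref_matches <- function(pred, data) {
  ok <- rep(TRUE, nrow(data))
  for (f in c("strain", "genotype", "treatment")) {
    v <- pred[[f]]
    if (!is.null(v) && !is.na(v)) ok <- ok & data[[f]] == v
  }
  ok
}

#' Normalize rates to the first reference sample of each block
#'
#' Every rate in a block is divided by the rate of that block's reference
#' sample: the sample matching the reference predicate with the smallest
#' `acquisition_index` ("first sample" rule). The reference sample itself maps
#' to exactly 1. With `per_strain = TRUE` (wildtype-only designs) the
#' reference is resolved within each block x strain group instead, so each
#' strain is scaled to its own first standard-treatment sample.
#'
#' @param data Data frame with columns `block_id`, `strain`, `genotype`,
#'   `treatment`, `acquisition_index` and the rate column.
#' @param rate_col Name of the column holding per-fly rates.
#' @param reference A [reference_predicate()].
#' @param per_strain Resolve the reference per block x strain group.
#' @return `data` with a `normalized` column appended.
#' @export
normalize_block <- function(data, rate_col = "per_fly_per_hr",
                            reference = reference_predicate(),
                            per_strain = FALSE) {
  stopifnot(is.data.frame(data), rate_col %in% names(data))
  key <- if (per_strain) interaction(data$block_id, data$strain, drop = TRUE)
         else factor(data$block_id)
  norm <- rep(NA_real_, nrow(data))
  for (grp in levels(key)) {
    idx <- which(key == grp)
    blk <- data[idx, , drop = FALSE]
    cand <- which(ref_matches(reference, blk))
    if (length(cand) == 0L)
      stop("missing-reference: no reference sample in block '",
           as.character(blk$block_id[1]),
           if (per_strain) paste0("' strain '", blk$strain[1]) else "",
           "'", call. = FALSE)
    first <- cand[which.min(blk$acquisition_index[cand])]
    ref_rate <- blk[[rate_col]][first]
    if (!is.finite(ref_rate) || ref_rate <= 0)
      stop("degenerate-reference: reference rate <= 0 in block '",
           as.character(blk$block_id[1]), "'", call. = FALSE)
    norm[idx] <- blk[[rate_col]] / ref_rate
  }
  data$normalized <- norm
  data
}

respirometry_cols <- c("sample_id", "block_id", "strain", "mtdna_species",
                       "genotype", "treatment", "n_flies", "incubation_min",
                       "mass_mg", "FRe", "FiO2", "FeO2", "FiCO2", "FeCO2",
                       "acquisition_index")

#' Process a respirometry samples table into normalized metabolic rates
#'
#' Runs the full respirometry path on a samples data frame (or CSV file):
#' VO2 and VCO2 from the gas fractions, RQ, total O2 over the incubation,
#' per-fly hourly rate, and within-block reference normalization.
#'
#' @param samples Data frame with the columns listed in
#'   `mitonuc:::respirometry_cols`, or a path to such a CSV.
#' @param reference A [reference_predicate()] selecting the block reference.
#' @param per_strain Passed to [normalize_block()].
#' @return The input table with `Vo2`, `Vco2`, `RQ`, `per_fly_per_hr` and
#'   `normalized` columns appended. Units: mL/min for rates, mL/fly/hr for the
#'   per-fly column; `normalized` is dimensionless (multiples of the
#'   block reference).
#' @export
process_respirometry <- function(samples, reference = reference_predicate(),
                                 per_strain = FALSE) {
  if (is.character(samples))
    samples <- utils::read.csv(samples, stringsAsFactors = FALSE)
  miss <- setdiff(respirometry_cols, names(samples))
  if (length(miss))
    stop("samples table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples[c("block_id", "acquisition_index")]))
    stop("acquisition_index must be unique within block", call. = FALSE)
  samples$Vo2 <- vo2_rate(samples$FRe, samples$FiO2, samples$FeO2,
                          samples$FeCO2, samples$FiCO2)
  samples$Vco2 <- vco2_rate(samples$FRe, samples$FeCO2, samples$FiCO2,
                            samples$FiO2, samples$FeO2)
  samples$RQ <- ifelse(samples$Vo2 > 0, samples$Vco2 / samples$Vo2, NA_real_)
  vo2_total <- samples$Vo2 * samples$incubation_min
  samples$per_fly_per_hr <- per_fly_rate(vo2_total, samples$n_flies,
                                         samples$incubation_min)
  normalize_block(samples, "per_fly_per_hr", reference, per_strain)
}
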