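#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-population generator. Defaults
#' describe a desk-scale analog of a commercial crossbred pig cohort: a
#' multi-generation random-mating pedigree whose final generation is the
#' phenotyped (and mostly genotyped) cohort, biallelic markers with
#' pedigree-induced linkage disequilibrium and an SNP/INDEL class label,
#' a polygenic trait with moderate heritability, and categorical fixed
#' effects (sex, farm, birth batch analogs) contaminating the raw records.
#'
#' @param n_founders number of unrelated, non-inbred founders (generation 0).
#' @param n_generations number of discrete generations of random non-self
#'   matings after the founders.
#' @param offspring_per_mating offspring produced by each mating pair.
#' @param n_markers number of biallelic markers.
#' @param indel_fraction probability that a marker is labelled `INDEL`
#'   (class label only; INDELs are statistically identical to SNPs).
#' @param founder_maf_range founder allele frequencies are drawn uniformly
#'   on this interval (default `c(0.05, 0.5)`).
#' @param n_chromosomes number of autosomes carrying the markers.
#' @param morgans_per_chromosome genetic length per chromosome in Morgans;
#'   recombination follows a Haldane map (Poisson crossovers, no
#'   interference).
#' @param architecture genetic architecture of the trait: `"polygenic"`
#'   (every marker a small normal effect), `"sparse"` (only `n_qtl`
#'   markers have normal effects) or `"mixture"` (QTL effects drawn from a
#'   four-component zero/small/medium/moderate normal mixture).
#' @param n_qtl number of causal markers for the sparse and mixture
#'   architectures (ignored for polygenic).
#' @param target_h2 narrow-sense heritability, strictly inside (0, 1).
#'   The residual SD is calibrated to the realized genetic variance so the
#'   in-sample heritability equals the target exactly.
#' @param fixed_effect_spec list of fixed effects, each a list with
#'   elements `name`, `n_levels`, `effect_sd` (level values are drawn
#'   `N(0, effect_sd^2)`).
#' @param genotyped_fraction_last_gen fraction of the final generation
#'   that is genotyped (the rest stay in the pedigree, phenotyped only).
#' @param mu trait grand mean.
#' @param seed integer seed; identical configurations reproduce
#'   bit-identical pedigree, genotypes and phenotypes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 80,
                       n_generations = 3,
                       offspring_per_mating = 4,
                       n_markers = 2000,
                       indel_fraction = 0.25,
                       founder_maf_range = c(0.05, 0.5),
                       n_chromosomes = 10,
                       morgans_per_chromosome = 1,
                       architecture = c("polygenic", "sparse", "mixture"),
                       n_qtl = 100,
                       target_h2 = 0.45,
                       fixed_effect_spec = list(
                         list(name = "sex", n_levels = 2, effect_sd = 1),
                         list(name = "farm", n_levels = 3, effect_sd = 1),
                         list(name = "batch", n_levels = 6, effect_sd = 0.5)
                       ),
                       genotyped_fraction_last_gen = 1,
                       mu = 100,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_mating = as.integer(offspring_per_mating),
    n_markers = as.integer(n_markers),
    indel_fraction = indel_fraction,
    founder_maf_range = founder_maf_range,
    n_chromosomes = as.integer(n_chromosomes),
    morgans_per_chromosome = morgans_per_chromosome,
    architecture = architecture,
    n_qtl = as.integer(n_qtl),
    target_h2 = target_h2,
    fixed_effect_spec = fixed_effect_spec,
    genotyped_fraction_last_gen = genotyped_fraction_last_gen,
    mu = mu,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_founders < 2) stop("configuration error: at least 2 founders are required")
  if (cfg$n_generations < 0) stop("configuration error: n_generations must be >= 0")
  if (cfg$n_generations > 0 && cfg$offspring_per_mating < 1) {
    stop("configuration error: offspring_per_mating must be positive")
  }
  for (fld in c("n_markers", "n_chromosomes")) {
    if (cfg[[fld]] < 1) stop("configuration error: ", fld, " must be positive")
  }
  if (cfg$morgans_per_chromosome < 0) stop("configuration error: negative genetic length")
  if (cfg$indel_fraction < 0 || cfg$indel_fraction > 1) {
    stop("configuration error: indel_fraction must lie in [0, 1]")
  }
  if (cfg$target_h2 <= 0 || cfg$target_h2 >= 1) {
    stop("configuration error: target_h2 must lie strictly inside (0, 1)")
  }
  if (cfg$architecture != "polygenic") {
    if (cfg$n_qtl < 1) stop("configuration error: n_qtl must be positive")
    if (cfg$n_qtl > cfg$n_markers) stop("configuration error: n_qtl exceeds n_markers")
  }
  r <- cfg$founder_maf_range
  if (length(r) != 2 || r[1] < 0 || r[2] > 1 || r[1] > r[2]) {
    stop("configuration error: founder_maf_range must be an interval within [0, 1]")
  }
  if (cfg$genotyped_fraction_last_gen < 0 || cfg$genotyped_fraction_last_gen > 1) {
    stop("configuration error: genotyped_fraction_last_gen must lie in [0, 1]")
  }
  invisible(cfg)
}

# stage-specific seed so each operation is individually reproducible
sim_seed <- function(cfg, stage) {
  (abs(cfg$seed) + 104729L * stage) %% 2147483647L
}
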