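#' Simulate a multi-generation random-mating pedigree
#'
#' Founders form generation 0. In each later generation the previous
#' generation is randomly paired (without replacement, so matings are
#' never selfings) and each pair produces `offspring_per_mating`
#' offspring. Ids are dense and parents always precede offspring.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()] with a `gen` column.
#' @export
simulate_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, 0L))
  id <- seq_len(cfg$n_founders)
  sire <- dam <- rep(0L, cfg$n_founders)
  gen <- rep(0L, cfg$n_founders)
  prev <- id
  next_id <- cfg$n_founders + 1L
  for (g in seq_len(cfg$n_generations)) {
    if (length(prev) < 2) {
      stop("generation ", g - 1L, " has fewer than 2 individuals; cannot mate")
    }
    perm <- sample(prev)
    n_mat <- length(prev) %/% 2L
    sires <- perm[seq_len(n_mat)]
    dams <- perm[n_mat + seq_len(n_mat)]
    n_off <- n_mat * cfg$offspring_per_mating
    off_ids <- next_id - 1L + seq_len(n_off)
    id <- c(id, off_ids)
    sire <- c(sire, rep(sires, each = cfg$offspring_per_mating))
    dam <- c(dam, rep(dams, each = cfg$offspring_per_mating))
    gen <- c(gen, rep(g, n_off))
    prev <- off_ids
    next_id <- next_id + n_off
  }
  pedigree(id, sire, dam, gen = gen)
}

# Marker map: markers split into contiguous equal-size chromosome blocks,
# genetic positions uniform (sorted) along each chromosome.
make_marker_map <- function(cfg) {
  m <- cfg$n_markers
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), m))
  gpos <- numeric(m)
  for (c_ in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom == c_)
    gpos[idx] <- sort(runif(length(idx), 0, cfg$morgans_per_chromosome))
  }
  cls <- ifelse(rbinom(m, 1, cfg$indel_fraction) == 1, "INDEL", "SNP")
  data.frame(
    marker_id = sprintf("m%05d", seq_len(m)),
    chrom = chrom,
    pos = as.integer(round(gpos * 1e6)) + seq_len(m), # bp-scale, strictly informative
    gpos = gpos,
    class = cls,
    allele_a = rep("A", m),
    allele_b = rep("B", m),
    stringsAsFactors = FALSE
  )
}

# One gamete from parent haplotypes h1, h2 (vectors over one chromosome),
# Haldane model: Poisson(L) crossovers placed uniformly, random start phase.
recombine_chromosome <- function(h1, h2, gpos, L) {
  start <- sample.int(2L, 1L) - 1L
  n_xo <- if (L > 0) rpois(1L, L) else 0L
  if (n_xo == 0L) {
    if (start == 0L) return(h1) else return(h2)
  }
  xo <- sort(runif(n_xo, 0, L))
  phase <- (start + findInterval(gpos, xo)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes are drawn per marker from the founder allele
#' frequency law; descendants inherit recombinant gametes (Haldane map,
#' no interference) from their parents. Each marker carries an SNP/INDEL
#' class label. No missingness is introduced (see
#' [inject_missingness()]).
#'
#' @param ped a [pedigree()] from [simulate_pedigree()].
#' @param cfg the matching [sim_config()].
#' @return a [genotype_matrix()] over all pedigree individuals, with the
#'   founder allele frequencies in `attr(, "founder_freq")`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  validate_sim_config(cfg)
  set.seed(sim_seed(cfg, 1L))
  map <- make_marker_map(cfg)
  m <- nrow(map)
  n <- nrow(ped)
  p <- runif(m, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  row_of <- integer(max(ped$id))
  row_of[ped$id] <- seq_len(n)
  chrom_idx <- split(seq_len(m), map$chrom)
  is_founder <- ped$sire == 0L & ped$dam == 0L
  for (k in seq_len(n)) {
    if (is_founder[k]) {
      H1[k, ] <- rbinom(m, 1L, p)
      H2[k, ] <- rbinom(m, 1L, p)
    } else {
      rs <- row_of[ped$sire[k]]
      rd <- row_of[ped$dam[k]]
      for (idx in chrom_idx) {
        gpos <- map$gpos[idx]
        H1[k, idx] <- recombine_chromosome(H1[rs, idx], H2[rs, idx], gpos,
                                           cfg$morgans_per_chromosome)
        H2[k, idx] <- recombine_chromosome(H1[rd, idx], H2[rd, idx], gpos,
                                           cfg$morgans_per_chromosome)
      }
    }
  }
  geno <- genotype_matrix(H1 + H2,
                          markers = map[, c("marker_id", "chrom", "pos",
                                            "class", "allele_a", "allele_b")],
                          ids = as.character(ped$id))
  attr(geno, "founder_freq") <- p
  attr(geno, "gpos") <- map$gpos
  geno
}

#' Draw marker effects and phenotypes
#'
#' Effects follow the configured architecture: `polygenic` gives every
#' marker an i.i.d. normal effect; `sparse` gives normal effects to
#' `n_qtl` randomly chosen markers; `mixture` draws each of the `n_qtl`
#' effects from a four-component normal mixture (zero / very small /
#' small / moderate variance, relative weights 0.5/0.3/0.15/0.05 and
#' relative variances 0, 1e-4, 1e-3, 1e-2). The true genetic value is
#' `dosage %*% effects`. The residual SD is scaled to the realized
#' genetic variance so the in-sample heritability equals `target_h2`
#' exactly; categorical fixed-effect values are added on top.
#'
#' @param geno a [genotype_matrix()] over the individuals to phenotype.
#' @param cfg the matching [sim_config()].
#' @return list with `truth` (per-individual `g_true`, per-marker
#'   `effects`, QTL indices, realized variances and heritability) and
#'   `pheno`, a data frame with `id`, raw phenotype `y`, and one factor
#'   column per configured fixed effect.
#' @export
simulate_effects_and_phenotypes <- function(geno, cfg) {
  validate_sim_config(cfg)
  if (n_individuals(geno) == 0 || n_markers(geno) == 0) stop("empty genotype matrix")
  set.seed(sim_seed(cfg, 2L))
  m <- n_markers(geno)
  n <- n_individuals(geno)
  effects <- numeric(m)
  if (cfg$architecture == "polygenic") {
    qtl <- seq_len(m)
    effects <- rnorm(m)
  } else if (cfg$architecture == "sparse") {
    qtl <- sort(sample.int(m, cfg$n_qtl))
    effects[qtl] <- rnorm(cfg$n_qtl)
  } else {
    qtl <- sort(sample.int(m, cfg$n_qtl))
    comp <- sample.int(4L, cfg$n_qtl, replace = TRUE,
                       prob = c(0.5, 0.3, 0.15, 0.05))
    comp_sd <- sqrt(c(0, 1e-4, 1e-3, 1e-2))
    effects[qtl] <- rnorm(cfg$n_qtl) * comp_sd[comp]
  }
  g_true <- drop(geno$dosage %*% effects)
  if (anyNA(g_true)) stop("genotypes contain missing dosages; phenotype simulation needs complete data")
  vg <- var(g_true)
  if (vg <= .Machine$double.eps) {
    stop("zero realized genetic variance (all QTL fixed?); cannot calibrate residual variance")
  }
  ve <- vg * (1 - cfg$target_h2) / cfg$target_h2
  e <- rnorm(n)
  e <- e * sqrt(ve / var(e))
  pheno <- data.frame(id = geno$ids, stringsAsFactors = FALSE)
  fixed_part <- numeric(n)
  for (fe in cfg$fixed_effect_spec) {
    lev <- sample.int(fe$n_levels, n, replace = TRUE)
    vals <- rnorm(fe$n_levels, 0, fe$effect_sd)
    fixed_part <- fixed_part + vals[lev]
    pheno[[fe$name]] <- factor(paste0(fe$name, lev))
  }
  pheno$y <- cfg$mu + fixed_part + g_true + e
  truth <- list(
    g_true = setNames(g_true, geno$ids),
    effects = effects,
    qtl = qtl,
    sigma_g2_realized = vg,
    sigma_e2_realized = var(e),
    realized_h2 = vg / (vg + var(e)),
    fixed_part = setNames(fixed_part, geno$ids)
  )
  list(truth = truth, pheno = pheno)
}

#' Inject missing genotype calls uniformly at random
#'
#' Used only to exercise quality control; the generator itself emits
#' complete data.
#'
#' @param geno a [genotype_matrix()]
#' @param rate per-call missingness probability in \[0, 1\].
#' @param seed integer seed.
#' @return a `genotype_matrix` with `NA` dosages injected.
#' @export
inject_missingness <- function(geno, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  d <- geno$dosage
  drop_mask <- matrix(runif(length(d)) < rate, nrow(d), ncol(d))
  d[drop_mask] <- NA_real_
  genotype_matrix(d, markers = geno$markers, ids = geno$ids)
}

#' Simulate a complete study population
#'
#' Convenience wrapper running pedigree, genotype and phenotype
#' simulation, then restricting phenotypes to the final-generation cohort
#' (the study analog of a phenotyped slaughter cohort). A configurable
#' fraction of the cohort is genotyped; ungenotyped cohort members remain
#' phenotyped pedigree members, which is what makes single-step methods
#' testable.
#'
#' @param n_cohort approximate size of the final-generation cohort.
#' @param ... overrides passed to [sim_config()] (e.g. `n_markers`,
#'   `target_h2`, `architecture`, `fixed_effect_spec`, `seed`).
#' @return list with `cfg`, `ped`, `geno_all` (all pedigree individuals),
#'   `geno` (genotyped cohort members only), `cohort_ids`,
#'   `genotyped_ids`, `pheno` (cohort phenotype table), `truth`.
#' @export
simulate_population <- function(n_cohort = 500, ...) {
  dots <- list(...)
  gens <- if (!is.null(dots$n_generations)) dots$n_generations else 3L
  opm <- if (!is.null(dots$offspring_per_mating)) dots$offspring_per_mating else 4L
  growth <- (opm / 2)^gens
  dots$n_founders <- if (!is.null(dots$n_founders)) dots$n_founders else
    max(4L, as.integer(ceiling(n_cohort / growth)))
  dots$n_generations <- gens
  dots$offspring_per_mating <- opm
  cfg <- do.call(sim_config, dots)
  ped <- simulate_pedigree(cfg)
  geno_all <- simulate_genotypes(ped, cfg)
  cohort_ids <- as.character(ped$id[ped$gen == max(ped$gen)])
  geno_cohort <- subset_individuals(geno_all, cohort_ids)
  sim <- simulate_effects_and_phenotypes(geno_cohort, cfg)
  set.seed(sim_seed(cfg, 3L))
  n_gt <- round(cfg$genotyped_fraction_last_gen * length(cohort_ids))
  genotyped_ids <- sort(sample(cohort_ids, n_gt))
  list(cfg = cfg, ped = ped, geno_all = geno_all,
       geno = subset_individuals(geno_all, genotyped_ids),
       geno_cohort = geno_cohort,
       cohort_ids = cohort_ids, genotyped_ids = genotyped_ids,
       pheno = sim$pheno, truth = sim$truth)
}
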