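#' Write genotypes in PLINK text format
#'
#' Emits `<prefix>.ped` (whitespace dialect, alleles A/B, missing
#' genotype "0 0") and `<prefix>.map` (chromosome, marker id, genetic
#' distance, bp position).
#'
#' @param geno a [genotype_matrix()]
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(geno, prefix) {
  d <- geno$dosage
  mk <- geno$markers
  code <- function(x, a, b) {
    out <- character(length(x))
    out[is.na(x)] <- "0 0"
    out[!is.na(x) & x == 0] <- paste(a[!is.na(x) & x == 0], a[!is.na(x) & x == 0])
    out[!is.na(x) & x == 1] <- paste(a[!is.na(x) & x == 1], b[!is.na(x) & x == 1])
    out[!is.na(x) & x == 2] <- paste(b[!is.na(x) & x == 2], b[!is.na(x) & x == 2])
    out
  }
  lines <- vapply(seq_len(nrow(d)), function(i) {
    paste(c("FAM1", geno$ids[i], "0", "0", "0", "-9",
            code(d[i, ], mk$allele_a, mk$allele_b)), collapse = " ")
  }, "")
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  writeLines(lines, ped_path)
  write.table(data.frame(mk$chrom, mk$marker_id, 0, mk$pos),
              map_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from PLINK text format
#'
#' Counts copies of the B allele (the lexicographically later observed
#' allele at each marker) as the dosage; "0 0" becomes `NA`. When only a
#' single allele is observed the marker is read as monomorphic reference
#' (dosage 0): the text format cannot distinguish all-reference from
#' all-alternate homozygotes.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return a [genotype_matrix()] (variant class defaults to SNP).
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "marker_id", "cm", "pos"),
                    stringsAsFactors = FALSE)
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  ids <- as.character(ped[[2]])
  al <- as.matrix(ped[, 7:(6 + 2 * m), drop = FALSE])
  a1 <- al[, seq(1, 2 * m, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * m, by = 2), drop = FALSE]
  dosage <- matrix(NA_real_, length(ids), m)
  for (j in seq_len(m)) {
    obs <- a1[, j] != "0" & a2[, j] != "0"
    alleles <- sort(unique(c(a1[obs, j], a2[obs, j])))
    if (length(alleles) < 2) {
      dosage[obs, j] <- 0
    } else {
      bal <- alleles[length(alleles)]
      dosage[obs, j] <- (a1[obs, j] == bal) + (a2[obs, j] == bal)
    }
  }
  markers <- data.frame(marker_id = map$marker_id, chrom = map$chrom,
                        pos = map$pos, class = "SNP",
                        allele_a = "A", allele_b = "B",
                        stringsAsFactors = FALSE)
  genotype_matrix(dosage, markers = markers, ids = ids)
}

#' Write / read a pedigree as CSV (id, sire, dam header)
#' @param ped a [pedigree()]
#' @param path file path.
#' @return invisibly, the path (writer) or the pedigree (reader).
#' @export
write_pedigree_csv <- function(ped, path) {
  write.table(as.data.frame(ped)[, c("id", "sire", "dam")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  pedigree(df$id, df$sire, df$dam)
}

#' Write / read a phenotype table as TSV
#' @param pheno phenotype data frame (id, trait and fixed-effect columns).
#' @param path file path.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Persist a relationship matrix as TSV with an id header
#' @param M matrix with ids as dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(M, path) {
  df <- data.frame(id = rownames(M), as.data.frame(as.matrix(M)), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist a sparse symmetric matrix as coordinate triplets (i, j, x)
#' @param M a sparse `Matrix`.
#' @param path file path.
#' @export
write_sparse_triplets <- function(M, path) {
  tm <- as(as(M, "generalMatrix"), "TsparseMatrix")
  write.table(data.frame(i = tm@i + 1L, j = tm@j + 1L, x = tm@x), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Emit a complete small synthetic dataset directory
#'
#' Writes PLINK .ped/.map genotypes, a pedigree CSV and a phenotype TSV
#' for a simulated population — a self-contained fixture for downstream
#' tools.
#'
#' @param dir output directory (created if absent).
#' @param cfg a [sim_config()] (defaults to a small population).
#' @return invisibly, the directory path.
#' @export
write_fixture_dataset <- function(dir, cfg = sim_config(n_founders = 10,
                                                        n_generations = 2,
                                                        n_markers = 50,
                                                        n_chromosomes = 2,
                                                        seed = 1L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  sim <- simulate_effects_and_phenotypes(geno, cfg)
  write_plink(geno, file.path(dir, "genotypes"))
  write_pedigree_csv(ped, file.path(dir, "pedigree.csv"))
  write_phenotypes_tsv(sim$pheno, file.path(dir, "phenotypes.tsv"))
  invisible(dir)
}

#' Published summary statistics for the reference DLY pig cohort
#'
#' Trait-level sample size, mean, SD, printed coefficient of variation
#' and heritability (with SE) for the eight carcass and body measurement
#' traits of a commercial Duroc x (Landrace x Yorkshire) cohort, as
#' published. Used as worked-example input: the coefficient of variation
#' is recomputable as 100 * SD / mean.
#'
#' @return data frame with columns `trait`, `n`, `mean`, `sd`,
#'   `cv_printed`, `h2`, `h2_se`.
#' @export
dly_trait_summary <- function() {
  path <- system.file("extdata", "dly_trait_summary.tsv", package = "gpcomp",
                      mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
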