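#' Marker and individual quality control
#'
#' Filters follow chip-data practice with strict inequalities: individuals
#' with call rate > `ind_call_rate_min` are kept first; then markers with
#' call rate > `marker_call_rate_min` (computed on the retained
#' individuals), minor allele frequency > `maf_min` (observed genotypes
#' only, never imputed), and finally only autosomal markers when
#' `autosomes_only`. The step order matters for the retained counts and is
#' fixed as stated.
#'
#' @param geno a [genotype_matrix()]
#' @param ind_call_rate_min minimum individual call rate (exclusive).
#' @param marker_call_rate_min minimum marker call rate (exclusive).
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param autosomes_only drop markers on non-autosomal chromosomes
#'   (X, Y, XY, MT or any non-numeric label).
#' @return list with `geno` (the filtered panel) and `report`, a
#'   `qc_report` whose removed + retained counts reconcile with the input.
#' @export
quality_control <- function(geno,
                            ind_call_rate_min = 0.9,
                            marker_call_rate_min = 0.9,
                            maf_min = 0.05,
                            autosomes_only = TRUE) {
  if (n_individuals(geno) == 0 || n_markers(geno) == 0) stop("empty genotype matrix")
  n0 <- n_individuals(geno)
  m0 <- n_markers(geno)

  ind_cr <- rowMeans(!is.na(geno$dosage))
  keep_ind <- ind_cr > ind_call_rate_min
  g <- if (all(keep_ind)) geno else subset_individuals(geno, which(keep_ind))
  if (n_individuals(g) == 0) stop("quality control removed every individual")

  mk_cr <- colMeans(!is.na(g$dosage))
  keep_cr <- mk_cr > marker_call_rate_min
  removed_cr <- sum(!keep_cr)
  g <- subset_markers(g, keep_cr)

  mk_maf <- maf(g)
  keep_maf <- !is.na(mk_maf) & mk_maf > maf_min
  removed_maf <- sum(!keep_maf)
  g <- subset_markers(g, keep_maf)

  removed_auto <- 0L
  if (autosomes_only) {
    keep_auto <- is_autosome(g$markers$chrom)
    removed_auto <- sum(!keep_auto)
    g <- subset_markers(g, keep_auto)
  }
  if (n_markers(g) == 0) stop("empty panel: quality control removed every marker")

  report <- structure(list(
    n_individuals_input = n0,
    n_individuals_removed = sum(!keep_ind),
    n_individuals_retained = sum(keep_ind),
    n_markers_input = m0,
    n_markers_removed_by = c(call_rate = removed_cr,
                             maf = removed_maf,
                             non_autosomal = removed_auto),
    n_markers_retained = n_markers(g)
  ), class = "qc_report")
  stopifnot(report$n_individuals_removed + report$n_individuals_retained == n0,
            sum(report$n_markers_removed_by) + report$n_markers_retained == m0)
  list(geno = g, report = report)
}

is_autosome <- function(chrom) {
  lab <- toupper(sub("^CHR", "", toupper(as.character(chrom))))
  grepl("^[0-9]+$", lab)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("quality control report\n")
  cat("  individuals:", x$n_individuals_retained, "retained /",
      x$n_individuals_removed, "removed (call rate)\n")
  cat("  markers:    ", x$n_markers_retained, "retained;",
      "removed:", paste(names(x$n_markers_removed_by),
                        x$n_markers_removed_by, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Partition a panel by variant class
#'
#' @param geno a [genotype_matrix()] whose marker table carries
#'   SNP/INDEL class labels.
#' @param which `"SNP"`, `"INDEL"` or `"BOTH"` (identity).
#' @return a `genotype_matrix` restricted to the class, marker order
#'   preserved.
#' @export
partition_by_class <- function(geno, which = c("BOTH", "SNP", "INDEL")) {
  which <- match.arg(which)
  if (which == "BOTH") return(geno)
  keep <- geno$markers$class == which
  if (!any(keep)) stop("empty panel: no markers of class ", which)
  subset_markers(geno, keep)
}

#' Thin a panel to a target marker count
#'
#' Uniform random subset without replacement of
#' `min(target_count, n_markers)` markers; genome order is preserved and
#' the draw is deterministic under the seed.
#'
#' @param geno a [genotype_matrix()]
#' @param target_count desired number of markers (>= 1).
#' @param seed integer seed.
#' @return a thinned `genotype_matrix`.
#' @export
thin_markers <- function(geno, target_count, seed = 1L) {
  stopifnot(target_count >= 1)
  m <- n_markers(geno)
  if (target_count >= m) return(geno)
  set.seed(seed)
  keep <- sort(sample.int(m, target_count))
  subset_markers(geno, keep)
}

#' Marker-density tiers
#'
#' Named density presets mirroring chip-to-sequence panel studies
#' (1K/3K/7K low, 10K/30K/100K medium, 500K/1000K high), optionally
#' scaled down proportionally for desk-scale synthetic panels.
#'
#' @param scale multiplicative scale factor applied to every count.
#' @return data frame with `name`, `count`, `tier`.
#' @export
density_tiers <- function(scale = 1) {
  counts <- c(`1K` = 1e3, `3K` = 3e3, `7K` = 7e3, `10K` = 1e4,
              `30K` = 3e4, `100K` = 1e5, `500K` = 5e5, `1000K` = 1e6)
  data.frame(
    name = names(counts),
    count = as.integer(round(counts * scale)),
    tier = rep(c("low", "medium", "high"), times = c(3, 3, 2)),
    stringsAsFactors = FALSE
  )
}
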