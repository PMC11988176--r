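#' Construct a genotype matrix
#'
#' Container for additive-coded genotypes together with per-marker metadata.
#' Genotypes AA, AB and BB are coded 0, 1 and 2 (copies of the B allele);
#' `NA` marks a missing call.
#'
#' @param dosage numeric matrix, individuals in rows, markers in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param markers data frame with one row per marker and columns
#'   `marker_id`, `chrom`, `pos`, `class` (`"SNP"` or `"INDEL"`),
#'   `allele_a`, `allele_b`. Generated automatically when omitted.
#' @param ids character vector of individual identifiers (defaults to the
#'   row names of `dosage`, or `ind1..indn`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `markers` and `ids`.
#' @export
genotype_matrix <- function(dosage, markers = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(ids)) ids <- rownames(dosage)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) {
    stop("length of 'ids' (", length(ids), ") does not match rows of 'dosage' (", n, ")")
  }
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (is.null(markers)) {
    markers <- data.frame(
      marker_id = paste0("m", seq_len(m)),
      chrom = rep(1L, m),
      pos = seq_len(m),
      class = rep("SNP", m),
      allele_a = rep("A", m),
      allele_b = rep("B", m),
      stringsAsFactors = FALSE
    )
  }
  required <- c("marker_id", "chrom", "pos", "class", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("marker table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(markers) != m) {
    stop("marker table has ", nrow(markers), " rows but dosage has ", m, " columns")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    stop("dosages must lie in {0, 1, 2} or be NA")
  }
  rownames(dosage) <- ids
  colnames(dosage) <- markers$marker_id
  structure(list(dosage = dosage, markers = markers, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x", nrow(x$markers), "markers\n")
  cl <- table(x$markers$class)
  cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of individuals / markers
#' @param geno a [genotype_matrix()]
#' @return integer count.
#' @export
n_individuals <- function(geno) length(geno$ids)

#' @rdname n_individuals
#' @export
n_markers <- function(geno) nrow(geno$markers)

#' Subset a genotype matrix by marker index
#' @param geno a [genotype_matrix()]
#' @param j integer or logical index over markers
#' @return a `genotype_matrix` with the selected markers, order preserved.
#' @export
subset_markers <- function(geno, j) {
  genotype_matrix(geno$dosage[, j, drop = FALSE],
                  markers = geno$markers[j, , drop = FALSE],
                  ids = geno$ids)
}

#' Subset a genotype matrix by individual
#' @param geno a [genotype_matrix()]
#' @param i integer/logical index or character ids
#' @return a `genotype_matrix` with the selected individuals.
#' @export
subset_individuals <- function(geno, i) {
  if (is.character(i)) {
    idx <- match(i, geno$ids)
    if (anyNA(idx)) stop("unknown individual id(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  genotype_matrix(geno$dosage[i, , drop = FALSE],
                  markers = geno$markers,
                  ids = geno$ids[i])
}

#' Allele frequency of the counted (B) allele per marker
#'
#' Computed from observed (non-missing) genotypes only.
#' @param geno a [genotype_matrix()]
#' @return numeric vector of frequencies, `NaN` where all calls are missing.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

#' Minor allele frequency per marker
#' @param geno a [genotype_matrix()]
#' @return numeric vector, min(p, 1 - p) of the counted-allele frequency.
#' @export
maf <- function(geno) {
  p <- allele_freq(geno)
  pmin(p, 1 - p)
}
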