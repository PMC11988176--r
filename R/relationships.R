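#' VanRaden genomic relationship matrix
#'
#' G = M M' / (2 * sum p_i (1 - p_i)), where M is the genotype matrix
#' centered by twice the per-marker allele frequency. Monomorphic markers
#' contribute to neither numerator nor denominator. By default p_i is the
#' frequency of the counted (B) allele, which gives E(M) = 0; the literal
#' minor-allele convention is available for sensitivity checks (it only
#' changes the centering, not the denominator).
#'
#' Note that with observed frequencies G is always singular (the centered
#' genotype columns sum to zero, so G annihilates the all-ones vector);
#' either blend it ([blend_G()]) before inverting, or center at external
#' frequencies via `freq`.
#'
#' @param geno a [genotype_matrix()] or a plain dosage matrix.
#' @param freq_convention `"counted"` (default) or `"minor"`.
#' @param impute_missing impute missing dosages to the marker mean before
#'   centering; otherwise missing dosages are an error.
#' @param freq optional externally supplied per-marker allele frequencies
#'   (e.g. base-population frequencies) used for both centering and the
#'   denominator; default: frequencies observed in `geno`.
#' @return symmetric n x n matrix with individual ids as dimnames and
#'   attributes `kind = "G"`, `p` (centering frequencies of the retained
#'   markers), `denom`.
#' @export
compute_G <- function(geno, freq_convention = c("counted", "minor"),
                      impute_missing = FALSE, freq = NULL) {
  freq_convention <- match.arg(freq_convention)
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  ids <- rownames(d)
  if (anyNA(d)) {
    if (!impute_missing) stop("missing dosages; set impute_missing = TRUE or fill them first")
    mns <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mns[idx[, 2]]
  }
  p <- if (is.null(freq)) colMeans(d) / 2 else {
    stopifnot(length(freq) == ncol(d))
    freq
  }
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("zero denominator: all markers are monomorphic")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  p_center <- if (freq_convention == "counted") p else pmin(p, 1 - p)
  M <- sweep(d, 2, 2 * p_center)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(ids, ids)
  attr(G, "kind") <- "G"
  attr(G, "p") <- p_center
  attr(G, "denom") <- denom
  G
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Founders are unrelated and non-inbred; a(i,j) = 0.5 (a(j,s) + a(j,d))
#' and a(i,i) = 1 + 0.5 a(s,d).
#'
#' @param ped a [pedigree()] (parents precede offspring).
#' @return symmetric matrix A with ids as dimnames, `kind = "A"`.
#' @export
compute_A <- function(ped) {
  n <- nrow(ped)
  row_of <- integer(max(ped$id))
  row_of[ped$id] <- seq_len(n)
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    s <- ped$sire[k]; d <- ped$dam[k]
    rs <- if (s > 0) row_of[s] else 0L
    rd <- if (d > 0) row_of[d] else 0L
    if (k > 1) {
      prev <- seq_len(k - 1L)
      as_ <- if (rs > 0) A[prev, rs] else numeric(k - 1L)
      ad_ <- if (rd > 0) A[prev, rd] else numeric(k - 1L)
      val <- 0.5 * (as_ + ad_)
      A[prev, k] <- val
      A[k, prev] <- val
    }
    A[k, k] <- 1 + if (rs > 0 && rd > 0) 0.5 * A[rs, rd] else 0
  }
  dimnames(A) <- list(as.character(ped$id), as.character(ped$id))
  attr(A, "kind") <- "A"
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding: with F_s, F_d the parental
#' inbreeding coefficients, the Mendelian-sampling variance of individual
#' i is d_i = 1 - 0.25 (1 + F_s) - 0.25 (1 + F_d) (parent terms dropped
#' when unknown), and A-inverse accumulates 1/d_i over the (i, sire, dam)
#' triangle. Inbreeding coefficients are taken from the tabular A, so the
#' construction is exact for any (desk-scale) pedigree.
#'
#' @param ped a [pedigree()]
#' @param A optional precomputed [compute_A()] result (avoids recomputing
#'   inbreeding coefficients).
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`) with ids as
#'   dimnames.
#' @export
compute_A_inverse <- function(ped, A = NULL) {
  n <- nrow(ped)
  if (is.null(A)) A <- compute_A(ped)
  Fcoef <- diag(A) - 1
  row_of <- integer(max(ped$id))
  row_of[ped$id] <- seq_len(n)
  tri_i <- vector("list", n); tri_j <- vector("list", n); tri_x <- vector("list", n)
  for (k in seq_len(n)) {
    s <- ped$sire[k]; d <- ped$dam[k]
    rs <- if (s > 0) row_of[s] else 0L
    rd <- if (d > 0) row_of[d] else 0L
    dk <- 1 - (if (rs > 0) 0.25 * (1 + Fcoef[rs]) else 0) -
              (if (rd > 0) 0.25 * (1 + Fcoef[rd]) else 0)
    a <- 1 / dk
    is_ <- k; js_ <- k; vs_ <- a
    if (rs > 0) {
      is_ <- c(is_, rs, k, rs); js_ <- c(js_, k, rs, rs)
      vs_ <- c(vs_, -0.5 * a, -0.5 * a, 0.25 * a)
    }
    if (rd > 0) {
      is_ <- c(is_, rd, k, rd); js_ <- c(js_, k, rd, rd)
      vs_ <- c(vs_, -0.5 * a, -0.5 * a, 0.25 * a)
    }
    if (rs > 0 && rd > 0) {
      is_ <- c(is_, rs, rd); js_ <- c(js_, rd, rs)
      vs_ <- c(vs_, 0.25 * a, 0.25 * a)
    }
    tri_i[[k]] <- is_; tri_j[[k]] <- js_; tri_x[[k]] <- vs_
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                               x = unlist(tri_x), dims = c(n, n),
                               dimnames = list(as.character(ped$id),
                                               as.character(ped$id)))
  Matrix::forceSymmetric(Ainv)
}

#' Blend G with the pedigree relationships of the genotyped individuals
#'
#' G* = (1 - epsilon) G + epsilon A22 guarantees a strictly positive
#' definite genomic matrix, which the single-step inverse requires.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship sub-matrix of the same individuals in
#'   the same order.
#' @param epsilon blending weight in \[0, 1); 0 disables blending.
#' @return blended matrix.
#' @export
blend_G <- function(G, A22, epsilon = 0.05) {
  stopifnot(epsilon >= 0, epsilon < 1, all(dim(G) == dim(A22)))
  if (epsilon == 0) return(G)
  out <- (1 - epsilon) * G + epsilon * as.matrix(A22)
  dimnames(out) <- dimnames(G)
  attr(out, "kind") <- "G"
  out
}

#' Assemble the single-step relationship inverse
#'
#' H-inverse = A-inverse plus, on the genotyped block, the increment
#' G-inverse - A22-inverse. No tau/omega scaling weights are applied.
#'
#' @param A_inv pedigree relationship inverse over all individuals
#'   (dense or sparse).
#' @param A22_inv inverse of the pedigree relationship sub-matrix of the
#'   genotyped individuals.
#' @param G_inv inverse of the (blended) genomic relationship matrix, same
#'   order as `A22_inv`.
#' @param genotyped_index integer positions of the genotyped individuals
#'   within the row order of `A_inv`.
#' @return dense symmetric matrix `H_inv` with `kind = "Hinv"`.
#' @export
assemble_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped_index) {
  H <- as.matrix(A_inv)
  q <- length(genotyped_index)
  stopifnot(all(dim(G_inv) == c(q, q)), all(dim(A22_inv) == c(q, q)))
  if (q > 0) {
    H[genotyped_index, genotyped_index] <-
      H[genotyped_index, genotyped_index] + (as.matrix(G_inv) - as.matrix(A22_inv))
  }
  H <- (H + t(H)) / 2
  attr(H, "kind") <- "Hinv"
  H
}

#' One-call single-step inverse from pedigree and genotypes
#'
#' Computes A and its sparse inverse, extracts A22 for the genotyped
#' individuals, blends G with A22 for invertibility, and assembles
#' H-inverse.
#'
#' @param ped a [pedigree()]
#' @param G genomic relationship matrix with genotyped ids as dimnames.
#' @param epsilon blending weight passed to [blend_G()].
#' @return list with `H_inv`, `A`, `A_inv`, `A22`, `G_blend`,
#'   `genotyped_index`.
#' @export
compute_H_inverse <- function(ped, G, epsilon = 0.05) {
  ids <- as.character(ped$id)
  gids <- rownames(G)
  if (is.null(gids)) stop("G must carry individual ids as dimnames")
  idx <- match(gids, ids)
  if (anyNA(idx)) {
    stop("genotyped individual(s) absent from pedigree: ",
         paste(gids[is.na(idx)], collapse = ", "))
  }
  A <- compute_A(ped)
  A_inv <- compute_A_inverse(ped, A = A)
  A22 <- A[idx, idx, drop = FALSE]
  Gb <- blend_G(G, A22, epsilon = epsilon)
  G_inv <- tryCatch(chol2inv(chol(Gb)), error = function(e) {
    stop("G is singular; increase the blending weight epsilon (currently ",
         epsilon, ")")
  })
  dimnames(G_inv) <- dimnames(Gb)
  A22_inv <- chol2inv(chol(A22))
  H_inv <- assemble_H_inverse(A_inv, A22_inv, G_inv, idx)
  dimnames(H_inv) <- list(ids, ids)
  list(H_inv = H_inv, A = A, A_inv = A_inv, A22 = A22,
       G_blend = Gb, genotyped_index = idx)
}
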