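#' Construct and validate a pedigree
#'
#' A pedigree is an ordered table of individuals with sire and dam links.
#' Ids are dense positive integers, `0` denotes an unknown parent, and
#' parents must be declared before their offspring (so recursive
#' relationship algorithms can run in a single pass).
#'
#' @param id integer ids, ordered parents-first.
#' @param sire,dam integer parent ids (0 = unknown).
#' @param gen optional generation number per individual.
#' @return A data frame of class `pedigree` with columns `id`, `sire`,
#'   `dam` (and `gen` when given).
#' @export
pedigree <- function(id, sire, dam, gen = NULL) {
  id <- as.integer(id); sire <- as.integer(sire); dam <- as.integer(dam)
  n <- length(id)
  if (length(sire) != n || length(dam) != n) stop("id, sire, dam must have equal length")
  if (any(id <= 0)) stop("ids must be positive integers")
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  seen <- logical(max(id))
  for (k in seq_len(n)) {
    for (p in c(sire[k], dam[k])) {
      if (p != 0 && (p > length(seen) || !seen[p])) {
        stop("parent ", p, " of individual ", id[k],
             " is not declared before its offspring")
      }
    }
    if (sire[k] == id[k] || dam[k] == id[k]) {
      stop("individual ", id[k], " is its own parent")
    }
    seen[id[k]] <- TRUE
  }
  out <- data.frame(id = id, sire = sire, dam = dam)
  if (!is.null(gen)) out$gen <- as.integer(gen)
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x), "individuals,",
      sum(x$sire == 0 & x$dam == 0), "founders\n")
  NextMethod()
}
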