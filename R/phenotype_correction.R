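#' Correct phenotypes for categorical fixed effects
#'
#' Fits an ordinary least-squares model of the trait on an intercept plus
#' the named categorical fixed effects (reference-level dummy coding) and
#' returns the corrected phenotype `y_c = residual + intercept`. Keeping
#' the intercept leaves y_c on the grand-mean scale, so the overall mean
#' in downstream prediction models stays meaningful. After correction the
#' mean of `y_c` is equal across the levels of every fitted effect (up to
#' numerical tolerance).
#'
#' By default the model is fitted on the full table (the two-stage
#' scheme: correction precedes cross-validation). `fit_on` restricts the
#' fit to a subset of rows (e.g. a training fold) and applies the fitted
#' correction to all rows; rows carrying a factor level unseen in the fit
#' subset are an error.
#'
#' @param pheno data frame with the trait column and factor columns.
#' @param trait name of the trait column.
#' @param fixed_effects character vector of fixed-effect column names
#'   (empty = no correction, `y_c = y`).
#' @param fit_on optional integer/logical row index used for fitting.
#' @return `pheno` with an added `y_c` column.
#' @export
correct_phenotypes <- function(pheno, trait = "y", fixed_effects = character(),
                               fit_on = NULL) {
  if (!trait %in% names(pheno)) stop("trait column '", trait, "' not found")
  missing_fe <- setdiff(fixed_effects, names(pheno))
  if (length(missing_fe)) {
    stop("fixed-effect column(s) not found: ", paste(missing_fe, collapse = ", "))
  }
  y <- pheno[[trait]]
  if (length(fixed_effects) == 0) {
    pheno$y_c <- y
    return(pheno)
  }
  if (sum(!is.na(y)) < 2) stop("need at least 2 phenotype records")
  fit_rows <- if (is.null(fit_on)) seq_len(nrow(pheno)) else seq_len(nrow(pheno))[fit_on]
  dat <- pheno
  for (fe in fixed_effects) dat[[fe]] <- factor(dat[[fe]])
  # unseen levels in the apply set are an error, not silent NA
  for (fe in fixed_effects) {
    unseen <- setdiff(unique(as.character(dat[[fe]])),
                      unique(as.character(dat[fit_rows, fe])))
    if (length(unseen)) {
      stop("level(s) of '", fe, "' absent from the fitting subset: ",
           paste(unseen, collapse = ", "))
    }
  }
  fml <- stats::reformulate(fixed_effects, response = trait)
  fit_dat <- droplevels(dat[fit_rows, , drop = FALSE])
  X <- model.matrix(fml, fit_dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  fit <- lm(fml, data = fit_dat)
  fitted_all <- predict(fit, newdata = dat)
  pheno$y_c <- y - fitted_all + unname(coef(fit)[1])
  pheno
}
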