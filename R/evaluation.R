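#' Random equal cross-validation folds
#'
#' Individuals are randomly and equally divided into `n_folds` groups
#' (fold sizes differ by at most one; the remainder is spread one per
#' fold). Each round re-randomizes the partition; within a round every
#' individual appears in exactly one validation fold.
#'
#' @param ids character vector of individual ids.
#' @param n_folds number of folds (2..n).
#' @param n_rounds number of independent partitions.
#' @param seed integer seed.
#' @return data frame with columns `round`, `id`, `fold`.
#' @export
make_folds <- function(ids, n_folds, n_rounds = 1, seed = 1L) {
  n <- length(ids)
  if (n_folds > n) stop("more folds (", n_folds, ") than individuals (", n, ")")
  if (n_folds < 2) stop("need at least 2 folds")
  set.seed(seed)
  out <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    perm <- sample(ids)
    fold <- rep(seq_len(n_folds), length.out = n)
    out[[r]] <- data.frame(round = r, id = perm, fold = fold,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted breeding values and the
#' corrected phenotypes of the validation individuals.
#'
#' @param gebv,y_c numeric vectors of equal length (>= 3).
#' @return correlation, or `NA` (with a warning) when either vector is
#'   constant so the correlation is undefined.
#' @export
accuracy <- function(gebv, y_c) {
  stopifnot(length(gebv) == length(y_c))
  if (length(gebv) < 3) stop("need at least 3 validation individuals")
  if (sd(gebv) == 0 || sd(y_c) == 0) {
    warning("undefined accuracy: constant predictor or phenotype")
    return(NA_real_)
  }
  cor(gebv, y_c)
}

#' Dispersion bias of predictions
#'
#' OLS regression slope of corrected phenotype on GEBV; a slope of 1
#' means no over- or under-dispersion of the predictions.
#'
#' @param gebv,y_c numeric vectors of equal length.
#' @return slope, or `NA` (with a warning) for a zero-variance predictor.
#' @export
bias <- function(gebv, y_c) {
  stopifnot(length(gebv) == length(y_c))
  if (var(gebv) == 0) {
    warning("undefined bias: zero-variance predictor")
    return(NA_real_)
  }
  cov(y_c, gebv) / var(gebv)
}

#' Cross-validate a predictor
#'
#' Generic CV loop: for every round and fold the predictor is fitted on
#' the training phenotypes and asked for breeding values of the
#' validation individuals; accuracy and bias are recorded per fit.
#' Training and validation sets are disjoint by construction and
#' asserted per fit.
#'
#' @param y_c named vector of corrected phenotypes.
#' @param predictor function `(y_train, val_ids) -> named gebv` covering
#'   at least the validation ids (see [gblup_predictor()] and friends).
#' @param n_folds,n_rounds,seed cross-validation plan; the default plan
#'   (5 folds x 5 rounds = 25 validation fits) mirrors standard practice
#'   in genomic-prediction studies.
#' @return data frame of class `cv_result` with one row per fit:
#'   `round`, `fold`, `n_val`, `accuracy`, `bias`.
#' @export
run_cv <- function(y_c, predictor, n_folds = 5, n_rounds = 5, seed = 1L) {
  ids <- names(y_c)
  if (is.null(ids)) stop("y_c must be a named vector")
  folds <- make_folds(ids, n_folds, n_rounds, seed = seed)
  res <- vector("list", n_rounds * n_folds)
  k <- 0
  for (r in seq_len(n_rounds)) {
    fr <- folds[folds$round == r, ]
    for (f in seq_len(n_folds)) {
      val_ids <- fr$id[fr$fold == f]
      train_ids <- setdiff(ids, val_ids)
      stopifnot(length(intersect(train_ids, val_ids)) == 0)
      gebv <- predictor(y_c[train_ids], val_ids)
      gv <- gebv[val_ids]
      k <- k + 1
      res[[k]] <- data.frame(round = r, fold = f, n_val = length(val_ids),
                             accuracy = suppressWarnings(accuracy(gv, y_c[val_ids])),
                             bias = suppressWarnings(bias(gv, y_c[val_ids])))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Summarize a cross-validation result
#' @param cv a `cv_result` (or any data frame with accuracy/bias columns).
#' @return one-row data frame with means and SDs over fits.
#' @export
summarize_cv <- function(cv) {
  data.frame(n_fits = nrow(cv),
             accuracy_mean = mean(cv$accuracy, na.rm = TRUE),
             accuracy_sd = sd(cv$accuracy, na.rm = TRUE),
             bias_mean = mean(cv$bias, na.rm = TRUE),
             bias_sd = sd(cv$bias, na.rm = TRUE))
}

#' Predictor factories for cross-validation
#'
#' Each factory captures the data once and returns a
#' `function(y_train, val_ids)` for [run_cv()]. Variance ratios are
#' re-estimated by REML on each training fold unless a fixed `k` is
#' supplied (the "estimate once" shortcut).
#'
#' @param G genomic relationship matrix (blend first if needed).
#' @param k optional fixed variance ratio sigma_e2/sigma_g2.
#' @param blend_epsilon ridge added as `epsilon * I` only if G needs
#'   stabilizing for inversion (0 = off).
#' @return a predictor function.
#' @export
gblup_predictor <- function(G, k = NULL, blend_epsilon = 0) {
  if (blend_epsilon > 0) G <- G + diag(blend_epsilon, nrow(G))
  G_inv <- chol2inv(chol(G))
  dimnames(G_inv) <- dimnames(G)
  eg <- NULL
  function(y_train, val_ids) {
    kk <- k
    if (is.null(kk)) {
      idx <- match(names(y_train), rownames(G))
      vc <- estimate_reml(y_train, G[idx, idx])
      kk <- vc$sigma_e2 / max(vc$sigma_g2, 1e-8 * var(y_train))
    }
    solve_gblup(y_train, G_inv = G_inv, k = kk)$gebv
  }
}

#' @rdname gblup_predictor
#' @param H_inv assembled single-step inverse over the whole pedigree.
#' @param G_reml genomic relationship of the genotyped individuals used
#'   to estimate the variance ratio on each training fold (its genotyped
#'   subset); required when `k` is `NULL`.
#' @param y_extra named phenotypes of individuals that always stay in
#'   training (typically the phenotyped-but-ungenotyped relatives, the
#'   information source that distinguishes single-step from plain
#'   GBLUP). They must never appear among the cross-validated ids.
#' @export
ssgblup_predictor <- function(H_inv, G_reml = NULL, k = NULL,
                              y_extra = NULL) {
  H_inv <- as.matrix(H_inv)
  function(y_train, val_ids) {
    if (!is.null(y_extra)) {
      overlap <- intersect(names(y_extra), val_ids)
      if (length(overlap)) stop("extra training individuals leak into validation")
      y_train <- c(y_train, y_extra)
    }
    kk <- k
    if (is.null(kk)) {
      if (is.null(G_reml)) stop("supply G_reml or a fixed k for ssGBLUP CV")
      tr <- intersect(names(y_train), rownames(G_reml))
      vc <- estimate_reml(y_train[tr], G_reml[tr, tr])
      kk <- vc$sigma_e2 / max(vc$sigma_g2, 1e-8 * var(y_train))
    }
    solve_ssgblup(y_train, H_inv, k = kk)$gebv
  }
}

#' @rdname gblup_predictor
#' @param geno genotype matrix covering all individuals to predict.
#' @param cfg an [mcmc_config()] for the Bayesian models; its seed is
#'   advanced deterministically per fit.
#' @export
bayes_predictor <- function(geno, cfg) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  fit_counter <- 0L
  function(y_train, val_ids) {
    fit_counter <<- fit_counter + 1L
    cfg_fit <- cfg
    if (!is.null(cfg$seed)) cfg_fit$seed <- cfg$seed + 131L * fit_counter
    tr <- match(names(y_train), rownames(d))
    ps <- run_mcmc(d[tr, , drop = FALSE], y_train, cfg_fit)
    gebv_from_effects(d, ps)$gebv
  }
}

#' @rdname gblup_predictor
#' @param k_marker ridge penalty for [solve_snp_blup()]; when `NULL` it
#'   is derived per fold from REML as `k * 2 sum p(1-p)`.
#' @export
snp_blup_predictor <- function(geno, k_marker = NULL) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  function(y_train, val_ids) {
    km <- k_marker
    if (is.null(km)) {
      tr <- match(names(y_train), rownames(d))
      Gtr <- compute_G(d[tr, , drop = FALSE])
      vc <- estimate_reml(y_train, Gtr)
      km <- vc$sigma_e2 / max(vc$sigma_g2, 1e-8 * var(y_train)) * attr(Gtr, "denom")
    }
    solve_snp_blup(d, y_train, km)$gebv
  }
}

#' @rdname gblup_predictor
#' @param g_true named true genetic values (simulation ground truth);
#'   gives the accuracy ceiling sqrt(h2).
#' @export
oracle_predictor <- function(g_true) {
  function(y_train, val_ids) g_true
}

#' Run a factorial model x panel x fold-count experiment grid
#'
#' Executes cross-validation for every combination of model, marker
#' panel and fold count, with per-cell seeds derived reproducibly from
#' the master seed. A failing cell is recorded (message kept, metrics
#' NA) and the grid continues.
#'
#' @param data list with at least `geno` (a [genotype_matrix()] of the
#'   genotyped cohort) and `y_c` (named corrected phenotypes); optional
#'   `ped` and `g_true` enable the `ssGBLUP` and `oracle` models.
#' @param models character subset of `c("GBLUP", "ssGBLUP", "SNPBLUP",
#'   "BayesA", "BayesB", "BayesC", "BL", "BayesR", "oracle")`.
#' @param panels named list of [genotype_matrix()] panels (default: the
#'   full panel, named `"all"`).
#' @param fold_counts integer vector of fold counts (2..10 in the full
#'   design).
#' @param n_rounds CV rounds per cell.
#' @param seed master seed.
#' @param mcmc an [mcmc_config()] template for the Bayesian models (its
#'   `model` field is overridden per cell).
#' @param blend_epsilon blending weight for the single-step G.
#' @return long-format data frame of class `cv_grid`: one row per fit
#'   with `model`, `panel`, `n_markers`, `folds`, `round`, `fold`,
#'   `accuracy`, `bias`, plus an `errors` attribute listing failed cells.
#' @export
run_experiment_grid <- function(data, models = "GBLUP", panels = NULL,
                                fold_counts = 5, n_rounds = 5, seed = 1L,
                                mcmc = mcmc_config("BayesA", n_iter = 3000,
                                                   burn_in = 500),
                                blend_epsilon = 0.05) {
  stopifnot(!is.null(data$geno), !is.null(data$y_c), !is.null(names(data$y_c)))
  if (is.null(panels)) panels <- list(all = data$geno)
  cells <- expand.grid(model = models, panel = names(panels),
                       folds = fold_counts, stringsAsFactors = FALSE)
  rows <- list()
  errors <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cell_seed <- (abs(seed) + 7919L * ci) %% 2147483647L
    pg <- panels[[cell$panel]]
    res <- tryCatch({
      pred <- build_predictor(cell$model, pg, data, mcmc, blend_epsilon,
                              cell_seed)
      y_use <- pred$y
      cv <- run_cv(y_use, pred$fun, n_folds = cell$folds,
                   n_rounds = n_rounds, seed = cell_seed)
      cbind(model = cell$model, panel = cell$panel,
            n_markers = n_markers(pg), folds = cell$folds, cv)
    }, error = function(e) {
      errors[[length(errors) + 1]] <<- paste0(cell$model, "/", cell$panel,
                                              "/", cell$folds, ": ",
                                              conditionMessage(e))
      cbind(model = cell$model, panel = cell$panel, n_markers = n_markers(pg),
            folds = cell$folds,
            data.frame(round = NA_integer_, fold = NA_integer_,
                       n_val = NA_integer_, accuracy = NA_real_,
                       bias = NA_real_))
    })
    rows[[ci]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "errors") <- unlist(errors)
  class(out) <- c("cv_grid", "data.frame")
  out
}

# Map a model name to a predictor over a given panel.
build_predictor <- function(model, panel_geno, data, mcmc, blend_epsilon,
                            seed) {
  y_c <- data$y_c
  gt_ids <- intersect(names(y_c), panel_geno$ids)
  y_gt <- y_c[gt_ids]
  if (model == "GBLUP") {
    G <- compute_G(subset_individuals(panel_geno, gt_ids))
    list(y = y_gt, fun = gblup_predictor(G, blend_epsilon = 1e-6))
  } else if (model == "SNPBLUP") {
    list(y = y_gt, fun = snp_blup_predictor(subset_individuals(panel_geno, gt_ids)))
  } else if (model == "ssGBLUP") {
    if (is.null(data$ped)) stop("ssGBLUP requires a pedigree in data$ped")
    G <- compute_G(panel_geno)
    hh <- compute_H_inverse(data$ped, G, epsilon = blend_epsilon)
    # ungenotyped phenotyped relatives stay in training; validation runs
    # on the genotyped ids so accuracies are comparable across models
    y_extra <- y_c[setdiff(names(y_c), gt_ids)]
    if (!length(y_extra)) y_extra <- NULL
    list(y = y_gt, fun = ssgblup_predictor(hh$H_inv, G_reml = hh$G_blend,
                                           y_extra = y_extra))
  } else if (model == "oracle") {
    if (is.null(data$g_true)) stop("oracle model requires data$g_true")
    list(y = y_gt, fun = oracle_predictor(data$g_true))
  } else if (model %in% c("BayesA", "BayesB", "BayesC", "BL", "BayesR")) {
    cfg <- mcmc
    cfg$model <- model
    cfg$seed <- seed
    list(y = y_gt, fun = bayes_predictor(subset_individuals(panel_geno, gt_ids), cfg))
  } else {
    stop("unknown model: ", model)
  }
}

#' Summarize an experiment grid per cell
#' @param grid a `cv_grid` from [run_experiment_grid()].
#' @return data frame with mean/SD accuracy and bias per
#'   (model, panel, folds) cell.
#' @export
summarize_grid <- function(grid) {
  key <- interaction(grid$model, grid$panel, grid$folds, drop = TRUE)
  parts <- split(grid, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    cbind(g[1, c("model", "panel", "n_markers", "folds")], summarize_cv(g))
  }))
  rownames(out) <- NULL
  out[order(out$model, out$panel, out$folds), ]
}

#' Plot cross-validated accuracy
#'
#' Mean accuracy per cell against fold count or panel, one line per
#' model. Requires ggplot2.
#'
#' @param grid a `cv_grid`.
#' @param x `"folds"` or `"panel"`.
#' @return a ggplot object.
#' @export
plot_cv_results <- function(grid, x = c("folds", "panel")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  x <- match.arg(x)
  s <- summarize_grid(grid)
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[x]], y = .data$accuracy_mean,
                                  colour = .data$model,
                                  group = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "mean CV accuracy", x = x) +
    ggplot2::theme_minimal()
}
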