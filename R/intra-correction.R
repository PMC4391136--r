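#' Gene-property tables
#'
#' A KO-by-property numeric matrix of gene-specific properties (for
#' example mean GC content, gene length standard deviation, species
#' prevalence, short-read annotation recall/precision) used as covariates
#' of the intra-sample bias model. Missing values are allowed on input and
#' are imputed with training-set medians during model fitting.
#'
#' @param values numeric matrix, KOs as rows, properties as columns, with
#'   dimnames.
#' @param standardized whether each property already has mean 0 and unit
#'   variance (the fitting code standardizes internally either way, from
#'   training data only).
#' @return an object of class `gene_property_table`.
#' @export
gene_property_table <- function(values, standardized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have KO rownames and property colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate KO identifier in property table")
  structure(list(values = values, standardized = isTRUE(standardized)),
            class = "gene_property_table")
}

#' @export
print.gene_property_table <- function(x, ...) {
  cat(sprintf("gene_property_table: %d KOs x %d properties%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

property_values <- function(properties) {
  if (inherits(properties, "gene_property_table")) properties$values
  else if (is.matrix(properties)) properties
  else stop("'properties' must be a gene_property_table or matrix")
}

#' Marker fold-change responses within one sample
#'
#' The response modeled by the intra-sample correction: the fold-change
#' between each marker's abundance and the mean abundance of all markers in
#' the sample. Responses always average to 1 over the marker set.
#'
#' @param sample_abundances named per-KO abundance vector for one sample;
#'   markers absent from it count as zero.
#' @param markers a [marker_set()].
#' @return named numeric vector of per-marker fold-changes.
#' @export
marker_response <- function(sample_abundances, markers) {
  stopifnot(inherits(markers, "marker_set"))
  if (is.null(names(sample_abundances)))
    stop("'sample_abundances' must be named by KO")
  mk <- markers$ko_ids
  a <- stats::setNames(rep(0, length(mk)), mk)
  found <- intersect(mk, names(sample_abundances))
  a[found] <- sample_abundances[found]
  m <- mean(a)
  if (m <= 0) stop("mean marker abundance is not positive")
  a / m
}

# shared elastic-net nested-CV engine.
# y: response per observation; X: raw covariates per observation;
# group: grouping factor (observations of one marker share a group so
# cross-validation never splits a marker across train/test).
fit_enet_cv <- function(y, X, group, folds, seed, alpha, scope) {
  n_groups <- length(unique(group))
  if (folds < 2) stop("'folds' must be >= 2")
  if (n_groups < 2 * folds)
    stop("need at least ", 2 * folds, " markers for ", folds,
         "-fold cross-validation, got ", n_groups)
  if (stats::var(y) < 1e-12) {
    warning("zero-variance response: returning a null model")
    w <- stats::setNames(rep(0, ncol(X)), colnames(X))
    return(new_intra_model(
      intercept = mean(y), weights = w,
      std_mean = stats::setNames(rep(0, ncol(X)), colnames(X)),
      std_sd = stats::setNames(rep(1, ncol(X)), colnames(X)),
      impute = stats::setNames(rep(0, ncol(X)), colnames(X)),
      lambda = NA_real_, alpha = alpha, heldout_r2 = 0,
      fold_r2 = numeric(0), scope = scope, n_obs = length(y)))
  }
  set.seed(seed)
  glevels <- unique(group)
  gfold <- stats::setNames(sample(rep(seq_len(folds),
                                      length.out = length(glevels))),
                           glevels)
  foldid <- gfold[as.character(group)]
  fold_r2 <- rep(NA_real_, folds)
  lambdas <- rep(NA_real_, folds)
  gammas <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    tr <- foldid != k
    prep <- prep_covariates(X[tr, , drop = FALSE])
    Ztr <- prep$Z
    Zte <- apply_prep(X[!tr, , drop = FALSE], prep)
    inner_id <- make_inner_foldid(group[tr], folds)
    # do.call embeds evaluated arguments in the recorded call; the
    # relaxed path re-evaluates that call internally
    cvfit <- do.call(glmnet::cv.glmnet,
                     list(x = Ztr, y = y[tr], alpha = alpha,
                          foldid = inner_id, standardize = FALSE,
                          relax = TRUE))
    lambdas[k] <- cvfit$lambda.min
    gammas[k] <- cvfit$relaxed$gamma.min
    yhat <- as.numeric(stats::predict(cvfit, newx = Zte,
                                      s = "lambda.min",
                                      gamma = "gamma.min"))
    yte <- y[!tr]
    # baseline: intercept-only model learned on the training fold, so
    # everything the held-out R^2 compares against is train-derived
    ss_tot <- sum((yte - mean(y[tr]))^2)
    if (ss_tot > 0)
      fold_r2[k] <- 1 - sum((yte - yhat)^2) / ss_tot
  }
  lambda_final <- stats::median(lambdas, na.rm = TRUE)
  gamma_final <- stats::median(gammas, na.rm = TRUE)
  prep <- prep_covariates(X)
  fit <- do.call(glmnet::glmnet,
                 list(x = prep$Z, y = y, alpha = alpha,
                      standardize = FALSE, relax = TRUE))
  cf <- as.numeric(stats::coef(fit, s = lambda_final,
                               gamma = gamma_final))
  new_intra_model(
    intercept = cf[1],
    weights = stats::setNames(cf[-1], colnames(X)),
    std_mean = prep$mean, std_sd = prep$sd, impute = prep$impute,
    lambda = lambda_final, alpha = alpha,
    heldout_r2 = mean(fold_r2, na.rm = TRUE),
    fold_r2 = fold_r2, scope = scope, n_obs = length(y))
}

# impute (median) + standardize from the rows given; returns the
# transformed matrix and the parameters needed to transform new data
prep_covariates <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1  # constant property: z-score 0 everywhere
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  list(Z = Z, mean = mu, sd = sd, impute = med)
}

apply_prep <- function(X, prep) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- prep$impute[j]
  sweep(sweep(X, 2, prep$mean, "-"), 2, prep$sd, "/")
}

# inner-CV fold ids at the group (marker) level
make_inner_foldid <- function(group, folds) {
  glevels <- unique(group)
  nf <- max(2L, min(folds, length(glevels)))
  gf <- stats::setNames(sample(rep(seq_len(nf), length.out = length(glevels))),
                        glevels)
  unname(gf[as.character(group)])
}

new_intra_model <- function(intercept, weights, std_mean, std_sd, impute,
                            lambda, alpha, heldout_r2, fold_r2, scope,
                            n_obs) {
  structure(list(intercept = intercept, weights = weights,
                 std_mean = std_mean, std_sd = std_sd, impute = impute,
                 lambda = lambda, alpha = alpha, heldout_r2 = heldout_r2,
                 fold_r2 = fold_r2, scope = scope, n_obs = n_obs),
            class = "intra_model")
}

#' Fit the intra-sample bias model for one sample
#'
#' Learns an elastic-net regularized linear model predicting the marker
#' fold-changes of one sample (see [marker_response()]) from standardized
#' gene-specific properties, under a strict nested cross-validation scheme:
#' outer folds estimate the held-out fraction of variance explained
#' (`heldout_r2`, averaged over folds, against an intercept-only baseline
#' learned on the training fold), the penalty is chosen within each outer
#' training set by inner cross-validation, and the reported model is refit
#' on all markers at the median selected penalty. The relaxed elastic net
#' is used throughout (the debiasing blend is selected by the same inner
#' cross-validation), which counters the coefficient shrinkage a plain
#' penalized fit would impose at this sample size. Covariate imputation
#' (property medians) and standardization are computed from training data
#' only within each fold, and from all markers for the final model.
#'
#' @param responses named per-marker fold-change vector.
#' @param properties a [gene_property_table()] (or matrix) covering the
#'   markers in `responses`.
#' @param folds number of outer (and inner) cross-validation folds,
#'   default 5.
#' @param seed integer seed controlling fold assignment.
#' @param alpha elastic-net mixing parameter in (0, 1]; 0.5 by default,
#'   1 gives the pure L1 (lasso) model.
#' @return an object of class `intra_model`.
#' @export
fit_intra_model <- function(responses, properties, folds = 5, seed = 1,
                            alpha = 0.5) {
  P <- property_values(properties)
  if (is.null(names(responses)))
    stop("'responses' must be named by marker KO")
  miss <- setdiff(names(responses), rownames(P))
  if (length(miss))
    stop("no properties for marker(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- P[names(responses), , drop = FALSE]
  fit_enet_cv(as.numeric(responses), X, group = names(responses),
              folds = folds, seed = seed, alpha = alpha,
              scope = "per_sample")
}

#' Fit one generic bias model pooled across samples
#'
#' Pools per-sample (marker, fold-change) observations from all samples of
#' an inter-corrected table and fits a single elastic-net model as in
#' [fit_intra_model()]. Cross-validation folds are assigned at the marker
#' level, so no marker contributes to both training and test sets. The
#' resulting model can be applied unchanged to new samples.
#'
#' @param table an [abundance_table()] at stage `"inter_corrected"`.
#' @param markers a [marker_set()].
#' @param properties a [gene_property_table()] covering the markers.
#' @inheritParams fit_intra_model
#' @return an `intra_model` with `scope = "generic"`.
#' @export
fit_generic_model <- function(table, markers, properties, folds = 5,
                              seed = 1, alpha = 0.5) {
  stopifnot(inherits(table, "abundance_table"))
  if (ncol(table$values) < 2)
    stop("need at least 2 samples to fit a generic model")
  P <- property_values(properties)
  ys <- list(); gs <- list()
  for (s in seq_len(ncol(table$values))) {
    r <- marker_response(table$values[, s], markers)
    ys[[s]] <- as.numeric(r)
    gs[[s]] <- names(r)
  }
  y <- unlist(ys)
  group <- unlist(gs)
  miss <- setdiff(unique(group), rownames(P))
  if (length(miss))
    stop("no properties for marker(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- P[group, , drop = FALSE]
  fit_enet_cv(y, X, group = group, folds = folds, seed = seed,
              alpha = alpha, scope = "generic")
}

#' @export
print.intra_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf(paste0("intra_model [%s]: %d/%d nonzero property weights, ",
                     "held-out R^2 = %.3f\n"),
              x$scope, nz, length(x$weights), x$heldout_r2))
  invisible(x)
}

#' @export
summary.intra_model <- function(object, ...) {
  w <- object$weights[object$weights != 0]
  cat(sprintf("Elastic-net intra-sample bias model (%s scope)\n",
              object$scope))
  cat(sprintf("  observations: %d   alpha: %.2f   lambda: %.4g\n",
              object$n_obs, object$alpha, object$lambda))
  cat(sprintf("  held-out R^2: %.3f (per fold: %s)\n", object$heldout_r2,
              paste(sprintf("%.3f", object$fold_r2), collapse = ", ")))
  cat(sprintf("  intercept: %.4f\n", object$intercept))
  if (length(w)) {
    cat("  nonzero weights (standardized covariates):\n")
    for (p in names(sort(abs(w), decreasing = TRUE)))
      cat(sprintf("    %-24s %+.4f\n", p, w[p]))
  } else cat("  all property weights are zero\n")
  invisible(object)
}

#' @export
coef.intra_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Predicted fold-changes for a set of genes
#'
#' Applies the fitted bias model to a property table: properties are
#' imputed and standardized with the parameters captured at training, and
#' the linear predictor is clamped below at `clamp` to prevent sign flips
#' or explosion for genes far outside the marker property range.
#'
#' @param object an `intra_model`.
#' @param properties a [gene_property_table()] (or matrix).
#' @param clamp lower clamp for predicted fold-changes (default 0.01).
#' @param ... unused.
#' @return named vector of predicted fold-changes, one per KO in
#'   `properties`.
#' @export
predict.intra_model <- function(object, properties, clamp = 0.01, ...) {
  X <- property_values(properties)
  miss <- setdiff(names(object$weights), colnames(X))
  if (length(miss))
    stop("property table lacks model properties: ",
         paste(miss, collapse = ", "))
  X <- X[, names(object$weights), drop = FALSE]
  Z <- apply_prep(X, list(impute = object$impute, mean = object$std_mean,
                          sd = object$std_sd))
  p <- object$intercept + as.numeric(Z %*% object$weights)
  n_clamped <- sum(p < clamp)
  if (n_clamped > 0)
    log_msg("info", n_clamped, " predicted fold-change(s) clamped at ",
            clamp)
  stats::setNames(pmax(p, clamp), rownames(X))
}

#' Intra-MUSiCC: correct gene-specific abundance bias
#'
#' Divides every gene's inter-corrected abundance by the fold-change the
#' marker-trained bias model predicts from that gene's properties. A gene
#' whose bias is perfectly predicted is mapped back to its expected
#' average copy number; zeros remain zero. KOs lacking a row in the
#' property table pass through uncorrected (a log line reports how many).
#'
#' @param table an [abundance_table()] at stage `"inter_corrected"`.
#' @param model an `intra_model`.
#' @param properties a [gene_property_table()].
#' @param clamp lower clamp for predicted fold-changes (default 0.01).
#' @return an [abundance_table()] at stage `"intra_corrected"`.
#' @export
apply_intra_correction <- function(table, model, properties, clamp = 0.01) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(model, "intra_model"))
  P <- property_values(properties)
  v <- table$values
  covered <- intersect(rownames(v), rownames(P))
  n_uncov <- nrow(v) - length(covered)
  if (n_uncov > 0)
    log_msg("info", n_uncov, " KO(s) without properties pass through",
            " uncorrected")
  if (length(covered)) {
    p <- predict(model, P[covered, , drop = FALSE], clamp = clamp)
    v[covered, ] <- v[covered, , drop = FALSE] / p
  }
  abundance_table(v, stage = "intra_corrected")
}

#' Serialize an intra-sample bias model to flat key-value text
#'
#' The format is a two-column tab-delimited file (`key<TAB>value`) so
#' models are diffable and portable; [read_intra_model()] reads it back.
#'
#' @param model an `intra_model`.
#' @param path output file path.
#' @export
write_intra_model <- function(model, path) {
  stopifnot(inherits(model, "intra_model"))
  kv <- c(scope = model$scope, alpha = model$alpha, lambda = model$lambda,
          heldout_r2 = model$heldout_r2, intercept = model$intercept,
          n_obs = model$n_obs)
  lines <- paste(names(kv), kv, sep = "\t")
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  for (p in names(model$weights))
    lines <- c(lines,
               paste0("weight.", p, "\t", fmt(model$weights[p])),
               paste0("std_mean.", p, "\t", fmt(model$std_mean[p])),
               paste0("std_sd.", p, "\t", fmt(model$std_sd[p])),
               paste0("impute.", p, "\t", fmt(model$impute[p])))
  writeLines(lines, path)
  invisible(NULL)
}

#' @rdname write_intra_model
#' @export
read_intra_model <- function(path) {
  lines <- read_text_lines(path)
  parts <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, character(1), 1)
  vals <- vapply(parts, `[`, character(1), 2)
  kv <- stats::setNames(vals, keys)
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    stats::setNames(as.numeric(vals[sel]),
                    sub(paste0("^", prefix), "", keys[sel]))
  }
  new_intra_model(
    intercept = as.numeric(kv[["intercept"]]),
    weights = pick("weight."), std_mean = pick("std_mean."),
    std_sd = pick("std_sd."), impute = pick("impute."),
    lambda = as.numeric(kv[["lambda"]]),
    alpha = as.numeric(kv[["alpha"]]),
    heldout_r2 = as.numeric(kv[["heldout_r2"]]),
    fold_r2 = numeric(0), scope = kv[["scope"]],
    n_obs = as.integer(kv[["n_obs"]]))
}
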