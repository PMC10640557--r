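#' Flatten a comodulogram tensor into a segment-level feature table
#'
#' Each channel-segment becomes one sample: a 256-length flattened
#' comodulogram (fixed column-major raster of the 16 x 16 grid) with the
#' channel's SOZ/NSOZ label. Rows are ordered channel-major, chronological
#' within channel; the metadata keeps both identifiers so the
#' cross-validation can split by segment time.
#'
#' @param tensor A `comodulogram_tensor`.
#' @return A `pac_features` object: list with `X` (samples x 256 matrix) and
#'   `meta` (tibble: `channel`, `label`, `segment`, `y` with SOZ = 1).
#' @export
as_feature_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "comodulogram_tensor"))
  d <- dim(tensor$values)
  idx <- tidyr::expand_grid(ch = seq_len(d[1]), seg = seq_len(d[2]))
  X <- t(vapply(seq_len(nrow(idx)), function(i) {
    as.vector(tensor$values[idx$ch[i], idx$seg[i], , ])
  }, numeric(d[3] * d[4])))
  meta <- tibble::tibble(
    channel = tensor$channels$channel[idx$ch],
    label = tensor$channels$label[idx$ch],
    segment = idx$seg,
    y = as.numeric(tensor$channels$label[idx$ch] == "SOZ")
  )
  structure(list(X = X, meta = meta), class = "pac_features")
}

#' @export
print.pac_features <- function(x, ...) {
  cat("<pac_features> ", nrow(x$X), " segments x ", ncol(x$X), " features (",
      sum(x$meta$y == 1), " SOZ / ", sum(x$meta$y == 0), " NSOZ)\n", sep = "")
  invisible(x)
}

#' Default hyperparameter grids for the five classifiers
#'
#' Boosted-tree and CNN-loss grids follow the published tuning ranges
#' (`num_leaves` 35-65 by 5, `max_depth` {4,6,8,10}, `learning_rate`
#' {0.01,0.05,0.1,0.15}, `min_data_in_leaf` {20,40,60,100}; focal
#' `alpha`/class-balance `beta` in {0.75,0.9,0.99,0.999,0.9999} and `gamma`
#' in {0.5,1,2,5}). SVM grids are the conventional log-spaced ranges
#' (overridable in [run_nested_cv()]); `gamma = NA` means the scale
#' heuristic `1 / (n_features * mean variance)`.
#'
#' @param kind One of `"svm_linear"`, `"svm_rbf"`, `"gbm"`, `"cnn_focal"`,
#'   `"cnn_cbfocal"`.
#' @return Tibble with one row per hyperparameter configuration.
#' @export
default_grid <- function(kind = c("svm_linear", "svm_rbf", "gbm",
                                  "cnn_focal", "cnn_cbfocal")) {
  kind <- match.arg(kind)
  switch(kind,
    svm_linear = tibble::tibble(C = c(0.1, 1, 10, 100)),
    svm_rbf = tidyr::expand_grid(C = c(0.1, 1, 10, 100),
                                 gamma = c(1e-3, 1e-2, 1e-1, 1, NA)),
    gbm = tidyr::expand_grid(num_leaves = seq(35, 65, by = 5),
                             max_depth = c(4, 6, 8, 10),
                             learning_rate = c(0.01, 0.05, 0.1, 0.15),
                             min_data_in_leaf = c(20, 40, 60, 100)),
    cnn_focal = tidyr::expand_grid(alpha = c(0.75, 0.9, 0.99, 0.999, 0.9999),
                                   gamma = c(0.5, 1, 2, 5)),
    cnn_cbfocal = tidyr::expand_grid(beta = c(0.75, 0.9, 0.99, 0.999, 0.9999),
                                     gamma = c(0.5, 1, 2, 5))
  )
}

classifier_kinds <- function() {
  c("svm_linear", "svm_rbf", "gbm", "cnn_focal", "cnn_cbfocal")
}

#' Fit one of the five SOZ classifiers
#'
#' Uniform training entry point used by [run_nested_cv()]: every kind
#' consumes the same (samples x 256) feature matrix and 0/1 labels and
#' returns an object whose [predict_prob()] yields segment-level SOZ
#' probabilities.
#'
#' Imbalance handling per kind: the SVMs scale the misclassification penalty
#' by the inverse-frequency [class_weights()] (`C_i = C * omega_i`); the
#' boosted trees weight positives by `omega_SOZ / omega_NSOZ`; the CNNs use
#' the focal or class-balanced focal loss. SVM features are standardized
#' with training-split statistics; trees and CNN consume raw features.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Labels in `{0, 1}` (1 = SOZ). Both classes must be present.
#' @param kind Classifier kind, see [default_grid()].
#' @param params One-row data frame / named list of hyperparameters for this
#'   kind (a row of its grid). `NULL` uses the first grid row.
#' @param validation Optional `list(X =, y =)`; used by the CNNs for early
#'   stopping and ignored by the other kinds.
#' @param platt For SVMs: also fit a Platt probability model (used for
#'   calibrated per-electrode reporting; ranking, hence AUC, is unchanged).
#' @param seed Seed controlling initialization/shuffling.
#' @param epochs,batch_size CNN training-loop controls.
#' @return Object of class `soz_model` (subclass per kind).
#' @export
fit_soz_classifier <- function(X, y, kind = classifier_kinds(), params = NULL,
                               validation = NULL, platt = FALSE, seed = 1L,
                               epochs = 100, batch_size = 128) {
  kind <- match.arg(kind)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  if (is.null(params)) params <- default_grid(kind)[1, ]
  params <- as.list(params)
  model <- switch(kind,
    svm_linear = fit_svm(X, y, "linear", params, platt, seed),
    svm_rbf = fit_svm(X, y, "radial", params, platt, seed),
    gbm = fit_gbm(X, y, params, seed),
    cnn_focal = fit_cnn_kind(X, y, "focal", params, validation, seed,
                             epochs, batch_size),
    cnn_cbfocal = fit_cnn_kind(X, y, "cb_focal", params, validation, seed,
                               epochs, batch_size)
  )
  model$kind <- kind
  class(model) <- c(class(model), "soz_model")
  model
}

fit_svm <- function(X, y, kernel, params, platt, seed) {
  centre <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, centre, scl)
  cw <- class_weights(table(factor(y, levels = c(0, 1))))
  gamma <- params$gamma
  if (kernel == "radial" && (is.null(gamma) || is.na(gamma))) {
    gamma <- 1 / (ncol(X) * mean(apply(Xs, 2, stats::var)))
  }
  set.seed(seed)
  fit <- e1071::svm(Xs, factor(y, levels = c(0, 1)), kernel = kernel,
                    cost = params$C,
                    gamma = if (kernel == "radial") gamma else 1 / ncol(X),
                    class.weights = stats::setNames(as.numeric(cw),
                                                    c("0", "1")),
                    probability = platt, scale = FALSE)
  structure(list(fit = fit, centre = centre, scl = scl, platt = platt),
            class = "soz_svm")
}

fit_gbm <- function(X, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  spw <- sum(y == 0) / sum(y == 1)    # = omega_SOZ / omega_NSOZ
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", tree_method = "hist",
                  grow_policy = "lossguide",
                  max_leaves = params$num_leaves %||% 35,
                  max_depth = params$max_depth %||% 6,
                  eta = params$learning_rate %||% 0.1,
                  # leaf-size floor is declared in samples; xgboost counts
                  # hessian mass, ~0.25/sample for logistic loss
                  min_child_weight = 0.25 * (params$min_data_in_leaf %||% 20),
                  scale_pos_weight = spw, nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds %||% 100, verbose = 0
  )
  structure(list(fit = fit), class = "soz_gbm")
}

fit_cnn_kind <- function(X, y, loss, params, validation, seed, epochs,
                         batch_size) {
  model <- build_cnn(loss = loss,
                     alpha = params$alpha %||% 0.75,
                     gamma = params$gamma %||% 2,
                     beta = params$beta %||% 0.999,
                     seed = seed)
  model <- cnn_fit(model, X, y, epochs = epochs, batch_size = batch_size,
                   validation = validation)
  model
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Segment-level SOZ probabilities from a fitted classifier
#'
#' The uniform prediction contract: every classifier kind returns a
#' probability-scaled score per row of `X`, monotone in its native decision
#' score, so AUC and per-electrode aggregation need no model-specific
#' branches. SVMs fitted with `platt = TRUE` return Platt-calibrated
#' probabilities; otherwise the decision value is mapped through the
#' logistic function (same ranking).
#'
#' @param model A `soz_model`.
#' @param X Feature matrix, samples x 256.
#' @return Numeric vector in (0, 1).
#' @export
predict_prob <- function(model, X) {
  UseMethod("predict_prob")
}

#' @export
predict_prob.soz_svm <- function(model, X) {
  Xs <- scale(X, model$centre, model$scl)
  pred <- stats::predict(model$fit, Xs, decision.values = TRUE,
                         probability = model$platt)
  if (model$platt) {
    pr <- attr(pred, "probabilities")
    return(as.numeric(pr[, "1"]))
  }
  dv <- as.numeric(attr(pred, "decision.values"))
  # decision values are oriented toward the first factor level ("0" = NSOZ)
  if (colnames(attr(pred, "decision.values"))[1] == "0/1") dv <- -dv
  stats::plogis(dv)
}

#' @export
predict_prob.soz_gbm <- function(model, X) {
  as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
}

#' @export
predict_prob.soz_cnn <- function(model, X) {
  stats::predict(model, X)
}
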