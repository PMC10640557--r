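#' Plan a chronological nested cross-validation
#'
#' The segment timeline is cut into `K + 1` equal chronological folds,
#' identically for every electrode (segment *t* of every channel lands in
#' the same fold, so a time period can never sit in train and test via
#' different channels). Split *k* trains on folds `1..k` and tests on fold
#' `k + 1`; within each training set the first 80% of segments form the
#' training subset and the last 20% the validation set for hyperparameter
#' selection. With 180 segments and `K = 5`, each fold has 30 segments per
#' electrode and split *k* has `N_train = k*30*N_electrode*0.8`,
#' `N_validation = k*30*N_electrode*0.2`, `N_test = 30*N_electrode`.
#'
#' @param n_segments_per_electrode Total chronological segments per
#'   electrode (must be divisible by `K + 1`).
#' @param n_electrodes Number of electrodes.
#' @param K Number of splits (default 5).
#' @return A `split_plan`: list with `K`, `fold_size`, `n_electrodes`, and a
#'   `splits` tibble holding, per split, the segment-index vectors
#'   `train_segments`, `subset_segments`, `validation_segments`,
#'   `test_segments` (list columns) and the sample counts `n_train`,
#'   `n_validation`, `n_test`.
#' @examples
#' plan_splits(180, n_electrodes = 10, K = 5)$splits$n_train
#' @export
plan_splits <- function(n_segments_per_electrode, n_electrodes, K = 5) {
  if (n_segments_per_electrode %% (K + 1) != 0) {
    stop("n_segments_per_electrode (", n_segments_per_electrode,
         ") is not divisible by K + 1 = ", K + 1,
         "; trim the recording to ",
         (n_segments_per_electrode %/% (K + 1)) * (K + 1), " segments",
         call. = FALSE)
  }
  fold <- n_segments_per_electrode %/% (K + 1)
  splits <- purrr::map_dfr(seq_len(K), function(k) {
    train <- seq_len(k * fold)
    n_sub <- floor(0.8 * length(train))
    tibble::tibble(
      split = k,
      train_segments = list(train),
      subset_segments = list(train[seq_len(n_sub)]),
      validation_segments = list(train[(n_sub + 1):length(train)]),
      test_segments = list(seq(k * fold + 1, (k + 1) * fold)),
      n_train = n_sub * n_electrodes,
      n_validation = (length(train) - n_sub) * n_electrodes,
      n_test = fold * n_electrodes
    )
  })
  structure(list(K = K, fold_size = fold,
                 n_segments = n_segments_per_electrode,
                 n_electrodes = n_electrodes, splits = splits),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> K = ", x$K, ", ", x$K + 1, " chronological folds of ",
      x$fold_size, " segments x ", x$n_electrodes, " electrodes\n", sep = "")
  invisible(x)
}

#' Area under the ROC curve by rank statistic
#'
#' Probability that a random positive outranks a random negative, with ties
#' counting one half -- i.e. the Mann-Whitney U statistic normalized by
#' `n1 * n2`.
#'
#' @param scores Numeric scores (higher = more SOZ-like).
#' @param labels Labels in `{0, 1}`; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0))   # 0.875
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n2 <- sum(labels == 0)
  if (n1 == 0 || n2 == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Aggregate segment probabilities to per-electrode SOZ scores
#'
#' Per electrode: the mean of its test-segment probabilities within each
#' split, then the mean of those split means -- so every split contributes
#' equally regardless of its test-fold size.
#'
#' @param predictions Tibble with columns `channel`, `split`, `prob` (e.g.
#'   the `predictions` element of a [run_nested_cv()] result).
#' @param channels Optional character vector of electrodes that must all be
#'   present; an electrode without predictions is an error.
#' @return Tibble `channel`, `prob` (plus `label` if present in the input),
#'   sorted by decreasing probability.
#' @export
electrode_probabilities <- function(predictions, channels = NULL) {
  if (!is.null(channels)) {
    missing <- setdiff(channels, unique(predictions$channel))
    if (length(missing)) {
      stop("no predictions for electrode(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  keys <- intersect(c("channel", "label"), names(predictions))
  per_split <- dplyr::summarise(
    dplyr::group_by(predictions, dplyr::across(dplyr::all_of(c(keys, "split")))),
    prob = mean(.data$prob), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_split, dplyr::across(dplyr::all_of(keys))),
    prob = mean(.data$prob), .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$prob))
}

#' Chronological nested cross-validation of an SOZ classifier
#'
#' The outer loop walks the chronological splits of `plan`; the inner loop
#' is a grid search trained on the first 80% of each training set and scored
#' by AUC on the last 20%. The best configuration (ties broken by grid
#' order) is refit on the full training set and evaluated on the test fold,
#' which lies strictly later in time. Per-electrode SOZ probabilities are
#' the mean test-segment probability per split, averaged over splits.
#'
#' @param features A `pac_features` object from [as_feature_matrix()].
#' @param kind Classifier kind (see [default_grid()]).
#' @param plan A [plan_splits()] plan consistent with `features`.
#' @param grid Hyperparameter tibble (default [default_grid()] for `kind`).
#' @param seed Seed for model initialization/shuffling.
#' @param epochs,batch_size CNN training controls (ignored otherwise).
#' @param verbose Print per-split progress.
#' @return A `soz_cv` object: `splits` (chosen hyperparameters, validation
#'   and test AUC per split), `predictions` (per test segment),
#'   `electrodes` (per-electrode mean SOZ probability), `auc_mean`,
#'   `auc_sd`. A split whose validation or test fold contains one class
#'   yields `NA` AUC and is excluded from the summary with a warning.
#' @export
run_nested_cv <- function(features, kind = classifier_kinds(), plan,
                          grid = NULL, seed = 1L, epochs = 100,
                          batch_size = 128, verbose = FALSE) {
  stopifnot(inherits(features, "pac_features"), inherits(plan, "split_plan"))
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid(kind)
  meta <- features$meta
  n_elec <- length(unique(meta$channel))
  if (n_elec != plan$n_electrodes ||
      max(meta$segment) != plan$n_segments) {
    stop("plan is inconsistent with features (",
         n_elec, " electrodes x ", max(meta$segment), " segments)",
         call. = FALSE)
  }
  is_cnn <- kind %in% c("cnn_focal", "cnn_cbfocal")
  rows_for <- function(segs) which(meta$segment %in% segs)
  split_res <- purrr::map(seq_len(plan$K), function(k) {
    sp <- plan$splits[k, ]
    sub_i <- rows_for(sp$subset_segments[[1]])
    val_i <- rows_for(sp$validation_segments[[1]])
    tr_i <- rows_for(sp$train_segments[[1]])
    te_i <- rows_for(sp$test_segments[[1]])
    val <- list(X = features$X[val_i, , drop = FALSE], y = meta$y[val_i])
    val_ok <- length(unique(val$y)) == 2
    val_auc <- rep(NA_real_, nrow(grid))
    if (val_ok) {
      for (j in seq_len(nrow(grid))) {
        m <- fit_soz_classifier(features$X[sub_i, , drop = FALSE],
                                meta$y[sub_i], kind, grid[j, ],
                                validation = if (is_cnn) val,
                                seed = seed, epochs = epochs,
                                batch_size = batch_size)
        val_auc[j] <- auc_score(predict_prob(m, val$X), val$y)
        if (verbose) {
          message("split ", k, " config ", j, "/", nrow(grid),
                  " val AUC ", round(val_auc[j], 3))
        }
      }
      best_j <- which.max(val_auc)
    } else {
      warning("split ", k, ": validation fold has a single class; ",
              "using the first grid configuration")
      best_j <- 1L
    }
    final <- fit_soz_classifier(features$X[tr_i, , drop = FALSE],
                                meta$y[tr_i], kind, grid[best_j, ],
                                validation = if (is_cnn) val,
                                platt = TRUE, seed = seed, epochs = epochs,
                                batch_size = batch_size)
    probs <- predict_prob(final, features$X[te_i, , drop = FALSE])
    test_auc <- if (length(unique(meta$y[te_i])) == 2) {
      auc_score(probs, meta$y[te_i])
    } else {
      warning("split ", k, ": test fold has a single class; AUC undefined")
      NA_real_
    }
    list(
      row = tibble::tibble(split = k, params = list(grid[best_j, ]),
                           val_auc = val_auc[best_j], test_auc = test_auc),
      preds = tibble::tibble(split = k, channel = meta$channel[te_i],
                             label = meta$label[te_i],
                             segment = meta$segment[te_i], prob = probs)
    )
  })
  splits <- purrr::map_dfr(split_res, "row")
  predictions <- purrr::map_dfr(split_res, "preds")
  aucs <- splits$test_auc[!is.na(splits$test_auc)]
  structure(
    list(kind = kind, splits = splits, predictions = predictions,
         electrodes = electrode_probabilities(predictions,
                                              unique(meta$channel)),
         auc_mean = mean(aucs), auc_sd = stats::sd(aucs), plan = plan),
    class = "soz_cv"
  )
}

#' @export
print.soz_cv <- function(x, ...) {
  cat("<soz_cv> ", x$kind, ", K = ", x$plan$K, ": test AUC ",
      round(x$auc_mean, 3), " +/- ", round(x$auc_sd, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.soz_cv <- function(x, ...) {
  dplyr::mutate(x$splits,
                params = purrr::map_chr(.data$params, function(p) {
                  paste(names(p), unlist(p), sep = "=", collapse = ", ")
                }))
}

#' @export
glance.soz_cv <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_splits = x$plan$K,
                 auc_mean = x$auc_mean, auc_sd = x$auc_sd)
}

#' Horizontal bar chart of per-electrode SOZ probabilities
#'
#' @param object A `soz_cv` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soz_cv <- function(object, ...) {
  df <- dplyr::mutate(object$electrodes,
                      channel = stats::reorder(.data$channel, .data$prob))
  ggplot2::ggplot(df, ggplot2::aes(.data$prob, .data$channel,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean predicted SOZ probability", y = NULL,
                  fill = NULL)
}
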