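#' Flatten a 16 x 16 comodulogram to a 256-feature vector
#'
#' Fixed column-major raster (amplitude index varies fastest), invertible by
#' [unflatten_comodulogram()]. This is the feature layout consumed by the
#' vector classifiers; the CNN consumes the 2-D matrix directly.
#'
#' @param com 16 x 16 numeric matrix.
#' @return Numeric vector of length 256.
#' @export
flatten_comodulogram <- function(com) {
  if (!is.matrix(com) || nrow(com) != 16 || ncol(com) != 16) {
    stop("expected a 16 x 16 matrix", call. = FALSE)
  }
  as.vector(com)
}

#' @rdname flatten_comodulogram
#' @param v Numeric vector of length 256.
#' @export
unflatten_comodulogram <- function(v) {
  if (length(v) != 256) stop("expected a length-256 vector", call. = FALSE)
  matrix(v, 16, 16)
}

#' Inverse-frequency class weights
#'
#' `omega_i = N_samples / (N_classes * N_samples_i)`: the minority class is
#' up-weighted and the majority class down-weighted so that
#' `sum_i n_i * omega_i = N_samples` (the balance identity). Used to scale
#' the misclassification penalty `C_i = C * omega_i` in the SVM and the
#' positive-class weight of the boosted trees.
#'
#' @param n_per_class Named or unnamed vector of per-class counts (all >= 1).
#' @return Numeric vector of weights, same names/order as `n_per_class`.
#' @examples
#' class_weights(c(SOZ = 16, NSOZ = 64))   # 2.5, 0.625
#' @export
class_weights <- function(n_per_class) {
  if (any(n_per_class < 1)) stop("all class counts must be >= 1",
                                 call. = FALSE)
  sum(n_per_class) / (length(n_per_class) * n_per_class)
}

clamp_p <- function(p) {
  if (any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1] before clamping", call. = FALSE)
  }
  pmin(pmax(p, 1e-7), 1 - 1e-7)
}

p_t <- function(p, y) ifelse(y == 1, p, 1 - p)

#' Focal loss for binary classification
#'
#' Alpha-balanced cross-entropy scaled by the modulating factor
#' `(1 - p_t)^gamma`, which down-weights well-classified (easy) samples so
#' that training concentrates on the hard ones:
#' `FL = -alpha_t * (1 - p_t)^gamma * log(p_t)`, with `p_t = p` for positive
#' samples and `1 - p` otherwise, and `alpha_t = alpha` / `1 - alpha`
#' correspondingly. Natural logarithm; `p` is clamped to
#' `[1e-7, 1 - 1e-7]`. With `gamma = 0` this reduces exactly to
#' alpha-balanced cross-entropy.
#'
#' @param p Predicted probability (of the positive class), vectorized.
#' @param y Label in `{0, 1}` (1 = positive/SOZ), vectorized.
#' @param alpha Balance weight in (0, 1) for the positive class.
#' @param gamma Focusing exponent, `>= 0`.
#' @param reduce If `TRUE` (default) return the mean over samples, else the
#'   per-sample losses.
#' @return Non-negative scalar (or vector if `reduce = FALSE`).
#' @examples
#' focal_loss(0.9, 1, alpha = 0.75, gamma = 2)   # ~7.902e-4
#' @export
focal_loss <- function(p, y, alpha = 0.75, gamma = 2, reduce = TRUE) {
  pt <- p_t(clamp_p(p), y)
  at <- ifelse(y == 1, alpha, 1 - alpha)
  l <- -at * (1 - pt)^gamma * log(pt)
  if (reduce) mean(l) else l
}

#' Effective number of samples
#'
#' `E_n = (1 - beta^n) / (1 - beta)`: a saturating count that models the
#' diminishing marginal value of additional samples from the same class.
#' Its reciprocal is the class weight of the class-balanced focal loss.
#'
#' @param n Per-class sample count (`>= 1`), vectorized.
#' @param beta Saturation parameter in `[0, 1)`.
#' @return `E_n >= 1`.
#' @export
effective_number <- function(n, beta) {
  if (any(beta >= 1) || any(beta < 0)) {
    stop("beta must lie in [0, 1)", call. = FALSE)
  }
  (1 - beta^n) / (1 - beta)
}

#' Class-balanced focal loss
#'
#' Focal modulation combined with a class weight inversely proportional to
#' the effective number of samples of the sample's own class:
#' `CB = (1 / E_n) * (1 - p_t)^gamma * (-log(p_t))` with
#' `E_n = (1 - beta^n) / (1 - beta)`. Implemented as a non-negative loss.
#' The weight `(1 - beta) / (1 - beta^n)` decreases in `n`, so the majority
#' class is down-weighted.
#'
#' @inheritParams focal_loss
#' @param n_class_of_y Sample count of the class each sample belongs to
#'   (within the current training subset), vectorized.
#' @param beta Saturation parameter in `[0, 1)`; `beta = 1` is an error.
#' @return Non-negative scalar (or vector if `reduce = FALSE`).
#' @examples
#' cb_focal_loss(0.9, 1, n_class_of_y = 10, beta = 0.9, gamma = 2)
#' @export
cb_focal_loss <- function(p, y, n_class_of_y, beta = 0.999, gamma = 2,
                          reduce = TRUE) {
  if (any(beta == 1)) stop("beta = 1 is not allowed", call. = FALSE)
  if (any(n_class_of_y < 1)) stop("class counts must be >= 1", call. = FALSE)
  pt <- p_t(clamp_p(p), y)
  w <- 1 / effective_number(n_class_of_y, beta)
  l <- -w * (1 - pt)^gamma * log(pt)
  if (reduce) mean(l) else l
}
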