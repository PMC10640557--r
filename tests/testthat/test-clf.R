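test_that("flatten/unflatten is an exact, shape-checked round trip", {
  set.seed(1)
  m <- matrix(stats::rnorm(256), 16, 16)
  v <- flatten_comodulogram(m)
  expect_length(v, 256)
  expect_identical(unflatten_comodulogram(v), m)
  one <- matrix(0, 16, 16); one[2, 5] <- 1
  expect_equal(sum(flatten_comodulogram(one) != 0), 1)
  expect_error(flatten_comodulogram(matrix(0, 4, 4)), "16 x 16")
  expect_error(unflatten_comodulogram(numeric(10)), "256")
})

test_that("class weights are inverse-frequency with the balance identity", {
  expect_equal(unname(class_weights(c(16, 64))), c(2.5, 0.625))
  expect_equal(unname(class_weights(c(50, 50))), c(1, 1))
  set.seed(2)
  for (i in 1:10) {
    n <- sample(1:500, 2)
    w <- class_weights(n)
    expect_equal(n[1] * w[1], n[2] * w[2])             # equal per-class mass
    expect_equal(sum(n * w), sum(n))                   # sum n_i w_i = N
  }
  expect_error(class_weights(c(0, 5)), ">= 1")
})

test_that("focal loss reduces to balanced cross-entropy at gamma = 0", {
  set.seed(3)
  p <- stats::runif(50, 0.01, 0.99)
  y <- stats::rbinom(50, 1, 0.5)
  bce <- -ifelse(y == 1, log(p), log(1 - p))
  expect_equal(focal_loss(p, y, alpha = 0.5, gamma = 0, reduce = FALSE),
               0.5 * bce, tolerance = 1e-12)
  for (a in c(0.25, 0.75, 0.9)) {
    expect_equal(focal_loss(p, y, alpha = a, gamma = 0, reduce = FALSE),
                 ifelse(y == 1, a, 1 - a) * bce, tolerance = 1e-12)
  }
})

test_that("focal loss matches independent arithmetic and its limits", {
  expect_equal(focal_loss(0.9, 1, alpha = 0.75, gamma = 2),
               0.75 * (1 - 0.9)^2 * (-log(0.9)), tolerance = 1e-9)
  expect_equal(focal_loss(0.9, 1, alpha = 0.75, gamma = 2),
               7.9020387e-4, tolerance = 1e-7)
  # vanishes as p_t -> 1, monotone decreasing in p_t
  expect_lt(focal_loss(1 - 1e-7, 1), 1e-10)
  p <- seq(0.05, 0.95, by = 0.05)
  l <- focal_loss(p, rep(1, length(p)), reduce = FALSE)
  expect_true(all(diff(l) < 0))
  expect_error(focal_loss(1.2, 1), "\\[0, 1\\]")
})

test_that("class-balanced focal loss weight behaves as effective-number", {
  expect_equal(effective_number(1, 0.9), 1)
  expect_equal(effective_number(10, 0.9), 6.5132156, tolerance = 1e-6)
  expect_equal(1 / effective_number(10, 0.9), 0.15354, tolerance = 1e-4)
  expect_equal(effective_number(c(1, 5, 50), 0), c(1, 1, 1))
  # n = 1: equals the unweighted focal term
  expect_equal(cb_focal_loss(0.8, 1, 1, beta = 0.99, gamma = 2),
               (1 - 0.8)^2 * (-log(0.8)), tolerance = 1e-12)
  # weight decreasing in n: majority class down-weighted
  w <- 1 / effective_number(c(1, 2, 10, 100, 1000), 0.999)
  expect_true(all(diff(w) < 0))
  expect_error(cb_focal_loss(0.5, 1, 10, beta = 1), "beta = 1")
  expect_error(cb_focal_loss(0.5, 1, 0, beta = 0.9), ">= 1")
})

test_that("tuning grids match the declared search spaces", {
  expect_equal(nrow(default_grid("gbm")), 7 * 4 * 4 * 4)
  expect_setequal(unique(default_grid("gbm")$num_leaves), seq(35, 65, 5))
  expect_setequal(unique(default_grid("gbm")$learning_rate),
                  c(0.01, 0.05, 0.1, 0.15))
  expect_equal(nrow(default_grid("cnn_focal")), 20)
  expect_setequal(unique(default_grid("cnn_focal")$alpha),
                  c(0.75, 0.9, 0.99, 0.999, 0.9999))
  expect_setequal(unique(default_grid("cnn_cbfocal")$gamma), c(0.5, 1, 2, 5))
})

separable_toy <- function(n = 80, seed = 4) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(stats::rnorm(n * 256, sd = 0.3), n)
  X[y == 1, 1:8] <- X[y == 1, 1:8] + 3
  list(X = X, y = y)
}

test_that("class-weighted SVMs separate toys and recover the minority", {
  toy <- separable_toy()
  for (kind in c("svm_linear", "svm_rbf")) {
    m <- fit_soz_classifier(toy$X, toy$y, kind,
                            params = list(C = 1, gamma = NA))
    p <- predict_prob(m, toy$X)
    expect_equal(auc_score(p, toy$y), 1)
    expect_equal(mean((p > 0.5) == (toy$y == 1)), 1)   # training accuracy
  }
  # 19:1 imbalance, separable minority: Eq.-2 weighting recovers it fully
  set.seed(5)
  n1 <- 5; n0 <- 95
  X <- rbind(matrix(stats::rnorm(n1 * 256), n1),
             matrix(stats::rnorm(n0 * 256), n0))
  X[1:n1, 1:4] <- X[1:n1, 1:4] + 4
  y <- rep(c(1, 0), c(n1, n0))
  m <- fit_soz_classifier(X, y, "svm_rbf", params = list(C = 1, gamma = NA))
  expect_equal(mean(predict_prob(m, X)[1:n1] > 0.5), 1)  # minority recall
  expect_error(fit_soz_classifier(X, rep(0, 100), "svm_rbf"),
               "single class")
})

test_that("boosted trees fit separable toys and stay at chance under nulls", {
  toy <- separable_toy(seed = 6)
  m <- fit_soz_classifier(toy$X, toy$y, "gbm",
                          params = default_grid("gbm")[1, ])
  expect_equal(auc_score(predict_prob(m, toy$X), toy$y), 1)
  # permuted labels: held-out AUC near chance
  set.seed(7)
  yperm <- sample(toy$y)
  tr <- seq_len(60); te <- 61:80
  mp <- fit_soz_classifier(toy$X[tr, ], yperm[tr], "gbm",
                           params = default_grid("gbm")[1, ])
  aucp <- auc_score(predict_prob(mp, toy$X[te, ]), yperm[te])
  expect_gt(aucp, 0.2); expect_lt(aucp, 0.8)
})

test_that("CNN forward pass propagates the documented shapes", {
  m <- build_cnn("focal", seed = 8)
  X <- matrix(stats::rnorm(3 * 256), 3)
  fwd <- sozpac:::cnn_forward(m, X)
  expect_equal(dim(fwd$cache$b2$out), c(3 * 256, 64))  # block1: 16x16x64
  expect_equal(dim(fwd$cache$p1$Y), c(3 * 64, 64))     # pooled: 8x8x64
  expect_equal(dim(fwd$cache$b3$out), c(3 * 64, 128))  # block2: 8x8x128
  expect_equal(dim(fwd$cache$p2$Y), c(3 * 16, 128))    # pooled: 4x4x128
  expect_equal(ncol(fwd$cache$f), 2048)                # flatten
  p <- predict(m, X)
  expect_length(p, 3)
  expect_true(all(p > 0 & p < 1))                      # sigmoid range
  expect_error(predict(m, matrix(0, 2, 100)), "256")
})

test_that("CNN gradients agree with finite differences at the output layer", {
  m <- build_cnn("cb_focal", beta = 0.99, gamma = 1, seed = 9)
  X <- matrix(stats::rnorm(4 * 256), 4)
  y <- c(1, 0, 1, 0)
  fwd <- sozpac:::cnn_forward(m, X, training = TRUE)
  g <- sozpac:::cnn_backward(m, fwd, y, 2, 2)
  mask <- fwd$cache$mask
  lossfn <- function(model) {
    f <- sozpac:::cnn_forward(model, X, training = TRUE, dropout_mask = mask)
    sozpac:::cnn_loss(model, f$p, y, 2, 2)
  }
  eps <- 1e-5
  for (i in c(3, 57, 111)) {
    mp <- m; mp$w$fc2$W[i] <- mp$w$fc2$W[i] + eps
    mm <- m; mm$w$fc2$W[i] <- mm$w$fc2$W[i] - eps
    num <- (lossfn(mp) - lossfn(mm)) / (2 * eps)
    expect_equal(num, g$fc2$W[i], tolerance = 1e-4)
  }
})

test_that("the CNN can memorize a small strongly-signaled batch", {
  set.seed(10)
  n <- 64
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(stats::rnorm(n * 256), n)
  X[y == 1, 40] <- X[y == 1, 40] + 3
  m <- cnn_fit(build_cnn("focal", seed = 11), X, y, epochs = 60,
               batch_size = 128)
  expect_gte(auc_score(predict(m, X), y), 0.99)
})
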