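fake_tensor <- function(values, labels = c("SOZ", "NSOZ")) {
  structure(
    list(values = values, grid = band_grid(),
         channels = tibble::tibble(
           channel = sprintf("ch%02d", seq_len(dim(values)[1])),
           label = labels
         ),
         fs = 1200, seg_seconds = 20, spec = surrogate_spec()),
    class = "comodulogram_tensor"
  )
}

test_that("time averaging is the elementwise segment mean", {
  v <- array(0, c(2, 2, 16, 16))
  v[1, 1, , ] <- 1; v[1, 2, , ] <- 3
  v[2, 1, , ] <- 2; v[2, 2, , ] <- 2
  avg <- time_average(fake_tensor(v))
  expect_equal(avg[1, , ], matrix(2, 16, 16))
  expect_equal(avg[2, , ], matrix(2, 16, 16))       # idempotent on constants
  vperm <- v[, 2:1, , ]
  expect_equal(time_average(fake_tensor(vperm)), avg) # order-invariant
})

test_that("band pairs carry the canonical frequency ranges", {
  bp <- band_pair_set()
  expect_equal(nrow(bp), 8)
  expect_setequal(
    bp$pair,
    c("delta-ripple", "delta-fastripple", "theta-ripple", "theta-fastripple",
      "alpha-ripple", "alpha-fastripple", "beta-ripple", "beta-fastripple")
  )
  ranges <- unique(bp[, c("phase_band", "phase_low", "phase_high")])
  expect_equal(ranges$phase_low[match(c("delta", "theta", "alpha", "beta"),
                                      ranges$phase_band)], c(0.5, 4, 8, 12))
  expect_equal(ranges$phase_high[match(c("delta", "theta", "alpha", "beta"),
                                       ranges$phase_band)], c(4, 8, 12, 24))
  expect_equal(unique(bp[, c("amp_band", "amp_low", "amp_high")])$amp_low,
               c(80, 260))
  expect_equal(unique(bp[, c("amp_band", "amp_low", "amp_high")])$amp_high,
               c(260, 560))
})

test_that("band-pair extraction averages exactly the covered cells", {
  g <- band_grid()
  const <- matrix(7, 16, 16)
  expect_true(all(extract_band_pairs(const) == 7))

  # indicator on the delta x ripple block
  blk <- matrix(0, 16, 16)
  p_in <- g$phase$high <= 4
  a_in <- g$amplitude$high <= 260
  blk[a_in, p_in] <- 1
  vals <- extract_band_pairs(blk)
  expect_equal(unname(vals["delta-ripple"]), 1)
  expect_equal(unname(vals["delta-fastripple"]), 0)
  expect_equal(unname(vals["theta-ripple"]), 0)
  expect_equal(sum(p_in) * sum(a_in), 24)        # delta-ripple = 4 x 6 cells

  # a single hot cell inside delta-ripple contributes 1/24
  one <- matrix(0, 16, 16); one[1, 1] <- 1
  expect_equal(unname(extract_band_pairs(one)["delta-ripple"]), 1 / 24)

  # ranges not aligned to cell edges must error
  bad <- band_pair_set()
  bad$phase_high[1] <- 3.7
  expect_error(extract_band_pairs(const, bad), "not aligned")
})

test_that("electrode table has one labelled row per channel", {
  v <- array(stats::rnorm(2 * 3 * 256), c(2, 3, 16, 16))
  tab <- electrode_band_pairs(fake_tensor(v))
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("channel", "label", band_pair_set()$pair))
  expect_true(all(is.finite(as.matrix(tab[, -(1:2)]))))
})

test_that("Mann-Whitney matches exact enumeration and closed cases", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  same <- mann_whitney(c(1, 2), c(1, 2))
  expect_gte(same$p_value, 0.999)

  # cross-check the small-sample path against wilcox.test's exact p
  set.seed(4)
  for (i in 1:5) {
    x <- sample(seq(1, 199, 2), 5); y <- sample(seq(2, 200, 2), 7) # tie-free
    ours <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }

  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(5)
  x <- stats::rnorm(30); y <- stats::rnorm(25, 0.5)
  expect_equal(mann_whitney(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-12)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("U and p are invariant under a common shift", {
  set.seed(6)
  x <- stats::rnorm(6); y <- stats::rnorm(8)
  a <- mann_whitney(x, y)
  b <- mann_whitney(x + 5, y + 5)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("strong separation is detected and the null rate is controlled", {
  set.seed(7)
  for (i in 1:5) {
    expect_lt(mann_whitney(stats::rnorm(50, 3), stats::rnorm(50))$p_value,
              0.001)
  }
  rej <- vapply(1:2000, function(i) {
    set.seed(i)
    mann_whitney(stats::rnorm(20), stats::rnorm(20))$p_value < 0.001
  }, logical(1))
  expect_lte(mean(rej), 0.005)
})

test_that("per-band-pair tests separate coupled from uncoupled electrodes", {
  set.seed(8)
  v <- array(stats::rnorm(20 * 4 * 256, sd = 0.3), c(20, 4, 16, 16))
  v[1:4, , 1:6, 1:4] <- v[1:4, , 1:6, 1:4] + 2      # delta-ripple block
  ten <- fake_tensor(v, labels = rep(c("SOZ", "NSOZ"), c(4, 16)))
  tst <- soz_band_tests(electrode_band_pairs(ten))
  expect_equal(nrow(tst), 8)
  dr <- tst[tst$band_pair == "delta-ripple", ]
  expect_lt(dr$p_value, 0.01)
  expect_false(tst$significant[tst$band_pair == "beta-fastripple"])
})
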