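test_that("raw MVL-MI matches closed forms", {
  expect_equal(mvl_raw(rep(0.3, 10), rep(2, 10)), 2)
  phi <- seq(0, 2 * pi, length.out = 100001)[-1]
  expect_lt(mvl_raw(phi, rep(1, length(phi))), 1e-3)     # vectors cancel
  expect_equal(mvl_raw(phi, 1 + cos(phi)), 0.5, tolerance = 1e-6)
  expect_error(mvl_raw(1:3, 1:4), "equal length")
  expect_error(mvl_raw(1, 1), "at least 2")
})

test_that("FFT all-shift surrogate path equals explicit circular shifting", {
  for (seed in 1:3) {
    set.seed(seed + 100)
    n <- 400
    ph <- stats::runif(n, -pi, pi)
    am <- stats::runif(n)
    spec <- surrogate_spec(40, min_shift = 25, seed = seed)
    expect_equal(surrogate_z(ph, am, spec),
                 brute_force_z(ph, am, spec, 25), tolerance = 1e-10)
  }
})

test_that("z-scored MI is scale invariant, seeded, and guards degeneracy", {
  seg <- null_segment(seed = 5)
  spec <- surrogate_spec(60, seed = 2)
  z1 <- surrogate_z(seg$phase, seg$amplitude, spec, fs = 250)
  expect_identical(z1, surrogate_z(seg$phase, seg$amplitude, spec, fs = 250))
  z10 <- surrogate_z(seg$phase, 10 * seg$amplitude, spec, fs = 250)
  expect_equal(z1, z10, tolerance = 1e-9)
  expect_warning(z0 <- surrogate_z(seg$phase, rep(1, length(seg$phase)),
                                   spec, fs = 250),
                 "degenerate")   # constant amplitude is shift-invariant
  expect_identical(z0, 0)
})

test_that("under independence z-scored MI is approximately standard normal", {
  zs <- vapply(1:200, function(i) {
    seg <- null_segment(fs = 250, seed = 1000 + i)
    surrogate_z(seg$phase, seg$amplitude, surrogate_spec(100, seed = i),
                fs = 250)
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(stats::sd(zs), 0.8)
  expect_lt(stats::sd(zs), 1.2)
})

test_that("comodulogram has the comodulogram orientation and null ceiling", {
  fs <- 1200
  set.seed(21)
  x <- stats::rnorm(fs * 40)
  g <- band_grid()
  ph <- sozpac:::segmented_analytic(x, g$phase, "phase", fs, 20)
  am <- sozpac:::segmented_analytic(x, g$amplitude, "amplitude", fs, 20)
  com <- comodulogram(ph[1, , ], am[1, , ], g, surrogate_spec(100, seed = 3),
                      fs = fs)
  expect_identical(dim(com), c(16L, 16L))
  expect_identical(rownames(com)[1], "80-110")
  expect_identical(colnames(com)[1], "0.5-1")
  # white noise: no cell should clear a 5-sigma threshold
  expect_lt(max(abs(com)), 5)
  expect_error(comodulogram(ph[1, , 1:10], am[1, , ], g), "phase")
})

test_that("injected coupling is recovered at the right grid cell", {
  cfg <- synth_config(fs = 1200, duration = 60, n_soz = 1, n_nsoz = 1,
                      phase_freq = 3, amp_freq = 120, kappa = 1,
                      snr_sd = 0.5, seed = 31)
  rec <- generate_recording(cfg)
  ten <- compute_comodulograms(rec, spec = surrogate_spec(50, seed = 4))
  g <- ten$grid
  soz_mean <- apply(ten$values[1, , , , drop = FALSE], c(3, 4), mean)
  hit <- which(soz_mean == max(soz_mean), arr.ind = TRUE)
  expect_equal(unname(unlist(g$amplitude[hit[1], ])), c(110, 140))
  expect_true(g$phase$low[hit[2]] %in% c(2, 3))      # 2-3 or 3-4 Hz
  expect_gt(max(soz_mean), 3)                        # strong coupling
  # the uncoupled channel stays at null level
  expect_lt(max(abs(apply(ten$values[2, , , , drop = FALSE], c(3, 4), mean))),
            5)
  # seeded determinism of the full tensor
  ten2 <- compute_comodulograms(rec, spec = surrogate_spec(50, seed = 4))
  expect_identical(ten$values, ten2$values)
})

test_that("mean z-MI at the injected cell increases with coupling depth", {
  fs <- 1200
  zbar <- vapply(c(0, 0.25, 0.5, 1), function(kap) {
    cfg <- synth_config(fs = fs, duration = 420, n_soz = 1, n_nsoz = 1,
                        phase_freq = 3, amp_freq = 120, kappa = kap,
                        snr_sd = 0.5, seed = 77)
    x <- generate_coupled_signal(cfg, "SOZ")
    ph <- segment_series(hilbert_phase_amplitude(
      fir_bandpass(x, list(low = 3, high = 4), fs), "phase"), fs, 20)
    am <- segment_series(hilbert_phase_amplitude(
      fir_bandpass(x, list(low = 110, high = 140), fs), "amplitude"), fs, 20)
    mean(vapply(seq_len(nrow(ph)), function(s) {
      surrogate_z(ph[s, ], am[s, ], surrogate_spec(50, seed = s), fs = fs)
    }, numeric(1)))
  }, numeric(1))
  # monotone response over 21 segments per depth (small sampling slack)
  expect_true(all(diff(zbar) > -0.2))
  expect_gt(zbar[4], zbar[1] + 3)
})

test_that("comodulogram tensors round-trip through delimited text", {
  set.seed(41)
  values <- array(stats::rnorm(2 * 3 * 256), c(2, 3, 16, 16))
  ten <- structure(
    list(values = values, grid = band_grid(),
         channels = tibble::tibble(channel = c("a", "b"),
                                   label = c("SOZ", "NSOZ")),
         fs = 1200, seg_seconds = 20, spec = surrogate_spec()),
    class = "comodulogram_tensor"
  )
  path <- tempfile(fileext = ".tsv")
  write_comodulograms(ten, path)
  back <- read_comodulograms(path, fs = 1200)
  expect_equal(back$values, ten$values, tolerance = 1e-6)
  expect_equal(back$channels, ten$channels)
})
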