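test_that("degenerate AR cases behave as pure innovation noise", {
  w <- ar_waveform(50, coeffs = rep(0, 5), noise_sd = 1, rng_seed = 2)
  expect_length(w, 50)
  w0 <- ar_waveform(50, coeffs = rep(0, 5), noise_sd = 0, rng_seed = 2)
  expect_true(all(w0 == 0))
})

test_that("unstable AR coefficients are refused with the spectral radius named", {
  expect_error(ar_waveform(10, coeffs = c(1.2, 0, 0, 0, 0.3)),
               "spectral radius")
})

test_that("AR waveform is deterministic given the seed", {
  expect_identical(ar_waveform(100, rng_seed = 9), ar_waveform(100, rng_seed = 9))
  expect_false(identical(ar_waveform(100, rng_seed = 9),
                         ar_waveform(100, rng_seed = 10)))
})

test_that("default AR(5) lag-1 autocorrelation matches the Yule-Walker value", {
  # Yule-Walker solution for the default coefficients, solved independently
  a <- ar5_default_coeffs()
  M <- matrix(0, 5, 5); rhs <- numeric(5)
  for (k in 1:5) for (i in 1:5) {
    j <- abs(k - i)
    if (j == 0) rhs[k] <- rhs[k] + a[i] else M[k, j] <- M[k, j] + a[i]
  }
  rho1 <- solve(diag(5) - M, rhs)[1]
  expect_equal(rho1, 0.811804, tolerance = 1e-5)    # frozen oracle value
  w <- ar_waveform(1e4, rng_seed = 1)
  expect_lt(abs(cor(w[-1], w[-length(w)]) - rho1), 0.05)
})

test_that("a patch on the icosahedron is the center plus its 5 neighbors", {
  p <- sample_patches(fx("g0"), 1, rng_seed = 3)
  expect_length(p$members[[1]], 6)
  expect_equal(p$members[[1]][1], p$centers[1])
  expect_identical(sample_patches(fx("g0"), 1, rng_seed = 3)$members,
                   p$members)
})

test_that("multiple patches are vertex-disjoint", {
  for (s in 1:5) {
    p <- sample_patches(fx("g2"), 2, rng_seed = s)
    expect_equal(anyDuplicated(unlist(p$members)), 0)
  }
  expect_error(sample_patches(fx("g0"), 2, rng_seed = 1, max_retries = 1000),
               NA)
})

test_that("rendered sources scale neighbors and zero everything else", {
  sp <- fx("ico2"); g <- fx("g2")
  p <- sample_patches(g, 1, rng_seed = 4, neighbor_scale = 0.5)
  w <- ar_waveform(30, rng_seed = 4)
  s <- render_sources(sp, p, w)
  outside <- setdiff(seq_len(sp$m), p$members[[1]] + 1)
  expect_true(all(s[outside, ] == 0))
  ct <- p$centers[1] + 1
  nb <- p$members[[1]][-1] + 1
  expect_equal(s[ct, ], w)
  for (v in nb) expect_equal(s[v, ], 0.5 * w)
  # uniform amplitude at scale 1
  s1 <- render_sources(sp, p, w, neighbor_scale = 1)
  expect_equal(s1[nb[1], ], s1[ct, ])
  expect_error(render_sources(sp, p, w, neighbor_scale = 0), "neighbor_scale")
})

test_that("noise mixing realizes the requested SNR exactly", {
  set.seed(8)
  x <- matrix(rnorm(32 * 50), 32)
  for (snr in c(0, 20)) {
    xn <- add_noise_snr(x, snr, rng_seed = 2)
    noise <- xn - x
    realized <- 10 * log10(mean(x^2) / mean(noise^2))
    expect_equal(realized, snr, tolerance = 1e-9)
  }
  # 20 dB means a power ratio of exactly 100
  xn <- add_noise_snr(x, 20, rng_seed = 2)
  expect_equal(mean(x^2) / mean((xn - x)^2), 100, tolerance = 1e-9)
  expect_error(add_noise_snr(matrix(0, 2, 2), 10), "zero power")
})

test_that("largest-remainder split reproduces the 2052-trial sizes", {
  expect_equal(gftbilstm:::largest_remainder_split(2052, c(0.7, 0.15, 0.15)),
               c(1436L, 308L, 308L))
  expect_equal(gftbilstm:::largest_remainder_split(600, c(0.7, 0.15, 0.15)),
               c(420L, 90L, 90L))
})

test_that("dataset splits are disjoint, exhaustive and seeded", {
  ds <- fx("ds2")
  all_idx <- sort(unname(unlist(ds$split)))
  expect_equal(all_idx, seq_along(ds$samples))
  expect_equal(length(intersect(ds$split$train, ds$split$val)), 0)
  ds_b <- make_dataset(fx("ico2"), fx("g2"), fx("lf2"), n_samples = 30,
                       snr_db = c(20, 40), T_samples = 40, seed = 5L)
  expect_identical(ds$split, ds_b$split)
  expect_equal(ds$samples[[3]]$x_noisy[["20"]], ds_b$samples[[3]]$x_noisy[["20"]])
})

test_that("clean EEG is the exact forward projection and is linear in the source", {
  ds <- fx("ds2"); lf <- fx("lf2")
  s <- sample_source_movie(ds, 1)
  expect_equal(ds$samples[[1]]$x_clean, lf$gain %*% s, tolerance = 1e-12)
  expect_equal(lf$gain %*% (3 * s), 3 * ds$samples[[1]]$x_clean,
               tolerance = 1e-12)
})

test_that("every sample realizes its stated SNRs within 0.1 dB", {
  ds <- fx("ds2")
  for (i in c(1, 7)) {
    smp <- ds$samples[[i]]
    for (key in c("20", "40")) {
      noise <- smp$x_noisy[[key]] - smp$x_clean
      realized <- 10 * log10(mean(smp$x_clean^2) / mean(noise^2))
      expect_lt(abs(realized - as.numeric(key)), 0.1)
    }
  }
})

test_that("patch energy concentrates in the spatial low band", {
  # premise of the method: an extended patch is a spatially low-pass signal
  sp <- build_icosphere_source_space(3, 75)
  g <- adjacency_from_mesh(sp, 1)
  basis <- eigendecompose(laplacian(g))
  k <- round(0.3 * sp$m)
  set.seed(11)
  for (s in 1:3) {
    p <- sample_patches(g, 1, rng_seed = s)
    sig <- render_sources(sp, p, ar_waveform(20, rng_seed = s))
    co <- gft(basis, sig)
    frac <- sum(co[seq_len(k), ]^2) / sum(co^2)
    expect_gte(frac, 0.8)
  }
})

test_that("single-source trial counts beyond m are refused", {
  expect_error(make_dataset(fx("ico2"), fx("g2"), fx("lf2"), n_samples = 500),
               "more single-source trials")
  expect_error(make_dataset(fx("ico2"), fx("g2"), fx("lf2"), n_samples = 10,
                            fractions = c(0.9, 0.05, 0.05)),
               "non-empty")
})
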