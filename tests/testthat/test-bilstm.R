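zero_cell <- function(hidden, input) {
  Z <- matrix(0, hidden, hidden + input)
  lstm_cell_params(Z, Z, Z, Z, numeric(hidden), numeric(hidden),
                   numeric(hidden), numeric(hidden))
}

test_that("LSTM cell with zero parameters and zero state outputs zero", {
  cell <- zero_cell(3, 2)
  st <- lstm_cell_step(cell, c(1, -1), numeric(3), numeric(3))
  expect_equal(st$c, numeric(3))
  expect_equal(st$h, numeric(3))
  expect_equal(st$f, rep(0.5, 3))   # sigma(0) = 1/2
})

test_that("zero-weight gates halve the carried memory", {
  cell <- zero_cell(2, 1)
  cprev <- c(0.8, -0.4)
  st <- lstm_cell_step(cell, 0, numeric(2), cprev)
  expect_equal(st$c, 0.5 * cprev)
  expect_equal(st$h, 0.5 * tanh(0.5 * cprev))
})

test_that("scalar LSTM step matches the hand-computed oracle", {
  # hidden = input = 1, all weights 1, biases 0, x = 1, zero state:
  # f = i = o = sigma(1), c~ = tanh(1), c = sigma(1) tanh(1), h = o tanh(c)
  one <- matrix(1, 1, 2)
  cell <- lstm_cell_params(one, one, one, one, 0, 0, 0, 0)
  st <- lstm_cell_step(cell, 1, 0, 0)
  expect_equal(st$f, 0.7310585786, tolerance = 1e-9)
  expect_equal(st$c_tilde, 0.7615941560, tolerance = 1e-9)
  expect_equal(st$c, 0.5567699411, tolerance = 1e-9)
  expect_equal(st$h, 0.3696063529, tolerance = 1e-9)
})

test_that("cell rejects mismatched shapes", {
  cell <- zero_cell(3, 2)
  expect_error(lstm_cell_step(cell, c(1, 2, 3), numeric(3), numeric(3)),
               "shape mismatch")
})

test_that("gate activations stay in their ranges on random inputs", {
  set.seed(21)
  mdl <- new_bilstm_model(4, 12, 3, seed = 2)
  cell <- mdl$params$fw
  for (r in 1:20) {
    st <- lstm_cell_step(cell, rnorm(4, sd = 3), rnorm(6), rnorm(6))
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(st$c_tilde > -1 & st$c_tilde < 1))
  }
})

test_that("batched scan agrees with the step-by-step reference recurrence", {
  set.seed(22)
  mdl <- new_bilstm_model(5, 8, 2, seed = 3)
  x <- matrix(rnorm(5 * 12), 5)
  for (rev in c(FALSE, TRUE)) {
    sc <- gftbilstm:::lstm_scan_batch(mdl$params$fw,
                                      array(x, c(5, 1, 12)), reverse = rev)
    h <- numeric(4); cc <- numeric(4)
    ts <- if (rev) 12:1 else 1:12
    for (t in ts) {
      st <- lstm_cell_step(mdl$params$fw, x[, t], h, cc)
      h <- st$h; cc <- st$c
      expect_equal(sc$H[, 1, t], h, tolerance = 1e-12)
      expect_equal(sc$C[, 1, t], cc, tolerance = 1e-12)
    }
  }
})

test_that("BiLSTM with zero parameters and identity activation outputs zero", {
  mdl <- new_bilstm_model(3, 4, 2, init = "zero")
  y <- bilstm_forward(mdl, matrix(rnorm(3 * 6), 3))
  expect_equal(y, matrix(0, 2, 6))
})

test_that("T = 1 sequences use the same single step in both directions", {
  mdl <- new_bilstm_model(3, 8, 2, seed = 5)
  x1 <- matrix(rnorm(3), 3, 1)
  y <- bilstm_forward(mdl, x1)
  st_f <- lstm_cell_step(mdl$params$fw, x1[, 1], numeric(4), numeric(4))
  st_b <- lstm_cell_step(mdl$params$bw, x1[, 1], numeric(4), numeric(4))
  manual <- mdl$params$out$W %*% c(st_f$h, st_b$h) + mdl$params$out$b
  expect_equal(y, manual, tolerance = 1e-12)
})

test_that("swapping directions and reversing time reverses the output", {
  mdl <- new_bilstm_model(4, 12, 3, seed = 6)
  x <- matrix(rnorm(4 * 9), 4)
  y <- bilstm_forward(mdl, x)
  swapped <- mdl
  swapped$params$fw <- mdl$params$bw
  swapped$params$bw <- mdl$params$fw
  h <- mdl$hidden_per_direction
  swapped$params$out$W <- mdl$params$out$W[, c(h + seq_len(h), seq_len(h))]
  y_rev <- bilstm_forward(swapped, x[, 9:1])
  expect_equal(y_rev, y[, 9:1], tolerance = 1e-12)
})

test_that("empty sequences and wrong channel counts are rejected", {
  mdl <- new_bilstm_model(4, 8, 3, seed = 1)
  expect_error(bilstm_forward(mdl, matrix(0, 4, 0)), "empty")
  expect_error(bilstm_forward(mdl, matrix(0, 5, 3)), "channels")
})

test_that("mse_loss computes the mean squared difference", {
  expect_equal(mse_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(mse_loss(matrix(3, 2, 2), matrix(1, 2, 2)), 4)
  expect_equal(mse_loss(matrix(c(1, 2), 1), matrix(0, 1, 2)), 2.5)
  expect_error(mse_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shapes differ")
})

test_that("standardizer round-trips and flags constant features", {
  set.seed(31)
  M <- rbind(rnorm(40, 5, 2), rnorm(40, -1, 0.1), rep(7, 40))
  s <- fit_standardizer(M)
  expect_equal(s$constant, c(FALSE, FALSE, TRUE))
  expect_equal(s$sd[3], 1)
  z <- standardize(s, M)
  expect_equal(rowMeans(z)[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(unstandardize(s, z), M, tolerance = 1e-9)
})

test_that("prepared targets are the low-band GFT, standardized on train only", {
  ds <- fx("ds2")
  basis <- select_low_band(fx("basis2"), k = 30)
  prep <- prepare_targets(basis, ds, snr_db = 20)
  tr_mat <- matrix(prep$y[, ds$split$train, ], 30)
  expect_lt(max(abs(rowMeans(tr_mat))), 1e-6)
  expect_equal(apply(tr_mat, 1, function(r) sqrt(mean(r^2))), rep(1, 30),
               tolerance = 1e-6)
  # de-standardized targets equal U_k^T s_true
  i <- ds$split$test[1]
  y_raw <- unstandardize(prep$y_std, prep$y[, i, ])
  expect_equal(y_raw, crossprod(basis$U_k, sample_source_movie(ds, i)),
               tolerance = 1e-9)
  # k = m: targets are the full GFT
  bm <- select_low_band(fx("basis2"), k = fx("ico2")$m)
  prep_m <- prepare_targets(bm, ds, snr_db = 20, standardize_data = FALSE)
  expect_equal(prep_m$y[, i, ], gft(bm, sample_source_movie(ds, i)),
               tolerance = 1e-9)
})

test_that("prepare_targets validates basis, band and SNR level", {
  ds <- fx("ds2")
  expect_error(prepare_targets(fx("basis2"), ds), "select the low band")
  b <- select_low_band(fx("basis2"), k = 10)
  expect_error(prepare_targets(b, ds, snr_db = 33), "no noisy EEG")
})

test_that("the low-band output layer shrinks the parameter count by ~m/k", {
  m <- 642; k <- 193
  mk <- new_bilstm_model(64, 256, k, init = "zero")
  mm <- new_bilstm_model(64, 256, m, init = "zero")
  pk <- count_parameters(mk, "output")
  pm <- count_parameters(mm, "output")
  expect_lt(pk, pm)
  expect_equal(pm / pk, m / k, tolerance = 1e-12)
  expect_lt(count_parameters(mk), count_parameters(mm))
})

test_that("training learns a linear teacher to high accuracy", {
  # s~' = M x exactly is representable; the network should drive val MSE
  # far below the target variance at toy size
  set.seed(41)
  n <- 6; k <- 4; Tn <- 15; N <- 60
  M <- matrix(rnorm(k * n), k)
  X <- array(rnorm(n * N * Tn), c(n, N, Tn))
  mdl <- new_bilstm_model(n, 32, k, seed = 1)
  state <- gftbilstm:::nadam_init(mdl$params)
  flat <- gftbilstm:::params_to_flat(mdl$params)
  Y <- array(0, c(k, N, Tn))
  for (t in seq_len(Tn)) Y[, , t] <- M %*% X[, , t]
  tr <- 1:48; va <- 49:60
  for (ep in 1:150) {
    ord <- sample(tr)
    for (s0 in seq(1, length(ord), by = 16)) {
      b <- ord[s0:min(s0 + 15, length(ord))]
      res <- gftbilstm:::batch_loss_grad(mdl, X[, b, , drop = FALSE],
                                         Y[, b, , drop = FALSE])
      st <- gftbilstm:::nadam_step(flat, res$grads, state, 1e-2)
      flat <- st$params; state <- st$state
      mdl$params <- gftbilstm:::flat_to_params(flat)
    }
  }
  val <- gftbilstm:::eval_loss(mdl, X, Y, va)
  expect_lt(val, 0.01 * mean(Y[, va, ]^2))
})

test_that("fitting on a small simulated dataset is seeded and reproducible", {
  ds <- fx("ds2")
  basis <- select_low_band(fx("basis2"), k = 30)
  fit1 <- gft_bilstm(ds, basis, snr_db = 40, hidden = 16, epochs = 2,
                     batch_size = 8, seed = 3)
  expect_equal(nrow(fit1$history), 2)
  expect_true(all(is.finite(fit1$history$val_mse)))
  fit2 <- gft_bilstm(ds, basis, snr_db = 40, hidden = 16, epochs = 2,
                     batch_size = 8, seed = 3)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params$out$W, fit2$params$out$W)
})

test_that("recovered sources lie in the low-band span and invert oracle coefficients", {
  ds <- fx("ds2")
  basis <- select_low_band(fx("basis2"), k = 30)
  fit <- gft_bilstm(ds, basis, snr_db = 40, hidden = 16, epochs = 1,
                    batch_size = 8, seed = 3)
  i <- ds$split$test[1]
  s_hat <- recover_sources(fit, basis, ds$samples[[i]]$x_noisy[["40"]])
  expect_equal(dim(s_hat), c(162, 40))
  proj <- basis$U_k %*% crossprod(basis$U_k, s_hat)
  expect_lt(max(abs(s_hat - proj)), 1e-9 * max(abs(s_hat)))
  # oracle coefficients (bypassing the network) reproduce the projection
  s_true <- sample_source_movie(ds, i)
  expect_equal(igft(basis, crossprod(basis$U_k, s_true)),
               basis$U_k %*% crossprod(basis$U_k, s_true), tolerance = 1e-12)
  # zero predicted coefficients give a zero source map
  expect_equal(igft(basis, matrix(0, 30, 4)), matrix(0, 162, 4))
})

test_that("recover_sources rejects a mismatched basis", {
  ds <- fx("ds2")
  basis <- select_low_band(fx("basis2"), k = 30)
  fit <- gft_bilstm(ds, basis, snr_db = 40, hidden = 16, epochs = 1,
                    batch_size = 8, seed = 3)
  expect_error(recover_sources(fit, select_low_band(fx("basis2"), k = 20),
                               ds$samples[[1]]$x_noisy[["40"]]),
               "does not match")
})

test_that("model S3 methods print, summarize, plot and expose coefficients", {
  ds <- fx("ds2")
  basis <- select_low_band(fx("basis2"), k = 30)
  fit <- gft_bilstm(ds, basis, snr_db = 40, hidden = 16, epochs = 1,
                    batch_size = 8, seed = 3)
  expect_output(print(fit), "BiLSTM")
  sm <- summary(fit)
  expect_output(print(sm), "parameters")
  co <- coef(fit)
  expect_named(co, c("forward", "backward", "W_s", "b_s"))
  expect_equal(dim(co$forward$W_f), c(8, 8 + 32))
  expect_equal(length(residuals(fit)), length(ds$split$val))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
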