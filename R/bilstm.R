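sigmoid <- function(z) 1 / (1 + exp(-z))

# gate row blocks within the stacked weight matrix: forget, input, candidate, output
gate_rows <- function(h) list(f = 1:h, i = h + 1:h, c = 2 * h + 1:h, o = 3 * h + 1:h)

#' Construct LSTM cell parameters
#'
#' Bundles the four gate weight matrices and bias vectors of one LSTM cell.
#' Each W is hidden x (hidden + input); the cell consumes the concatenation
#' [h_{t-1}, x_t] in that order.
#'
#' @param W_f,W_i,W_c,W_o Gate weight matrices (forget, input, candidate,
#'   output), each hidden x (hidden + input).
#' @param b_f,b_i,b_c,b_o Gate bias vectors of length hidden.
#' @return An object of class \code{lstm_cell}.
#' @export
lstm_cell_params <- function(W_f, W_i, W_c, W_o, b_f, b_i, b_c, b_o) {
  h <- nrow(W_f)
  dims_ok <- all(vapply(list(W_i, W_c, W_o), function(W)
    identical(dim(W), dim(W_f)), logical(1))) &&
    all(lengths(list(b_f, b_i, b_c, b_o)) == h)
  if (!dims_ok) stop("inconsistent gate parameter shapes")
  W <- rbind(W_f, W_i, W_c, W_o)
  b <- c(b_f, b_i, b_c, b_o)
  if (!all(is.finite(W)) || !all(is.finite(b)))
    stop("non-finite cell parameters")
  structure(list(W = W, b = b, hidden = h, input = ncol(W_f) - h),
            class = "lstm_cell")
}

cell_from_stacked <- function(W, b) {
  h <- nrow(W) / 4
  structure(list(W = W, b = b, hidden = h, input = ncol(W) - h),
            class = "lstm_cell")
}

unstack_cell <- function(cell) {
  g <- gate_rows(cell$hidden)
  list(W_f = cell$W[g$f, , drop = FALSE], W_i = cell$W[g$i, , drop = FALSE],
       W_c = cell$W[g$c, , drop = FALSE], W_o = cell$W[g$o, , drop = FALSE],
       b_f = cell$b[g$f], b_i = cell$b[g$i],
       b_c = cell$b[g$c], b_o = cell$b[g$o])
}

#' One LSTM cell step
#'
#' Applies the standard gated update to one time sample:
#' f_t = sigma(W_f [h_{t-1}, x_t] + b_f), i_t and o_t likewise,
#' c~_t = tanh(W_c [h_{t-1}, x_t] + b_c),
#' c_t = f_t * c_{t-1} + i_t * c~_t, h_t = o_t * tanh(c_t),
#' with * the element-wise product.
#'
#' @param cell An \code{lstm_cell}.
#' @param x_t Input vector of length \code{cell$input}.
#' @param h_prev,c_prev Previous hidden and memory states (length hidden).
#' @return List with \code{h}, \code{c}, and the gate activations
#'   \code{f}, \code{i}, \code{c_tilde}, \code{o}.
#' @export
lstm_cell_step <- function(cell, x_t, h_prev, c_prev) {
  stopifnot(inherits(cell, "lstm_cell"))
  if (length(x_t) != cell$input || length(h_prev) != cell$hidden ||
      length(c_prev) != cell$hidden)
    stop(sprintf("shape mismatch: input %d (expected %d), states %d/%d (expected %d)",
                 length(x_t), cell$input, length(h_prev), length(c_prev),
                 cell$hidden))
  z <- as.numeric(cell$W %*% c(h_prev, x_t) + cell$b)
  g <- gate_rows(cell$hidden)
  f <- sigmoid(z[g$f]); i <- sigmoid(z[g$i])
  ct <- tanh(z[g$c]);   o <- sigmoid(z[g$o])
  c_new <- f * c_prev + i * ct
  list(h = o * tanh(c_new), c = c_new, f = f, i = i, c_tilde = ct, o = o)
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

init_bilstm_params <- function(input_dim, hidden, k_out, seed) {
  with_seed(seed, {
    mk_cell <- function() {
      W <- glorot_uniform(4 * hidden, hidden + input_dim,
                          hidden + input_dim, hidden)
      b <- numeric(4 * hidden)
      b[gate_rows(hidden)$f] <- 1        # forget-gate bias 1: remember by default
      cell_from_stacked(W, b)
    }
    fw <- mk_cell(); bw <- mk_cell()
    W_s <- glorot_uniform(k_out, 2 * hidden, 2 * hidden, k_out)
    list(fw = fw, bw = bw, out = list(W = W_s, b = numeric(k_out)))
  })
}

#' Build an (untrained) BiLSTM coefficient regressor
#'
#' Constructs the network that maps an n-channel EEG sequence to a k_out
#' dimensional output sequence: a forward and a backward LSTM cell whose
#' per-time hidden states are concatenated and passed through an affine
#' output layer.
#'
#' @param input_dim Number of input channels n.
#' @param hidden Hidden size; interpreted per \code{hidden_interpretation}.
#' @param k_out Output dimension (the spectral band size k).
#' @param hidden_interpretation \code{"concatenated"} (default): hidden is
#'   the concatenated bidirectional dimension, so each direction gets
#'   hidden/2 units; \code{"per_direction"}: each direction gets hidden.
#' @param output_activation \code{"identity"} (default; graph Fourier
#'   coefficients are signed and unbounded) or \code{"sigmoid"}.
#' @param init \code{"glorot"} (seeded uniform) or \code{"zero"}.
#' @param seed Integer seed for the initialization.
#' @return An object of class \code{gft_bilstm} (untrained: empty history).
#' @export
new_bilstm_model <- function(input_dim, hidden, k_out,
                             hidden_interpretation = c("concatenated",
                                                       "per_direction"),
                             output_activation = c("identity", "sigmoid"),
                             init = c("glorot", "zero"), seed = 1L) {
  hidden_interpretation <- match.arg(hidden_interpretation)
  output_activation <- match.arg(output_activation)
  init <- match.arg(init)
  h <- if (hidden_interpretation == "concatenated") {
    if (hidden %% 2 != 0) stop("concatenated hidden size must be even")
    hidden / 2
  } else hidden
  params <- if (init == "zero") {
    zc <- cell_from_stacked(matrix(0, 4 * h, h + input_dim), numeric(4 * h))
    list(fw = zc, bw = cell_from_stacked(zc$W, zc$b),
         out = list(W = matrix(0, k_out, 2 * h), b = numeric(k_out)))
  } else init_bilstm_params(input_dim, h, k_out, seed)
  structure(list(params = params, input_dim = input_dim,
                 hidden_per_direction = h, k_out = k_out,
                 output_activation = output_activation,
                 standardizer = NULL, basis = NULL,
                 history = NULL, best_epoch = NA_integer_,
                 config = list(hidden = hidden,
                               hidden_interpretation = hidden_interpretation,
                               seed = seed)),
            class = "gft_bilstm")
}

# ---- batched sequence machinery (internal) --------------------------------

# X_bt: input array n x B x T. Returns hidden states H (h x B x T, indexed by
# real time t) plus caches needed for backpropagation through time.
# Hot loops live in src/bilstm_core.cpp; lstm_cell_step() above is the plain-R
# reference implementation of the same recurrence.
lstm_scan_batch <- function(cell, X_bt, reverse = FALSE, want_cache = TRUE) {
  cpp_lstm_scan(cell$W, cell$b, X_bt, reverse, want_cache)
}

# dH_ext: h x B x T gradient into h_t from the output layer. Returns stacked
# dW (4h x (h+n)), db (4h).
lstm_backprop_batch <- function(cell, X_bt, scan, dH_ext) {
  cpp_lstm_backprop(cell$W, X_bt, scan$H, scan$C, scan$gates, dH_ext,
                    scan$reverse)
}

bilstm_forward_batch <- function(model, X_bt, want_cache = FALSE) {
  B <- dim(X_bt)[2]; Tn <- dim(X_bt)[3]
  h <- model$hidden_per_direction
  fw <- lstm_scan_batch(model$params$fw, X_bt, reverse = FALSE,
                        want_cache = want_cache)
  bw <- lstm_scan_batch(model$params$bw, X_bt, reverse = TRUE,
                        want_cache = want_cache)
  Hcat <- rbind(matrix(fw$H, h, B * Tn), matrix(bw$H, h, B * Tn))
  Z <- model$params$out$W %*% Hcat + model$params$out$b
  Y <- if (model$output_activation == "sigmoid") sigmoid(Z) else Z
  list(Y = Y, Hcat = Hcat, fw = fw, bw = bw)   # Y: k x (B*T), t-blocks of B
}

#' BiLSTM forward pass over one sequence
#'
#' Runs the forward cell over t = 1..T and the backward cell over t = T..1,
#' concatenates the two hidden states aligned at each time sample, and
#' applies the output layer: y_t = activation(W_s [h_t (+) h'_t] + b_s).
#'
#' @param model A \code{gft_bilstm} model.
#' @param x n x T input sequence (n = \code{model$input_dim}).
#' @return k_out x T output sequence.
#' @export
bilstm_forward <- function(model, x) {
  stopifnot(inherits(model, "gft_bilstm"))
  x <- as.matrix(x)
  if (ncol(x) == 0) stop("empty sequence")
  if (nrow(x) != model$input_dim)
    stop(sprintf("input has %d channels, model expects %d",
                 nrow(x), model$input_dim))
  X_bt <- array(x, c(nrow(x), 1, ncol(x)))
  matrix(bilstm_forward_batch(model, X_bt)$Y, model$k_out, ncol(x))
}

#' Mean squared error
#'
#' Mean of squared element-wise differences over all entries.
#' @param pred,target Conforming numeric arrays.
#' @return Nonnegative scalar.
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target shapes differ")
  mean((pred - target)^2)
}

# ---- standardization ------------------------------------------------------

#' Fit a per-feature standardizer
#'
#' Means and standard deviations per row of a features x observations
#' matrix. Features with zero variance get sd = 1 and are flagged.
#' @param M features x observations matrix.
#' @return Object of class \code{standardizer}: \code{mean}, \code{sd},
#'   \code{constant} (logical flags).
#' @export
fit_standardizer <- function(M) {
  mu <- rowMeans(M)
  sd <- sqrt(rowMeans((M - mu)^2))
  constant <- sd == 0
  sd[constant] <- 1
  structure(list(mean = mu, sd = sd, constant = constant),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s A \code{standardizer}.
#' @param x Matrix/array whose first dimension matches the features.
#' @export
standardize <- function(s, x) {
  dm <- dim(x)
  x <- (x - s$mean) / s$sd      # first-dim recycling over columns/slices
  dim(x) <- dm
  x
}

#' @rdname fit_standardizer
#' @export
unstandardize <- function(s, x) {
  dm <- dim(x)
  x <- x * s$sd + s$mean
  dim(x) <- dm
  x
}

#' Prepare standardized training pairs
#'
#' Computes the low-band graph Fourier coefficient targets
#' s~' = U_k^T s_true per time sample for every trial, assembles the EEG
#' inputs at one SNR level, and fits per-feature standardizers on the
#' training split only (applied to all splits).
#'
#' @param basis A \code{spectral_basis} with the low band selected.
#' @param dataset An \code{esi_dataset}.
#' @param snr_db Which stored SNR level to use as input (default: first).
#' @param standardize_data Standardize inputs and targets (default TRUE).
#' @param target_scaling How target coefficients are scaled:
#'   \code{"per_feature"} (each coefficient to unit variance),
#'   \code{"global"} (per-feature centering, one pooled scale — preserves
#'   the natural energy ordering of the spectral coefficients), or
#'   \code{"none"}.
#' @return List with \code{x} (n x N x T), \code{y} (k x N x T), the fitted
#'   \code{x_std} and \code{y_std}, and \code{split}.
#' @export
prepare_targets <- function(basis, dataset, snr_db = dataset$snr_db[1],
                            standardize_data = TRUE,
                            target_scaling = c("per_feature", "global",
                                               "none")) {
  target_scaling <- match.arg(target_scaling)
  stopifnot(inherits(basis, "spectral_basis"), inherits(dataset, "esi_dataset"))
  if (is.null(basis$k)) stop("select the low band first (select_low_band)")
  if (basis$m != dataset$m)
    stop(sprintf("basis m = %d does not match dataset m = %d",
                 basis$m, dataset$m))
  key <- as.character(snr_db)
  if (!key %in% names(dataset$samples[[1]]$x_noisy))
    stop(sprintf("dataset has no noisy EEG at %s dB (available: %s)",
                 key, paste(names(dataset$samples[[1]]$x_noisy), collapse = ", ")))
  N <- length(dataset$samples); Tn <- dataset$T_samples
  k <- basis$k; n <- dataset$n
  X <- array(0, c(n, N, Tn)); Y <- array(0, c(k, N, Tn))
  for (i in seq_len(N)) {
    smp <- dataset$samples[[i]]
    X[, i, ] <- smp$x_noisy[[key]]
    Y[, i, ] <- crossprod(basis$U_k[smp$members + 1, , drop = FALSE],
                          smp$amplitudes)
  }
  tr <- dataset$split$train
  x_std <- fit_standardizer(matrix(X[, tr, ], n))
  y_std <- fit_standardizer(matrix(Y[, tr, ], k))
  if (target_scaling == "global") {
    y_std$sd[] <- sqrt(mean((matrix(Y[, tr, ], k) - y_std$mean)^2))
    y_std$constant[] <- FALSE
  } else if (target_scaling == "none") {
    y_std$mean[] <- 0; y_std$sd[] <- 1
  }
  if (!standardize_data) {
    x_std$mean[] <- 0; x_std$sd[] <- 1
    y_std$mean[] <- 0; y_std$sd[] <- 1
  }
  list(x = standardize(x_std, X), y = standardize(y_std, Y),
       x_std = x_std, y_std = y_std, split = dataset$split,
       k = k, n = n, T_samples = Tn, snr_db = snr_db)
}

# ---- Nadam optimizer (Nesterov-accelerated adaptive moments) --------------

nadam_init <- function(params) {
  flat <- list(fw_W = params$fw$W, fw_b = params$fw$b,
               bw_W = params$bw$W, bw_b = params$bw$b,
               out_W = params$out$W, out_b = params$out$b)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0)
}

nadam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  for (nm in names(state$m)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    m_hat <- state$m[[nm]] / (1 - beta1^(t + 1))
    v_hat <- state$v[[nm]] / (1 - beta2^t)
    upd <- lr * (beta1 * m_hat + (1 - beta1) * gr / (1 - beta1^t)) /
      (sqrt(v_hat) + eps)
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

params_to_flat <- function(params) {
  list(fw_W = params$fw$W, fw_b = params$fw$b,
       bw_W = params$bw$W, bw_b = params$bw$b,
       out_W = params$out$W, out_b = params$out$b)
}

flat_to_params <- function(flat) {
  list(fw = cell_from_stacked(flat$fw_W, flat$fw_b),
       bw = cell_from_stacked(flat$bw_W, flat$bw_b),
       out = list(W = flat$out_W, b = flat$out_b))
}

batch_loss_grad <- function(model, X_bt, Y_bt) {
  k <- model$k_out
  B <- dim(X_bt)[2]; Tn <- dim(X_bt)[3]
  fwd <- bilstm_forward_batch(model, X_bt, want_cache = TRUE)
  Yt <- matrix(Y_bt, k, B * Tn)
  diff <- fwd$Y - Yt
  loss <- mean(diff^2)
  dY <- 2 * diff / length(diff)
  if (model$output_activation == "sigmoid") dY <- dY * fwd$Y * (1 - fwd$Y)
  h <- model$hidden_per_direction
  dW_s <- tcrossprod(dY, fwd$Hcat)
  db_s <- rowSums(dY)
  dHcat <- crossprod(model$params$out$W, dY)
  dHf <- array(dHcat[seq_len(h), , drop = FALSE], c(h, B, Tn))
  dHb <- array(dHcat[h + seq_len(h), , drop = FALSE], c(h, B, Tn))
  gf <- lstm_backprop_batch(model$params$fw, X_bt, fwd$fw, dHf)
  gb <- lstm_backprop_batch(model$params$bw, X_bt, fwd$bw, dHb)
  list(loss = loss,
       grads = list(fw_W = gf$dW, fw_b = gf$db,
                    bw_W = gb$dW, bw_b = gb$db,
                    out_W = dW_s, out_b = db_s))
}

eval_loss <- function(model, X, Y, idx, batch_size = 64) {
  total <- 0; count <- 0
  for (start in seq(1, length(idx), by = batch_size)) {
    b <- idx[start:min(start + batch_size - 1, length(idx))]
    X_bt <- X[, b, , drop = FALSE]; Y_bt <- Y[, b, , drop = FALSE]
    fwd <- bilstm_forward_batch(model, X_bt)
    Yt <- matrix(Y_bt, dim(Y_bt)[1], length(b) * dim(Y_bt)[3])
    total <- total + sum((fwd$Y - Yt)^2)
    count <- count + length(Yt)
  }
  total / count
}

#' Fit the graph-spectral BiLSTM source-imaging model
#'
#' The main fitting function. Targets are the low-band graph Fourier
#' coefficients of the true source signal (s~' = U_k^T s); inputs are the
#' noisy EEG sequences. The bidirectional LSTM is trained by minimizing the
#' mean squared error on the training split with the Nadam optimizer,
#' validation MSE is tracked per epoch, and the parameters of the best
#' validation epoch are returned. Source maps are recovered from predicted
#' coefficients by the truncated inverse graph Fourier transform
#' (\code{\link{predict.gft_bilstm}} / \code{\link{recover_sources}}).
#'
#' @param dataset An \code{esi_dataset} with nonempty train and val splits.
#' @param basis A \code{spectral_basis} with the low band selected
#'   (\code{\link{select_low_band}}).
#' @param snr_db Which stored SNR level to train on.
#' @param hidden Hidden size (concatenated bidirectional dimension by
#'   default; see \code{\link{new_bilstm_model}}).
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size (trials per batch).
#' @param learning_rate Nadam learning rate.
#' @param patience Early-stopping patience on validation MSE (epochs).
#' @param output_activation \code{"identity"} or \code{"sigmoid"}.
#' @param hidden_interpretation See \code{\link{new_bilstm_model}}.
#' @param standardize_data Standardize inputs/targets (fit on train only).
#' @param target_scaling Target coefficient scaling
#'   (\code{\link{prepare_targets}}); default \code{"global"}, which keeps
#'   the loss weighted by each coefficient's natural share of signal
#'   energy instead of inflating the near-noise fine-structure
#'   coefficients.
#' @param seed Integer seed covering initialization and batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return A fitted object of class \code{gft_bilstm}; see
#'   \code{\link{new_bilstm_model}} for the fields, plus \code{history}
#'   (per-epoch train/val MSE), \code{best_epoch}, \code{standardizer} and
#'   the embedded low-band basis.
#' @export
gft_bilstm <- function(dataset, basis, snr_db = dataset$snr_db[1],
                       hidden = 256, epochs = 40, batch_size = 32,
                       learning_rate = 1e-2, patience = 12,
                       output_activation = c("identity", "sigmoid"),
                       hidden_interpretation = c("concatenated",
                                                 "per_direction"),
                       standardize_data = TRUE, target_scaling = "global",
                       seed = 1L, verbose = FALSE) {
  output_activation <- match.arg(output_activation)
  hidden_interpretation <- match.arg(hidden_interpretation)
  if (!length(dataset$split$train) || !length(dataset$split$val))
    stop("dataset needs nonempty train and val splits")
  prep <- prepare_targets(basis, dataset, snr_db, standardize_data,
                          target_scaling)
  model <- new_bilstm_model(prep$n, hidden, prep$k,
                            hidden_interpretation = hidden_interpretation,
                            output_activation = output_activation,
                            init = "glorot", seed = derive_seed(seed, 0L))
  state <- nadam_init(model$params)
  flat <- params_to_flat(model$params)
  tr <- prep$split$train; va <- prep$split$val
  history <- data.frame(epoch = integer(), train_mse = numeric(),
                        val_mse = numeric())
  best_val <- Inf; best_flat <- flat; best_epoch <- 0L; wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 1000L + ep), sample(tr))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      b <- ord[start:min(start + batch_size - 1, length(ord))]
      res <- batch_loss_grad(model, prep$x[, b, , drop = FALSE],
                             prep$y[, b, , drop = FALSE])
      if (!is.finite(res$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      st <- nadam_step(flat, res$grads, state, learning_rate)
      flat <- st$params; state <- st$state
      model$params <- flat_to_params(flat)
      ep_loss <- ep_loss + res$loss; nb <- nb + 1
    }
    val <- eval_loss(model, prep$x, prep$y, va)
    history <- rbind(history, data.frame(epoch = ep, train_mse = ep_loss / nb,
                                         val_mse = val))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss / nb, val))
    if (val < best_val - 1e-12) {
      best_val <- val; best_flat <- flat; best_epoch <- ep; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  model$params <- flat_to_params(best_flat)
  model$history <- history
  model$best_epoch <- best_epoch
  model$standardizer <- list(x = prep$x_std, y = prep$y_std)
  model$basis <- list(U_k = basis$U_k, k = basis$k, m = basis$m,
                      fingerprint = basis_fingerprint(basis))
  model$config <- utils::modifyList(model$config, list(
    epochs = epochs, batch_size = batch_size, learning_rate = learning_rate,
    patience = patience, optimizer = "nadam", snr_db = snr_db, seed = seed,
    standardize = standardize_data))
  # per-trial validation residual MSE (coefficient domain), for residuals()
  model$val_trial_mse <- vapply(va, function(i)
    eval_loss(model, prep$x, prep$y, i), numeric(1))
  model
}

#' Fingerprint of a spectral basis
#'
#' Hash of the eigenvalue sequence, used to detect model/basis mismatch at
#' prediction time.
#' @param basis A \code{spectral_basis}.
#' @return Character scalar.
#' @export
basis_fingerprint <- function(basis) {
  v <- signif(basis$eigenvalues, 10)
  # order-sensitive polynomial hash over the rounded eigenvalues
  acc <- 0
  for (x in v) acc <- (acc * 31 + sum(utils::head(strtoi(
    charToRaw(format(x, digits = 10)), 16L), 20))) %% 2147483647
  sprintf("%d-%d", basis$m, acc)
}

#' Recover source maps from EEG with a trained model
#'
#' Standardizes the EEG, runs the BiLSTM, de-standardizes the predicted
#' low-band coefficients, and applies the truncated inverse graph Fourier
#' transform: s_hat = U_k s_hat'.
#'
#' @param model A trained \code{gft_bilstm}.
#' @param basis The \code{spectral_basis} used in training (checked by
#'   fingerprint and band size).
#' @param x n x T EEG matrix.
#' @return m x T source-signal matrix.
#' @export
recover_sources <- function(model, basis, x) {
  stopifnot(inherits(model, "gft_bilstm"))
  if (basis$k != model$k_out)
    stop(sprintf("basis band k = %s does not match model k_out = %d",
                 basis$k %||% "<unset>", model$k_out))
  if (!is.null(model$basis$fingerprint) &&
      model$basis$fingerprint != basis_fingerprint(basis))
    stop("spectral basis fingerprint mismatch: model was trained on a different basis")
  predict(model, x)
}

#' Total number of trainable parameters
#' @param model A \code{gft_bilstm}.
#' @param component \code{"all"} or \code{"output"} (output layer only).
#' @return Integer count.
#' @export
count_parameters <- function(model, component = c("all", "output")) {
  component <- match.arg(component)
  p <- model$params
  n_out <- length(p$out$W) + length(p$out$b)
  if (component == "output") return(n_out)
  length(p$fw$W) + length(p$fw$b) + length(p$bw$W) + length(p$bw$b) + n_out
}

# ---- S3 methods -----------------------------------------------------------

#' Predict source activity (or coefficients) from EEG
#'
#' @param object A trained \code{gft_bilstm}.
#' @param newdata n x T EEG matrix.
#' @param type \code{"sources"}: m x T source map via the truncated inverse
#'   transform; \code{"coefficients"}: k x T de-standardized low-band
#'   coefficients.
#' @param ... Unused.
#' @export
predict.gft_bilstm <- function(object, newdata,
                               type = c("sources", "coefficients"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (nrow(x) != object$input_dim)
    stop(sprintf("EEG has %d channels, model expects %d",
                 nrow(x), object$input_dim))
  if (!is.null(object$standardizer)) x <- standardize(object$standardizer$x, x)
  co <- bilstm_forward(object, x)
  if (!is.null(object$standardizer)) co <- unstandardize(object$standardizer$y, co)
  if (type == "coefficients") return(co)
  if (is.null(object$basis))
    stop("model has no embedded basis; train it first or use type = 'coefficients'")
  object$basis$U_k %*% co
}

#' @export
print.gft_bilstm <- function(x, ...) {
  cat(sprintf(
    "Graph-spectral BiLSTM source-imaging model\n  input channels: %d, hidden: %d per direction, output band k: %d\n",
    x$input_dim, x$hidden_per_direction, x$k_out))
  if (!is.null(x$history) && nrow(x$history)) {
    cat(sprintf("  trained %d epoch(s); best val MSE %.5g at epoch %d\n",
                nrow(x$history), min(x$history$val_mse), x$best_epoch))
  } else cat("  (untrained)\n")
  invisible(x)
}

#' @export
summary.gft_bilstm <- function(object, ...) {
  out <- list(
    input_dim = object$input_dim,
    hidden_per_direction = object$hidden_per_direction,
    k_out = object$k_out,
    n_parameters = count_parameters(object),
    n_parameters_output = count_parameters(object, "output"),
    output_activation = object$output_activation,
    best_epoch = object$best_epoch,
    best_val_mse = if (!is.null(object$history) && nrow(object$history))
      min(object$history$val_mse) else NA_real_,
    config = object$config)
  class(out) <- "summary.gft_bilstm"
  out
}

#' @export
print.summary.gft_bilstm <- function(x, ...) {
  cat("Graph-spectral BiLSTM source-imaging model\n")
  cat(sprintf("  n = %d input channels -> k = %d spectral outputs (hidden %d/direction)\n",
              x$input_dim, x$k_out, x$hidden_per_direction))
  cat(sprintf("  parameters: %d total, %d in the output layer\n",
              x$n_parameters, x$n_parameters_output))
  cat(sprintf("  output activation: %s\n", x$output_activation))
  if (!is.na(x$best_val_mse))
    cat(sprintf("  best validation MSE %.5g (epoch %d)\n",
                x$best_val_mse, x$best_epoch))
  invisible(x)
}

#' @export
coef.gft_bilstm <- function(object, ...) {
  list(forward = unstack_cell(object$params$fw),
       backward = unstack_cell(object$params$bw),
       W_s = object$params$out$W, b_s = object$params$out$b)
}

#' @export
plot.gft_bilstm <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history)) stop("untrained model")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE (standardized coefficients)",
                    main = "BiLSTM training history", log = "y", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.gft_bilstm <- function(object, ...) {
  if (is.null(object$val_trial_mse)) stop("untrained model")
  object$val_trial_mse
}
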