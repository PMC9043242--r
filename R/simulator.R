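#' Default autoregressive source dynamics
#'
#' Coefficients of the stable 5th-order autoregressive model used for source
#' waveforms: two damped oscillations at 10 Hz and 23 Hz (pole radii 0.95
#' and 0.90 at a 100 Hz sampling rate) plus a real pole at 0.75; companion
#' spectral radius 0.95.
#' @export
ar5_default_coeffs <- function() {
  c(2.512732, -3.381326, 2.993139, -1.817536, 0.548269)
}

ar_spectral_radius <- function(coeffs) {
  p <- length(coeffs)
  A <- rbind(coeffs, cbind(diag(p - 1), 0))
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Autoregressive source waveform
#'
#' Simulates s_t = sum_i a_i s_{t-i} + e_t with Gaussian innovations, zero
#' initial state and a discarded burn-in so the returned samples are from
#' the stationary regime. Deterministic given \code{rng_seed}.
#'
#' @param T_samples Number of samples to return.
#' @param fs_hz Sampling rate (metadata only; the coefficients are defined
#'   per sample).
#' @param coeffs AR coefficients (default \code{\link{ar5_default_coeffs}}).
#' @param noise_sd Innovation standard deviation.
#' @param rng_seed Integer seed.
#' @param burn_in Samples discarded before the output window (>= 200).
#' @return Numeric vector of length \code{T_samples}.
#' @export
ar_waveform <- function(T_samples, fs_hz = 100, coeffs = ar5_default_coeffs(),
                        noise_sd = 1, rng_seed = 1L, burn_in = 200L) {
  stopifnot(T_samples >= 1, burn_in >= 200)
  if (any(coeffs != 0)) {
    r <- ar_spectral_radius(coeffs)
    if (r >= 1)
      stop(sprintf("unstable AR coefficients: companion spectral radius %.4f >= 1", r))
  }
  n <- T_samples + burn_in
  e <- with_seed(rng_seed, stats::rnorm(n, sd = noise_sd))
  s <- if (all(coeffs == 0)) e
       else as.numeric(stats::filter(e, coeffs, method = "recursive"))
  s[(burn_in + 1):n]
}

#' Sample disjoint source patches
#'
#' Draws patch centers uniformly without replacement and forms each patch as
#' the center plus its level-1 mesh neighbors. Draws are repeated (bounded)
#' until all patches are vertex-disjoint.
#'
#' @param graph A \code{source_graph}.
#' @param n_patches Number of patches.
#' @param rng_seed Integer seed.
#' @param neighbor_scale Amplitude of neighbor vertices relative to the
#'   center, in (0, 1]; recorded in the patch object for rendering.
#' @param max_retries Resampling budget for the disjointness constraint.
#' @return An object of class \code{patch_spec}: list with \code{centers}
#'   (0-based vertex ids), \code{members} (list of 0-based id vectors,
#'   center first) and \code{neighbor_scale}.
#' @export
sample_patches <- function(graph, n_patches = 1, rng_seed = 1L,
                           neighbor_scale = 0.5, max_retries = 100L) {
  stopifnot(inherits(graph, "source_graph"), n_patches >= 1)
  m <- nrow(graph$adjacency)
  for (try in seq_len(max_retries)) {
    centers <- with_seed(derive_seed(rng_seed, try - 1L),
                         sample.int(m, n_patches)) - 1L
    members <- lapply(centers, function(ct) c(ct, neighbors_of(graph, ct)))
    if (n_patches == 1 || !anyDuplicated(unlist(members)))
      return(structure(list(centers = centers, members = members,
                            neighbor_scale = neighbor_scale),
                       class = "patch_spec"))
  }
  stop(sprintf("could not draw %d disjoint patches in %d attempts",
               n_patches, max_retries))
}

#' Render patch activations as a source-space signal
#'
#' Each patch center carries its waveform at full scale; its level-1
#' neighbors carry the same waveform at \code{neighbor_scale} (the adjacent
#' sources are activated at lower strength than the center); all other
#' vertices are exactly zero.
#'
#' @param space A \code{source_space} (for m).
#' @param patch A \code{patch_spec}.
#' @param waveforms Matrix with one row per patch (or vector for one patch).
#' @param neighbor_scale Override of the patch's neighbor scale, in (0, 1].
#' @return m x T matrix of source amplitudes.
#' @export
render_sources <- function(space, patch, waveforms,
                           neighbor_scale = patch$neighbor_scale) {
  stopifnot(inherits(patch, "patch_spec"))
  if (neighbor_scale <= 0 || neighbor_scale > 1)
    stop("neighbor_scale must be in (0, 1]")
  if (is.vector(waveforms)) waveforms <- matrix(waveforms, nrow = 1)
  if (nrow(waveforms) != length(patch$centers))
    stop("need exactly one waveform per patch")
  s <- matrix(0, space$m, ncol(waveforms))
  for (p in seq_along(patch$centers)) {
    mem <- patch$members[[p]]
    scale <- c(1, rep(neighbor_scale, length(mem) - 1))
    s[mem + 1, ] <- s[mem + 1, ] + scale %o% waveforms[p, ]
  }
  s
}

#' Add sensor noise at an exact signal-to-noise ratio
#'
#' Adds i.i.d. zero-mean Gaussian noise to the clean EEG, globally rescaled
#' so the realized SNR = 10 log10(P_signal / P_noise) equals \code{snr_db}
#' exactly, where the powers are mean squares over all channels and samples
#' jointly.
#'
#' @param x_clean n x T clean EEG.
#' @param snr_db Target SNR in dB.
#' @param rng_seed Integer seed.
#' @return n x T noisy EEG.
#' @export
add_noise_snr <- function(x_clean, snr_db, rng_seed = 1L) {
  x_clean <- as.matrix(x_clean)
  p_sig <- mean(x_clean^2)
  if (p_sig == 0) stop("clean signal has zero power; SNR undefined")
  eps <- with_seed(rng_seed, stats::rnorm(length(x_clean)))
  eps <- matrix(eps, nrow(x_clean), ncol(x_clean))
  p_target <- p_sig / 10^(snr_db / 10)
  eps <- eps * sqrt(p_target / mean(eps^2))
  x_clean + eps
}

largest_remainder_split <- function(n, fractions) {
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-9)
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1
  }
  as.integer(sizes)
}

#' Simulate a patch-source EEG dataset
#'
#' Generates trials of extended source activation: patch sampling (every
#' trial has \code{n_patches} disjoint patches), AR(5) waveforms at
#' \code{fs_hz}, forward projection through the lead field, and additive
#' white sensor noise mixed at each requested SNR level. Single-source
#' protocol: with \code{n_samples = NULL} every vertex serves as the patch
#' center in turn; otherwise a seeded subsample of distinct centers of size
#' \code{n_samples} is used (for scaled-down runs). Multi-source protocol
#' (\code{n_patches > 1}): centers are drawn at random per trial.
#'
#' Ground truth is stored sparsely (patch membership + member amplitudes);
#' use \code{\link{sample_source_movie}} for the dense m x T source signal.
#'
#' @param space,graph,leadfield Source space, its graph, and the lead field.
#' @param n_samples Number of trials (NULL = one per vertex, single-source
#'   mode only).
#' @param n_patches Patches per trial.
#' @param snr_db Numeric vector of SNR levels (dB); each trial carries one
#'   noisy EEG per level.
#' @param T_samples,fs_hz Trial length in samples and sampling rate (Hz).
#' @param neighbor_scale Neighbor-to-center amplitude ratio in (0, 1].
#' @param fractions Train/validation/test fractions (sum to 1); sizes by
#'   largest-remainder rounding, membership seeded.
#' @param ar_coeffs AR coefficients for the source dynamics.
#' @param seed Global integer seed; all per-trial seeds derive from it.
#' @return An object of class \code{esi_dataset}: list with \code{samples}
#'   (each: \code{patch}, \code{amplitudes} (|members| x T), \code{x_clean},
#'   \code{x_noisy} named list by SNR, \code{seed}), \code{split} (list of
#'   index vectors train/val/test), and the generating configuration.
#' @export
make_dataset <- function(space, graph, leadfield, n_samples = NULL,
                         n_patches = 1, snr_db = c(20, 30, 40),
                         T_samples = 100, fs_hz = 100, neighbor_scale = 0.5,
                         fractions = c(train = 0.7, val = 0.15, test = 0.15),
                         ar_coeffs = ar5_default_coeffs(), seed = 1L) {
  stopifnot(inherits(space, "source_space"), inherits(graph, "source_graph"),
            inherits(leadfield, "lead_field"))
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0))
    stop("split fractions must be positive and sum to 1")
  m <- space$m
  if (is.null(n_samples)) {
    if (n_patches != 1) stop("exhaustive center enumeration is single-source only")
    centers <- seq_len(m) - 1L
  } else if (n_patches == 1) {
    if (n_samples > m) stop("more single-source trials than vertices")
    centers <- with_seed(derive_seed(seed, 1L), sample.int(m, n_samples)) - 1L
  } else {
    centers <- rep(NA_integer_, n_samples)   # drawn per trial
  }
  n_tr <- length(centers)
  sizes <- largest_remainder_split(n_tr, fractions)
  if (any(sizes == 0)) stop("too few samples for non-empty train/val/test splits")
  perm <- with_seed(derive_seed(seed, 2L), sample.int(n_tr))
  split <- list(train = sort(perm[seq_len(sizes[1])]),
                val   = sort(perm[sizes[1] + seq_len(sizes[2])]),
                test  = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))

  H <- leadfield$gain
  samples <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    s_i <- derive_seed(seed, 100L + i)
    patch <- if (n_patches == 1) {
      ct <- centers[i]
      structure(list(centers = ct,
                     members = list(c(ct, neighbors_of(graph, ct))),
                     neighbor_scale = neighbor_scale),
                class = "patch_spec")
    } else {
      sample_patches(graph, n_patches, rng_seed = s_i,
                     neighbor_scale = neighbor_scale)
    }
    wf <- t(vapply(seq_len(n_patches),
                   function(p) ar_waveform(T_samples, fs_hz, ar_coeffs,
                                           rng_seed = derive_seed(s_i, p)),
                   numeric(T_samples)))
    members <- unlist(patch$members)
    amp <- matrix(0, length(members), T_samples)
    off <- 0
    for (p in seq_along(patch$members)) {
      npv <- length(patch$members[[p]])
      amp[off + seq_len(npv), ] <-
        c(1, rep(neighbor_scale, npv - 1)) %o% wf[p, ]
      off <- off + npv
    }
    x_clean <- H[, members + 1, drop = FALSE] %*% amp
    x_noisy <- lapply(seq_along(snr_db), function(j)
      add_noise_snr(x_clean, snr_db[j], rng_seed = derive_seed(s_i, 50L + j)))
    names(x_noisy) <- as.character(snr_db)
    samples[[i]] <- list(patch = patch, members = members, amplitudes = amp,
                         x_clean = x_clean, x_noisy = x_noisy, seed = s_i)
  }
  structure(list(samples = samples, split = split, snr_db = snr_db,
                 m = m, n = nrow(H), T_samples = T_samples, fs_hz = fs_hz,
                 n_patches = n_patches, neighbor_scale = neighbor_scale,
                 fractions = fractions, seed = seed),
            class = "esi_dataset")
}

#' @export
print.esi_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated ESI dataset: %d trials (%d/%d/%d train/val/test), %d patch(es)/trial,\n  m = %d sources, n = %d electrodes, T = %d @ %g Hz, SNR dB: %s\n",
    length(x$samples), length(x$split$train), length(x$split$val),
    length(x$split$test), x$n_patches, x$m, x$n, x$T_samples, x$fs_hz,
    paste(x$snr_db, collapse = "/")))
  invisible(x)
}

#' Dense source movie of one simulated trial
#'
#' Expands the sparse ground-truth storage of \code{\link{make_dataset}}
#' into the full m x T source signal.
#' @param dataset An \code{esi_dataset}.
#' @param i Trial index.
#' @return m x T matrix.
#' @export
sample_source_movie <- function(dataset, i) {
  smp <- dataset$samples[[i]]
  s <- matrix(0, dataset$m, dataset$T_samples)
  s[smp$members + 1, ] <- smp$amplitudes
  s
}

#' Active-vertex mask of one simulated trial
#' @param dataset An \code{esi_dataset}.
#' @param i Trial index.
#' @return Logical vector of length m (TRUE for patch member vertices).
#' @export
sample_active_mask <- function(dataset, i) {
  mask <- logical(dataset$m)
  mask[dataset$samples[[i]]$members + 1] <- TRUE
  mask
}
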