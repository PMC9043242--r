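#' ROC AUC for active-vertex detection
#'
#' Scores each vertex by the maximum absolute reconstructed amplitude over
#' time (or by the amplitude at the global energy-peak sample) and computes
#' the probability that a randomly chosen active vertex outscores a
#' randomly chosen inactive one, ties counted one half (the Mann-Whitney
#' form of the area under the ROC curve).
#'
#' @param true_active Logical mask of length m (at least one TRUE and one
#'   FALSE).
#' @param estimate m x T reconstructed source signal (reduced to per-vertex
#'   scores by the \code{score} rule), or a plain length-m vector of
#'   already-computed scores (used as given).
#' @param score \code{"max_abs"} (default) or \code{"peak_time"} (absolute
#'   amplitude at the time sample of maximum total energy).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(true_active, estimate, score = c("max_abs", "peak_time")) {
  score <- match.arg(score)
  true_active <- as.logical(true_active)
  if (!any(true_active) || all(true_active))
    stop("mask must contain at least one active and one inactive vertex")
  if (is.matrix(estimate)) {
    if (nrow(estimate) != length(true_active))
      stop("estimate rows must match the mask length")
    s <- if (score == "max_abs") apply(abs(estimate), 1, max)
         else abs(estimate[, which.max(colSums(estimate^2))])
  } else {
    if (length(estimate) != length(true_active))
      stop("estimate rows must match the mask length")
    s <- as.numeric(estimate)
  }
  r <- rank(s, ties.method = "average")
  n_pos <- sum(true_active); n_neg <- sum(!true_active)
  (sum(r[true_active]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# geodesic hop distances from a set of vertices (0-based), by BFS
hop_distances <- function(adjacency, from0) {
  m <- nrow(adjacency)
  d <- rep(Inf, m)
  d[from0 + 1] <- 0
  frontier <- from0 + 1
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nb <- which(colSums(adjacency[frontier, , drop = FALSE] != 0) > 0)
    nb <- nb[!is.finite(d[nb])]
    d[nb] <- lev
    frontier <- nb
  }
  d
}

# P strongest spatially-distinct local maxima of a vertex score (1-based ids)
find_peaks <- function(graph, score, n_peaks, distinct_hops = 2) {
  A <- graph$adjacency
  ord <- order(score, decreasing = TRUE)
  peaks <- integer(0)
  for (v in ord) {
    nb <- which(A[v, ] != 0)
    if (any(score[nb] > score[v])) next           # not a local maximum
    if (length(peaks)) {
      d <- hop_distances(A, peaks - 1L)
      if (d[v] < distinct_hops) next              # too close to a chosen peak
    }
    peaks <- c(peaks, v)
    if (length(peaks) == n_peaks) break
  }
  if (length(peaks) < n_peaks) {
    # degenerate landscapes: fall back to the globally strongest remaining
    extra <- setdiff(ord, peaks)
    peaks <- c(peaks, extra[seq_len(n_peaks - length(peaks))])
  }
  peaks
}

#' Localization error in millimetres
#'
#' Distance between true and estimated peak source locations. The estimate
#' is reduced to a spatial profile at \code{t_eval} (default: the time
#' sample of maximum total energy), its P strongest spatially-distinct
#' local maxima are taken as estimated peaks (P = number of true centers,
#' distinctness radius in mesh hops), and true centers are matched
#' one-to-one to estimated peaks greedily by increasing distance. The
#' reported LE is the mean distance over true centers.
#'
#' @param space A \code{source_space}.
#' @param graph The matching \code{source_graph} (for local maxima).
#' @param true_centers 0-based vertex indices of the true patch centers.
#' @param estimate m x T reconstructed source signal.
#' @param t_eval Time index, or \code{"peak"} for the global energy peak.
#' @param distinct_hops Minimum mesh-hop separation between reported peaks.
#' @return LE in mm. An identically-zero estimate returns the mesh diameter
#'   with a warning.
#' @export
localization_error <- function(space, graph, true_centers, estimate,
                               t_eval = "peak", distinct_hops = 2) {
  stopifnot(inherits(space, "source_space"), length(true_centers) >= 1)
  est <- as.matrix(estimate)
  if (all(est == 0)) {
    warning("estimate is identically zero; reporting the mesh diameter")
    return(mesh_diameter(space))
  }
  ti <- if (identical(t_eval, "peak")) which.max(colSums(est^2)) else t_eval
  profile <- abs(est[, ti])
  P <- length(true_centers)
  peaks <- find_peaks(graph, profile, P, distinct_hops) - 1L   # 0-based
  true_pos <- space$positions[true_centers + 1, , drop = FALSE]
  est_pos <- space$positions[peaks + 1, , drop = FALSE]
  D <- as.matrix(stats::dist(rbind(true_pos, est_pos)))[seq_len(P),
                                                        P + seq_len(P),
                                                        drop = FALSE]
  # greedy one-to-one matching by increasing distance
  matched <- numeric(P)
  used_t <- logical(P); used_e <- logical(P)
  for (step in seq_len(P)) {
    Dm <- D
    Dm[used_t, ] <- Inf; Dm[, used_e] <- Inf
    ij <- arrayInd(which.min(Dm), dim(Dm))
    matched[ij[1]] <- D[ij[1], ij[2]]
    used_t[ij[1]] <- TRUE; used_e[ij[2]] <- TRUE
  }
  mean(matched)
}

mesh_diameter <- function(space) {
  max(stats::dist(space$positions))
}

#' Run the full evaluation grid
#'
#' Evaluates the trained graph-spectral BiLSTM and the linear benchmark
#' solvers on the test split of a simulated dataset, for every stored SNR
#' level: per-trial ROC AUC and localization error, aggregated as means per
#' method and SNR. Linear-solver regularization is derived from the SNR
#' (\code{\link{lambda2_from_snr}}) unless given.
#'
#' @param dataset An \code{esi_dataset}.
#' @param space,graph,leadfield The geometry the dataset was simulated on.
#' @param models Named list of trained \code{gft_bilstm} models, one per
#'   SNR level (names = SNR in dB as character); or a single model applied
#'   to every level.
#' @param basis The \code{spectral_basis} used for the models.
#' @param methods Character vector of methods to evaluate (subset of
#'   \code{"gft_bilstm"}, \code{"dspm"}, \code{"mne"}, \code{"sloreta"},
#'   \code{"oracle"}; oracle returns the true sources, an upper bound).
#' @param snr_db SNR levels to evaluate (default: all stored).
#' @param lambda2 Optional fixed regularization for the linear solvers.
#' @param split Which split to evaluate (default \code{"test"}).
#' @return An object of class \code{esi_eval}: list with \code{table} (one
#'   row per method; columns \code{auc_<snr>}, \code{le_<snr>}) and
#'   \code{per_trial} (long data.frame: method, snr_db, trial, auc, le_mm).
#' @export
run_experiment <- function(dataset, space, graph, leadfield, models = NULL,
                           basis = NULL,
                           methods = c("gft_bilstm", "dspm", "mne", "sloreta"),
                           snr_db = dataset$snr_db, lambda2 = NULL,
                           split = "test") {
  stopifnot(inherits(dataset, "esi_dataset"))
  idx <- dataset$split[[split]]
  if (!length(idx)) stop(sprintf("empty split '%s'", split))
  if ("gft_bilstm" %in% methods) {
    if (is.null(models))
      stop("no trained model supplied; fit one with gft_bilstm() first")
    if (inherits(models, "gft_bilstm"))
      models <- stats::setNames(rep(list(models), length(snr_db)),
                                as.character(snr_db))
  }
  rows <- list()
  for (snr in snr_db) {
    key <- as.character(snr)
    kernels <- list()
    for (meth in intersect(methods, c("mne", "dspm", "sloreta"))) {
      l2 <- lambda2 %||% lambda2_from_snr(leadfield, snr)
      kernels[[meth]] <- inverse_kernel(leadfield, meth, l2)
    }
    for (i in idx) {
      x <- dataset$samples[[i]]$x_noisy[[key]]
      if (is.null(x)) stop(sprintf("dataset has no noisy EEG at %s dB", key))
      mask <- sample_active_mask(dataset, i)
      centers <- dataset$samples[[i]]$patch$centers
      for (meth in methods) {
        est <- switch(meth,
          gft_bilstm = {
            mod <- models[[key]] %||% models[[1]]
            predict(mod, x)
          },
          oracle = sample_source_movie(dataset, i),
          apply_kernel(kernels[[meth]], x))
        rows[[length(rows) + 1]] <- data.frame(
          method = meth, snr_db = snr, trial = i,
          auc = auc_score(mask, est),
          le_mm = localization_error(space, graph, centers, est))
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  tab <- NULL
  for (meth in methods) {
    row <- data.frame(method = meth)
    for (snr in snr_db) {
      sub <- per_trial[per_trial$method == meth & per_trial$snr_db == snr, ]
      row[[paste0("auc_", snr)]] <- mean(sub$auc)
      row[[paste0("le_", snr)]] <- mean(sub$le_mm)
    }
    tab <- rbind(tab, row)
  }
  structure(list(table = tab, per_trial = per_trial, split = split,
                 snr_db = snr_db, n_trials = length(idx)),
            class = "esi_eval")
}

#' @export
print.esi_eval <- function(x, ...) {
  cat(sprintf("ESI evaluation on %d %s trial(s):\n", x$n_trials, x$split))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
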