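#' SNR-derived Tikhonov regularization
#'
#' Standard heuristic mapping a known sensor SNR to the minimum-norm
#' regularization scale: lambda2 = trace(H H^T) / (n * 10^(SNR_dB / 10)).
#'
#' @param leadfield A \code{lead_field}.
#' @param snr_db SNR in dB.
#' @return Positive scalar.
#' @export
lambda2_from_snr <- function(leadfield, snr_db) {
  H <- leadfield$gain
  sum(H^2) / (nrow(H) * 10^(snr_db / 10))
}

mne_kernel_matrix <- function(H, lambda2) {
  n <- nrow(H)
  G <- tcrossprod(H) + lambda2 * diag(n)
  K <- t(solve(G, H))            # H^T (H H^T + lambda2 I)^{-1}
  if (!all(is.finite(K))) stop("singular forward system beyond regularization")
  K
}

#' Linear inverse operators: MNE, dSPM, sLORETA
#'
#' Builds the classical Tikhonov minimum-norm inverse kernel
#' K = H^T (H H^T + lambda2 I)^{-1} (identity source and noise
#' covariances) and its two standardized variants:
#' \describe{
#'   \item{dSPM}{each row divided by sqrt((K C K^T)_ii), C the noise
#'     covariance — noise normalization.}
#'   \item{sLORETA}{each row divided by sqrt((K H)_ii), the diagonal of the
#'     resolution matrix — gives zero localization bias for a single
#'     noiseless source.}
#' }
#'
#' @param leadfield A \code{lead_field}.
#' @param method One of \code{"mne"}, \code{"dspm"}, \code{"sloreta"}.
#' @param lambda2 Regularization scalar (> 0); see
#'   \code{\link{lambda2_from_snr}}.
#' @param noise_cov Optional n x n noise covariance for dSPM (default
#'   identity).
#' @param floor_frac sLORETA resolution-diagonal floor, as a fraction of
#'   the largest diagonal entry; nonpositive entries are floored with a
#'   warning.
#' @return An object of class \code{inverse_kernel}: list with \code{K}
#'   (m x n), \code{method}, \code{lambda2}.
#' @export
inverse_kernel <- function(leadfield, method = c("mne", "dspm", "sloreta"),
                           lambda2, noise_cov = NULL, floor_frac = 1e-12) {
  method <- match.arg(method)
  stopifnot(inherits(leadfield, "lead_field"), lambda2 > 0)
  H <- leadfield$gain
  K <- mne_kernel_matrix(H, lambda2)
  if (method == "dspm") {
    C <- noise_cov %||% diag(nrow(H))
    d <- rowSums((K %*% C) * K)          # diag(K C K^T)
    if (any(d <= 0)) stop("zero row norm in dSPM normalization")
    K <- K / sqrt(d)
  } else if (method == "sloreta") {
    d <- rowSums(K * t(H))               # diag(K H), resolution matrix diagonal
    fl <- floor_frac * max(d)
    if (any(d < fl)) {
      warning("nonpositive sLORETA resolution diagonal entries floored")
      d <- pmax(d, fl)
    }
    K <- K / sqrt(d)
  }
  structure(list(K = K, method = method, lambda2 = lambda2),
            class = "inverse_kernel")
}

#' @rdname inverse_kernel
#' @export
mne_kernel <- function(leadfield, lambda2)
  inverse_kernel(leadfield, "mne", lambda2)

#' @rdname inverse_kernel
#' @export
dspm_kernel <- function(leadfield, lambda2, noise_cov = NULL)
  inverse_kernel(leadfield, "dspm", lambda2, noise_cov)

#' @rdname inverse_kernel
#' @export
sloreta_kernel <- function(leadfield, lambda2)
  inverse_kernel(leadfield, "sloreta", lambda2)

#' Apply a linear inverse kernel to EEG
#'
#' @param kernel An \code{inverse_kernel}.
#' @param x n x T EEG matrix.
#' @return m x T source estimate K x.
#' @export
apply_kernel <- function(kernel, x) {
  stopifnot(inherits(kernel, "inverse_kernel"))
  x <- as.matrix(x)
  if (nrow(x) != ncol(kernel$K))
    stop(sprintf("EEG has %d channels, kernel expects %d",
                 nrow(x), ncol(kernel$K)))
  kernel$K %*% x
}

#' @export
print.inverse_kernel <- function(x, ...) {
  cat(sprintf("%s inverse kernel: %d sources x %d electrodes, lambda2 = %.4g\n",
              toupper(x$method), nrow(x$K), ncol(x$K), x$lambda2))
  invisible(x)
}

#' @export
predict.inverse_kernel <- function(object, newdata, ...) {
  apply_kernel(object, newdata)
}
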