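#' Graph Laplacian of a source graph
#'
#' Combinatorial Laplacian L = D - A, where D is the diagonal degree matrix
#' with d_ii = sum_j a_ij. Every row of L sums to zero, so the constant
#' vector is always in its null space.
#'
#' @param graph A \code{source_graph} (symmetric adjacency, zero diagonal).
#' @return An object of class \code{graph_laplacian}: list with \code{L}
#'   (m x m) and \code{D} (degree vector of length m).
#' @export
laplacian <- function(graph) {
  A <- if (inherits(graph, "source_graph")) graph$adjacency else graph
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  if (!all(is.finite(A))) stop("adjacency has non-finite entries")
  if (max(abs(A - t(A))) > 0) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  if (any(A < 0)) stop("adjacency weights must be nonnegative")
  d <- rowSums(A)
  L <- -A
  diag(L) <- d
  structure(list(L = L, D = d), class = "graph_laplacian")
}

#' Eigendecomposition of the graph Laplacian
#'
#' Returns the full spectral basis: eigenvalues in ascending order and the
#' orthonormal eigenvector matrix U (column i paired with lambda_i). The
#' sign of each eigenvector is fixed deterministically: the entry of
#' largest magnitude is made positive, ties broken by the lowest index, so
#' serialized bases are reproducible across platforms.
#'
#' @param lap A \code{graph_laplacian} (or symmetric matrix).
#' @return An object of class \code{spectral_basis}: list with
#'   \code{eigenvalues} (ascending), \code{U} (orthogonal m x m), \code{m},
#'   and unset truncation fields \code{k}, \code{U_k}, \code{T_f}.
#' @export
eigendecompose <- function(lap) {
  L <- if (inherits(lap, "graph_laplacian")) lap$L else lap
  if (!all(is.finite(L))) stop("Laplacian has non-finite entries")
  if (max(abs(L - t(L))) > 1e-12 * max(1, max(abs(L))))
    stop("Laplacian must be symmetric")
  e <- eigen(L, symmetric = TRUE)
  ord <- order(e$values)            # eigen() returns descending; make ascending
  lambda <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  # deterministic sign convention
  for (i in seq_len(ncol(U))) {
    u <- U[, i]
    j <- which(abs(u) == max(abs(u)))[1]
    if (u[j] < 0) U[, i] <- -u
  }
  lambda[1] <- max(lambda[1], 0) * (lambda[1] > 0)  # clamp tiny negative round-off
  structure(list(eigenvalues = lambda, U = U, m = nrow(U),
                 k = NULL, U_k = NULL, T_f = NULL,
                 graph_frequencies = NULL),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("Spectral basis: m = %d, lambda in [%.4g, %.4g]",
              x$m, x$eigenvalues[1], x$eigenvalues[x$m]))
  if (!is.null(x$k)) cat(sprintf(", low band k = %d", x$k))
  cat("\n")
  invisible(x)
}

#' Graph Fourier transform
#'
#' Projects a vertex-domain signal onto the Laplacian eigenbasis:
#' coefficients = U^T s, applied column-wise over time.
#'
#' @param basis A \code{spectral_basis}.
#' @param s Numeric vector of length m or m x T matrix (one column per
#'   time sample).
#' @return m x T matrix of graph Fourier coefficients (a matrix even for
#'   vector input).
#' @export
gft <- function(basis, s) {
  stopifnot(inherits(basis, "spectral_basis"))
  s <- as.matrix(s)
  if (nrow(s) != basis$m)
    stop(sprintf("signal has %d rows but the basis has m = %d", nrow(s), basis$m))
  crossprod(basis$U, s)
}

#' Inverse graph Fourier transform
#'
#' Reconstructs a vertex-domain signal from graph Fourier coefficients.
#' Full-length coefficients (m rows) use the whole basis; truncated
#' coefficients (k rows, requires \code{\link{select_low_band}}) use the
#' low-band eigenvectors U_k, giving the orthogonal projection of the
#' original signal onto the low band when the coefficients came from it.
#'
#' @param basis A \code{spectral_basis}.
#' @param coeffs m x T or k x T coefficient matrix (or vector).
#' @return m x T matrix in the vertex domain.
#' @export
igft <- function(basis, coeffs) {
  stopifnot(inherits(basis, "spectral_basis"))
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) == basis$m) return(basis$U %*% coeffs)
  if (!is.null(basis$k) && nrow(coeffs) == basis$k)
    return(basis$U_k %*% coeffs)
  stop(sprintf(
    "coefficient length %d is neither m = %d nor the selected band k = %s",
    nrow(coeffs), basis$m, if (is.null(basis$k)) "<unset>" else basis$k))
}

#' Graph frequency of each eigenvector
#'
#' The graph frequency f_G of an eigenvector is its number of sign flips
#' across graph edges: the count of edges whose endpoint values have
#' strictly opposite signs (a zero value at either endpoint contributes no
#' flip). Low graph frequency corresponds to spatial smoothness; the
#' constant eigenvector at eigenvalue 0 has f_G = 0.
#'
#' @param basis A \code{spectral_basis}.
#' @param graph The \code{source_graph} the basis was built from.
#' @return Integer vector of length m, one count per eigenvector.
#' @export
graph_frequency <- function(basis, graph) {
  stopifnot(inherits(basis, "spectral_basis"))
  A <- graph$adjacency
  if (nrow(A) != basis$m) stop("basis and graph disagree on m")
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  prod_sign <- basis$U[idx[, 1], , drop = FALSE] * basis$U[idx[, 2], , drop = FALSE]
  as.integer(colSums(prod_sign < 0))
}

#' Select the spatial low band of a spectral basis
#'
#' Truncates the basis to its k lowest-frequency eigenvectors, either by an
#' eigenvalue threshold \code{T_f} (k = number of eigenvalues strictly less
#' than \code{T_f}) or by giving \code{k} directly. The truncated basis
#' U_k acts as a spatial low-pass filter for extended source patches.
#'
#' @param basis A \code{spectral_basis}.
#' @param T_f Eigenvalue threshold (exclusive); give exactly one of
#'   \code{T_f}, \code{k}.
#' @param k Band size, integer in [1, m].
#' @return The basis with \code{k}, \code{U_k} (and \code{T_f} if given) set.
#' @export
select_low_band <- function(basis, T_f = NULL, k = NULL) {
  stopifnot(inherits(basis, "spectral_basis"))
  if (is.null(T_f) == is.null(k))
    stop("give exactly one of T_f and k")
  if (!is.null(T_f)) {
    k <- sum(basis$eigenvalues < T_f)
    if (k == 0)
      stop(sprintf("T_f = %g selects an empty band (lambda_1 = %g)",
                   T_f, basis$eigenvalues[1]))
    basis$T_f <- T_f
  } else {
    if (k < 1 || k > basis$m || k != round(k))
      stop(sprintf("k must be an integer in [1, %d]", basis$m))
  }
  basis$k <- as.integer(k)
  basis$U_k <- basis$U[, seq_len(k), drop = FALSE]
  basis
}
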