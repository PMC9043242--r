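#' Build an icosphere source space
#'
#' Constructs a triangulated sphere by repeated 4-to-1 subdivision of a
#' regular icosahedron, with every vertex projected back onto the sphere.
#' The result stands in for a cortical source space: each vertex is a
#' candidate source location. Vertex count follows the icosphere law
#' \eqn{m = 10 \cdot 4^{s} + 2}.
#'
#' @param subdivisions Number of subdivision rounds (non-negative integer).
#'   0 gives the icosahedron (12 vertices), 2 gives 162, 3 gives 642.
#' @param radius_mm Sphere radius in millimetres.
#' @param max_vertices Safety cap on the vertex count; subdivision levels
#'   that would exceed it are refused.
#' @return An object of class \code{source_space}: a list with
#'   \code{positions} (m x 3 matrix, mm), \code{triangles} (0-based integer
#'   matrix of vertex triples, one triangle per row) and \code{m}.
#' @examples
#' sp <- build_icosphere_source_space(2, radius_mm = 75)
#' sp$m  # 162
#' @export
build_icosphere_source_space <- function(subdivisions, radius_mm = 75,
                                         max_vertices = 50000L) {
  stopifnot(length(subdivisions) == 1, subdivisions >= 0,
            subdivisions == round(subdivisions),
            length(radius_mm) == 1, radius_mm > 0)
  m_target <- 10 * 4^subdivisions + 2
  if (m_target > max_vertices) {
    stop(sprintf(
      "subdivisions = %d would give %d vertices, exceeding the cap of %d",
      subdivisions, m_target, max_vertices))
  }

  # regular icosahedron on the unit sphere
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tri <- rbind(  # 0-based, outward-oriented
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  storage.mode(tri) <- "integer"

  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    new_v <- list()
    get_mid <- function(a, b) {
      key <- if (a < b) paste(a, b) else paste(b, a)
      idx <- midpoint[[key]]
      if (!is.null(idx)) return(idx)
      p <- (v[a + 1, ] + v[b + 1, ]) / 2
      p <- p / sqrt(sum(p^2))
      new_v[[length(new_v) + 1L]] <<- p
      idx <- nv + length(new_v) - 1L   # 0-based index of the new vertex
      midpoint[[key]] <- idx
      idx
    }
    new_tri <- matrix(0L, nrow = 4 * nrow(tri), ncol = 3)
    for (t in seq_len(nrow(tri))) {
      a <- tri[t, 1]; b <- tri[t, 2]; c <- tri[t, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      new_tri[4 * t - 3, ] <- c(a, ab, ca)
      new_tri[4 * t - 2, ] <- c(b, bc, ab)
      new_tri[4 * t - 1, ] <- c(c, ca, bc)
      new_tri[4 * t, ]     <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, new_v))
    tri <- new_tri
  }

  structure(list(positions = v * radius_mm,
                 triangles = tri,
                 m = nrow(v)),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  r <- sqrt(sum(x$positions[1, ]^2))
  cat(sprintf("Source space: %d vertices, %d triangles, radius %.1f mm\n",
              x$m, nrow(x$triangles), r))
  invisible(x)
}

edge_list_from_triangles <- function(triangles) {
  # undirected unique edges (0-based endpoints), each once with i < j
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Mesh adjacency graph of a source space
#'
#' Builds the undirected source graph: vertices are sources, and two sources
#' are connected when they are neighbors on the 3D mesh. With
#' \code{neighbor_order = 2}, vertices reachable in exactly two edges are
#' additionally connected. Weights are binary (1 for every neighbor pair).
#'
#' @param space A \code{source_space}.
#' @param neighbor_order 1 (mesh edges only) or 2 (also two-hop neighbors).
#' @return An object of class \code{source_graph}: list with
#'   \code{adjacency} (symmetric m x m 0/1 matrix, zero diagonal) and
#'   \code{neighbor_order}.
#' @export
adjacency_from_mesh <- function(space, neighbor_order = 1) {
  stopifnot(inherits(space, "source_space"), neighbor_order %in% c(1, 2))
  m <- space$m
  if (any(space$triangles < 0 | space$triangles >= m))
    stop("triangle indices out of range [0, m)")
  e <- edge_list_from_triangles(space$triangles)
  A <- matrix(0, m, m)
  A[cbind(e[, 1] + 1, e[, 2] + 1)] <- 1
  A[cbind(e[, 2] + 1, e[, 1] + 1)] <- 1
  if (neighbor_order == 2) {
    A2 <- (A %*% A > 0) * 1
    A <- ((A + A2) > 0) * 1
    diag(A) <- 0
  }
  g <- structure(list(adjacency = A, neighbor_order = neighbor_order),
                 class = "source_graph")
  if (n_components(A) != 1)
    stop("mesh is disconnected; the Laplacian spectral basis assumes a single component")
  g
}

n_components <- function(A) {
  m <- nrow(A)
  seen <- logical(m)
  ncomp <- 0L
  for (start in seq_len(m)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    frontier <- start
    seen[start] <- TRUE
    while (length(frontier)) {
      nb <- which(colSums(A[frontier, , drop = FALSE] != 0) > 0)
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      frontier <- nb
    }
  }
  ncomp
}

neighbors_of <- function(graph, vertex0) {
  # 0-based vertex id -> 0-based neighbor ids
  which(graph$adjacency[vertex0 + 1, ] != 0) - 1L
}

#' Quasi-uniform electrode montage on the upper scalp hemisphere
#'
#' Fibonacci-spiral points on the upper hemisphere of the scalp sphere, with
#' a seeded random rotation about the vertical axis so distinct seeds give
#' distinct (but equally uniform) montages.
#'
#' @keywords internal
fibonacci_electrodes <- function(n_electrodes, scalp_radius_mm, seed) {
  rot <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  i <- seq_len(n_electrodes) - 0.5
  z <- i / n_electrodes          # in (0, 1): upper hemisphere, pole excluded
  golden <- pi * (3 - sqrt(5))
  az <- golden * (seq_len(n_electrodes) - 1) + rot
  r_xy <- sqrt(pmax(0, 1 - z^2))
  scalp_radius_mm * cbind(r_xy * cos(az), r_xy * sin(az), z)
}

#' Closed-form potential of a radial dipole in a homogeneous sphere
#'
#' Surface potential of a unit-moment radial current dipole inside a
#' homogeneous conducting sphere with insulating exterior. For a dipole at
#' eccentricity b along unit vector s and a surface point at angle theta
#' (x = cos theta), with f = b/R and g = sqrt(1 - 2 f x + f^2):
#' V = 1/(4 pi sigma b R) * (2 f (x - f) / g^3 + 1/g - 1),
#' the closed form of the Legendre series sum_{l>=1} (2l+1) b^{l-1} R^{-(l+1)} P_l(x).
#'
#' @param src_pos m x 3 dipole positions (mm), radial orientation assumed.
#' @param elec_pos n x 3 surface electrode positions (mm).
#' @param sigma_s Conductivity (S/m); a global scale only.
#' @return n x m matrix of potentials.
#' @keywords internal
sphere_radial_dipole_potential <- function(src_pos, elec_pos, sigma_s = 0.33) {
  R <- sqrt(sum(elec_pos[1, ]^2))
  b <- sqrt(rowSums(src_pos^2))                    # length m
  if (any(b <= 0)) stop("radial dipole undefined at the sphere centre")
  s_hat <- src_pos / b
  e_hat <- elec_pos / R
  x <- e_hat %*% t(s_hat)                          # n x m, cos(theta)
  f <- rep(b / R, each = nrow(elec_pos))
  f <- matrix(f, nrow = nrow(elec_pos))
  g <- sqrt(pmax(1 - 2 * f * x + f^2, 1e-300))
  bm <- matrix(rep(b, each = nrow(elec_pos)), nrow = nrow(elec_pos))
  (2 * f * (x - f) / g^3 + 1 / g - 1) / (4 * pi * sigma_s * bm * R)
}

#' Synthesize an analytic spherical-head lead field
#'
#' Places \code{n_electrodes} quasi-uniformly on the upper hemisphere of a
#' spherical scalp and computes, for each source vertex, the scalp potential
#' of a unit current dipole oriented along the outward surface normal, from
#' the closed-form homogeneous-sphere solution. Each column is
#' average-referenced (zero mean over electrodes), the standard EEG
#' reference convention.
#'
#' @param space A \code{source_space} (vertices strictly inside the scalp).
#' @param n_electrodes Number of electrodes (>= 4).
#' @param scalp_radius_mm Scalp sphere radius (must exceed the source radius).
#' @param seed Integer seed for the montage rotation.
#' @param sigma_s Volume conductivity in S/m.
#' @return An object of class \code{lead_field}: list with \code{gain}
#'   (n x m), \code{electrode_positions} (n x 3, mm) and \code{n}.
#' @export
synthesize_lead_field <- function(space, n_electrodes = 64,
                                  scalp_radius_mm = 92.5, seed = 1L,
                                  sigma_s = 0.33) {
  stopifnot(inherits(space, "source_space"), n_electrodes >= 4)
  src_r <- max(sqrt(rowSums(space$positions^2)))
  if (src_r >= scalp_radius_mm)
    stop(sprintf("source radius %.1f mm must be smaller than scalp radius %.1f mm",
                 src_r, scalp_radius_mm))
  elec <- fibonacci_electrodes(n_electrodes, scalp_radius_mm, seed)
  G <- sphere_radial_dipole_potential(space$positions, elec, sigma_s)
  G <- sweep(G, 2, colMeans(G))       # average reference per column
  if (!all(is.finite(G))) stop("non-finite lead field entries")
  if (any(colSums(abs(G)) == 0)) stop("lead field has an all-zero column")
  structure(list(gain = G, electrode_positions = elec, n = n_electrodes),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("Lead field: %d electrodes x %d sources\n", nrow(x$gain), ncol(x$gain)))
  invisible(x)
}
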