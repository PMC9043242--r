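# Shared fixtures, built once per test run (all generated in code).

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    cache[[name]] <- switch(name,
      ico0 = build_icosphere_source_space(0, radius_mm = 75),
      ico2 = build_icosphere_source_space(2, radius_mm = 75),
      g0 = adjacency_from_mesh(fx("ico0"), 1),
      g2 = adjacency_from_mesh(fx("ico2"), 1),
      basis2 = eigendecompose(laplacian(fx("g2"))),
      lf2 = synthesize_lead_field(fx("ico2"), 32, 92.5, seed = 7L),
      ds2 = make_dataset(fx("ico2"), fx("g2"), fx("lf2"), n_samples = 30,
                         snr_db = c(20, 40), T_samples = 40, seed = 5L),
      stop("unknown fixture ", name))
    cache[[name]]
  }
})

# path graph 1-2-3 with unit weights, as a source_graph
path3_graph <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  structure(list(adjacency = A, neighbor_order = 1L), class = "source_graph")
}

# 3-vertex single-triangle mesh
tri3_space <- function() {
  structure(list(positions = diag(3) * 10,
                 triangles = matrix(c(0L, 1L, 2L), 1),
                 m = 3L), class = "source_space")
}
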