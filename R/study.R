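#' Run the scaled-down simulation study end to end
#'
#' Builds the study geometry (icosphere source space, spherical lead field),
#' selects the spatial low band (k = 30\% of m), simulates patch-source
#' trials with AR(5) dynamics at the requested SNR levels, trains one
#' BiLSTM per SNR level on the training split, and evaluates all methods on
#' the test split. This is the package's reference experiment; every stage
#' seed derives from the single \code{seed}.
#'
#' @param seed Global integer seed.
#' @param n_patches Active patches per trial (1 = single-source protocol,
#'   2 = multi-source).
#' @param snr_db SNR levels (dB); one model is trained per level.
#' @param n_samples Number of trials.
#' @param subdivisions,radius_mm Icosphere source-space parameters.
#' @param n_electrodes,scalp_radius_mm Lead-field parameters.
#' @param k_fraction Low-band size as a fraction of m.
#' @param hidden,epochs,batch_size,learning_rate,patience Training
#'   parameters passed to \code{\link{gft_bilstm}}.
#' @param methods Methods to evaluate (see \code{\link{run_experiment}}).
#' @param verbose Print training progress.
#' @return List with \code{eval} (an \code{esi_eval}), \code{models}
#'   (named by SNR), \code{dataset}, \code{basis}, \code{space},
#'   \code{graph}, \code{leadfield}.
#' @export
simulation_study <- function(seed = 1L, n_patches = 1,
                             snr_db = c(20, 30, 40), n_samples = 600,
                             subdivisions = 3, radius_mm = 75,
                             n_electrodes = 64, scalp_radius_mm = 92.5,
                             k_fraction = 0.3, hidden = 256, epochs = 40,
                             batch_size = 32, learning_rate = 1e-2,
                             patience = 12,
                             methods = c("gft_bilstm", "dspm", "mne",
                                         "sloreta"),
                             verbose = FALSE) {
  space <- build_icosphere_source_space(subdivisions, radius_mm)
  graph <- adjacency_from_mesh(space, 1)
  leadfield <- synthesize_lead_field(space, n_electrodes, scalp_radius_mm,
                                     seed = derive_seed(seed, 1L))
  basis <- select_low_band(eigendecompose(laplacian(graph)),
                           k = round(k_fraction * space$m))
  dataset <- make_dataset(space, graph, leadfield, n_samples = n_samples,
                          n_patches = n_patches, snr_db = snr_db,
                          seed = derive_seed(seed, 2L + n_patches))
  models <- NULL
  if ("gft_bilstm" %in% methods) {
    models <- lapply(seq_along(snr_db), function(j) {
      if (verbose) message(sprintf("training at %g dB ...", snr_db[j]))
      gft_bilstm(dataset, basis, snr_db = snr_db[j], hidden = hidden,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, patience = patience,
                 seed = derive_seed(seed, 10L + j), verbose = verbose)
    })
    names(models) <- as.character(snr_db)
  }
  eval <- run_experiment(dataset, space, graph, leadfield, models = models,
                         basis = basis, methods = methods, snr_db = snr_db)
  list(eval = eval, models = models, dataset = dataset, basis = basis,
       space = space, graph = graph, leadfield = leadfield)
}
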