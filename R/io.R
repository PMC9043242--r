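#' Write / read a mesh in OFF format
#'
#' Plain-text Object File Format: vertex positions then triangle index
#' triples (0-based on disk, as in the format).
#'
#' @param space A \code{source_space}.
#' @param path Output file.
#' @export
write_off <- function(space, path) {
  stopifnot(inherits(space, "source_space"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", space$m, nrow(space$triangles)), con)
  utils::write.table(format(space$positions, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, space$triangles), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' @rdname write_off
#' @return \code{read_off}: a \code{source_space}.
#' @export
read_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[(3 + nv):(2 + nv + nf)], quiet = TRUE),
              nf, 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("only triangle faces are supported")
  structure(list(positions = v, triangles = matrix(as.integer(f[, 2:4]), nf, 3),
                 m = nv), class = "source_space")
}

#' Write / read an EEG matrix file
#'
#' Plain-text container for multichannel EEG: a comment header line
#' \code{# fs: <Hz>} followed by a CSV body, one row per channel, one
#' column per sample.
#'
#' @param x n x T numeric matrix.
#' @param fs_hz Sampling rate (Hz).
#' @param path File path.
#' @export
write_eeg_matrix <- function(x, fs_hz, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", fs_hz), con)
  utils::write.table(format(x, digits = 17), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
}

#' @rdname write_eeg_matrix
#' @param leadfield Optional \code{lead_field}; if given, the channel count
#'   is checked against it.
#' @return \code{load_eeg_matrix}: list with \code{x} (n x T) and
#'   \code{fs_hz}.
#' @export
load_eeg_matrix <- function(path, leadfield = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fs <- NA_real_
  fs_line <- grep("fs\\s*[:=]", hdr, value = TRUE)
  if (length(fs_line))
    fs <- as.numeric(sub(".*fs\\s*[:=]\\s*([0-9.eE+-]+).*", "\\1", fs_line[1]))
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  x <- as.matrix(utils::read.csv(text = body, header = FALSE))
  dimnames(x) <- NULL
  if (!all(is.finite(x))) stop("EEG matrix contains non-finite values")
  if (!is.null(leadfield) && nrow(x) != nrow(leadfield$gain))
    stop(sprintf("EEG has %d channels but the lead field has %d",
                 nrow(x), nrow(leadfield$gain)))
  list(x = x, fs_hz = fs)
}

#' Write the head-model container
#'
#' Directory of plain-text artifacts describing a source space and lead
#' field: \code{positions.csv}, \code{triangles.csv} (0-based),
#' \code{gain.csv}, \code{electrode_positions.csv}, plus a YAML manifest
#' with shapes and provenance.
#'
#' @param space A \code{source_space}.
#' @param leadfield A \code{lead_field} (optional).
#' @param dir Output directory (created).
#' @export
write_head_container <- function(space, leadfield = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(m, f) utils::write.table(
    m, file.path(dir, f), sep = ",", row.names = FALSE, col.names = FALSE)
  wt(space$positions, "positions.csv")
  wt(space$triangles, "triangles.csv")
  manifest <- list(m = space$m, n_triangles = nrow(space$triangles),
                   index_base = 0L, units = "mm")
  if (!is.null(leadfield)) {
    wt(leadfield$gain, "gain.csv")
    wt(leadfield$electrode_positions, "electrode_positions.csv")
    manifest$n_electrodes <- leadfield$n
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_head_container
#' @return \code{read_head_container}: list with \code{space} and (if
#'   present) \code{leadfield}.
#' @export
read_head_container <- function(dir) {
  rd <- function(f) {
    m <- as.matrix(utils::read.csv(file.path(dir, f), header = FALSE))
    dimnames(m) <- NULL
    m
  }
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  space <- structure(list(positions = rd("positions.csv"),
                          triangles = matrix(as.integer(rd("triangles.csv")),
                                             ncol = 3),
                          m = manifest$m), class = "source_space")
  out <- list(space = space)
  if (file.exists(file.path(dir, "gain.csv"))) {
    gain <- rd("gain.csv")
    out$leadfield <- structure(
      list(gain = gain, electrode_positions = rd("electrode_positions.csv"),
           n = nrow(gain)), class = "lead_field")
  }
  out
}

#' Export the graph-frequency spectrum as CSV
#'
#' One row per eigenvector: eigenvalue and graph frequency (sign-flip
#' count), for spectrum plots.
#' @param basis A \code{spectral_basis}.
#' @param graph The matching \code{source_graph}.
#' @param path Output CSV.
#' @export
write_spectrum_csv <- function(basis, graph, path) {
  fg <- graph_frequency(basis, graph)
  utils::write.csv(data.frame(eigenvalue = basis$eigenvalues,
                              graph_frequency = fg),
                   path, row.names = FALSE)
  invisible(path)
}

hash_string <- function(s) {
  acc <- 0
  for (by in as.integer(charToRaw(s))) acc <- (acc * 131 + by) %% 2147483647
  sprintf("%08x", acc)
}
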