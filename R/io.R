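# Persistence: epochs containers, configs, TSV exports.  The epochs
# container is a self-describing directory: one full-precision TSV matrix
# per (subject, region, item) slice index is avoided by storing the whole
# items x channels x time array as a (items * channels) x time TSV, plus a
# JSON sidecar with the schema (time axis, sampling rate, labels, validity
# mask, channel coordinates).  Round-trips are bit-identical.

format_full <- function(x) sprintf("%.17g", x)

write_matrix_tsv <- function(mat, path) {
  lines <- apply(mat, 1L, function(r) paste(format_full(r),
                                            collapse = "\t"))
  writeLines(lines, path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

#' Write an epochs container to disk
#'
#' @param epochs an [epochs_set()].
#' @param path directory to create (must not already contain an epochs
#'   container unless `overwrite = TRUE`).
#' @param overwrite replace an existing container.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, overwrite = FALSE) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (dir.exists(path) && file.exists(file.path(path, "epochs.json")) &&
      !overwrite)
    stop("epochs container already exists at ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  flat <- matrix(epochs$data, d[1L] * d[2L], d[3L])
  write_matrix_tsv(flat, file.path(path, "data.tsv"))
  meta <- list(
    shape = d, time_ms = format_full(epochs$time_ms),
    sfreq = format_full(epochs$sfreq), item_labels = epochs$item_labels,
    valid_items = epochs$valid_items, region = epochs$region,
    channel_coord_names = colnames(epochs$channel_coords))
  if (!is.null(epochs$channel_coords))
    write_matrix_tsv(as.matrix(epochs$channel_coords),
                     file.path(path, "channel_coordinates.tsv"))
  jsonlite::write_json(meta, file.path(path, "epochs.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read an epochs container from disk
#'
#' Validates the schema on read: a missing required field fails with a
#' message naming it.
#'
#' @param path directory written by [write_epochs()].
#' @return an [epochs_set()], bit-identical to the one written.
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "epochs.json")
  if (!file.exists(meta_path)) stop("no epochs container at ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("shape", "time_ms", "sfreq", "item_labels", "region"))
    if (is.null(meta[[field]]))
      stop("epochs container is missing required field '", field, "'")
  coord_path <- file.path(path, "channel_coordinates.tsv")
  if (!file.exists(coord_path))
    stop("epochs container is missing 'channel_coordinates'")
  coords <- read_matrix_tsv(coord_path)
  colnames(coords) <- meta$channel_coord_names
  flat <- read_matrix_tsv(file.path(path, "data.tsv"))
  d <- as.integer(meta$shape)
  epochs_set(array(flat, d), time_ms = as.numeric(meta$time_ms),
             sfreq = as.numeric(meta$sfreq),
             item_labels = meta$item_labels,
             channel_coords = coords,
             valid_items = meta$valid_items %||% rep(TRUE, d[1L]),
             region = meta$region)
}

#' Export an RDV as a pair-labelled TSV
#'
#' @param rdv an `rdv`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rdv_tsv <- function(rdv, path) {
  labels <- attr(rdv, "item_labels")
  pi <- pair_index(length(labels))
  df <- data.frame(item_a = labels[pi[, 1L]], item_b = labels[pi[, 2L]],
                   dissimilarity = as.numeric(rdv))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a cluster report as TSV
#'
#' One row per cluster: id, start/end in ms, member count, mass, p-value.
#'
#' @param cluster_set a `cluster_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(cluster_set, path) {
  cl <- cluster_set$clusters
  df <- data.frame(
    cluster = seq_along(cl),
    start_ms = vapply(cl, `[[`, numeric(1L), "start_ms"),
    end_ms = vapply(cl, `[[`, numeric(1L), "end_ms"),
    n_members = vapply(cl, `[[`, numeric(1L), "n_members"),
    mass = vapply(cl, `[[`, numeric(1L), "mass"),
    p_value = vapply(cl, `[[`, numeric(1L), "p_value"))
  if (!nrow(df)) df <- df[0, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read or write a pipeline configuration
#'
#' Configurations are plain-text YAML and round-trip unchanged.
#'
#' @param path file path.
#' @return for `read_config`, a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
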