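# Neural RDM time-series: dissimilarity structure of multichannel epoched
# data, computed per timepoint from spatiotemporal sensor patterns.

#' Construct an epochs container
#'
#' Holds one subject's epoched data for one region: an items x channels x
#' time array (one trial per item; if several trials per item are supplied
#' upstream they must be averaged within item first), plus the metadata the
#' pipeline needs.
#'
#' @param data numeric array items x channels x time.
#' @param time_ms numeric vector of sample times in milliseconds.
#' @param sfreq sampling rate in Hz.
#' @param item_labels character vector of item labels.
#' @param channel_coords channels x k numeric matrix of sensor coordinates;
#'   must contain a column named `y` for the anterior/posterior split.
#' @param valid_items logical mask of items that survived behavioural
#'   screening (e.g. correctly named trials).
#' @param region region label.
#' @return an object of class `epochs_set`.
#' @export
epochs_set <- function(data, time_ms, sfreq, item_labels = NULL,
                       channel_coords = NULL, valid_items = NULL,
                       region = "region") {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[3L] != length(time_ms))
    stop("time axis length does not match data")
  if (is.unsorted(time_ms, strictly = TRUE))
    stop("time axis must be strictly increasing")
  item_labels <- item_labels %||% paste0("item", seq_len(dim(data)[1L]))
  valid_items <- valid_items %||% rep(TRUE, dim(data)[1L])
  structure(list(data = data, time_ms = as.numeric(time_ms),
                 sfreq = sfreq, item_labels = item_labels,
                 channel_coords = channel_coords,
                 valid_items = valid_items, region = region),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "epochs_set '%s': %d items x %d channels x %d samples (%g Hz, %g..%g ms)\n",
    x$region, d[1L], d[2L], d[3L], x$sfreq, min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

new_neural_rdm_series <- function(rdvs, time_ms, window_ms, item_labels,
                                  valid_timepoints, channel_set) {
  structure(list(rdvs = rdvs, time_ms = time_ms, window_ms = window_ms,
                 item_labels = item_labels,
                 valid_timepoints = valid_timepoints,
                 channel_set = channel_set),
            class = "neural_rdm_series")
}

#' @export
print.neural_rdm_series <- function(x, ...) {
  cat(sprintf(
    "neural_rdm_series '%s': %d timepoints x %d pairs (window %g ms, %d valid)\n",
    x$channel_set, nrow(x$rdvs), ncol(x$rdvs), x$window_ms,
    sum(x$valid_timepoints)))
  invisible(x)
}

#' @export
subset_items.neural_rdm_series <- function(x, valid_items) {
  labels <- x$item_labels
  keep <- resolve_mask(valid_items, labels)
  pi <- pair_index(length(labels))
  sel <- pi[, 1L] %in% keep & pi[, 2L] %in% keep
  new_neural_rdm_series(x$rdvs[, sel, drop = FALSE], x$time_ms,
                        x$window_ms, labels[keep], x$valid_timepoints,
                        x$channel_set)
}

# One timepoint's RDV from an items x (channels * window) pattern matrix.
pattern_rdv <- function(patterns) {
  d <- 1 - stats::cor(t(patterns))
  d <- pmin(pmax(d, 0), 2)
  n <- nrow(d)
  pi <- pair_index(n)
  d[cbind(pi[, 1L], pi[, 2L])]
}

#' Sliding-window neural RDM time-series
#'
#' At each timepoint t the pattern for an item is the channels x
#' window-samples block centred on t, flattened channels-major; the RDM
#' entry is one minus the Pearson correlation between item patterns.
#' Timepoints whose window would extend past the epoch edges are marked
#' invalid (NA rows), never silently truncated.
#'
#' @param epochs an [epochs_set()].
#' @param window_ms window width in milliseconds (40 by default, matching
#'   standard sensor-level RSA practice); the realised window is the odd
#'   number of samples closest to `window_ms`, centred on t.
#' @param channels optional integer/logical selection of channels (e.g. one
#'   output of [split_channels_by_y()]); default all.
#' @return a `neural_rdm_series` on the valid-item subset.
#' @export
sliding_window_rdms <- function(epochs, window_ms = 40, channels = NULL) {
  stopifnot(inherits(epochs, "epochs_set"))
  dat <- epochs$data
  if (!is.null(channels)) dat <- dat[, channels, , drop = FALSE]
  keep <- which(epochs$valid_items)
  if (length(keep) < 3L) stop("fewer than 3 valid items")
  dat <- dat[keep, , , drop = FALSE]
  n_t <- dim(dat)[3L]
  step <- 1000 / epochs$sfreq
  half <- max(0L, round(window_ms / (2 * step)))
  if (2L * half + 1L > n_t) stop("window longer than epoch")
  n_pairs <- length(keep) * (length(keep) - 1L) / 2L
  rdvs <- matrix(NA_real_, n_t, n_pairs)
  valid <- rep(FALSE, n_t)
  for (t in seq_len(n_t)) {
    if (t - half < 1L || t + half > n_t) next
    pat <- dat[, , (t - half):(t + half), drop = FALSE]
    dim(pat) <- c(dim(pat)[1L], dim(pat)[2L] * dim(pat)[3L])
    rdvs[t, ] <- pattern_rdv(pat)
    valid[t] <- TRUE
  }
  new_neural_rdm_series(rdvs, epochs$time_ms,
                        window_ms = (2L * half + 1L) * step,
                        item_labels = epochs$item_labels[keep],
                        valid_timepoints = valid,
                        channel_set = epochs$region)
}

#' Single-timepoint neural RDM time-series
#'
#' Equivalent to [sliding_window_rdms()] with a one-sample window.  Used
#' for connectivity analyses, where time-lagged RDVs from two regions must
#' not share any samples.
#'
#' @inheritParams sliding_window_rdms
#' @return a `neural_rdm_series`.
#' @export
single_timepoint_rdms <- function(epochs, channels = NULL) {
  sliding_window_rdms(epochs, window_ms = 0, channels = channels)
}

#' Split channels into posterior and anterior halves by y-coordinate
#'
#' Median split on the sensor y-coordinate: the half with the smaller y
#' values is the posterior set.  For even channel counts the sets are
#' equal-sized; for odd counts the posterior set takes the extra channel.
#' Ties straddling the median are resolved by stable channel-index order.
#'
#' @param channel_coords channels x k matrix with a column named `y` (or a
#'   numeric vector of y-coordinates).
#' @return list with integer index vectors `posterior` and `anterior`.
#' @export
split_channels_by_y <- function(channel_coords) {
  y <- if (is.matrix(channel_coords) || is.data.frame(channel_coords)) {
    if (!"y" %in% colnames(channel_coords))
      stop("channel_coords must contain a 'y' column")
    as.numeric(channel_coords[, "y"])
  } else as.numeric(channel_coords)
  if (length(y) < 2L || any(!is.finite(y)))
    stop("need at least 2 channels with finite y")
  ord <- order(y, seq_along(y))    # stable in channel index
  n_post <- ceiling(length(y) / 2)
  list(posterior = sort(ord[seq_len(n_post)]),
       anterior  = sort(ord[(n_post + 1L):length(y)]))
}

#' Searchlight neural RDMs over a point cloud
#'
#' Repeats RDM construction in a spatial neighbourhood around every point:
#' the neighbourhood is all points within Euclidean `radius` (inclusive) of
#' the centre, centre always included.  With a time axis this is the
#' spatiotemporal searchlight (patterns are neighbourhood-points x
#' window-samples); with a static points x items matrix it reproduces the
#' volumetric (fMRI-style) searchlight with a single RDM per point.
#'
#' @param point_signals array points x items x time, or points x items
#'   matrix for static mode.
#' @param point_coords points x k coordinate matrix (same units as
#'   `radius`, conventionally millimetres).
#' @param radius neighbourhood radius (inclusive).
#' @param window_ms window width in ms (ignored in static mode).
#' @param time_ms time axis in ms (required with a time axis).
#' @param sfreq sampling rate in Hz (required with a time axis).
#' @return list of per-point `neural_rdm_series` (static mode: one-row
#'   series per point).
#' @export
searchlight_rdms <- function(point_signals, point_coords, radius,
                             window_ms = 40, time_ms = NULL, sfreq = NULL) {
  coords <- as.matrix(point_coords)
  n_pts <- nrow(coords)
  d2 <- as.matrix(stats::dist(coords))
  static <- length(dim(point_signals)) == 2L
  if (!static && (is.null(time_ms) || is.null(sfreq)))
    stop("time_ms and sfreq are required for spatiotemporal searchlights")
  out <- vector("list", n_pts)
  for (p in seq_len(n_pts)) {
    nb <- which(d2[p, ] <= radius)
    if (static) {
      pat <- t(point_signals[nb, , drop = FALSE])  # items x points
      rdv <- pattern_rdv(pat)
      out[[p]] <- new_neural_rdm_series(
        matrix(rdv, 1L), time_ms = 0, window_ms = 0,
        item_labels = colnames(point_signals) %||%
          paste0("item", seq_len(ncol(point_signals))),
        valid_timepoints = TRUE,
        channel_set = sprintf("searchlight_%d", p))
    } else {
      sl <- aperm(point_signals[nb, , , drop = FALSE], c(2L, 1L, 3L))
      eps <- epochs_set(sl, time_ms = time_ms, sfreq = sfreq,
                        region = sprintf("searchlight_%d", p))
      out[[p]] <- sliding_window_rdms(eps, window_ms = window_ms)
    }
  }
  out
}
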