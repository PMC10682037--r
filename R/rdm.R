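# Representational dissimilarity matrices (RDMs) and their vectorised
# upper triangles (RDVs): the common currency of the pipeline.

#' Construct an RDM object
#'
#' An RDM is a symmetric items x items matrix of pairwise dissimilarities
#' with a zero diagonal.  Item labels are carried in the dimnames.
#'
#' @param mat symmetric numeric matrix with zero diagonal.
#' @param metric dissimilarity metric label, e.g. `"pearson-distance"` or
#'   `"cosine-distance"`.
#' @param item_labels optional character vector of item labels; defaults to
#'   existing dimnames or `item1..itemN`.
#' @return an object of class `rdm` (a matrix with a `metric` attribute).
#' @export
new_rdm <- function(mat, metric = "pearson-distance", item_labels = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("RDM must be square")
  if (max(abs(mat - t(mat))) > 1e-8) stop("RDM must be symmetric")
  if (max(abs(diag(mat))) > 1e-8) stop("RDM must have a zero diagonal")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  labels <- item_labels %||% rownames(mat) %||%
    paste0("item", seq_len(nrow(mat)))
  dimnames(mat) <- list(labels, labels)
  structure(mat, metric = metric, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d items, metric = %s\n", nrow(x), attr(x, "metric")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Pearson-distance RDM from a continuous feature matrix
#'
#' Entry (i, j) is `1 - Pearson(row_i, row_j)` over the feature dimension,
#' i.e. the correlation distance between the activation vectors of items i
#' and j.  Entries lie in `[0, 2]`.
#'
#' @param features items x features numeric matrix; rownames are item
#'   labels.  Every row must have nonzero variance.
#' @return an `rdm` with metric `"pearson-distance"`.
#' @export
rdm_from_activations <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need at least 3 items")
  if (ncol(features) < 2L) stop("need at least 2 features")
  v <- apply(features, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(features)[v == 0] %||% which(v == 0)
    stop("zero-variance item row(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - stats::cor(t(features))
  d <- pmin(pmax(d, 0), 2)
  new_rdm(d, metric = "pearson-distance",
          item_labels = rownames(features))
}

#' Cosine-distance RDM from a binary feature matrix
#'
#' Entry (i, j) is `1 - (a . b) / (||a|| ||b||)` where a and b are the
#' binary feature vectors of items i and j.  For 0/1 inputs entries lie in
#' `[0, 1]`: identical vectors give 0, feature-disjoint vectors give 1.
#'
#' @param features items x features matrix with entries in `{0, 1}`; no
#'   all-zero row.
#' @return an `rdm` with metric `"cosine-distance"`.
#' @export
rdm_from_binary_features <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need at least 3 items")
  if (!all(features %in% c(0, 1))) stop("features must be 0/1")
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm == 0)) {
    bad <- rownames(features)[nrm == 0] %||% which(nrm == 0)
    stop("all-zero feature row(s): ", paste(bad, collapse = ", "))
  }
  s <- tcrossprod(features / nrm)
  d <- pmin(pmax(1 - s, 0), 1)
  new_rdm(d, metric = "cosine-distance", item_labels = rownames(features))
}

#' Vectorise the upper triangle of an RDM
#'
#' Returns the row-major upper triangle (diagonal excluded): pairs are
#' ordered (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).  This ordering is
#' fixed; [devectorize()] inverts it.
#'
#' @param rdm an `rdm` or symmetric matrix.
#' @return an `rdv`: numeric vector of length `n (n - 1) / 2` with
#'   attributes `item_labels` and `metric`.
#' @export
vectorize_upper <- function(rdm) {
  m <- as.matrix(rdm)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("input must be a symmetric matrix")
  n <- nrow(m)
  idx <- which(upper.tri(m))
  # which() on upper.tri is column-major: (1,2), (1,3), (2,3), ... which is
  # identical to row-major upper-triangle order for a symmetric matrix's
  # pair set ordered by (min, max); reorder to row-major explicitly.
  pairs <- arrayInd(idx, c(n, n))
  ord <- order(pairs[, 1L], pairs[, 2L])
  structure(m[idx][ord],
            item_labels = rownames(m) %||% paste0("item", seq_len(n)),
            metric = attr(rdm, "metric"),
            class = "rdv")
}

#' Rebuild an RDM from its vectorised upper triangle
#'
#' @param rdv an `rdv` as produced by [vectorize_upper()].
#' @param item_labels optional labels overriding the ones stored on `rdv`.
#' @return an `rdm`.
#' @export
devectorize <- function(rdv, item_labels = NULL) {
  v <- as.numeric(rdv)
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n)) stop("length is not n(n-1)/2 for any integer n")
  n <- as.integer(n)
  m <- matrix(0, n, n)
  m[t(upper.tri(m))] <- v        # fill row-major upper triangle
  m <- t(m)
  m <- m + t(m)
  labels <- item_labels %||% attr(rdv, "item_labels")
  new_rdm(m, metric = attr(rdv, "metric") %||% "unknown",
          item_labels = labels)
}

#' @export
print.rdv <- function(x, ...) {
  cat(sprintf("RDV: %d pairs (%d items)\n", length(x),
              length(attr(x, "item_labels"))))
  print(utils::head(as.numeric(x)))
  invisible(x)
}

# Pair index helper: for n items, returns the (i, j) row/col of each RDV
# element in row-major upper-triangle order.
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = j)
}

#' Restrict RDM-like objects to a subset of items
#'
#' Drops invalid items (e.g. incorrectly named trials) consistently from
#' model and neural objects so that pair orderings stay aligned.
#' Subsetting commutes with vectorisation.
#'
#' @param x an `rdm`, `rdv`, or `neural_rdm_series`.
#' @param valid_items logical mask over items, or integer indices, or
#'   character labels to keep.
#' @return an object of the same class restricted to the surviving items.
#' @export
subset_items <- function(x, valid_items) UseMethod("subset_items")

resolve_mask <- function(valid_items, labels) {
  n <- length(labels)
  if (is.logical(valid_items)) {
    if (length(valid_items) != n) stop("mask length must equal item count")
    keep <- which(valid_items)
  } else if (is.character(valid_items)) {
    keep <- match(valid_items, labels)
    if (anyNA(keep)) stop("unknown item label(s)")
  } else {
    keep <- as.integer(valid_items)
    if (any(keep < 1L | keep > n)) stop("item index out of range")
  }
  if (length(keep) < 3L) stop("fewer than 3 items survive the mask")
  sort(keep)
}

#' @export
subset_items.rdm <- function(x, valid_items) {
  keep <- resolve_mask(valid_items, rownames(x))
  new_rdm(unclass(x)[keep, keep, drop = FALSE], metric = attr(x, "metric"),
          item_labels = rownames(x)[keep])
}

#' @export
subset_items.rdv <- function(x, valid_items) {
  labels <- attr(x, "item_labels")
  keep <- resolve_mask(valid_items, labels)
  n <- length(labels)
  pi <- pair_index(n)
  sel <- pi[, 1L] %in% keep & pi[, 2L] %in% keep
  structure(as.numeric(x)[sel], item_labels = labels[keep],
            metric = attr(x, "metric"), class = "rdv")
}
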