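# Group-level inference: sign-flip cluster-mass permutation tests
# (temporal and spatiotemporal) and leave-n-out jackknife confidence
# intervals for peak latencies.

# Contiguous supra-threshold runs in a t-value vector.  NA (invalid)
# timepoints break runs: clusters cannot bridge gaps.
find_runs <- function(supra) {
  r <- rle(ifelse(is.na(supra), FALSE, supra))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) starts[k]:ends[k])
}

# t statistics for every column of a subjects x timepoints matrix under a
# set of sign-flip vectors.  `signs` is permutations x subjects; returns
# permutations x timepoints.  Uses the identity that flipping signs leaves
# each subject's squared value unchanged, so only the mean changes.
flip_t_matrix <- function(effects, signs) {
  n <- nrow(effects)
  ss <- colSums(effects^2)                       # invariant under flips
  m <- (signs %*% effects) / n                   # perms x T
  varr <- sweep(-n * m^2, 2L, ss, `+`) / (n - 1)
  varr[varr < 0] <- 0
  m / sqrt(varr / n)
}

cluster_stats <- function(tvals, threshold, tail) {
  if (tail == "positive") {
    runs <- find_runs(tvals > threshold)
    masses <- vapply(runs, function(ix) sum(tvals[ix]), numeric(1L))
  } else {
    runs_p <- find_runs(tvals > threshold)
    runs_n <- find_runs(tvals < -threshold)
    runs <- c(runs_p, runs_n)
    masses <- vapply(runs, function(ix) sum(abs(tvals[ix])), numeric(1L))
  }
  list(runs = runs, masses = masses)
}

sign_matrix <- function(n_subjects, n_permutations) {
  if (2^n_subjects <= n_permutations) {
    # Full enumeration of all sign patterns (identity included).
    g <- as.matrix(expand.grid(rep(list(c(1, -1)), n_subjects)))
    dimnames(g) <- NULL
    list(signs = g, exact = TRUE)
  } else {
    list(signs = matrix(sample(c(1, -1), n_permutations * n_subjects,
                               replace = TRUE),
                        n_permutations, n_subjects),
         exact = FALSE)
  }
}

new_cluster_set <- function(clusters, alpha_forming, n_permutations, tail,
                            exact, time_ms = NULL) {
  structure(list(clusters = clusters, alpha_forming = alpha_forming,
                 n_permutations = n_permutations, tail = tail,
                 exact_enumeration = exact, time_ms = time_ms),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s), alpha_forming = %g, %s (%d)\n",
              length(x$clusters), x$alpha_forming,
              if (x$exact_enumeration) "exact enumeration" else "permutations",
              x$n_permutations))
  for (cl in x$clusters)
    cat(sprintf("  [%g..%g ms] n = %d, mass = %.2f, p = %.5g\n",
                cl$start_ms, cl$end_ms, cl$n_members, cl$mass, cl$p_value))
  invisible(x)
}

#' Significant clusters of a cluster set
#'
#' @param x a `cluster_set`.
#' @param alpha significance level (default 0.05).
#' @return the subset of clusters with `p_value < alpha`.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  Filter(function(cl) cl$p_value < alpha, x$clusters)
}

#' Temporal sign-flip cluster-mass permutation test
#'
#' One-sample t-test against zero at each timepoint; clusters are
#' contiguous runs of supra-threshold t-values (positive tail by default),
#' with cluster mass the sum of member t-values.  The null distribution is
#' the maximum cluster mass after randomly flipping the sign of each
#' subject's whole time-course; p-values include the observed statistic in
#' the reference set, so p >= 1 / (n_permutations + 1).  When
#' `2^n_subjects <= n_permutations` all sign patterns are enumerated and
#' the p-values are exact.
#'
#' @param effects subjects x timepoints matrix (or `rsa_timecourses`).
#'   NA columns (window-invalid edges) are excluded from cluster forming;
#'   clusters cannot bridge them.
#' @param time_ms time axis (taken from `effects` if it carries one).
#' @param alpha_forming cluster-forming significance level (default 0.01).
#' @param n_permutations number of sign-flip permutations (default 10000).
#' @param tail `"positive"` (default) or `"two-sided"`.
#' @param seed RNG seed for the sign flips.
#' @return a `cluster_set`; each cluster records member timepoints, start
#'   and end in ms, mass, and p-value.
#' @export
cluster_test_temporal <- function(effects, time_ms = NULL,
                                  alpha_forming = 0.01,
                                  n_permutations = 10000,
                                  tail = c("positive", "two-sided"),
                                  seed = 1L) {
  tail <- match.arg(tail)
  if (inherits(effects, "rsa_timecourses")) {
    time_ms <- time_ms %||% effects$time_ms
    effects <- effects$effects
  }
  effects <- as.matrix(effects)
  n <- nrow(effects)
  if (n < 4L) stop("need at least 4 subjects")
  if (n_permutations < 100L) warning("fewer than 100 permutations")
  col_ok <- colSums(is.na(effects)) == 0L
  if (any(!is.finite(effects[, col_ok]))) stop("non-finite effects")
  time_ms <- time_ms %||% seq_len(ncol(effects))
  work <- effects[, col_ok, drop = FALSE]
  df <- n - 1L
  thr <- stats::qt(1 - alpha_forming, df)

  sm <- with_seed(seed, sign_matrix(n, n_permutations))
  tmat <- flip_t_matrix(work, sm$signs)
  t_obs_work <- if (sm$exact) {
    # take the identity row of the enumeration itself so the observed
    # masses are bitwise comparable with the null distribution
    tmat[which(rowSums(sm$signs == 1) == n)[1L], ]
  } else flip_t_matrix(work, matrix(1, 1L, n))[1L, ]
  # Re-embed observed t-values into the full (gappy) time axis so run
  # boundaries respect invalid timepoints.
  t_obs <- rep(NA_real_, ncol(effects))
  t_obs[col_ok] <- t_obs_work
  obs <- cluster_stats(t_obs, thr, tail)

  null_max <- vapply(seq_len(nrow(tmat)), function(p) {
    tv <- rep(NA_real_, ncol(effects))
    tv[col_ok] <- tmat[p, ]
    cs <- cluster_stats(tv, thr, tail)
    if (length(cs$masses)) max(cs$masses) else 0
  }, numeric(1L))

  clusters <- lapply(seq_along(obs$runs), function(i) {
    ix <- obs$runs[[i]]
    p_val <- if (sm$exact) mean(null_max >= obs$masses[i])
    else (1 + sum(null_max >= obs$masses[i])) / (nrow(tmat) + 1)
    list(members = ix, start_ms = time_ms[min(ix)],
         end_ms = time_ms[max(ix)], n_members = length(ix),
         mass = obs$masses[i], p_value = p_val)
  })
  new_cluster_set(clusters, alpha_forming,
                  if (sm$exact) nrow(tmat) else n_permutations,
                  tail, sm$exact, time_ms)
}

# Connected components of a spatiotemporal supra-threshold mask: elements
# (point, time) connect to the same point at adjacent timepoints and to
# adjacent points at the same timepoint.  Breadth-first labelling.
spatiotemporal_components <- function(mask, adjacency) {
  n_p <- nrow(mask); n_t <- ncol(mask)
  labels <- matrix(0L, n_p, n_t)
  nb <- lapply(seq_len(n_p), function(p) which(adjacency[p, ]))
  comp <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      el <- queue[[1L]]; queue <- queue[-1L]
      p <- (el - 1L) %% n_p + 1L
      t <- (el - 1L) %/% n_p + 1L
      cand <- integer()
      if (t > 1L) cand <- c(cand, el - n_p)
      if (t < n_t) cand <- c(cand, el + n_p)
      if (length(nb[[p]])) cand <- c(cand, (t - 1L) * n_p + nb[[p]])
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- comp
      queue <- c(queue, cand)
    }
  }
  labels
}

#' Spatiotemporal sign-flip cluster-mass permutation test
#'
#' As [cluster_test_temporal()], but supra-threshold (point, time)
#' elements are clustered by connectivity in space (a symmetric adjacency
#' relation over points) and time (same point, consecutive timepoints).
#' With a single point it reduces exactly to the temporal test.
#'
#' @param effects array points x timepoints x subjects.
#' @param adjacency symmetric logical points x points matrix (diagonal
#'   ignored).
#' @param time_ms optional time axis.
#' @param alpha_forming cluster-forming level (default 0.01).
#' @param n_permutations number of permutations (default 1000).
#' @param tail `"positive"` or `"two-sided"`.
#' @param seed RNG seed.
#' @return a `cluster_set`; members are (point, time) index pairs.
#' @export
cluster_test_spatiotemporal <- function(effects, adjacency, time_ms = NULL,
                                        alpha_forming = 0.01,
                                        n_permutations = 1000,
                                        tail = c("positive", "two-sided"),
                                        seed = 1L) {
  tail <- match.arg(tail)
  stopifnot(length(dim(effects)) == 3L)
  n_p <- dim(effects)[1L]; n_t <- dim(effects)[2L]; n <- dim(effects)[3L]
  if (n < 4L) stop("need at least 4 subjects")
  adjacency <- as.matrix(adjacency)
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  diag(adjacency) <- FALSE
  if (any(!is.finite(effects))) stop("non-finite effects")
  time_ms <- time_ms %||% seq_len(n_t)
  df <- n - 1L
  thr <- stats::qt(1 - alpha_forming, df)

  flat <- matrix(aperm(effects, c(3L, 1L, 2L)), n)   # subjects x (p*t)
  sm <- with_seed(seed, sign_matrix(n, n_permutations))
  tperm <- flip_t_matrix(flat, sm$signs)
  t_obs_vec <- if (sm$exact)
    tperm[which(rowSums(sm$signs == 1) == n)[1L], ]
  else flip_t_matrix(flat, matrix(1, 1L, n))[1L, ]
  t_obs <- matrix(t_obs_vec, n_p, n_t)

  mask_stats <- function(tv) {
    mask <- if (tail == "positive") tv > thr else abs(tv) > thr
    if (!any(mask)) return(list(labels = NULL, masses = numeric()))
    labels <- spatiotemporal_components(mask, adjacency)
    ids <- seq_len(max(labels))
    masses <- vapply(ids, function(i) sum(abs(tv)[labels == i]),
                     numeric(1L))
    list(labels = labels, masses = masses)
  }
  obs <- mask_stats(t_obs)
  null_max <- vapply(seq_len(nrow(tperm)), function(p) {
    st <- mask_stats(matrix(tperm[p, ], n_p, n_t))
    if (length(st$masses)) max(st$masses) else 0
  }, numeric(1L))

  clusters <- lapply(seq_along(obs$masses), function(i) {
    el <- which(obs$labels == i, arr.ind = TRUE)
    p_val <- if (sm$exact) mean(null_max >= obs$masses[i])
    else (1 + sum(null_max >= obs$masses[i])) / (nrow(tperm) + 1)
    list(members = el, start_ms = time_ms[min(el[, 2L])],
         end_ms = time_ms[max(el[, 2L])], n_members = nrow(el),
         n_points = length(unique(el[, 1L])), mass = obs$masses[i],
         p_value = p_val)
  })
  new_cluster_set(clusters, alpha_forming,
                  if (sm$exact) nrow(tperm) else n_permutations,
                  tail, sm$exact, time_ms)
}

#' Exact number of leave-n-out jackknife resamples
#'
#' The binomial coefficient `C(pool, n_leave_out)`, computed with exact
#' integer arithmetic.
#'
#' @param pool pool size (number of subjects).
#' @param n_leave_out subjects left out per resample.
#' @return the exact count as a numeric scalar.
#' @export
count_resamples <- function(pool, n_leave_out) {
  if (pool < 0 || n_leave_out < 0) stop("arguments must be nonnegative")
  if (n_leave_out > pool) return(0)
  k <- min(n_leave_out, pool - n_leave_out)
  res <- 1
  for (i in seq_len(k)) res <- (res * (pool - k + i)) / i  # exact at each step
  round(res)
}

#' Jackknife confidence intervals for peak-latency differences
#'
#' For every leave-`n_leave_out`-out subset of the subject pool, the
#' retained subjects' time-courses are averaged per model and the time of
#' the maximum effect inside the search window recorded (first occurrence
#' on ties).  The 95% CI of each pairwise latency difference is the
#' 2.5th/97.5th percentile of the resample distribution of differences;
#' the difference is significant when its CI excludes zero.
#'
#' @param effects_list named list of subjects x timepoints matrices (or
#'   `rsa_timecourses`), same subjects and time axis throughout.
#' @param time_ms time axis in ms.
#' @param n_leave_out subjects left out per resample (default 4).
#' @param search_window_ms length-2 window restricting the peak search;
#'   default post-stimulus times (`time >= 0`).
#' @param max_resamples cap on the enumeration; beyond it a random
#'   subsample of this size is used and flagged.
#' @param seed RNG seed (used only when subsampling).
#' @return a `peak_latency_result`: resample peak times per model, the
#'   95% CI of each pairwise difference, and bookkeeping fields.
#' @export
jackknife_peak_ci <- function(effects_list, time_ms = NULL,
                              n_leave_out = 4L, search_window_ms = NULL,
                              max_resamples = 100000L, seed = 1L) {
  effects_list <- lapply(effects_list, function(e) {
    if (inherits(e, "rsa_timecourses")) {
      time_ms <<- time_ms %||% e$time_ms
      e$effects
    } else as.matrix(e)
  })
  if (is.null(names(effects_list)))
    names(effects_list) <- paste0("model", seq_along(effects_list))
  pool <- nrow(effects_list[[1L]])
  if (pool <= n_leave_out + 1L) stop("pool too small for n_leave_out")
  time_ms <- time_ms %||% seq_len(ncol(effects_list[[1L]]))
  win <- search_window_ms %||% c(0, max(time_ms))
  in_win <- which(time_ms >= win[1L] & time_ms <= win[2L])
  if (!length(in_win)) stop("empty search window")

  n_total <- count_resamples(pool, n_leave_out)
  combos <- utils::combn(pool, n_leave_out)
  subsampled <- FALSE
  if (ncol(combos) > max_resamples) {
    combos <- combos[, with_seed(seed, sample.int(ncol(combos),
                                                  max_resamples)),
                     drop = FALSE]
    subsampled <- TRUE
    warning("resample enumeration capped at ", max_resamples,
            " of ", n_total)
  }
  n_res <- ncol(combos)
  n_keep <- pool - n_leave_out

  peaks <- sapply(effects_list, function(e) {
    e_win <- e[, in_win, drop = FALSE]
    tot <- colSums(e_win)
    vapply(seq_len(n_res), function(r) {
      m <- (tot - colSums(e_win[combos[, r], , drop = FALSE])) / n_keep
      time_ms[in_win[which.max(m)]]
    }, numeric(1L))
  })
  peaks <- matrix(peaks, nrow = n_res,
                  dimnames = list(NULL, names(effects_list)))

  mods <- names(effects_list)
  ci <- list()
  if (length(mods) > 1L) {
    for (a in seq_along(mods)) for (b in seq_along(mods)) {
      if (a >= b) next
      d <- peaks[, a] - peaks[, b]
      ci[[paste(mods[a], mods[b], sep = " - ")]] <-
        unname(stats::quantile(d, c(0.025, 0.975)))
    }
  }
  structure(list(resample_peaks = peaks, n_leave_out = n_leave_out,
                 n_resamples = n_res, n_possible = n_total,
                 subsampled = subsampled, ci_95 = ci,
                 search_window_ms = win),
            class = "peak_latency_result")
}

#' @export
print.peak_latency_result <- function(x, ...) {
  cat(sprintf(
    "peak_latency_result: %d resamples (leave-%d-out%s)\n",
    x$n_resamples, x$n_leave_out,
    if (x$subsampled) ", subsampled" else ""))
  for (nm in names(x$ci_95))
    cat(sprintf("  %s: 95%% CI [%g, %g] ms\n", nm,
                x$ci_95[[nm]][1L], x$ci_95[[nm]][2L]))
  invisible(x)
}
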