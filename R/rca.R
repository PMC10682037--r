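# Representational connectivity analysis (RCA): direction-specific,
# time-lagged information flow between regions, measured as the drop in a
# model's partial-correlation RSA when the source region's past RDVs are
# additionally partialled out.

#' Lag window for representational connectivity
#'
#' The set of strictly negative lags (in ms) at which past source-region
#' RDVs enter the partial correlation as covariates.  The default covers
#' -30 to -2 ms inclusive at the data's sampling step: at 500 Hz that is
#' -30, -28, ..., -2; at 200 Hz it is -30, -25, ..., -5.  Each lag
#' contributes one covariate RDV.
#'
#' @param sfreq sampling rate in Hz.
#' @param range_ms length-2 negative range, default `c(-30, -2)`.
#' @return numeric vector of negative lags in ms (multiples of the sample
#'   period).
#' @export
lag_window_ms <- function(sfreq, range_ms = c(-30, -2)) {
  if (any(range_ms >= 0)) stop("lags must be strictly negative")
  step <- 1000 / sfreq
  k <- seq(floor(range_ms[1L] / step), ceiling(range_ms[2L] / step))
  lags <- k * step
  lags <- lags[lags >= range_ms[1L] - 1e-9 & lags <= range_ms[2L] + 1e-9]
  if (!length(lags)) stop("no sample lags inside the requested range")
  sort(lags)
}

# Rank every valid row of a neural RDM series once; invalid rows are NA.
rank_series <- function(series) {
  out <- matrix(NA_real_, nrow(series$rdvs), ncol(series$rdvs))
  for (t in which(series$valid_timepoints)) {
    v <- series$rdvs[t, ]
    if (!anyNA(v)) out[t, ] <- rank(v)
  }
  out
}

#' Time-lagged representational connectivity flow (one subject)
#'
#' At each timepoint t two partial Spearman correlations between the
#' target region's RDV and the model RDV are computed.  The first controls
#' for the covariate model RDVs (and, in the multivariate variant, the
#' lagged RDVs of every control region); the second additionally controls
#' for the source region's lagged RDVs at every lag in the window.  The
#' flow is their difference: positive flow means the source's earlier
#' representational state helps explain the target's current model-related
#' geometry.  Timepoints whose full lag window falls outside the epoch are
#' undefined (NA).
#'
#' Source, target, and control series must be single-timepoint RDM series
#' on a shared time axis, so lagged source RDVs never share samples with
#' the current target RDV.
#'
#' @param source,target `neural_rdm_series` for the two regions.
#' @param model model RDV.
#' @param model_covariates list of other model RDVs controlled in both
#'   correlations.
#' @param lag_window negative lags in ms (default: [lag_window_ms()] at
#'   the series' sampling step).
#' @param region_covariates list of `neural_rdm_series` whose lagged RDVs
#'   are partialled out in both correlations (three-region variant).
#' @return an `rca_result`: list with `flow`, `rho1`, `rho2` (one value
#'   per timepoint), `time_ms`, `direction`, `lag_window`.
#' @export
rca_flow <- function(source, target, model, model_covariates = list(),
                     lag_window = NULL, region_covariates = list()) {
  stopifnot(inherits(source, "neural_rdm_series"),
            inherits(target, "neural_rdm_series"))
  if (!isTRUE(all.equal(source$time_ms, target$time_ms)))
    stop("source and target must share a time axis")
  if (!identical(source$item_labels, target$item_labels))
    stop("source and target must share an item set")
  check_item_alignment(target, model)
  step <- stats::median(diff(target$time_ms))
  lag_window <- lag_window %||% lag_window_ms(1000 / step)
  lag_samp <- round(lag_window / step)
  if (max(abs(lag_window - lag_samp * step)) > 1e-6)
    warning("lags rounded to the nearest sample")
  lag_samp <- as.integer(lag_samp)
  if (any(lag_samp >= 0L)) stop("all lags must be strictly negative")

  n_t <- nrow(target$rdvs)
  n_pairs <- ncol(target$rdvs)
  rm_ <- rank(as.numeric(model))
  zc <- if (length(model_covariates))
    vapply(model_covariates, function(v) rank(as.numeric(v)),
           numeric(n_pairs))
  r_tgt <- rank_series(target)
  r_src <- rank_series(source)
  r_ctl <- lapply(region_covariates, rank_series)

  rho1 <- rho2 <- rep(NA_real_, n_t)
  rank_deficient <- FALSE
  for (t in seq_len(n_t)) {
    if (anyNA(r_tgt[t, ])) next
    t_lag <- t + lag_samp
    if (any(t_lag < 1L)) next
    src_block <- t(r_src[t_lag, , drop = FALSE])
    if (anyNA(src_block)) next
    ctl_block <- NULL
    if (length(r_ctl)) {
      ctl_block <- do.call(cbind, lapply(r_ctl, function(rc)
        t(rc[t_lag, , drop = FALSE])))
      if (anyNA(ctl_block)) next
    }
    z1 <- cbind(zc, ctl_block)
    z2 <- cbind(z1, src_block)
    if (!is.null(z1) && qr(cbind(1, z1))$rank < ncol(z1) + 1L)
      rank_deficient <- TRUE
    rho1[t] <- as.numeric(partial_cor_ranked(r_tgt[t, ], rm_, z1))
    rho2[t] <- as.numeric(partial_cor_ranked(r_tgt[t, ], rm_, z2))
  }
  if (rank_deficient)
    warning("rank-deficient covariates at some timepoints; ",
            "dependent covariates dropped")
  structure(list(flow = rho1 - rho2, rho1 = rho1, rho2 = rho2,
                 time_ms = target$time_ms,
                 direction = c(source = source$channel_set,
                               target = target$channel_set),
                 lag_window = lag_window,
                 n_region_covariates = length(region_covariates)),
            class = "rca_result")
}

#' @export
print.rca_result <- function(x, ...) {
  ok <- !is.na(x$flow)
  cat(sprintf("rca_result %s -> %s: %d defined timepoints, peak flow %.3f\n",
              x$direction[["source"]], x$direction[["target"]],
              sum(ok), if (any(ok)) max(x$flow[ok]) else NA))
  invisible(x)
}

#' Feedforward and feedback flow for a region pair (one subject)
#'
#' Runs [rca_flow()] in both directions with identical model and region
#' covariates.  By convention region A is the lower-order (posterior)
#' region, so `forward` is A -> B and `backward` is B -> A.
#'
#' @param region_a,region_b single-timepoint `neural_rdm_series`.
#' @inheritParams rca_flow
#' @return list with elements `forward` (A as source) and `backward`
#'   (B as source), both `rca_result`s.
#' @export
feedforward_feedback_pair <- function(region_a, region_b, model,
                                      model_covariates = list(),
                                      lag_window = NULL,
                                      region_covariates = list()) {
  list(forward = rca_flow(region_a, region_b, model, model_covariates,
                          lag_window, region_covariates),
       backward = rca_flow(region_b, region_a, model, model_covariates,
                           lag_window, region_covariates))
}

#' Stack per-subject RCA flows into a group matrix
#'
#' @param results list of `rca_result`s (one per subject).
#' @return subjects x timepoints matrix of flows with the time axis as an
#'   attribute.
#' @export
rca_flow_matrix <- function(results) {
  flows <- t(vapply(results, function(r) r$flow,
                    numeric(length(results[[1L]]$flow))))
  attr(flows, "time_ms") <- results[[1L]]$time_ms
  flows
}

#' Median split of subjects by response time
#'
#' Orders subjects by mean response time (ties broken by subject index)
#' and splits at the median: the faster half first.  For odd counts the
#' slow group takes the extra subject, so group sizes differ by at most 1.
#'
#' @param rts_ms per-subject mean response times.
#' @return list with integer index vectors `fast` and `slow`.
#' @export
median_split <- function(rts_ms) {
  n <- length(rts_ms)
  if (n < 6L) stop("too few subjects for a median split")
  ord <- order(rts_ms, seq_len(n))
  n_fast <- floor(n / 2)
  list(fast = sort(ord[seq_len(n_fast)]),
       slow = sort(ord[(n_fast + 1L):n]))
}

#' Group contrast of RCA flows (independent groups)
#'
#' Independent-samples t-test (pooled variance) per timepoint of
#' group 1 minus group 2, followed by cluster-mass correction with a
#' label-exchange permutation scheme: group assignments are reshuffled
#' across subjects, preserving group sizes.  Positive tail by default
#' (testing group 1 > group 2); two-sided available.
#'
#' @param flows1,flows2 subjects x timepoints flow matrices (e.g. from
#'   [rca_flow_matrix()]); timepoints undefined in either group are
#'   excluded.
#' @param time_ms time axis (defaults to the attribute on `flows1`).
#' @param alpha_forming cluster-forming level (default 0.05; between-
#'   subject contrasts carry less power than within-subject tests).
#' @param n_permutations label permutations (default 1000).
#' @param tail `"positive"` or `"two-sided"`.
#' @param seed RNG seed.
#' @return a `cluster_set`.
#' @export
rca_group_contrast <- function(flows1, flows2, time_ms = NULL,
                               alpha_forming = 0.05,
                               n_permutations = 1000,
                               tail = c("positive", "two-sided"),
                               seed = 1L) {
  tail <- match.arg(tail)
  flows1 <- as.matrix(flows1); flows2 <- as.matrix(flows2)
  n1 <- nrow(flows1); n2 <- nrow(flows2)
  if (min(n1, n2) < 3L) stop("each group needs at least 3 subjects")
  time_ms <- time_ms %||% attr(flows1, "time_ms") %||%
    seq_len(ncol(flows1))
  all_f <- rbind(flows1, flows2)
  col_ok <- colSums(is.na(all_f)) == 0L
  work <- all_f[, col_ok, drop = FALSE]
  if (any(apply(work, 2L, stats::sd) == 0))
    stop("zero-variance timepoint; degenerate input")
  df <- n1 + n2 - 2L
  thr <- stats::qt(1 - if (tail == "positive") alpha_forming
                   else alpha_forming / 2, df)

  two_sample_t <- function(g1) {
    a <- work[g1, , drop = FALSE]
    b <- work[-g1, , drop = FALSE]
    ma <- colMeans(a); mb <- colMeans(b)
    sp <- ((n1 - 1) * apply(a, 2L, stats::var) +
             (n2 - 1) * apply(b, 2L, stats::var)) / df
    (ma - mb) / sqrt(sp * (1 / n1 + 1 / n2))
  }
  embed <- function(tv) {
    out <- rep(NA_real_, ncol(all_f)); out[col_ok] <- tv; out
  }
  t_obs <- embed(two_sample_t(seq_len(n1)))
  obs <- cluster_stats(t_obs, thr, tail)
  null_max <- with_seed(seed, vapply(seq_len(n_permutations), function(p) {
    g1 <- sample.int(n1 + n2, n1)
    cs <- cluster_stats(embed(two_sample_t(g1)), thr, tail)
    if (length(cs$masses)) max(cs$masses) else 0
  }, numeric(1L)))
  clusters <- lapply(seq_along(obs$runs), function(i) {
    ix <- obs$runs[[i]]
    list(members = ix, start_ms = time_ms[min(ix)],
         end_ms = time_ms[max(ix)], n_members = length(ix),
         mass = obs$masses[i],
         p_value = (1 + sum(null_max >= obs$masses[i])) /
           (n_permutations + 1))
  })
  new_cluster_set(clusters, alpha_forming, n_permutations, tail,
                  exact = FALSE, time_ms)
}

#' Paired contrast between two connections
#'
#' For the same subjects measured on two connections (or conditions),
#' feeds the per-subject difference time-courses to the temporal sign-flip
#' cluster test.
#'
#' @param flows1,flows2 subjects x timepoints flow matrices with matching
#'   subject order.
#' @inheritParams cluster_test_temporal
#' @return a `cluster_set` on the differences (`flows1 - flows2`).
#' @export
rca_connection_contrast <- function(flows1, flows2, time_ms = NULL,
                                    alpha_forming = 0.05,
                                    n_permutations = 1000,
                                    tail = c("positive", "two-sided"),
                                    seed = 1L) {
  flows1 <- as.matrix(flows1); flows2 <- as.matrix(flows2)
  if (!all(dim(flows1) == dim(flows2)))
    stop("subject mismatch between the two connections")
  time_ms <- time_ms %||% attr(flows1, "time_ms")
  cluster_test_temporal(flows1 - flows2, time_ms = time_ms,
                        alpha_forming = alpha_forming,
                        n_permutations = n_permutations,
                        tail = tail, seed = seed)
}
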