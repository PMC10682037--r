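# Synthetic-data generator: model feature matrices and multi-region
# epoched datasets with known injected representational geometry, known
# latencies, and lagged inter-region coupling.  Every downstream stage of
# the pipeline can be validated against the ground truth this module
# records.

#' Specify a synthetic model feature matrix
#'
#' Stands in for the feature spaces from which model RDMs are built:
#' continuous activations (ANN-layer style) or binary semantic features
#' (property-norm style).  `correlation_to` requests that the resulting
#' RDV correlate with another model's RDV at a target Spearman rho,
#' achieved by mixing a shared latent feature block with private features.
#'
#' @param name model label.
#' @param n_items number of items (>= 3).
#' @param n_features number of features (>= 2).
#' @param family `"continuous-activation"` or `"binary-feature"`.
#' @param correlation_to optional label of a previously built model.
#' @param target_rho target Spearman correlation between the two RDVs
#'   (required with `correlation_to`).
#' @param seed integer seed for this model's draws.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(name, n_items, n_features,
                       family = c("continuous-activation", "binary-feature"),
                       correlation_to = NULL, target_rho = NULL,
                       seed = 1L) {
  family <- match.arg(family)
  if (n_items < 3L) stop("n_items must be >= 3")
  if (n_features < 2L) stop("n_features must be >= 2")
  if (!is.null(correlation_to) && is.null(target_rho))
    stop("target_rho is required with correlation_to")
  structure(list(name = name, n_items = as.integer(n_items),
                 n_features = as.integer(n_features), family = family,
                 correlation_to = correlation_to, target_rho = target_rho,
                 seed = as.integer(seed)),
            class = "model_spec")
}

rdm_for_family <- function(features, family) {
  if (family == "binary-feature") rdm_from_binary_features(features)
  else rdm_from_activations(features)
}

#' Generate a feature matrix from a model specification
#'
#' Continuous models draw i.i.d. Gaussian activations; binary models draw
#' per-feature occurrence probabilities in (0.05, 0.5) and Bernoulli
#' entries (resampling any all-zero item row), so the expected feature
#' count per item exceeds 1.  When `correlation_to` is set, items share a
#' latent block with the reference model: the mixing weight is calibrated
#' by bisection on the realised RDV Spearman correlation, which is
#' monotone in the weight.  Binary models threshold the mixed latent at
#' the drawn per-feature rates.
#'
#' @param spec a [model_spec()].
#' @param reference optional named list with the reference model's
#'   `features` matrix and `rdv` (required when `correlation_to` is set).
#' @return items x features numeric matrix with item-label rownames.
#' @export
make_feature_matrix <- function(spec, reference = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n_items
  p <- spec$n_features
  labels <- paste0("item", seq_len(n))
  with_seed(spec$seed, {
    if (is.null(spec$correlation_to)) {
      if (spec$family == "continuous-activation") {
        f <- matrix(stats::rnorm(n * p), n, p)
      } else {
        prob <- stats::runif(p, 0.05, 0.5)
        f <- matrix(stats::rbinom(n * p, 1L, rep(prob, each = n)), n, p)
        f <- fix_zero_rows(f, prob)
      }
      rownames(f) <- labels
      return(f)
    }
    if (is.null(reference) || is.null(reference$features))
      stop("reference features are required with correlation_to")
    if (spec$target_rho > 0.95) {
      ref_fam <- reference$family %||% "continuous-activation"
      if (!identical(ref_fam, spec$family))
        stop("target_rho > 0.95 is unsatisfiable across disjoint families")
    }
    # Shared latent block: standardised reference features, recycled to
    # this model's width; private block: fresh Gaussian noise.
    ref <- scale(reference$features)
    ref[!is.finite(ref)] <- 0
    cols <- sample.int(ncol(ref), p, replace = p > ncol(ref))
    shared <- ref[, cols, drop = FALSE]
    noise <- matrix(stats::rnorm(n * p), n, p)
    prob <- stats::runif(p, 0.05, 0.5)
    ref_rdv <- reference$rdv %||%
      vectorize_upper(rdm_for_family(reference$features,
                                     reference$family %||%
                                       "continuous-activation"))
    build <- function(lambda) {
      latent <- lambda * shared + sqrt(1 - lambda^2) * noise
      if (spec$family == "binary-feature") {
        f <- sweep(latent, 2L, stats::qnorm(1 - prob), `>`) * 1L
        fix_zero_rows(f, prob)
      } else latent
    }
    realised <- function(lambda) {
      f <- build(lambda)
      stats::cor(as.numeric(vectorize_upper(rdm_for_family(f, spec$family))),
                 as.numeric(ref_rdv), method = "spearman")
    }
    lo <- 0; hi <- 1
    if (realised(1) < spec$target_rho - 0.1)
      stop("correlation_to target ", spec$target_rho,
           " is unattainable for model '", spec$name, "'")
    lambda <- 1
    for (it in seq_len(20L)) {
      lambda <- (lo + hi) / 2
      r <- realised(lambda)
      if (abs(r - spec$target_rho) < 0.02) break
      if (r < spec$target_rho) lo <- lambda else hi <- lambda
    }
    f <- build(lambda)
    rownames(f) <- labels
    f
  })
}

fix_zero_rows <- function(f, prob) {
  zero <- which(rowSums(f) == 0)
  for (i in zero) f[i, sample.int(ncol(f), 1L, prob = prob)] <- 1L
  f
}

#' Embed an RDM as multichannel item patterns
#'
#' Produces an items x channels pattern matrix whose pairwise
#' Pearson-distance RDM reproduces the input RDM.  Construction: the
#' similarity matrix `1 - D` is eigendecomposed, non-negative components
#' are kept (classical-scaling coordinates) and renormalised to unit item
#' norms, then mixed into channel space through a random orthonormal basis
#' whose vectors are mean-free across channels.  That mean-free mixing
#' makes the sample Pearson correlation of two pattern rows equal their
#' latent inner product, so the recovered RDM matches the input exactly
#' when `1 - D` is positive semi-definite (as it is for any
#' correlation-distance RDM) and to high rank-accuracy otherwise.
#'
#' @param rdm an `rdm` (symmetric, zero diagonal).
#' @param n_channels number of channels (must exceed the embedding rank).
#' @param seed integer seed for the random channel mixing.
#' @return items x channels numeric matrix.
#' @export
embed_item_patterns <- function(rdm, n_channels, seed = 1L) {
  d <- as.matrix(rdm)
  if (max(abs(d - t(d))) > 1e-8 || max(abs(diag(d))) > 1e-8)
    stop("rdm must be symmetric with zero diagonal")
  n <- nrow(d)
  with_seed(seed, {
    if (all(d == 0)) {
      # Degenerate: all items identical; emit one shared random pattern.
      q <- stats::rnorm(n_channels)
      return(matrix(q, n, n_channels, byrow = TRUE,
                    dimnames = list(rownames(d), NULL)))
    }
    s <- 1 - d
    eig <- eigen(s, symmetric = TRUE)
    pos <- eig$values > 1e-10 * max(abs(eig$values))
    k <- sum(pos)
    if (k < 2L)
      stop("rdm has fewer than 2 positive similarity components; ",
           "cannot embed")
    k <- min(k, n_channels - 1L)
    if (k < 2L) stop("n_channels too small to embed this rdm")
    x <- eig$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(eig$values[seq_len(k)]), k)
    x <- x / sqrt(rowSums(x^2))          # unit-norm items
    q <- random_centered_basis(n_channels, k)   # channels x k
    patterns <- x %*% t(q)
    rownames(patterns) <- rownames(d)
    patterns
  })
}

#' Specify an injected representational event
#'
#' Adds envelope-weighted item-specific patterns carrying one model's RDM
#' geometry to one region's channels.  The envelope is a Hanning window
#' over `[onset_ms, onset_ms + duration_ms]` (smooth evoked-like
#' morphology without edge artefacts).  `snr` is the ratio of the injected
#' signal's per-channel RMS at the envelope peak to the noise standard
#' deviation.
#'
#' @param model model label.
#' @param region region label.
#' @param onset_ms envelope onset in ms.
#' @param duration_ms envelope duration in ms (> 0).
#' @param snr nonnegative signal-to-noise ratio at the envelope peak.
#' @return an object of class `injection_event`.
#' @export
injection_event <- function(model, region, onset_ms, duration_ms, snr) {
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (snr < 0) stop("snr must be nonnegative")
  structure(list(model = model, region = region, onset_ms = onset_ms,
                 duration_ms = duration_ms, snr = snr),
            class = "injection_event")
}

#' Specify lagged inter-region coupling
#'
#' The target region receives a gain-scaled, lag-shifted copy of the
#' source region's item-specific (pattern) component — not its noise —
#' through a fixed random channel projection.  Couplings chain: what a
#' region receives is itself transmitted onwards, so indirect routes
#' (P -> M -> A) propagate geometry with summed lags.  Couplings of type
#' `"feedback"` get per-subject gain variability (see [scenario()]),
#' which is what links feedback strength to behaviour.
#'
#' @param source_region,target_region region labels (must differ).
#' @param lag_ms transmission lag in ms (strictly positive).
#' @param gain coupling gain in `[0, 1]`.
#' @param model label of the model whose pattern component is transmitted.
#' @param type `"feedforward"` (fixed gain) or `"feedback"` (per-subject
#'   gain jitter).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(source_region, target_region, lag_ms, gain,
                          model, type = c("feedforward", "feedback")) {
  type <- match.arg(type)
  if (lag_ms <= 0) stop("lag_ms must be strictly positive")
  if (identical(source_region, target_region))
    stop("a region must not couple to itself")
  if (gain < 0 || gain > 1) stop("gain must be in [0, 1]")
  structure(list(source_region = source_region,
                 target_region = target_region, lag_ms = lag_ms,
                 gain = gain, model = model, type = type),
            class = "coupling_spec")
}

#' Define a complete simulation scenario
#'
#' @param models named list of [model_spec()]s (order matters: models that
#'   reference another via `correlation_to` must come after it).
#' @param regions named list; each element is a list with `n_channels`
#'   and optionally `coords` (channels x 2 matrix with columns x, y).
#'   Missing coordinates are auto-generated with y spanning the region.
#' @param injections list of [injection_event()]s.
#' @param couplings list of [coupling_spec()]s.
#' @param n_subjects number of simulated subjects.
#' @param epoch_window_ms length-2 numeric `(start, end)` in ms.
#' @param sampling_rate_hz sampling rate (default 200 Hz, i.e. a 5 ms
#'   sample period).
#' @param noise_sd standard deviation of the i.i.d. Gaussian sensor noise.
#' @param pattern_jitter_frac fraction of injected signal energy carried
#'   by per-sample item-specific pattern jitter (the representational
#'   innovation process), in `[0, 1)`.  The static component carries the
#'   model geometry; the jitter is fresh at every sample and propagates
#'   through couplings along with it.  Time-lagged connectivity is
#'   direction-specific only because of this innovation component — a
#'   purely static geometry is equally explainable from either region's
#'   past — mirroring the role of innovations in Granger causality.
#'   Default 0.8: most moment-to-moment pattern variance is not
#'   model-locked.
#' @param subject_gain_sd SD of per-subject jitter on feedback-type
#'   coupling gains (clipped back to `[0, 1]`).
#' @param rt_model length-3 numeric `(intercept_ms, slope_ms_per_unit_gain,
#'   noise_sd_ms)` generating per-subject mean response times linearly from
#'   the subject's mean feedback gain.
#' @param master_seed integer; all randomness derives deterministically
#'   from it via [child_seed()].
#' @return an object of class `scenario`.
#' @export
scenario <- function(models, regions, injections = list(),
                     couplings = list(), n_subjects = 10L,
                     epoch_window_ms = c(-100, 400),
                     sampling_rate_hz = 200, noise_sd = 1,
                     pattern_jitter_frac = 0.8,
                     subject_gain_sd = 0, rt_model = c(900, 0, 0),
                     master_seed = 1L) {
  stopifnot(length(epoch_window_ms) == 2L,
            epoch_window_ms[2L] > epoch_window_ms[1L])
  if (pattern_jitter_frac < 0 || pattern_jitter_frac >= 1)
    stop("pattern_jitter_frac must be in [0, 1)")
  model_names <- vapply(models, function(m) m$name, character(1L))
  names(models) <- model_names
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("regions must be a named list")
  for (inj in injections) {
    if (!inj$model %in% model_names) stop("unknown model: ", inj$model)
    if (!inj$region %in% names(regions)) stop("unknown region: ", inj$region)
    if (inj$onset_ms < epoch_window_ms[1L] ||
        inj$onset_ms + inj$duration_ms > epoch_window_ms[2L])
      stop("injection for model '", inj$model,
           "' does not fit in the epoch window")
  }
  for (cp in couplings) {
    if (!cp$model %in% model_names) stop("unknown model: ", cp$model)
    if (!all(c(cp$source_region, cp$target_region) %in% names(regions)))
      stop("coupling references an unknown region")
    if (cp$lag_ms >= diff(epoch_window_ms))
      stop("coupling lag exceeds the epoch window")
  }
  structure(list(models = models, regions = regions,
                 injections = injections, couplings = couplings,
                 n_subjects = as.integer(n_subjects),
                 epoch_window_ms = as.numeric(epoch_window_ms),
                 sampling_rate_hz = sampling_rate_hz,
                 noise_sd = noise_sd,
                 pattern_jitter_frac = pattern_jitter_frac,
                 subject_gain_sd = subject_gain_sd,
                 rt_model = as.numeric(rt_model),
                 master_seed = as.integer(master_seed)),
            class = "scenario")
}

hanning_envelope <- function(time_ms, onset_ms, duration_ms) {
  u <- (time_ms - onset_ms) / duration_ms
  env <- numeric(length(time_ms))
  inside <- u >= 0 & u <= 1
  env[inside] <- 0.5 * (1 - cos(2 * pi * u[inside]))
  env
}

default_region_coords <- function(n_channels) {
  side <- ceiling(sqrt(n_channels))
  g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n_channels), ]
  m <- as.matrix(g)
  rownames(m) <- NULL
  m
}

#' Simulate multi-region epoched data with known ground truth
#'
#' Builds all model feature matrices and RDMs, embeds each model's
#' geometry as canonical item patterns (shared across subjects), then per
#' subject: draws fresh channel-mixing bases per region (shared geometry,
#' subject-specific topography), adds envelope-weighted injections,
#' propagates couplings forward in time sample by sample (so chains and
#' bidirectional loops work), and adds i.i.d. Gaussian sensor noise.
#' Feedback-type coupling gains are jittered per subject and drive the
#' simulated response times through the linear `rt_model`.
#'
#' @param scn a [scenario()].
#' @return list with `epochs` (region -> list of per-subject
#'   [epochs_set()]s), `models` (features, rdms, rdvs per model), and
#'   `ground_truth` (injection/coupling schedule, per-subject feedback
#'   gains, response times, seeds).
#' @export
simulate_epochs <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  step <- 1000 / scn$sampling_rate_hz
  time_ms <- seq(scn$epoch_window_ms[1L], scn$epoch_window_ms[2L], by = step)
  n_t <- length(time_ms)
  region_names <- names(scn$regions)
  n_ch <- vapply(scn$regions, function(r) as.integer(r$n_channels),
                 integer(1L))
  coords <- lapply(region_names, function(rn) {
    scn$regions[[rn]]$coords %||% default_region_coords(n_ch[[rn]])
  })
  names(coords) <- region_names

  # Models: features, RDMs, RDVs, canonical embedding coordinates.
  models <- list()
  for (m in scn$models) {
    ref <- if (!is.null(m$correlation_to)) {
      if (is.null(models[[m$correlation_to]]))
        stop("correlation_to references model '", m$correlation_to,
             "' which is not yet built")
      models[[m$correlation_to]]
    }
    feats <- make_feature_matrix(m, reference = ref)
    rdm <- rdm_for_family(feats, m$family)
    models[[m$name]] <- list(name = m$name, family = m$family,
                             features = feats, rdm = rdm,
                             rdv = vectorize_upper(rdm))
  }
  n_items <- nrow(models[[1L]]$features)
  item_labels <- rownames(models[[1L]]$features)

  # Canonical unit-norm item coordinates per model (shared across
  # subjects); channel bases are per subject.
  canon <- lapply(models, function(mod) {
    s <- 1 - as.matrix(mod$rdm)
    eig <- eigen(s, symmetric = TRUE)
    pos <- which(eig$values > 1e-10 * max(abs(eig$values)))
    x <- eig$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(eig$values[pos]), length(pos))
    x / sqrt(rowSums(x^2))
  })

  lag_samp <- vapply(scn$couplings, function(cp) {
    ls <- round(cp$lag_ms / step)
    if (ls < 1L) stop("coupling lag shorter than one sample")
    as.integer(ls)
  }, integer(1L))

  epochs <- lapply(region_names, function(r) vector("list", scn$n_subjects))
  names(epochs) <- region_names
  fb_gains <- numeric(scn$n_subjects)
  rts <- numeric(scn$n_subjects)

  for (s in seq_len(scn$n_subjects)) {
    with_seed(child_seed(scn$master_seed, s), {
      # Per-subject channel mixing for every (region, model) pair.
      clean <- lapply(region_names, function(rn)
        array(0, c(n_items, n_ch[[rn]], n_t)))
      names(clean) <- region_names
      w_jit <- scn$pattern_jitter_frac
      for (inj in scn$injections) {
        x <- canon[[inj$model]]
        nc <- n_ch[[inj$region]]
        k <- min(ncol(x), nc - 1L)
        q <- random_centered_basis(nc, k)
        p <- x[, seq_len(k), drop = FALSE] %*% t(q)
        amp <- inj$snr * scn$noise_sd
        p <- p * (sqrt(1 - w_jit) * amp / rms(p))
        env <- hanning_envelope(time_ms, inj$onset_ms, inj$duration_ms)
        idx <- which(env > 0)
        for (t in idx) {
          jit <- matrix(stats::rnorm(n_items * nc), n_items, nc)
          jit <- jit * (sqrt(w_jit) * amp / rms(jit))
          clean[[inj$region]][, , t] <-
            clean[[inj$region]][, , t] + env[t] * (p + jit)
        }
      }
      # Per-subject coupling gains and projections.
      gains <- vapply(scn$couplings, function(cp) {
        if (cp$type == "feedback" && scn$subject_gain_sd > 0)
          min(1, max(0, cp$gain + stats::rnorm(1L, 0, scn$subject_gain_sd)))
        else cp$gain
      }, numeric(1L))
      projs <- lapply(scn$couplings, function(cp)
        random_projection(n_ch[[cp$source_region]],
                          n_ch[[cp$target_region]]))
      # Forward pass in time: couplings read the source's clean signal at
      # t - lag, so chains and cycles resolve naturally.
      if (length(scn$couplings)) {
        for (t in seq_len(n_t)) {
          for (ci in seq_along(scn$couplings)) {
            cp <- scn$couplings[[ci]]
            t_src <- t - lag_samp[[ci]]
            if (t_src < 1L) next
            src <- clean[[cp$source_region]][, , t_src]
            if (all(src == 0)) next
            clean[[cp$target_region]][, , t] <-
              clean[[cp$target_region]][, , t] +
              gains[[ci]] * (src %*% projs[[ci]])
          }
        }
      }
      fb <- which(vapply(scn$couplings, function(cp) cp$type == "feedback",
                         logical(1L)))
      fb_gains[s] <- if (length(fb)) mean(gains[fb]) else 0
      rts[s] <- scn$rt_model[1L] + scn$rt_model[2L] * fb_gains[s] +
        stats::rnorm(1L, 0, scn$rt_model[3L])
      for (rn in region_names) {
        noise <- array(stats::rnorm(n_items * n_ch[[rn]] * n_t,
                                    sd = scn$noise_sd),
                       c(n_items, n_ch[[rn]], n_t))
        epochs[[rn]][[s]] <- epochs_set(
          clean[[rn]] + noise, time_ms = time_ms,
          sfreq = scn$sampling_rate_hz, item_labels = item_labels,
          channel_coords = coords[[rn]], region = rn)
      }
    })
  }

  list(epochs = epochs,
       models = models,
       ground_truth = list(
         injections = scn$injections, couplings = scn$couplings,
         subject_feedback_gains = fb_gains, response_times_ms = rts,
         time_ms = time_ms, master_seed = scn$master_seed))
}
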