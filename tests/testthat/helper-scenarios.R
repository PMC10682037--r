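# Shared fixture builders.  Everything is generated in code; scenario
# sizes are kept small so the default test run stays fast.

fixture_model <- function(name = "V", n_items = 24L, seed = 11L) {
  model_spec(name, n_items = n_items, n_features = 40L, seed = seed)
}

# One injected model in region P, optional lagged coupling P -> A.
fixture_scenario <- function(master_seed = 1L, n_subjects = 10L,
                             couple = TRUE, gain = 0.8, lag_ms = 10,
                             snr = 2, n_items = 24L, n_channels = 12L) {
  m <- fixture_model(n_items = n_items)
  scenario(
    models = list(m),
    regions = list(P = list(n_channels = n_channels),
                   A = list(n_channels = n_channels)),
    injections = list(injection_event("V", "P", onset_ms = 80,
                                      duration_ms = 160, snr = snr)),
    couplings = if (couple)
      list(coupling_spec("P", "A", lag_ms = lag_ms, gain = gain,
                         model = "V")) else list(),
    n_subjects = n_subjects, master_seed = master_seed)
}

# Small white-noise epochs for unit tests.
fixture_noise_epochs <- function(seed = 1L, n_items = 12L,
                                 n_channels = 8L, n_t = 40L,
                                 sfreq = 200) {
  withr::with_seed(seed, {
    step <- 1000 / sfreq
    epochs_set(array(rnorm(n_items * n_channels * n_t),
                     c(n_items, n_channels, n_t)),
               time_ms = seq(0, by = step, length.out = n_t),
               sfreq = sfreq,
               channel_coords = cbind(x = seq_len(n_channels),
                                      y = seq_len(n_channels)))
  })
}

# Hand-built single-timepoint RDM series from a timepoints x pairs matrix
# of RDV rows (used to test RCA mechanics directly).
fixture_series <- function(rdvs, sfreq = 200, label = "region") {
  n_pairs <- ncol(rdvs)
  n <- (1 + sqrt(1 + 8 * n_pairs)) / 2
  step <- 1000 / sfreq
  structure(list(rdvs = rdvs,
                 time_ms = seq(0, by = step, length.out = nrow(rdvs)),
                 window_ms = step, item_labels = paste0("item", seq_len(n)),
                 valid_timepoints = rep(TRUE, nrow(rdvs)),
                 channel_set = label),
            class = "neural_rdm_series")
}

# Independent brute-force partial Spearman oracle: explicit ranks,
# normal-equation residuals, Pearson of residuals.
oracle_partial_spearman <- function(x, y, covariates = list()) {
  rx <- rank(x); ry <- rank(y)
  if (!length(covariates)) return(stats::cor(rx, ry))
  X <- cbind(1, sapply(covariates, rank))
  bx <- solve(crossprod(X), crossprod(X, rx))
  by <- solve(crossprod(X), crossprod(X, ry))
  as.numeric(stats::cor(rx - X %*% bx, ry - X %*% by))
}
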