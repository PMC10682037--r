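test_that("binary feature matrices have the stated shape and coding", {
  spec <- model_spec("sem", n_items = 302, n_features = 3026,
                     family = "binary-feature", seed = 1)
  f <- make_feature_matrix(spec)
  expect_equal(dim(f), c(302, 3026))
  expect_true(all(f %in% c(0, 1)))
  expect_true(all(rowSums(f) >= 1))
  expect_gt(mean(rowSums(f)), 1)
  r <- rdm_from_binary_features(f)
  expect_equal(dim(r), c(302, 302))   # symmetric 302 x 302 dissimilarities
})

test_that("correlated model pairs realise the target RDV correlation", {
  # Monte-Carlo over seeds: requested rho = 0.6, realised within [0.5, 0.7]
  rho <- vapply(1:20, function(s) {
    a <- model_spec("A", 30, 60, seed = s)
    fa <- make_feature_matrix(a)
    b <- model_spec("B", 30, 60, correlation_to = "A", target_rho = 0.6,
                    seed = 1000 + s)
    fb <- make_feature_matrix(b, reference = list(
      features = fa, family = "continuous-activation"))
    cor(as.numeric(vectorize_upper(rdm_from_activations(fb))),
        as.numeric(vectorize_upper(rdm_from_activations(fa))),
        method = "spearman")
  }, numeric(1))
  expect_true(all(rho > 0.5 & rho < 0.7))
})

test_that("cross-family correlation targets near 1 are rejected", {
  a <- model_spec("A", 20, 40, seed = 1)
  fa <- make_feature_matrix(a)
  b <- model_spec("B", 20, 40, family = "binary-feature",
                  correlation_to = "A", target_rho = 0.97, seed = 2)
  expect_error(
    make_feature_matrix(b, reference = list(features = fa,
                                            family = "continuous-activation")),
    "unsatisfiable|unattainable")
})

test_that("embedded patterns reproduce the source RDM geometry", {
  # exact recovery for a correlation-distance RDM (PSD similarity)
  set.seed(20)
  rd <- rdm_from_activations(matrix(rnorm(20 * 50), 20))
  pat <- embed_item_patterns(rd, n_channels = 30, seed = 3)
  rec <- rdm_from_activations(pat)
  expect_gt(cor(as.numeric(vectorize_upper(rec)),
                as.numeric(vectorize_upper(rd)), method = "spearman"), 0.9)
  expect_lt(max(abs(unclass(rec) - unclass(rd))), 1e-8)
})

test_that("embedding handles degenerate geometries", {
  # three equidistant items -> equidistant patterns (to numerical precision)
  d3 <- new_rdm(matrix(0.8, 3, 3) - diag(0.8, 3))
  pat <- embed_item_patterns(d3, n_channels = 10, seed = 4)
  rec <- rdm_from_activations(pat)
  off <- rec[upper.tri(rec)]
  expect_lt(max(off) - min(off), 1e-6)
  # all-zero RDM -> identical patterns
  pat0 <- embed_item_patterns(new_rdm(matrix(0, 4, 4)), 8, seed = 5)
  expect_equal(pat0[1, ], pat0[3, ])
  # rank-1 similarity cannot carry 2-dimensional geometry
  v <- c(1, 1, -1)
  d_rank1 <- new_rdm(1 - outer(v, v) + diag(0, 3))
  expect_error(embed_item_patterns(d_rank1, 8, seed = 6), "positive")
})

test_that("specification invariants are enforced", {
  expect_error(model_spec("x", 2, 10), "n_items")
  expect_error(injection_event("V", "P", 0, -5, 1), "duration")
  expect_error(coupling_spec("P", "P", 10, 0.5, "V"), "itself")
  expect_error(coupling_spec("P", "A", 0, 0.5, "V"), "lag")
  m <- fixture_model()
  expect_error(scenario(list(m), list(P = list(n_channels = 4)),
                        injections = list(injection_event("X", "P", 0, 10, 1))),
               "unknown model")
  expect_error(scenario(list(m), list(P = list(n_channels = 4),
                                      A = list(n_channels = 4)),
                        couplings = list(coupling_spec("P", "A", 900, 0.5, "V"))),
               "lag exceeds")
  expect_error(scenario(list(m), list(P = list(n_channels = 4)),
                        injections = list(
                          injection_event("V", "P", 300, 200, 1))),
               "fit in the epoch")
})

test_that("simulation is bit-identical under the same master seed", {
  scn <- fixture_scenario(master_seed = 77, n_subjects = 3)
  a <- simulate_epochs(scn)
  b <- simulate_epochs(scn)
  expect_identical(a$epochs$P[[2]]$data, b$epochs$P[[2]]$data)
  expect_identical(a$epochs$A[[3]]$data, b$epochs$A[[3]]$data)
  expect_identical(a$ground_truth$response_times_ms,
                   b$ground_truth$response_times_ms)
  c_ <- simulate_epochs(fixture_scenario(master_seed = 78, n_subjects = 3))
  expect_false(identical(a$epochs$P[[1]]$data, c_$epochs$P[[1]]$data))
})

test_that("a null scenario produces pure noise", {
  m <- fixture_model(n_items = 12)
  scn <- scenario(list(m), list(P = list(n_channels = 8)),
                  n_subjects = 2, noise_sd = 1.5, master_seed = 5)
  sim <- simulate_epochs(scn)
  x <- sim$epochs$P[[1]]$data
  expect_equal(mean(x), 0, tolerance = 0.05)
  expect_equal(sd(x), 1.5, tolerance = 0.05)
})

test_that("injected geometry appears at the injection latency", {
  scn <- fixture_scenario(master_seed = 31, n_subjects = 4, couple = FALSE)
  sim <- simulate_epochs(scn)
  mv <- as.numeric(sim$models$V$rdv)
  tc <- rowMeans(sapply(1:4, function(s) {
    ser <- sliding_window_rdms(sim$epochs$P[[s]])
    apply(ser$rdvs, 1, function(v)
      if (anyNA(v)) NA_real_ else cor(v, mv, method = "spearman"))
  }))
  t_ms <- sim$ground_truth$time_ms
  # injection: onset 80 ms, duration 160 ms -> envelope peak at 160 ms
  peak <- t_ms[which.max(tc)]
  expect_lt(abs(peak - 160), 25)   # within one window half-width + sample
  expect_true(all(abs(tc[!is.na(tc) & t_ms < 40]) < 0.15))
})

test_that("coupled regions carry the geometry only after onset + lag", {
  scn <- fixture_scenario(master_seed = 32, n_subjects = 4, couple = TRUE,
                          lag_ms = 10)
  sim <- simulate_epochs(scn)
  mv <- as.numeric(sim$models$V$rdv)
  t_ms <- sim$ground_truth$time_ms
  tc <- rowMeans(sapply(1:4, function(s) {
    ser <- single_timepoint_rdms(sim$epochs$A[[s]])
    apply(ser$rdvs, 1, cor, y = mv, method = "spearman")
  }))
  before <- tc[t_ms < 90]            # injection onset 80 + lag 10
  after <- tc[t_ms >= 120 & t_ms <= 240]
  expect_lt(abs(mean(before)), 0.05)
  expect_gt(mean(after), 0.03)
})

test_that("response times track the subject's feedback gain", {
  m <- fixture_model()
  scn <- scenario(
    models = list(m),
    regions = list(P = list(n_channels = 8), A = list(n_channels = 8)),
    injections = list(injection_event("V", "P", 80, 160, 2)),
    couplings = list(coupling_spec("A", "P", 10, 0.5, "V",
                                   type = "feedback")),
    n_subjects = 30, subject_gain_sd = 0.25, rt_model = c(900, 300, 20),
    master_seed = 9)
  sim <- simulate_epochs(scn)
  gt <- sim$ground_truth
  expect_gt(cor(gt$subject_feedback_gains, gt$response_times_ms), 0)
  expect_true(all(gt$subject_feedback_gains >= 0 &
                    gt$subject_feedback_gains <= 1))
})
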