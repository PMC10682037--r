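test_that("lag windows follow the sampling grid", {
  expect_equal(lag_window_ms(500), seq(-30, -2, by = 2))
  expect_equal(lag_window_ms(200), seq(-30, -5, by = 5))
  expect_equal(lag_window_ms(100), c(-30, -20, -10))
  expect_error(lag_window_ms(500, c(-30, 2)), "negative")
})

test_that("flow is exactly the difference of the two partial correlations", {
  set.seed(21)
  src <- fixture_series(matrix(rnorm(30 * 45), 30), label = "P")
  tgt <- fixture_series(matrix(rnorm(30 * 45), 30), label = "A")
  mv <- rnorm(45)
  res <- rca_flow(src, tgt, mv)
  ok <- !is.na(res$flow)
  expect_true(any(ok))
  expect_equal(res$flow[ok], (res$rho1 - res$rho2)[ok])
  # early timepoints without a full lag window are undefined
  expect_true(all(is.na(res$flow[1:6])))   # 6 lags at 200 Hz
  # rho1 ignores the source: it equals the direct partial correlation
  t0 <- 10
  expect_equal(res$rho1[t0],
               partial_spearman(tgt$rdvs[t0, ], mv))
})

test_that("independent noise series produce no systematic flow", {
  set.seed(22)
  flows <- t(sapply(1:10, function(s) {
    src <- fixture_series(matrix(rnorm(40 * 45), 40), label = "P")
    tgt <- fixture_series(matrix(rnorm(40 * 45), 40), label = "A")
    rca_flow(src, tgt, rnorm(45))$flow
  }))
  m <- colMeans(flows)
  se <- apply(flows, 2, sd) / sqrt(10)
  ok <- !is.na(m)
  expect_true(all(abs(m[ok]) <= 3.5 * se[ok] + 1e-3))
})

test_that("an exact lagged copy is fully explained at the true lag", {
  set.seed(23)
  n_t <- 40
  lag_samples <- 2                      # 10 ms at 200 Hz
  mv <- rnorm(45)
  # source RDVs: temporally white innovations plus a weak constant
  # model-geometry component (so rho1 > 0 at the target)
  src_rdvs <- matrix(rnorm(n_t * 45), n_t) +
    0.25 * matrix(mv, n_t, 45, byrow = TRUE)
  tgt_rdvs <- rbind(matrix(rnorm(lag_samples * 45), lag_samples),
                    src_rdvs[1:(n_t - lag_samples), ])
  src <- fixture_series(src_rdvs, label = "P")
  tgt <- fixture_series(tgt_rdvs, label = "A")
  res <- rca_flow(src, tgt, mv)        # window -30..-5 ms contains -10
  ok <- which(!is.na(res$flow))
  expect_gt(mean(res$rho1[ok]), 0.15)
  expect_lt(mean(abs(res$rho2[ok])), 0.05)   # copy explained away
  expect_equal(mean(res$flow[ok]), mean(res$rho1[ok]), tolerance = 0.06)
  # with the true lag outside the window most of the flow disappears;
  # what remains is the second-order leak through the constant component
  res_miss <- rca_flow(src, fixture_series(
    rbind(matrix(rnorm(8 * 45), 8), src_rdvs[1:(n_t - 8), ]), label = "A"),
    mv)                                 # true lag -40 ms, window -30..-5
  ok2 <- which(!is.na(res_miss$flow))
  expect_lt(mean(res_miss$flow[ok2]), 0.35 * mean(res_miss$rho1[ok2]))
})

test_that("feedforward and feedback wrap the two directions consistently", {
  sim <- simulate_epochs(fixture_scenario(master_seed = 51, n_subjects = 2))
  mv <- sim$models$V$rdv
  sp <- single_timepoint_rdms(sim$epochs$P[[1]])
  sa <- single_timepoint_rdms(sim$epochs$A[[1]])
  pr <- feedforward_feedback_pair(sp, sa, mv)
  expect_equal(pr$forward$direction, c(source = "P", target = "A"))
  expect_equal(pr$backward$direction, c(source = "A", target = "P"))
  expect_equal(pr$forward$flow,
               rca_flow(sp, sa, mv)$flow)
})

test_that("region covariates enter both correlations", {
  set.seed(24)
  src <- fixture_series(matrix(rnorm(30 * 45), 30), label = "P")
  tgt <- fixture_series(matrix(rnorm(30 * 45), 30), label = "A")
  ctl <- fixture_series(matrix(rnorm(30 * 45), 30), label = "M")
  mv <- rnorm(45)
  plain <- rca_flow(src, tgt, mv)
  multi <- rca_flow(src, tgt, mv, region_covariates = list(ctl))
  ok <- !is.na(multi$flow)
  expect_true(any(ok))
  # rho1 now conditions on the control region's past, so it changes
  expect_false(isTRUE(all.equal(plain$rho1[ok], multi$rho1[ok])))
  expect_equal(multi$flow[ok], (multi$rho1 - multi$rho2)[ok])
})

test_that("median splits are balanced and ordered", {
  gs <- median_split(c(900, 700, 1100, 800, 1000, 950))
  expect_equal(gs$fast, c(1, 2, 4))
  expect_equal(gs$slow, c(3, 5, 6))
  gs7 <- median_split(c(1, 7, 3, 6, 2, 5, 4))
  expect_length(gs7$fast, 3)
  expect_length(gs7$slow, 4)
  expect_equal(abs(length(gs7$slow) - length(gs7$fast)), 1)
})

test_that("group contrasts find injected differences and reject degenerate input", {
  set.seed(25)
  base <- matrix(rnorm(20 * 30, sd = 0.1), 20, 30)
  shifted <- base
  shifted[, 10:20] <- shifted[, 10:20] + 0.3
  cs <- rca_group_contrast(shifted[1:10, ], base[11:20, ],
                           time_ms = seq_len(30) * 5,
                           n_permutations = 300, seed = 7)
  sig <- significant_clusters(cs)
  expect_gt(length(sig), 0)
  expect_true(any(vapply(sig, function(cl)
    cl$start_ms <= 50 + 50 && cl$end_ms >= 95, logical(1))))
  # identical groups: relabelling cannot produce systematic clusters
  cs0 <- rca_group_contrast(base[1:10, ], base[1:10, ],
                            n_permutations = 300, seed = 8)
  expect_length(significant_clusters(cs0, 0.01), 0)
  expect_error(rca_group_contrast(matrix(0, 5, 10), matrix(0, 5, 10)),
               "zero-variance")
  expect_error(rca_group_contrast(base[1:2, ], base[3:20, ]), "3 subjects")
})

test_that("paired connection contrasts behave under null and forced offsets", {
  set.seed(26)
  f1 <- matrix(rnorm(10 * 25, sd = 0.05), 10, 25)
  cs_null <- rca_connection_contrast(f1, f1, n_permutations = 200, seed = 9)
  expect_length(cs_null$clusters, 0)      # all differences exactly zero
  f2 <- f1 + 0.5                          # constant positive offset
  cs <- rca_connection_contrast(f2, f1, time_ms = seq_len(25) * 2,
                                n_permutations = 500, seed = 10)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]]$n_members, 25)   # whole-window cluster
  expect_equal(cs$clusters[[1]]$p_value, 1 / 501, tolerance = 1e-12)
  expect_error(rca_connection_contrast(f1, f1[1:5, ]), "mismatch")
})
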