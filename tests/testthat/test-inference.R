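test_that("exact binomial resample counts", {
  expect_equal(count_resamples(10, 0), 1)
  expect_equal(count_resamples(31, 4), 31465)
  expect_equal(count_resamples(36, 4), 58905)
  expect_equal(count_resamples(5, 6), 0)
  expect_equal(count_resamples(50, 25), choose(50, 25))
  expect_error(count_resamples(-1, 2), "nonnegative")
})

test_that("all-zero effects yield an empty cluster set", {
  cs <- cluster_test_temporal(matrix(0, 5, 20), n_permutations = 200,
                              seed = 1)
  expect_length(cs$clusters, 0)
})

test_that("small-n sign enumeration matches an independent oracle", {
  # 4 subjects -> all 16 sign patterns are enumerated; p-values must equal
  # a brute-force enumeration written independently here.
  set.seed(13)
  eff <- matrix(rnorm(4 * 30, mean = 0.4, sd = 0.3), 4, 30)
  alpha <- 0.05
  cs <- cluster_test_temporal(eff, alpha_forming = alpha,
                              n_permutations = 10000, seed = 2)
  expect_true(cs$exact_enumeration)

  oracle_masses <- function(e) {
    tv <- apply(e, 2, function(v) t.test(v)$statistic)
    thr <- qt(1 - alpha, 3)
    supra <- tv > thr
    masses <- numeric(); cur <- 0; runs <- list(); members <- integer()
    for (i in seq_along(supra)) {
      if (supra[i]) { cur <- cur + tv[i]; members <- c(members, i) }
      if ((!supra[i] || i == length(supra)) && length(members)) {
        masses <- c(masses, cur); runs <- c(runs, list(members))
        cur <- 0; members <- integer()
      }
    }
    list(masses = masses, runs = runs)
  }
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), 4)))
  null_max <- apply(signs, 1, function(s) {
    m <- oracle_masses(s * eff)$masses
    if (length(m)) max(m) else 0
  })
  obs <- oracle_masses(eff)
  expect_length(cs$clusters, length(obs$masses))
  for (i in seq_along(cs$clusters)) {
    expect_equal(cs$clusters[[i]]$mass, obs$masses[[i]], tolerance = 1e-10)
    expect_equal(cs$clusters[[i]]$p_value,
                 mean(null_max >= obs$masses[[i]]))
  }
})

test_that("cluster p-values respect the permutation lower bound and scale invariance", {
  set.seed(14)
  eff <- matrix(rnorm(8 * 40, mean = 0.5), 8, 40)
  cs <- cluster_test_temporal(eff, n_permutations = 500, seed = 3)
  expect_true(all(vapply(cs$clusters, `[[`, numeric(1), "p_value") >=
                    1 / 501))
  # multiplying all subjects by one positive constant leaves t-values,
  # hence p-values, unchanged
  cs2 <- cluster_test_temporal(3.7 * eff, n_permutations = 500, seed = 3)
  expect_equal(vapply(cs$clusters, `[[`, numeric(1), "p_value"),
               vapply(cs2$clusters, `[[`, numeric(1), "p_value"))
})

test_that("clusters cannot bridge invalid timepoints", {
  set.seed(15)
  eff <- matrix(rnorm(8 * 21, mean = 1.5, sd = 0.5), 8, 21)
  eff[, 11] <- NA
  cs <- cluster_test_temporal(eff, n_permutations = 200, seed = 4)
  for (cl in cs$clusters)
    expect_false(any(cl$members == 11) ||
                   (min(cl$members) < 11 && max(cl$members) > 11))
})

test_that("spatiotemporal test with one point reduces to the temporal test", {
  set.seed(16)
  eff <- matrix(rnorm(6 * 25, mean = 0.5), 6, 25)
  arr <- array(t(eff), c(1, 25, 6))
  cs_t <- cluster_test_temporal(eff, n_permutations = 300, seed = 5)
  cs_s <- cluster_test_spatiotemporal(arr, matrix(TRUE, 1, 1),
                                      n_permutations = 300, seed = 5)
  expect_equal(length(cs_t$clusters), length(cs_s$clusters))
  expect_equal(vapply(cs_t$clusters, `[[`, numeric(1), "mass"),
               vapply(cs_s$clusters, `[[`, numeric(1), "mass"))
  expect_equal(vapply(cs_t$clusters, `[[`, numeric(1), "p_value"),
               vapply(cs_s$clusters, `[[`, numeric(1), "p_value"))
})

test_that("spatiotemporal clusters respect adjacency components", {
  # two disconnected point groups with strong effects never share a cluster
  set.seed(17)
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 1] <- TRUE   # group {1,2}
  adj[3, 4] <- adj[4, 3] <- TRUE   # group {3,4}
  eff <- array(rnorm(4 * 15 * 6, mean = 1), c(4, 15, 6))
  cs <- cluster_test_spatiotemporal(eff, adj, n_permutations = 100,
                                    seed = 6)
  for (cl in cs$clusters) {
    pts <- unique(cl$members[, 1])
    expect_true(all(pts %in% c(1, 2)) || all(pts %in% c(3, 4)))
  }
})

test_that("connected-component labelling matches a flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(18)
  for (rep in 1:10) {
    n_p <- 5; n_t <- 10
    mask <- matrix(runif(n_p * n_t) < 0.45, n_p, n_t)
    adj <- matrix(FALSE, n_p, n_p)
    for (i in 1:(n_p - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    labels <- repconn:::spatiotemporal_components(mask, adj)
    # oracle: build the element graph in igraph and compare components
    els <- which(mask)
    if (!length(els)) next
    edges <- c()
    for (a in els) {
      pa <- (a - 1) %% n_p + 1; ta <- (a - 1) %/% n_p + 1
      for (b in els) {
        if (b <= a) next
        pb <- (b - 1) %% n_p + 1; tb <- (b - 1) %/% n_p + 1
        if ((pa == pb && abs(ta - tb) == 1) ||
            (ta == tb && adj[pa, pb]))
          edges <- c(edges, match(a, els), match(b, els))
      }
    }
    g <- igraph::make_empty_graph(length(els), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    # same partition: label pairs agree
    ours <- labels[els]
    expect_equal(length(unique(ours)), length(unique(comp)))
    expect_true(all(tapply(comp, ours, function(v) length(unique(v))) == 1))
  }
})

test_that("jackknife peaks and difference CIs behave deterministically", {
  t_ms <- seq(0, 400, by = 10)
  bump <- function(centre) exp(-(t_ms - centre)^2 / (2 * 30^2))
  eff_a <- t(replicate(10, bump(200))) + 0.01 * matrix(rnorm(10 * 41), 10)
  # identical peak for every subject -> every resample peaks at 200 ms
  res <- jackknife_peak_ci(list(a = eff_a, b = eff_a), time_ms = t_ms,
                           n_leave_out = 4)
  expect_equal(res$n_resamples, count_resamples(10, 4))
  expect_true(all(abs(res$resample_peaks[, "a"] - 200) <= 10))
  expect_equal(res$ci_95[["a - b"]], c(0, 0))
  # a pure 50 ms shift forces a difference CI of exactly [50, 50]
  eff_b <- t(apply(eff_a, 1, function(r) bump(250) + 0.01 * rnorm(41)))
  res2 <- jackknife_peak_ci(list(a = eff_a, b = eff_b), time_ms = t_ms)
  d <- res2$ci_95[["a - b"]]
  expect_true(d[1] >= -60 && d[2] <= -40)
  expect_true(all(d < 0))   # CI excludes zero
})

test_that("the jackknife enumeration cap subsamples with a warning", {
  eff <- matrix(rnorm(25 * 10), 25, 10)
  expect_warning(
    res <- jackknife_peak_ci(list(m = eff), time_ms = seq_len(10) * 10,
                             n_leave_out = 4, max_resamples = 500,
                             search_window_ms = c(0, 100), seed = 9),
    "capped")
  expect_true(res$subsampled)
  expect_equal(res$n_resamples, 500)
  expect_equal(res$n_possible, count_resamples(25, 4))
})
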