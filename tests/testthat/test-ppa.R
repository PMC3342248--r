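win <- plot_geometry(100, 100, 20)

test_that("K estimator counts pairs with interior weight one", {
  # two interior points far from every edge: weight 1, K jumps at d
  p <- point_pattern(c(40, 60), c(50, 50), win)
  r <- seq(0, 25, 0.5)
  k <- k_hat_isotropic(p, r)
  expect_true(all(k[r < 20] == 0))
  # |A|/(n(n-1)) * 2 ordered pairs with weight 1
  expect_equal(k[r >= 20], rep(1e4 / 2 * 2, sum(r >= 20)),
               tolerance = 1e-12)
  expect_error(k_hat_isotropic(point_pattern(1, 1, win), r),
               "at least 2")
  expect_warning(k_hat_isotropic(p, seq(0, 40, 5)), "quarter")
})

test_that("closed-form isotropic weights agree with independent arc
           oracles", {
  set.seed(71)
  for (i in 1:30) {
    x <- runif(1, 0, 100); y <- runif(1, 0, 100); d <- runif(1, 0.5, 24)
    w <- standforge:::ripley_weight(x, y, d, win)
    expect_equal(w, arc_union_weight(x, y, d, win), tolerance = 1e-10)
    expect_equal(w, ripley_weight_numeric(x, y, d, win), tolerance = 1e-3)
  }
  # interior circle: no correction
  expect_equal(standforge:::ripley_weight(50, 50, 10, win), 1)
  # circle centered on an edge: half outside
  expect_equal(standforge:::ripley_weight(0, 50, 10, win), 0.5,
               tolerance = 1e-12)
  # circle centered on a corner: three quarters outside
  expect_equal(standforge:::ripley_weight(0, 0, 10, win), 0.25,
               tolerance = 1e-12)
})

test_that("centered L is unbiased near zero under CSR", {
  set.seed(72)
  r <- seq(0, 25, 0.5)
  lbar <- rowMeans(replicate(100, l_hat(simulate_csr(100, win), r)$l))
  # below ~2 m the expected pair count is near zero and the square-root
  # transform is deterministically biased low (Jensen), so the
  # near-unbiasedness property is checked from 2 m outward
  expect_true(all(abs(lbar[r >= 2]) < 0.15))
  expect_equal(l_hat(simulate_csr(100, win), r)$l[1], 0)
})

test_that("bivariate K is symmetric in its two arguments", {
  set.seed(73)
  p1 <- simulate_csr(40, win)
  p2 <- simulate_csr(60, win)
  r <- seq(0, 20, 0.5)
  k12 <- k12_hat_isotropic(p1, p2, r)
  k21 <- k12_hat_isotropic(p2, p1, r)
  expect_equal(k12, k21, tolerance = 1e-10)
  expect_error(k12_hat_isotropic(p1, point_pattern(numeric(0), numeric(0),
                                                   win), r), "non-empty")
  other <- point_pattern(5, 5, plot_geometry(200, 100, 20))
  expect_error(k12_hat_isotropic(p1, other, r), "mismatched")
})

test_that("toroidal shifts preserve counts and toroidal distances", {
  set.seed(74)
  p <- simulate_csr(50, win)
  expect_equal(toroidal_shift(p, c(0, 0))$x, p$x)
  wrap <- toroidal_shift(p, c(100, 100))
  expect_equal(wrap$x, p$x, tolerance = 1e-12)
  expect_equal(wrap$y, p$y, tolerance = 1e-12)
  d0 <- toroidal_dist(p)
  for (i in 1:20) {
    s <- runif(2, 0, c(100, 100))
    q <- toroidal_shift(p, s)
    expect_equal(q$n, p$n)
    expect_equal(toroidal_dist(q), d0, tolerance = 1e-9)
  }
})

test_that("CSR simulation is uniform on the window", {
  expect_equal(simulate_csr(0, win)$n, 0)
  set.seed(75)
  xs <- replicate(1000, mean(simulate_csr(20, win)$x))
  se <- sd(xs) / sqrt(1000)
  expect_lt(abs(mean(xs) - 50), 3 * se)
})

test_that("envelopes run both null models and keep every simulated
           curve", {
  set.seed(76)
  p <- simulate_csr(30, win)
  r <- seq(0, 10, 0.5)
  e1 <- envelope(p, "csr", n_sim = 1, r_grid = r)
  expect_equal(nrow(e1$simulated), 1)
  e5 <- envelope(p, "csr", n_sim = 5, r_grid = r)
  expect_equal(dim(e5$simulated), c(5, length(r)))
  b <- envelope_bounds(e5)
  expect_true(all(b$lo <= b$hi))

  mk <- point_pattern(c(p$x, runif(10, 0, 100)),
                      c(p$y, runif(10, 0, 100)), win,
                      mark = rep(c("small", "large"), c(30, 10)))
  e2 <- envelope(mk, "population_independence", n_sim = 5, r_grid = r,
                 types = c("large", "small"))
  expect_equal(nrow(e2$simulated), 5)
  expect_error(envelope(p, "population_independence", n_sim = 5,
                        r_grid = r), "marked")
})

test_that("population-independence shifts keep each sub-pattern rigid", {
  set.seed(77)
  p <- simulate_csr(25, win)
  s <- runif(2, 0, 100)
  q <- toroidal_shift(p, s)
  expect_equal(sort(toroidal_dist(q)[upper.tri(diag(25))]),
               sort(toroidal_dist(p)[upper.tri(diag(25))]),
               tolerance = 1e-9)
})

test_that("Loosmore-Ford ranks give exact tie and extreme p-values", {
  r <- seq(0, 9, 0.5)
  obs <- structure(data.frame(r = r, l = rep(0.3, length(r))),
                   class = c("l_result", "data.frame"))
  env <- structure(list(observed = obs,
                        simulated = matrix(0.3, 99, length(r)),
                        r_grid = r, null_model = "csr"),
                   class = "envelope_result")
  # observed identical to every simulation: all deviations tie, p = 1
  expect_equal(gof_loosmore_ford(env)$p_value, 1)

  set.seed(78)
  clustered <- sample_thomas(0.003, 10, 2, win)
  e <- envelope(clustered, "csr", n_sim = 99, r_grid = r)
  g <- gof_loosmore_ford(e, 0, 9)
  expect_equal(g$p_value, 0.01)  # minimal rank, 1/(n_sim + 1)
  expect_error(gof_loosmore_ford(e, 0, 50), "bounds")
})

test_that("Bonferroni thresholds match the family-wise arithmetic", {
  expect_equal(bonferroni(0.05, 12), 0.004)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.06, 2), 0.03)
  expect_error(bonferroni(1.2, 3), "alpha")
})

test_that("the transect correlogram flags degenerate classes and detects
           a gradient", {
  mids <- cbind(seq(10, 200, by = 10), 50)
  flat <- rep(3, nrow(mids))
  out <- transect_correlogram(flat, mids, breaks = c(0, 30, 60, 200),
                              n_perm = 49)
  expect_true(all(!out$estimable))

  set.seed(79)
  grad <- mids[, 1] + rnorm(nrow(mids), 0, 2)
  out2 <- transect_correlogram(grad, mids, breaks = c(0, 30, 60, 200),
                               n_perm = 199)
  first <- out2[1, ]
  expect_true(first$estimable)
  expect_gt(first$correlation, 0)
  expect_lt(first$p_value, 0.05)
})
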