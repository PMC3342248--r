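win100 <- plot_geometry(100, 100, 20)

test_that("Thomas sampler hits its expected intensity", {
  set.seed(21)
  expect_equal(sample_thomas(0.002, 0, 4, win100)$n, 0)
  counts <- replicate(200, sample_thomas(0.002, 8, 4, win100)$n)
  expected <- 0.002 * 8 * 100 * 100
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("hard-core thinning enforces the minimum spacing", {
  set.seed(22)
  for (i in 1:5) {
    p <- sample_hardcore(0.01, 3, win100)
    d <- as.matrix(dist(cbind(p$x, p$y)))
    expect_gte(min(d[upper.tri(d)]), 3)
  }
  # h = 0 degenerates to a plain Poisson process
  counts <- replicate(200, sample_hardcore(0.005, 0, win100)$n)
  expect_lt(abs(mean(counts) - 50), 3 * sd(counts) / sqrt(200))
  # overpacked proposals warn and still satisfy the core
  expect_warning(p <- sample_hardcore(0.5, 5, win100), "infeasible")
  d <- as.matrix(dist(cbind(p$x, p$y)))
  expect_gte(min(d[upper.tri(d)]), 5)
})

test_that("segregation thinning removes small trees near large trees", {
  set.seed(23)
  small <- simulate_csr(400, win100)
  large <- simulate_csr(12, win100)
  expect_identical(apply_segregation(small, large, 10, 0), small)
  thinned <- apply_segregation(small, large, 10, 1)
  if (thinned$n) {
    d2 <- outer(thinned$x, large$x, "-")^2 + outer(thinned$y, large$y, "-")^2
    expect_gte(sqrt(min(d2)), 10)
  }
  expect_lt(thinned$n, small$n)
})

test_that("diameter models are truncated at the census threshold and
           the exponential rate is recoverable", {
  expect_length(sample_dbh(0, list(type = "negative_exponential",
                                   rate = 0.1)), 0)
  expect_error(sample_dbh(5, list(type = "negative_exponential", rate = 0)),
               "parameter error")
  set.seed(24)
  x <- sample_dbh(10000, list(type = "negative_exponential", rate = 0.08))
  expect_true(all(x >= 1))
  rate_hat <- 1 / mean(x - 1)  # maximum likelihood for the shifted model
  expect_lt(abs(rate_hat - 0.08) / 0.08, 0.05)
  y <- sample_dbh(5000, list(type = "rotated_sigmoid", rate = 0.08,
                             weight_hump = 0.2, hump_mean = 80,
                             hump_sd = 25))
  expect_true(all(y >= 1))
  # the hump shifts mass into mid-diameter classes
  expect_gt(mean(y > 50 & y < 110), mean(x > 50 & x < 110))
})

test_that("stand generation is deterministic and layers can be
           regenerated from their own streams", {
  cfg <- small_config(31L)
  a <- generate_stand(cfg)
  b <- generate_stand(cfg)
  expect_identical(a$stems, b$stems)
  expect_identical(a$snags, b$snags)
  expect_identical(a$transects, b$transects)
  expect_identical(a$intercepts, b$intercepts)
  expect_identical(a$shrub_patches$area_m2, b$shrub_patches$area_m2)

  # the debris layer stream regenerates the exact segment field, and the
  # recorded intercept diameters equal the diameters of crossing segments
  set.seed(cfg$rng_seed + 6L)
  segments <- sample_debris_field(cfg$debris, cfg$geometry)
  t1 <- a$transects[a$transects$transect_id == a$intercepts$transect_id[1], ]
  hits <- transect_crossings(segments, c(t1$x_m, t1$y_m), t1$azimuth_deg,
                             t1$length_m)
  got <- sort(a$intercepts$diameter_cm[a$intercepts$transect_id ==
                                         t1$transect_id])
  expect_equal(got, sort(round(hits$diameter_cm, 2)))
})

test_that("snag frequency and shrub cover match their targets", {
  cfg <- small_config(32L)
  stand <- generate_stand(cfg)
  n_live10 <- sum(stand$stems$dbh_cm >= 10)
  p <- cfg$snag_fraction
  sigma <- sqrt(n_live10 * p * (1 - p))
  expect_lt(abs(nrow(stand$snags) - n_live10 * p), 3 * sigma)
  cover <- sum(stand$shrub_patches$area_m2) /
    (cfg$geometry$width_m * cfg$geometry$height_m)
  expect_lt(abs(cover - cfg$shrub$cover_target), 0.02)
})

test_that("generated patterns carry the intended spatial structure", {
  set.seed(41)
  # clustering of the small-tree layer is detectable in L at 10 m
  p <- sample_thomas(0.002, 8, 4, plot_geometry(320, 320, 20))
  lv <- l_hat(p, seq(0, 20, 0.5))
  csr_l10 <- replicate(39, {
    l_hat(simulate_csr(p$n, p$window), seq(0, 20, 0.5))$l[21]
  })
  expect_gt(lv$l[21], quantile(csr_l10, 0.975))
  # hard-core large-tree layer shows inhibition at short range
  ph <- sample_hardcore(0.004, 3, plot_geometry(200, 200, 20))
  lh <- l_hat(ph, seq(0, 10, 0.5))
  expect_lt(lh$l[5], 0)  # r = 2 m, inside the core
})

test_that("transect crossing geometry is exact", {
  segments <- data.frame(x0 = c(10, 10, 50), y0 = c(-5, -5, 10),
                         x1 = c(10, 10, 70), y1 = c(5, 5, 10),
                         diameter_cm = c(25, 25, 40),
                         decay_class = c(2, 2, 3),
                         species = "ABCO", stringsAsFactors = FALSE)
  segments <- segments[-2, ]  # two distinct pieces
  # transect due east from (0,0) of length 20 crosses only the first piece
  hits <- transect_crossings(segments, c(0, 0), 90, 20)
  expect_equal(hits$diameter_cm, 25)
  # shorter transect stops before the piece
  expect_equal(nrow(transect_crossings(segments, c(0, 0), 90, 9)), 0)
  # collinear-but-parallel piece never intersects
  expect_equal(nrow(transect_crossings(segments[2, ], c(0, 0), 90, 20)), 0)
})
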