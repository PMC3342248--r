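reg <- demo_registry()

test_that("equation evaluation matches direct hand formulas", {
  registry <- data.frame(
    species = "SPX", component = "whole", form = "log10_linear",
    c0 = -2, c1 = 2.4, dbh_min_cm = 1, dbh_max_cm = 200,
    rmse_log = NA_real_, source_id = "hand", stringsAsFactors = FALSE)
  b <- tree_biomass(data.frame(species = "SPX", dbh_cm = 50), registry)
  expect_equal(b$total_kg, 10^(-2 + 2.4 * log10(50)), tolerance = 1e-12)

  registry$form <- "power"; registry$c0 <- 0.1; registry$c1 <- 2.3
  b2 <- tree_biomass(data.frame(species = "SPX", dbh_cm = 50), registry)
  expect_equal(b2$total_kg, 0.1 * 50^2.3, tolerance = 1e-12)

  expect_error(tree_biomass(data.frame(species = "SPX", dbh_cm = 0.5),
                            registry), "range error")
  expect_error(tree_biomass(data.frame(species = "NOPE", dbh_cm = 10),
                            registry), "unresolved-species")
})

test_that("branch and foliage caps freeze biomass above the cap diameter", {
  at110 <- tree_biomass(data.frame(species = "ABCO", dbh_cm = 110),
                        reg$equations, reg$rules)
  at120 <- tree_biomass(data.frame(species = "ABCO", dbh_cm = 120),
                        reg$equations, reg$rules)
  expect_identical(at120$components[["branch"]], at110$components[["branch"]])
  expect_identical(at120$components[["foliage"]],
                   at110$components[["foliage"]])
  # but the bole keeps growing (through the large-tree proxy equation)
  expect_gt(at120$components[["bole"]], at110$components[["bole"]])
})

test_that("vectorized biomass equals the per-stem reference path", {
  set.seed(51)
  n <- 200
  stems <- data.frame(
    tag = as.character(seq_len(n)),
    species = sample(c("ABCO", "PILA", "CADE", "QUKE", "CONU"), n, TRUE),
    dbh_cm = pmin(1 + rexp(n, 0.05), 99),
    stringsAsFactors = FALSE)
  stems$dbh_cm[1:10] <- runif(10, 100, 240)
  stems$species[1:10] <- sample(c("ABCO", "PILA", "CADE"), 10, TRUE)
  tab <- tree_biomass_table(stems, reg$equations, reg$rules)
  ref <- vapply(seq_len(n), function(i)
    tree_biomass(stems[i, ], reg$equations, reg$rules)$total_kg, 0)
  expect_equal(tab$biomass_kg, ref, tolerance = 1e-12)
})

test_that("biomass is monotone in dbh within and across regimes", {
  for (sp in c("ABCO", "PILA", "CADE")) {
    d <- seq(1, 240, by = 0.5)
    stems <- data.frame(tag = as.character(seq_along(d)), species = sp,
                        dbh_cm = d, stringsAsFactors = FALSE)
    m <- tree_biomass_table(stems, reg$equations, reg$rules)$biomass_kg
    expect_true(all(diff(m) >= -1e-9))
  }
})

test_that("log-scale RMSE converts to an arithmetic SD by the lognormal
           identity", {
  expect_equal(rmse_to_sd(1000, 0), 0)
  v <- rmse_to_sd(1000, 0.1, 10)
  expect_equal(v, 1000 * sqrt(exp((0.1 * log(10))^2) - 1), tolerance = 1e-12)
  # Monte-Carlo moment oracle: mean-preserving lognormal with the same
  # log-scale spread
  set.seed(52)
  sigma <- 0.1 * log(10)
  draws <- 1000 * exp(rnorm(2e5, 0, sigma) - sigma^2 / 2)
  expect_lt(abs(sd(draws) - v) / v, 0.02)
  # strictly increasing in the RMSE
  s <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(rmse_to_sd(1000, s)) > 0))
})

test_that("snag frustum volume degenerates correctly and matches hand
           calculation", {
  dens <- flat_densities(360)
  cyl <- data.frame(species = "Z", dbh_cm = 40, top_diameter_cm = 40,
                    height_m = 12, decay_class = 1)
  expect_equal(snag_biomass(cyl, dens), pi * 0.2^2 * 12 * 360 / 1000,
               tolerance = 1e-12)
  cone <- cyl; cone$top_diameter_cm <- 0
  expect_equal(snag_biomass(cone, dens), pi * 0.2^2 * 12 / 3 * 360 / 1000,
               tolerance = 1e-12)
  mid <- data.frame(species = "Z", dbh_cm = 100, top_diameter_cm = 50,
                    height_m = 20, decay_class = 1)
  v_hand <- pi * 20 / 3 * (0.25 + 0.125 + 0.0625)
  expect_equal(snag_biomass(mid, dens), v_hand * 360 / 1000,
               tolerance = 1e-12)
  expect_equal(round(snag_biomass(mid, dens), 3), 3.299)
})

test_that("shrub extrapolation reproduces published densities and routes
           proxies", {
  y <- yfdp_tables()
  proxies <- utils::read.csv(system.file("extdata", "registry",
                                         "shrub_proxies.csv",
                                         package = "standforge"))
  patches <- data.frame(species = y$shrub_cover$species,
                        area_m2 = y$shrub_cover$cover_m2)
  out <- shrub_extrapolate(patches, y$shrub_demography, y$geometry,
                           proxies)
  arpa <- out[out$species == "ARPA", ]
  expect_equal(round(arpa$biomass_Mg_per_ha, 3), 1.454)
  expect_equal(round(arpa$stems_per_ha), 526)
  coco <- out[out$species == "COCO", ]
  expect_equal(round(coco$biomass_Mg_per_ha, 3), 0.814)
  expect_equal(round(coco$stems_per_ha), 520)
  # half-biomass, zero-density proxy
  riro <- out[out$species == "RIRO", ]
  expect_equal(riro$stems_per_ha, 0)
  expect_equal(round(riro$biomass_Mg_per_ha, 3), 0.001)
  # unresolvable species fails loudly
  expect_error(shrub_extrapolate(data.frame(species = "ZZZZ", area_m2 = 10),
                                 y$shrub_demography, y$geometry, proxies),
               "ZZZZ")
  # zero cover gives a zero report
  empty <- shrub_extrapolate(NULL, y$shrub_demography, y$geometry)
  expect_equal(unname(attr(empty, "totals")["biomass_Mg_per_ha"]), 0)
})

test_that("planar-intercept coarse debris matches the hand formula", {
  tr <- data.frame(transect_id = c("T1", "T2"), length_m = 20)
  none <- coarse_debris_biomass(tr, data.frame(
    transect_id = character(0), diameter_cm = numeric(0),
    decay_class = integer(0), species = character(0)), flat_densities(400))
  expect_equal(unname(none$summary["total_Mg_ha"]), 0)

  ic <- data.frame(transect_id = "T1", diameter_cm = 20, decay_class = 1,
                   species = "UNKN", stringsAsFactors = FALSE)
  one <- coarse_debris_biomass(tr, ic, flat_densities(400))
  # pi^2 * 0.2^2 * 400 / (8*20) kg/m2 on T1, zero on T2
  expect_equal(one$per_transect$total_Mg_ha[1],
               pi^2 * 0.04 * 400 / 160 * 10, tolerance = 1e-12)
  expect_equal(unname(one$summary["total_Mg_ha"]),
               pi^2 * 0.04 * 400 / 160 * 10 / 2, tolerance = 1e-12)
  expect_equal(round(one$per_transect$total_Mg_ha[1], 4), 9.8696)
})

test_that("Brown fine-fuel classes are linear and match per-piece
           summation", {
  coef <- demo_registry()$fuel_coefficients
  tr0 <- data.frame(transect_id = "T1", count_1h = 0, count_10h = 0,
                    count_100h = 0, len_1h_m = 2, len_10h_m = 2,
                    len_100h_m = 4)
  z <- fine_fuel_biomass(tr0, coef)
  expect_equal(unname(z$summary$mean_Mg_ha), c(0, 0, 0))

  tr1 <- tr0; tr1$count_1h <- 7; tr1$count_10h <- 3; tr1$count_100h <- 2
  tr2 <- tr0; tr2$count_1h <- 14; tr2$count_10h <- 6; tr2$count_100h <- 4
  f1 <- fine_fuel_biomass(tr1, coef)$summary$mean_Mg_ha
  f2 <- fine_fuel_biomass(tr2, coef)$summary$mean_Mg_ha
  expect_equal(unname(f2), unname(2 * f1), tolerance = 1e-12)

  # algebraic oracle: n pieces of identical diameter, summed one by one
  n <- 7; qmd2_m2 <- coef$qmd2_cm2_1h / 1e4
  per_piece <- pi^2 / 8 * qmd2_m2 * coef$spgr_1h * 1000 * coef$angle_1h *
    coef$slope / 2
  expect_equal(f1[["1h"]], n * per_piece * 10, tolerance = 1e-12)
  expect_error(fine_fuel_biomass(tr1, NULL), "missing")
})

test_that("litter and duff mass is linear in depth", {
  expect_equal(litter_duff_biomass(0, 125.2)$mean_Mg_ha, 0)
  v <- litter_duff_biomass(1.05, 125.2)
  expect_equal(v$mean_Mg_ha, 0.0105 * 125.2 * 10, tolerance = 1e-12)
  expect_equal(round(v$mean_Mg_ha, 2), 13.15)
  expect_equal(litter_duff_biomass(2.10, 125.2)$mean_Mg_ha,
               2 * v$mean_Mg_ha, tolerance = 1e-12)
  expect_error(litter_duff_biomass(-1, 125.2), "negative")
})

test_that("pool aggregation is additive and ordered by threshold", {
  stand <- generate_stand(small_config(53L))
  rep <- aggregate_report(stand, reg$equations, reg$rules, reg$densities,
                          reg$species_groups, reg$fuel_coefficients,
                          shrub_proxies = reg$shrub_proxies)
  lt <- rep$live
  expect_true(all(lt$ge100_Mg_ha <= lt$ge10_Mg_ha + 1e-9))
  expect_true(all(lt$ge10_Mg_ha <= lt$ge1_Mg_ha + 1e-9))
  expect_equal(rep$totals$live_Mg_ha, sum(lt$ge1_Mg_ha), tolerance = 1e-12)
  expect_equal(rep$totals$live_sd_Mg_ha, sum(lt$ge1_sd), tolerance = 1e-12)
  expect_equal(rep$totals$grand_total_Mg_ha,
               rep$totals$live_Mg_ha + rep$totals$snag_Mg_ha +
                 rep$totals$debris_Mg_ha + rep$totals$shrub_Mg_ha +
                 rep$totals$fine_fuel_Mg_ha, tolerance = 1e-12)
  expect_true(rep$totals$live_large_prop_pct >= 0 &&
                rep$totals$live_large_prop_pct <= 100)
})
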