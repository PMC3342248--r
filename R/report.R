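#' Percentage of a subset, rounded half-even
#'
#' @param subset,all Non-negative counts or masses with
#'   \code{subset <= all}.
#' @param digits Decimal places (default 1, matching report tables).
#' @return \code{100 * subset / all} rounded half-even, or \code{NA} when
#'   \code{all} is zero (flagged undefined).
#' @export
proportions <- function(subset, all, digits = 1) {
  if (any(subset < 0) || any(all < 0)) stop("negative inputs")
  if (any(subset > all + 1e-9)) stop("subset exceeds total")
  out <- ifelse(all > 0, round(100 * subset / all, digits), NA_real_)
  out
}

#' Stand composition table
#'
#' Per-species density (stems/ha), basal area (m2/ha), stem counts at the
#' >= 1, >= 10 and >= 100 cm thresholds and the large-diameter proportion
#' of individuals — the standard composition summary for a mapped census.
#'
#' @param stand A \code{stand_dataset}.
#' @param threshold_cm Large-diameter threshold (default 100).
#' @return \code{data.frame} with one row per species plus a
#'   \code{"TOTAL"} row.
#' @export
composition_table <- function(stand, threshold_cm = 100) {
  live <- stand$stems[stand$stems$status == "live", , drop = FALSE]
  area_ha <- stand$geometry$area_ha
  sp <- sort(unique(live$species))
  cnt <- function(sel) {
    v <- tapply(rep(1, sum(sel)), live$species[sel], sum)
    out <- v[match(sp, names(v))]
    ifelse(is.na(out), 0, out)
  }
  n1 <- cnt(live$dbh_cm >= 1)
  n10 <- cnt(live$dbh_cm >= 10)
  n100 <- cnt(live$dbh_cm >= threshold_cm)
  ba <- tapply(basal_area_m2(live$dbh_cm), live$species, sum)
  ba <- ifelse(is.na(ba[match(sp, names(ba))]), 0,
               ba[match(sp, names(ba))])
  tab <- data.frame(
    species = sp,
    density_ha = round(n1 / area_ha, 1),
    basal_area_m2_ha = round(as.numeric(ba) / area_ha, 2),
    n_ge1 = as.integer(n1), n_ge10 = as.integer(n10),
    n_ge100 = as.integer(n100),
    large_prop_pct = proportions(n100, n1),
    stringsAsFactors = FALSE)
  total <- data.frame(
    species = "TOTAL",
    density_ha = round(nrow(live) / area_ha, 1),
    basal_area_m2_ha = round(sum(basal_area_m2(live$dbh_cm)) / area_ha, 2),
    n_ge1 = nrow(live), n_ge10 = sum(live$dbh_cm >= 10),
    n_ge100 = sum(live$dbh_cm >= threshold_cm),
    large_prop_pct = proportions(sum(live$dbh_cm >= threshold_cm),
                                 nrow(live)),
    stringsAsFactors = FALSE)
  rbind(tab, total)
}

#' Configuration for a full pipeline run
#'
#' @param stand_dir Directory of census layer files (read with
#'   \code{\link{read_stand}}), or \code{NULL} to generate a synthetic
#'   stand from \code{stand_config}.
#' @param stand_config A \code{\link{stand_config}} used when
#'   \code{stand_dir} is \code{NULL}.
#' @param registry_dir Directory holding \code{equations.csv},
#'   \code{substitutions.csv}, \code{decay_densities.csv},
#'   \code{species.csv}, \code{fuel_coefficients.toml},
#'   \code{shrub_proxies.csv} (defaults to the demonstration registry
#'   shipped with the package).
#' @param threshold_cm Large-diameter threshold (default 100).
#' @param spatial_species Species codes analyzed spatially (default the
#'   three most abundant in the stand).
#' @param n_sim Simulations per envelope (default 99).
#' @param r_max Maximum radius for L functions in meters (default a
#'   quarter of the minimum plot dimension).
#' @param gof_r_max Upper integration bound for the GoF test (default 9).
#' @param seed Integer seed for all Monte Carlo stages.
#' @param out_dir Output directory for the report bundle.
#' @return A \code{run_config} list.
#' @export
run_config <- function(stand_dir = NULL, stand_config = NULL,
                       registry_dir = system.file("extdata", "registry",
                                                  package = "standforge"),
                       threshold_cm = 100, spatial_species = NULL,
                       n_sim = 99, r_max = NULL, gof_r_max = 9,
                       seed = 1L, out_dir = tempfile("standforge_run_")) {
  if (threshold_cm <= 0) stop("threshold must be positive")
  structure(list(stand_dir = stand_dir, stand_config = stand_config,
                 registry_dir = registry_dir, threshold_cm = threshold_cm,
                 spatial_species = spatial_species, n_sim = n_sim,
                 r_max = r_max, gof_r_max = gof_r_max,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load the registry file set from a directory
#' @param dir Registry directory (see \code{\link{run_config}}).
#' @return List: \code{equations}, \code{rules}, \code{densities},
#'   \code{species} (table), \code{species_groups} (named vector),
#'   \code{fuel_coefficients}, \code{shrub_proxies}.
#' @export
load_registry <- function(dir) {
  species <- utils::read.csv(file.path(dir, "species.csv"),
                             stringsAsFactors = FALSE)
  proxies_path <- file.path(dir, "shrub_proxies.csv")
  list(
    equations = read_equations(file.path(dir, "equations.csv")),
    rules = read_substitutions(file.path(dir, "substitutions.csv")),
    densities = read_decay_densities(file.path(dir, "decay_densities.csv")),
    species = species,
    species_groups = stats::setNames(species$decay_group, species$code),
    fuel_coefficients = read_fuel_coefficients(
      file.path(dir, "fuel_coefficients.toml")),
    shrub_proxies = if (file.exists(proxies_path))
      utils::read.csv(proxies_path, stringsAsFactors = FALSE) else NULL)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' From raw census layers, regenerates every report product: the
#' composition table, shrub extrapolation table, multi-pool biomass report
#' with SDs and large-diameter proportions, per-quadrat summaries,
#' diameter-bin and scaling-fit exports, and (for each configured species)
#' univariate CSR and bivariate population-independence L curves with
#' envelope bounds and Loosmore-Ford GoF summaries. All outputs are CSV or
#' JSON; a run log records the seed, package version and a content hash of
#' the configuration. Identical seeds yield byte-identical bundles. Any
#' stage failure aborts the run and removes partial outputs.
#'
#' @param config A \code{\link{run_config}}.
#' @return The output directory, invisibly.
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out, recursive = TRUE))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  wcsv <- function(df, f) utils::write.csv(
    df, file.path(out, f), row.names = FALSE, quote = FALSE)

  stand <- stage("input", {
    if (!is.null(config$stand_dir)) read_stand(config$stand_dir)
    else generate_stand(if (is.null(config$stand_config)) stand_config()
                        else config$stand_config)
  })
  reg <- stage("registry", load_registry(config$registry_dir))

  stage("composition", wcsv(composition_table(stand, config$threshold_cm),
                            "composition.csv"))

  report <- stage("biomass", aggregate_report(
    stand, reg$equations, reg$rules, reg$densities, reg$species_groups,
    reg$fuel_coefficients, shrub_proxies = reg$shrub_proxies,
    threshold_cm = config$threshold_cm))
  stage("biomass", {
    wcsv(within(report$live, {
      ge1_Mg_ha <- round(ge1_Mg_ha, 3); ge1_sd <- round(ge1_sd, 3)
      ge10_Mg_ha <- round(ge10_Mg_ha, 3); ge10_sd <- round(ge10_sd, 3)
      ge100_Mg_ha <- round(ge100_Mg_ha, 3); ge100_sd <- round(ge100_sd, 3)
      large_prop_pct <- round(large_prop_pct, 1)
    }), "biomass_live.csv")
    if (!is.null(report$snags))
      wcsv(within(report$snags, {
        ge10_Mg_ha <- round(ge10_Mg_ha, 3)
        ge100_Mg_ha <- round(ge100_Mg_ha, 3)
        large_prop_pct <- round(large_prop_pct, 1)
      }), "biomass_snags.csv")
    sh <- report$shrubs
    sh$stems_per_ha <- round(sh$stems_per_ha, 0)
    sh$biomass_Mg_per_ha <- round(sh$biomass_Mg_per_ha, 3)
    wcsv(sh[, c("species", "cover_m2", "stems_per_ha",
                "biomass_Mg_per_ha")], "shrub_table.csv")
    jsonlite::write_json(
      lapply(report$totals, function(v) round(v, 3)),
      file.path(out, "biomass_totals.json"), auto_unbox = TRUE, digits = NA)
  })

  stage("quadrats", {
    live <- stand$stems[stand$stems$status == "live", , drop = FALSE]
    q <- quadratize(stand)
    q$basal_area_m2 <- round(q$basal_area_m2, 4)
    wcsv(q, "quadrats.csv")
  })

  stage("scaling", {
    live <- stand$stems[stand$stems$status == "live", , drop = FALSE]
    bt <- tree_biomass_table(live, reg$equations, reg$rules)
    bins <- bin_diameters(bt$dbh_cm, bt$biomass_kg)
    fits <- lapply(c("wbe_frequency", "wbe_biomass",
                     "negative_exponential"),
                   function(m) fit_scaling(bins, m))
    ex <- bins
    ex$biomass_Mg <- round(ex$biomass_Mg, 3)
    ex$pred_wbe_frequency <- round(fits[[1]]$predicted, 3)
    ex$pred_wbe_biomass <- round(fits[[2]]$predicted, 3)
    ex$pred_negative_exponential <- round(fits[[3]]$predicted, 3)
    wcsv(ex, "diameter_bins.csv")
    wcsv(data.frame(
      model = vapply(fits, `[[`, "", "model"),
      constants = vapply(fits, function(f)
        paste(sprintf("%s=%.6g", names(f$constants), f$constants),
              collapse = ";"), ""),
      r_squared = round(vapply(fits, `[[`, 0, "r_squared"), 2)),
      "scaling_fits.csv")
  })

  stage("spatial", {
    set.seed(config$seed)
    live <- stand$stems[stand$stems$status == "live", , drop = FALSE]
    spp <- config$spatial_species
    if (is.null(spp)) {
      tab <- sort(table(live$species), decreasing = TRUE)
      spp <- names(tab)[seq_len(min(3, length(tab)))]
    }
    win <- stand$geometry
    r_max <- if (is.null(config$r_max))
      min(win$width_m, win$height_m) / 4 else config$r_max
    r_grid <- seq(0, r_max, by = 0.25)
    gof_rows <- list()
    for (sp in spp) {
      sub <- live[live$species == sp, , drop = FALSE]
      cls <- classify_diameter(sub, config$threshold_cm)
      small <- point_pattern(cls$small$x_m, cls$small$y_m, win)
      if (small$n >= 2) {
        env <- envelope(small, "csr", n_sim = config$n_sim,
                        r_grid = r_grid)
        eb <- envelope_bounds(env)
        eb[] <- lapply(eb, function(v) round(v, 4))
        wcsv(eb, sprintf("l_univariate_small_%s.csv", sp))
        g <- gof_loosmore_ford(env, 0, config$gof_r_max)
        gof_rows[[length(gof_rows) + 1]] <- data.frame(
          species = sp, test = "univariate_small_csr",
          u_observed = g$u_observed, p_value = g$p_value,
          n_sim = g$n_sim)
      }
      if (nrow(cls$large) >= 1 && nrow(cls$small) >= 1) {
        mk <- point_pattern(
          c(cls$large$x_m, cls$small$x_m), c(cls$large$y_m, cls$small$y_m),
          win, mark = rep(c("large", "small"),
                          c(nrow(cls$large), nrow(cls$small))))
        env2 <- envelope(mk, "population_independence",
                         n_sim = config$n_sim, r_grid = r_grid,
                         types = c("large", "small"))
        eb2 <- envelope_bounds(env2)
        eb2[] <- lapply(eb2, function(v) round(v, 4))
        wcsv(eb2, sprintf("l_bivariate_%s.csv", sp))
        g2 <- gof_loosmore_ford(env2, 0, config$gof_r_max)
        gof_rows[[length(gof_rows) + 1]] <- data.frame(
          species = sp, test = "bivariate_population_independence",
          u_observed = g2$u_observed, p_value = g2$p_value,
          n_sim = g2$n_sim)
      }
    }
    if (length(gof_rows)) {
      gr <- do.call(rbind, gof_rows)
      gr$u_observed <- signif(gr$u_observed, 6)
      gr$bonferroni_threshold <- bonferroni(0.05, nrow(gr))
      wcsv(gr, "gof_summary.csv")
    }
  })

  stage("log", {
    cfgfile <- tempfile()
    dput(config[setdiff(names(config), "out_dir")], file = cfgfile)
    hash <- unname(tools::md5sum(cfgfile))
    unlink(cfgfile)
    jsonlite::write_json(list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("standforge")),
      threshold_cm = config$threshold_cm,
      n_sim = config$n_sim,
      config_md5 = hash), file.path(out, "run_log.json"),
      auto_unbox = TRUE, digits = NA)
  })
  ok <- TRUE
  invisible(out)
}
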