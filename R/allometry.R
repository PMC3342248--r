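#' Read an allometric equation registry
#'
#' The registry is a delimited file with one biomass-component model per
#' row: \code{species}, \code{component} (bole, branch, foliage, bark or
#' whole), \code{form} (\code{log10_linear}: \eqn{m = 10^{a + b
#' \log_{10}dbh}}; \code{ln_linear}: \eqn{m = e^{a + b \ln dbh}};
#' \code{power}: \eqn{m = a \cdot dbh^b}), coefficients \code{c0},
#' \code{c1}, the validity range \code{dbh_min_cm}/\code{dbh_max_cm}, the
#' log-scale root-mean-square error \code{rmse_log} (in the equation's
#' native log base; may be empty) and a \code{source_id} citation key.
#' Masses are kilograms, diameters centimeters.
#'
#' @param path CSV file path.
#' @return \code{data.frame} registry.
#' @export
read_equations <- function(path) {
  eq <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "component", "form", "c0", "c1",
            "dbh_min_cm", "dbh_max_cm", "rmse_log", "source_id")
  miss <- setdiff(need, names(eq))
  if (length(miss))
    stop("equation registry missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(eq$dbh_min_cm >= eq$dbh_max_cm))
    stop("equation registry: dbh_min_cm must be below dbh_max_cm")
  eq
}

#' Read substitution/capping rules
#'
#' Rules route components of one species to a proxy species' equations at
#' and above a diameter threshold, optionally capping branch and foliage
#' biomass at the value for a fixed diameter (used where no equations
#' exist for the very largest trees). Columns: \code{species},
#' \code{dbh_from_cm}, \code{proxy_species}, \code{components}
#' (semicolon-separated), \code{cap_dbh_cm} (may be empty).
#'
#' @param path CSV file path.
#' @return \code{data.frame} of rules.
#' @export
read_substitutions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read decay-class wood densities
#'
#' Long-format table: \code{species_group}, \code{decay_class} (1-5),
#' \code{density_kg_m3}. Densities must be positive and non-increasing
#' with decay class within a group.
#'
#' @param path CSV file path.
#' @return \code{data.frame}.
#' @export
read_decay_densities <- function(path) {
  dd <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(dd$density_kg_m3 <= 0)) stop("decay densities must be positive")
  for (g in unique(dd$species_group)) {
    v <- dd$density_kg_m3[dd$species_group == g][
      order(dd$decay_class[dd$species_group == g])]
    if (any(diff(v) > 1e-9))
      stop("decay densities must be non-increasing with decay class (group ",
           g, ")")
  }
  dd
}

#' Read fine-fuel coefficient sets
#'
#' Flat key-value file (\code{key = value} lines, \code{#} comments) with
#' per-class squared quadratic-mean diameters \code{qmd2_cm2_*}, specific
#' gravities \code{spgr_*}, nonhorizontal-angle corrections \code{angle_*}
#' and a common \code{slope} correction, for classes \code{1h}, \code{10h},
#' \code{100h}.
#'
#' @param path File path.
#' @return Named list of numeric coefficients.
#' @export
read_fuel_coefficients <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    if (length(p) != 2) stop("malformed coefficient line: ",
                             paste(p, collapse = " = "))
    out[[p[1]]] <- as.numeric(p[2])
  }
  need <- as.vector(outer(c("qmd2_cm2", "spgr", "angle"),
                          c("1h", "10h", "100h"), paste, sep = "_"))
  miss <- setdiff(c(need, "slope"), names(out))
  if (length(miss))
    stop("fuel coefficient set missing: ", paste(miss, collapse = ", "))
  out
}

# Evaluate one registry equation row at a vector of diameters (kg).
.eval_equation <- function(eq, dbh) {
  switch(eq$form,
         log10_linear = 10^(eq$c0 + eq$c1 * log10(dbh)),
         ln_linear = exp(eq$c0 + eq$c1 * log(dbh)),
         power = eq$c0 * dbh^eq$c1,
         stop("unknown equation form: ", eq$form))
}

.eq_log_base <- function(form) {
  if (form == "log10_linear") 10 else exp(1)
}

#' Convert a log-scale RMSE to an arithmetic standard deviation
#'
#' Uses the lognormal moment identity: for an estimate \eqn{\hat m} from a
#' regression with log-scale root-mean-square error \eqn{s} in base
#' \eqn{b}, \deqn{SD = \hat m \sqrt{e^{(s \ln b)^2} - 1}.}
#'
#' @param m_hat Estimated mass (kg, or any unit; SD is returned in the
#'   same unit).
#' @param rmse_log RMSE on the equation's log scale (>= 0).
#' @param log_base 10 or \code{exp(1)} per the equation form.
#' @return Arithmetic standard deviation.
#' @export
rmse_to_sd <- function(m_hat, rmse_log, log_base = 10) {
  if (any(rmse_log < 0)) stop("rmse_log must be non-negative")
  m_hat * sqrt(exp((rmse_log * log(log_base))^2) - 1)
}

# Resolve the equation row for (species, component), honoring proxy
# substitution rules at/above their diameter thresholds.
.find_equation <- function(registry, species, component) {
  hit <- registry[registry$species == species &
                    registry$component == component, , drop = FALSE]
  if (nrow(hit)) hit[1, , drop = FALSE] else NULL
}

#' Per-tree biomass with substitution and capping rules
#'
#' Evaluates the registered allometric model(s) for one stem. If the
#' species has a whole-tree equation it is used directly; otherwise the
#' component equations (bole, branch, foliage and optionally bark) are
#' evaluated on their native scale, back-transformed without smearing
#' correction, and summed. Substitution rules reroute components to proxy
#' species at and above a diameter threshold, and where a
#' \code{cap_dbh_cm} is set, branch and foliage biomass for larger stems
#' is held at the value for the cap diameter. The per-tree SD combines
#' each evaluated equation's log-scale RMSE through
#' \code{\link{rmse_to_sd}} by arithmetic summation (errors treated as
#' fully correlated across components).
#'
#' @param stem One-row stem record (needs \code{species} and
#'   \code{dbh_cm}).
#' @param registry Equation registry from \code{\link{read_equations}}.
#' @param rules Substitution rules (optional).
#' @return List: \code{components} (named kg), \code{total_kg},
#'   \code{sd_kg}.
#' @export
tree_biomass <- function(stem, registry, rules = NULL) {
  sp <- stem$species; dbh <- stem$dbh_cm
  sel <- .select_models(sp, dbh, registry, rules)
  comps <- numeric(0); sds <- numeric(0)
  for (nm in names(sel)) {
    eq <- sel[[nm]]$eq
    cap <- sel[[nm]]$cap
    d_eval <- if (!is.na(cap) && dbh > cap) cap else dbh
    if (d_eval < eq$dbh_min_cm)
      stop(sprintf("range error: dbh %.2f below equation minimum %.2f (%s %s)",
                   d_eval, eq$dbh_min_cm, eq$species, eq$component))
    if (d_eval > eq$dbh_max_cm)
      stop(sprintf("range error: dbh %.2f above equation maximum %.2f (%s %s)",
                   d_eval, eq$dbh_max_cm, eq$species, eq$component))
    m <- .eval_equation(eq, d_eval)
    comps[nm] <- m
    s <- if (is.na(eq$rmse_log)) 0 else eq$rmse_log
    sds[nm] <- rmse_to_sd(m, s, .eq_log_base(eq$form))
  }
  list(components = comps, total_kg = sum(comps), sd_kg = sum(sds))
}

# Choose the set of (component, equation, evaluation dbh) for one stem.
.select_models <- function(sp, dbh, registry, rules) {
  rule <- NULL
  if (!is.null(rules) && nrow(rules)) {
    cand <- rules[rules$species == sp & dbh >= rules$dbh_from_cm, ,
                  drop = FALSE]
    if (nrow(cand))
      rule <- cand[which.max(cand$dbh_from_cm), , drop = FALSE]
  }
  routed <- if (!is.null(rule))
    strsplit(rule$components, ";", fixed = TRUE)[[1]] else character(0)
  cap <- if (!is.null(rule) && !is.na(rule$cap_dbh_cm)) rule$cap_dbh_cm
         else NA_real_

  whole <- .find_equation(registry, sp, "whole")
  use_components <- length(routed) > 0 ||
    is.null(whole) ||
    nrow(registry[registry$species == sp &
                    registry$component != "whole", , drop = FALSE]) > 0
  sel <- list()
  if (!use_components) {
    if (is.null(whole))
      stop("unresolved-species error: no equation or rule for species ", sp)
    sel$whole <- list(eq = whole, cap = NA_real_)
    return(sel)
  }
  comps <- c("bole", "bark", "branch", "foliage")
  have_any <- FALSE
  for (cm in comps) {
    src_sp <- if (cm %in% routed) rule$proxy_species else sp
    eq <- .find_equation(registry, src_sp, cm)
    if (is.null(eq) && cm %in% routed)
      stop("unresolved-species error: proxy ", rule$proxy_species,
           " lacks a ", cm, " equation")
    if (is.null(eq)) next
    have_any <- TRUE
    sel[[cm]] <- list(
      eq = eq,
      cap = if (cm %in% c("branch", "foliage")) cap else NA_real_)
  }
  if (!have_any) {
    if (!is.null(whole)) {
      sel$whole <- list(eq = whole, cap = NA_real_)
    } else {
      stop("unresolved-species error: no equation or rule for species ", sp)
    }
  }
  sel
}

#' Biomass for a stem table
#'
#' Vectorized companion of \code{\link{tree_biomass}}: stems are grouped
#' by species and substitution regime (the rule thresholds partition the
#' diameter axis) and each selected equation is evaluated over the whole
#' group at once. Results are identical to the per-stem path.
#'
#' @param stems Stem \code{data.frame}.
#' @inheritParams tree_biomass
#' @return \code{data.frame} with \code{tag}, \code{species},
#'   \code{dbh_cm}, \code{biomass_kg}, \code{sd_kg}.
#' @export
tree_biomass_table <- function(stems, registry, rules = NULL) {
  n <- nrow(stems)
  bm <- numeric(n); sd <- numeric(n)
  for (sp in unique(stems$species)) {
    si <- which(stems$species == sp)
    d <- stems$dbh_cm[si]
    thr <- numeric(0)
    if (!is.null(rules) && nrow(rules))
      thr <- sort(unique(rules$dbh_from_cm[rules$species == sp]))
    regime <- if (length(thr)) findInterval(d, thr) else rep(0L, length(d))
    for (rg in unique(regime)) {
      di <- which(regime == rg)
      dd <- d[di]
      sel <- .select_models(sp, dd[1], registry, rules)
      tot <- numeric(length(dd)); tsd <- numeric(length(dd))
      for (nm in names(sel)) {
        eq <- sel[[nm]]$eq
        cap <- sel[[nm]]$cap
        d_eval <- if (!is.na(cap)) pmin(dd, cap) else dd
        low <- d_eval < eq$dbh_min_cm
        high <- d_eval > eq$dbh_max_cm
        if (any(low))
          stop(sprintf(
            "range error: dbh %.2f below equation minimum %.2f (%s %s)",
            d_eval[low][1], eq$dbh_min_cm, eq$species, eq$component))
        if (any(high))
          stop(sprintf(
            "range error: dbh %.2f above equation maximum %.2f (%s %s)",
            d_eval[high][1], eq$dbh_max_cm, eq$species, eq$component))
        m <- .eval_equation(eq, d_eval)
        s <- if (is.na(eq$rmse_log)) 0 else eq$rmse_log
        tot <- tot + m
        tsd <- tsd + rmse_to_sd(m, s, .eq_log_base(eq$form))
      }
      bm[si[di]] <- tot
      sd[si[di]] <- tsd
    }
  }
  data.frame(tag = stems$tag, species = stems$species,
             dbh_cm = stems$dbh_cm, biomass_kg = bm, sd_kg = sd,
             stringsAsFactors = FALSE)
}

#' Snag biomass from a frustum-of-cone bole volume
#'
#' \deqn{V = \frac{\pi h}{3} (R^2 + R r + r^2)} with basal radius
#' \eqn{R = dbh/200} m and top radius \eqn{r = top/200} m, converted to
#' mass with the decay-class wood density for the species group.
#'
#' @param snag One-row snag record (\code{dbh_cm}, \code{height_m},
#'   \code{top_diameter_cm}, \code{decay_class}, \code{species}).
#' @param densities Decay density table (\code{\link{read_decay_densities}}).
#' @param species_groups Named character vector mapping species codes to
#'   density groups; unmapped species use group \code{"unknown"}.
#' @return Mass in Mg.
#' @export
snag_biomass <- function(snag, densities, species_groups = NULL) {
  if (is.na(snag$decay_class)) stop("missing decay class")
  R <- snag$dbh_cm / 200; r <- snag$top_diameter_cm / 200
  V <- pi * snag$height_m / 3 * (R^2 + R * r + r^2)
  grp <- "unknown"
  if (!is.null(species_groups) && snag$species %in% names(species_groups))
    grp <- species_groups[[snag$species]]
  rho <- densities$density_kg_m3[densities$species_group == grp &
                                   densities$decay_class == snag$decay_class]
  if (!length(rho))
    rho <- densities$density_kg_m3[densities$species_group == "unknown" &
                                     densities$decay_class == snag$decay_class]
  if (!length(rho)) stop("no density for group ", grp, " decay class ",
                         snag$decay_class)
  V * rho[1] / 1000
}

#' Extrapolate shrub densities from patch cover and demography subplots
#'
#' Per species: summed patch cover (m2) times the demography-subplot
#' densities, scaled to the plot. Biomass in Mg/ha is
#' \eqn{\sum(\mathrm{cover}) \cdot \mathrm{kg/m^2} / (\mathrm{area_{ha}}
#' \cdot 1000)}; stem density per hectare is analogous with stems per m2.
#' Species without their own demography data are resolved through a proxy
#' table (\code{species}, \code{proxy_species}, \code{density_scale},
#' \code{biomass_scale}), e.g. a half-biomass proxy.
#'
#' @param patches \code{data.frame} with at least \code{species} and
#'   \code{area_m2} (one row per patch; rows are summed per species).
#' @param demography \code{data.frame} with \code{species},
#'   \code{stems_per_m2}, \code{biomass_kg_per_m2}.
#' @param geometry A \code{\link{plot_geometry}}.
#' @param proxies Optional proxy table as described above.
#' @return \code{data.frame} per species: \code{cover_m2},
#'   \code{stems_per_ha}, \code{biomass_Mg_per_ha}; attribute
#'   \code{totals} holds the plot sums.
#' @export
shrub_extrapolate <- function(patches, demography, geometry,
                              proxies = NULL) {
  if (is.null(patches) || !nrow(patches)) {
    out <- data.frame(species = character(0), cover_m2 = numeric(0),
                      stems_per_ha = numeric(0),
                      biomass_Mg_per_ha = numeric(0))
    attr(out, "totals") <- c(cover_m2 = 0, stems_per_ha = 0,
                             biomass_Mg_per_ha = 0)
    return(out)
  }
  cover <- tapply(patches$area_m2, patches$species, sum)
  area_ha <- geometry$area_ha
  sp <- names(cover)
  stems <- numeric(length(sp)); bm <- numeric(length(sp))
  for (i in seq_along(sp)) {
    s <- sp[i]
    dsc <- 1; bsc <- 1; src <- s
    if (!(s %in% demography$species)) {
      if (!is.null(proxies) && s %in% proxies$species) {
        row <- proxies[proxies$species == s, ][1, ]
        src <- row$proxy_species
        if (!is.null(row$density_scale) && !is.na(row$density_scale))
          dsc <- row$density_scale
        if (!is.null(row$biomass_scale) && !is.na(row$biomass_scale))
          bsc <- row$biomass_scale
      } else {
        stop("unresolvable shrub species (no demography data or proxy): ", s)
      }
    }
    if (!(src %in% demography$species))
      stop("unresolvable shrub species: proxy ", src, " for ", s,
           " has no demography data")
    dem <- demography[demography$species == src, ][1, ]
    stems[i] <- cover[[s]] * dem$stems_per_m2 * dsc / area_ha
    bm[i] <- cover[[s]] * dem$biomass_kg_per_m2 * bsc / (area_ha * 1000)
  }
  out <- data.frame(species = sp, cover_m2 = as.numeric(cover),
                    stems_per_ha = stems, biomass_Mg_per_ha = bm,
                    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(cover_m2 = sum(out$cover_m2),
                           stems_per_ha = sum(stems),
                           biomass_Mg_per_ha = sum(bm))
  out
}

#' Coarse woody debris biomass by the planar-intercept method
#'
#' Per transect, volume per unit area is \deqn{V/A = \frac{\pi^2 \sum
#' d_i^2}{8 L}} with intercept diameters \eqn{d_i} in meters and transect
#' length \eqn{L} in meters; each piece is converted to mass with the
#' decay-class wood density before summation. The plot estimate is the
#' mean over transects, with the across-transect SD.
#'
#' @param transects Transect table (needs \code{transect_id},
#'   \code{length_m}).
#' @param intercepts Coarse intercept table (\code{transect_id},
#'   \code{diameter_cm}, \code{decay_class}, \code{species}).
#' @param densities Decay density table.
#' @param species_groups Optional species-to-group map (see
#'   \code{\link{snag_biomass}}).
#' @param large_threshold_cm Diameter defining the large-diameter subset
#'   (default 100).
#' @return List with \code{per_transect} (Mg/ha for all pieces and the
#'   large subset per transect) and \code{summary} (means, SDs,
#'   large-diameter proportion in percent).
#' @export
coarse_debris_biomass <- function(transects, intercepts, densities,
                                  species_groups = NULL,
                                  large_threshold_cm = 100) {
  if (any(transects$length_m <= 0)) stop("zero-length transect")
  if (nrow(intercepts) && any(intercepts$diameter_cm < 10))
    stop("coarse intercept diameters must be >= 10 cm")
  piece_mass <- function(sub, L) {
    if (!nrow(sub)) return(0)
    grp <- rep("unknown", nrow(sub))
    if (!is.null(species_groups)) {
      known <- sub$species %in% names(species_groups)
      grp[known] <- unname(species_groups[sub$species[known]])
    }
    rho <- mapply(function(g, dc) {
      v <- densities$density_kg_m3[densities$species_group == g &
                                     densities$decay_class == dc]
      if (!length(v))
        v <- densities$density_kg_m3[densities$species_group == "unknown" &
                                       densities$decay_class == dc]
      v[1]
    }, grp, sub$decay_class)
    d_m <- sub$diameter_cm / 100
    sum(pi^2 * d_m^2 * rho / (8 * L)) * 10  # kg/m2 -> Mg/ha
  }
  per <- data.frame(transect_id = transects$transect_id,
                    total_Mg_ha = 0, large_Mg_ha = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(transects))) {
    sub <- intercepts[intercepts$transect_id == transects$transect_id[i], ,
                      drop = FALSE]
    per$total_Mg_ha[i] <- piece_mass(sub, transects$length_m[i])
    per$large_Mg_ha[i] <- piece_mass(
      sub[sub$diameter_cm >= large_threshold_cm, , drop = FALSE],
      transects$length_m[i])
  }
  tot <- mean(per$total_Mg_ha)
  lg <- mean(per$large_Mg_ha)
  list(per_transect = per,
       summary = c(total_Mg_ha = tot,
                   total_sd = stats::sd(per$total_Mg_ha),
                   large_Mg_ha = lg,
                   large_sd = stats::sd(per$large_Mg_ha),
                   large_prop_pct = if (tot > 0) 100 * lg / tot else NA))
}

#' Fine-fuel biomass by timelag class (Brown's planar-intercept method)
#'
#' Per transect and class, mass per area is \deqn{w = \frac{\pi^2}{8}
#' \cdot \frac{n \cdot QMD^2 \cdot SG \cdot c_{angle} \cdot
#' c_{slope}}{L}} with the class tally \eqn{n}, squared quadratic-mean
#' diameter \eqn{QMD^2} (m2, supplied in cm2), particle density
#' \eqn{SG \cdot 1000} kg/m3, nonhorizontal-angle and slope corrections,
#' and the sampled sub-length \eqn{L} (m); reported in Mg/ha.
#'
#' @param transects Transect table with class tallies and sub-lengths.
#' @param coefficients Coefficient set from
#'   \code{\link{read_fuel_coefficients}}.
#' @return List: \code{per_transect} (Mg/ha per class) and \code{summary}
#'   (mean and SD per class plus the total).
#' @export
fine_fuel_biomass <- function(transects, coefficients) {
  if (is.null(coefficients)) stop("missing fuel coefficient set")
  k <- pi^2 / 8
  cls <- c("1h", "10h", "100h")
  per <- data.frame(transect_id = transects$transect_id,
                    stringsAsFactors = FALSE)
  for (cl in cls) {
    n <- transects[[paste0("count_", cl)]]
    L <- transects[[paste0("len_", cl, "_m")]]
    qmd2_m2 <- coefficients[[paste0("qmd2_cm2_", cl)]] / 1e4
    sg <- coefficients[[paste0("spgr_", cl)]]
    a <- coefficients[[paste0("angle_", cl)]]
    w_kg_m2 <- k * n * qmd2_m2 * (sg * 1000) * a * coefficients$slope / L
    per[[paste0("fuel_", cl, "_Mg_ha")]] <- w_kg_m2 * 10
  }
  means <- vapply(cls, function(cl) mean(per[[paste0("fuel_", cl, "_Mg_ha")]]),
                  0)
  sds <- vapply(cls, function(cl) stats::sd(per[[paste0("fuel_", cl,
                                                        "_Mg_ha")]]), 0)
  list(per_transect = per,
       summary = list(mean_Mg_ha = means, sd_Mg_ha = sds,
                      total_Mg_ha = sum(means)))
}

#' Litter and duff biomass from depth and bulk density
#'
#' Mass in Mg/ha equals mean depth (m) times bulk density (kg/m3) times
#' 10. Default bulk densities (litter 125.2 kg/m3, duff 200.1 kg/m3) are
#' calibrated for Sierra Nevada mixed-conifer forest floors.
#'
#' @param depth_cm Depths in centimeters (one per transect, or a scalar
#'   mean).
#' @param bulk_density_kg_m3 Bulk density.
#' @return List: \code{per_transect} Mg/ha values, \code{mean_Mg_ha},
#'   \code{sd_Mg_ha}.
#' @export
litter_duff_biomass <- function(depth_cm, bulk_density_kg_m3) {
  if (any(depth_cm < 0)) stop("validation error: negative depth")
  v <- depth_cm / 100 * bulk_density_kg_m3 * 10
  list(per_transect = v, mean_Mg_ha = mean(v),
       sd_Mg_ha = if (length(v) > 1) stats::sd(v) else 0)
}

#' Default forest-floor bulk densities (kg/m3)
#' @return Named vector with elements \code{litter} and \code{duff}.
#' @export
default_bulk_densities <- function() c(litter = 125.2, duff = 200.1)

#' Aggregate all biomass pools into a plot report
#'
#' Computes every pool from the raw census layers and assembles a
#' table-style report: per-species live-tree biomass at the >= 1 cm,
#' >= 10 cm and >= 100 cm thresholds with SDs (per-species SD is the sum
#' of per-tree SDs, and the plot SD the sum of species SDs — the fully
#' correlated error convention for shared allometric equations), snag
#' biomass by species with the large-diameter subset, coarse debris,
#' shrubs, fine fuels, litter and duff, plus large-diameter proportions
#' and the live + dead grand total.
#'
#' @param stand A \code{stand_dataset}.
#' @param registry,rules Allometric registry and substitution rules.
#' @param densities Decay density table.
#' @param species_groups Species-to-density-group map.
#' @param fuel_coefficients Fine-fuel coefficient set.
#' @param bulk_densities Litter/duff bulk densities (named vector).
#' @param shrub_proxies Optional shrub proxy table.
#' @param threshold_cm Large-diameter threshold (default 100).
#' @return Object of class \code{biomass_report}.
#' @export
aggregate_report <- function(stand, registry, rules = NULL, densities,
                             species_groups = NULL, fuel_coefficients,
                             bulk_densities = default_bulk_densities(),
                             shrub_proxies = NULL, threshold_cm = 100) {
  area_ha <- stand$geometry$area_ha
  live <- stand$stems[stand$stems$status == "live", , drop = FALSE]
  bt <- tree_biomass_table(live, registry, rules)

  pool <- function(min_dbh) {
    sel <- bt$dbh_cm >= min_dbh
    agg <- function(v) tapply(v[sel], bt$species[sel], sum)
    m <- agg(bt$biomass_kg); s <- agg(bt$sd_kg)
    data.frame(species = names(m),
               biomass_Mg_ha = as.numeric(m) / (area_ha * 1000),
               sd_Mg_ha = as.numeric(s) / (area_ha * 1000),
               stringsAsFactors = FALSE)
  }
  p1 <- pool(1); p10 <- pool(10); p100 <- pool(threshold_cm)
  species <- sort(unique(bt$species))
  get <- function(p, sp, col) {
    v <- p[[col]][match(sp, p$species)]
    ifelse(is.na(v), 0, v)
  }
  live_tab <- data.frame(
    species = species,
    ge1_Mg_ha = get(p1, species, "biomass_Mg_ha"),
    ge1_sd = get(p1, species, "sd_Mg_ha"),
    ge10_Mg_ha = get(p10, species, "biomass_Mg_ha"),
    ge10_sd = get(p10, species, "sd_Mg_ha"),
    ge100_Mg_ha = get(p100, species, "biomass_Mg_ha"),
    ge100_sd = get(p100, species, "sd_Mg_ha"),
    stringsAsFactors = FALSE)
  live_tab$large_prop_pct <- ifelse(
    live_tab$ge1_Mg_ha > 0,
    100 * live_tab$ge100_Mg_ha / live_tab$ge1_Mg_ha, NA)

  sn <- stand$snags
  snag_tab <- NULL
  if (nrow(sn)) {
    m <- vapply(seq_len(nrow(sn)), function(i)
      snag_biomass(sn[i, ], densities, species_groups), 0)
    tot <- tapply(m, sn$species, sum) / area_ha
    big <- tapply(m * (sn$dbh_cm >= threshold_cm), sn$species, sum) / area_ha
    snag_tab <- data.frame(species = names(tot),
                           ge10_Mg_ha = as.numeric(tot),
                           ge100_Mg_ha = as.numeric(big),
                           stringsAsFactors = FALSE)
    snag_tab$large_prop_pct <- ifelse(snag_tab$ge10_Mg_ha > 0,
                                      100 * snag_tab$ge100_Mg_ha /
                                        snag_tab$ge10_Mg_ha, NA)
  }

  debris <- coarse_debris_biomass(stand$transects, stand$intercepts,
                                  densities, species_groups, threshold_cm)
  shrubs <- shrub_extrapolate(stand$shrub_patches, stand$demography,
                              stand$geometry, shrub_proxies)
  fuels <- fine_fuel_biomass(stand$transects, fuel_coefficients)
  litter <- litter_duff_biomass(stand$transects$litter_cm,
                                bulk_densities[["litter"]])
  duff <- litter_duff_biomass(stand$transects$duff_cm,
                              bulk_densities[["duff"]])

  live_total <- sum(live_tab$ge1_Mg_ha)
  live_large <- sum(live_tab$ge100_Mg_ha)
  snag_total <- if (is.null(snag_tab)) 0 else sum(snag_tab$ge10_Mg_ha)
  snag_large <- if (is.null(snag_tab)) 0 else sum(snag_tab$ge100_Mg_ha)
  shrub_total <- attr(shrubs, "totals")[["biomass_Mg_per_ha"]]
  fine_total <- fuels$summary$total_Mg_ha + litter$mean_Mg_ha +
    duff$mean_Mg_ha
  grand <- live_total + snag_total + debris$summary[["total_Mg_ha"]] +
    shrub_total + fine_total

  structure(list(
    live = live_tab, snags = snag_tab, debris = debris$summary,
    debris_per_transect = debris$per_transect,
    shrubs = shrubs, fuels = fuels$summary,
    litter = c(mean_Mg_ha = litter$mean_Mg_ha, sd_Mg_ha = litter$sd_Mg_ha),
    duff = c(mean_Mg_ha = duff$mean_Mg_ha, sd_Mg_ha = duff$sd_Mg_ha),
    totals = list(
      live_Mg_ha = live_total,
      live_sd_Mg_ha = sum(live_tab$ge1_sd),
      live_large_Mg_ha = live_large,
      live_large_prop_pct = if (live_total > 0)
        100 * live_large / live_total else NA,
      snag_Mg_ha = snag_total,
      snag_large_prop_pct = if (snag_total > 0)
        100 * snag_large / snag_total else NA,
      debris_Mg_ha = debris$summary[["total_Mg_ha"]],
      debris_large_prop_pct = debris$summary[["large_prop_pct"]],
      shrub_Mg_ha = shrub_total,
      fine_fuel_Mg_ha = fine_total,
      grand_total_Mg_ha = grand)),
    class = "biomass_report")
}

#' @export
print.biomass_report <- function(x, ...) {
  t <- x$totals
  cat("Biomass report (Mg/ha)\n")
  cat(sprintf("  live trees   %10.3f (SD %.3f), large-diameter %.1f%%\n",
              t$live_Mg_ha, t$live_sd_Mg_ha, t$live_large_prop_pct))
  cat(sprintf("  snags        %10.3f, large-diameter %.1f%%\n",
              t$snag_Mg_ha,
              if (is.na(t$snag_large_prop_pct)) 0 else t$snag_large_prop_pct))
  cat(sprintf("  woody debris %10.3f, large-diameter %.1f%%\n",
              t$debris_Mg_ha,
              if (is.na(t$debris_large_prop_pct)) 0
              else t$debris_large_prop_pct))
  cat(sprintf("  shrubs       %10.3f\n", t$shrub_Mg_ha))
  cat(sprintf("  fine fuels   %10.3f (incl. litter and duff)\n",
              t$fine_fuel_Mg_ha))
  cat(sprintf("  grand total  %10.1f\n", t$grand_total_Mg_ha))
  invisible(x)
}
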