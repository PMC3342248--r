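#' Configuration for the synthetic stand generator
#'
#' Default parameters emulate the structure of an old-growth Sierra Nevada
#' mixed-conifer census: clustered small trees (Thomas process, clustering
#' at scales under ~20 m), near-random large trees with a small-scale hard
#' core, large/small segregation within 10 m, a negative-exponential
#' small-tree diameter distribution, roughly 20 snags per 100 live stems
#' over 10 cm dbh, ~15% shrub cover and a coarse debris field sampled by
#' 20 m planar-intercept transects. Realized densities under the defaults
#' are approximately 1,350 stems/ha with ~19 large-diameter (>= 100 cm)
#' trees/ha.
#'
#' @param geometry Plot window (default 800 x 320 m).
#' @param species_weights Named stem-count mixture weights for tree species
#'   codes.
#' @param small Thomas-process parameters for small trees:
#'   \code{kappa} (parents/m2), \code{mu} (mean offspring per parent),
#'   \code{sigma} (Gaussian dispersal sd, m).
#' @param large Large-tree parameters: \code{lambda} (points/m2) and
#'   \code{hard_core_m} (minimum spacing, m).
#' @param segregation Thinning of small trees near large trees:
#'   \code{rho_m} (radius) and \code{p} (removal probability).
#' @param dbh_small Diameter model for small trees (see
#'   \code{\link{sample_dbh}}).
#' @param dbh_large Large-tree dbh: 100 cm plus an exponential excess with
#'   mean \code{mean_excess_cm}, truncated at \code{max_cm}.
#' @param snag_fraction Expected ratio of snag count to live stems >= 10 cm.
#' @param shrub Boolean-disc shrub model: \code{cover_target} (fraction of
#'   plot area), disc radius range \code{r_min}/\code{r_max} (m), and
#'   \code{species_weights}.
#' @param debris Coarse debris field: segment \code{intensity} (pieces/m2),
#'   length range \code{len_min}/\code{len_max} (m), lognormal diameter
#'   parameters \code{diam_meanlog}/\code{diam_sdlog} (cm scale) truncated
#'   at \code{min_diam_cm}.
#' @param fuels Fine-fuel tally means per transect (\code{mu_1h},
#'   \code{mu_10h}, \code{mu_100h}) and litter/duff depth moments (cm).
#' @param rng_seed Integer seed; each census layer draws from its own
#'   derived stream (seed + layer index) so layers regenerate independently.
#' @return A \code{stand_config} list.
#' @export
stand_config <- function(
    geometry = plot_geometry(800, 320),
    species_weights = c(ABCO = 0.710, PILA = 0.138, CONU = 0.069,
                        CADE = 0.046, QUKE = 0.032, PRSP = 0.005),
    small = list(kappa = 0.006, mu = 28.6, sigma = 4),
    large = list(lambda = 0.00191, hard_core_m = 2),
    segregation = list(rho_m = 10, p = 0.5),
    dbh_small = list(type = "negative_exponential", rate = 0.08),
    dbh_large = list(mean_excess_cm = 30, max_cm = 250),
    snag_fraction = 0.199,
    shrub = list(cover_target = 0.15, r_min = 1.5, r_max = 8,
                 species_weights = c(CHSE = 0.3, COCO = 0.3, ARPA = 0.15,
                                     CECO = 0.1, COSE = 0.1, LEDA = 0.05)),
    debris = list(intensity = 0.0184, len_min = 4, len_max = 16,
                  diam_meanlog = log(20), diam_sdlog = 0.85,
                  min_diam_cm = 10),
    fuels = list(mu_1h = 34.8, mu_10h = 8.3, mu_100h = 2.1,
                 litter_mean_cm = 1.05, litter_sd_cm = 0.38,
                 duff_mean_cm = 1.20, duff_sd_cm = 0.68),
    rng_seed = 1L) {
  stopifnot(small$kappa >= 0, small$mu >= 0, small$sigma >= 0,
            large$lambda >= 0, large$hard_core_m >= 0,
            segregation$p >= 0, segregation$p <= 1,
            snag_fraction >= 0, snag_fraction <= 1,
            shrub$cover_target >= 0, shrub$cover_target < 1,
            debris$intensity >= 0)
  structure(list(geometry = geometry, species_weights = species_weights,
                 small = small, large = large, segregation = segregation,
                 dbh_small = dbh_small, dbh_large = dbh_large,
                 snag_fraction = snag_fraction, shrub = shrub,
                 debris = debris, fuels = fuels,
                 rng_seed = as.integer(rng_seed)),
            class = "stand_config")
}

#' Simulate a Thomas cluster process
#'
#' Parents are Poisson with intensity \code{kappa} on the window expanded
#' by four dispersal standard deviations on every side (so clusters whose
#' parents fall just outside still contribute); each parent receives a
#' Poisson(\code{mu}) number of offspring displaced by isotropic Gaussian
#' noise with sd \code{sigma}; offspring outside the window are discarded.
#' The expected retained point count is \code{kappa * mu * area}.
#'
#' @param kappa Parent intensity per square meter.
#' @param mu Mean offspring per parent.
#' @param sigma Dispersal standard deviation in meters.
#' @param window A \code{\link{plot_geometry}}.
#' @return A \code{\link{point_pattern}} of offspring.
#' @export
sample_thomas <- function(kappa, mu, sigma, window) {
  stopifnot(kappa >= 0, mu >= 0, sigma >= 0)
  W <- window$width_m; H <- window$height_m
  e <- 4 * sigma
  n_par <- stats::rpois(1, kappa * (W + 2 * e) * (H + 2 * e))
  if (n_par == 0 || mu == 0)
    return(point_pattern(numeric(0), numeric(0), window))
  px <- stats::runif(n_par, -e, W + e)
  py <- stats::runif(n_par, -e, H + e)
  n_off <- stats::rpois(n_par, mu)
  x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
  keep <- x >= 0 & x <= W & y >= 0 & y <= H
  point_pattern(x[keep], y[keep], window)
}

#' Simulate a hard-core point process by dependent thinning
#'
#' Draws a Poisson(\code{lambda * area}) proposal pattern and accepts
#' points sequentially in their (already random) order, rejecting any
#' proposal closer than \code{h} to a previously accepted point. The
#' result has minimum pairwise distance >= \code{h}. If the packing is
#' infeasible (most proposals rejected) a warning is issued and the
#' achievable pattern returned.
#'
#' @param lambda Proposal intensity per square meter.
#' @param h Hard-core distance in meters (0 gives a plain Poisson pattern).
#' @param window A \code{plot_geometry}.
#' @return A \code{point_pattern}.
#' @export
sample_hardcore <- function(lambda, h, window) {
  stopifnot(lambda >= 0, h >= 0)
  W <- window$width_m; H <- window$height_m
  n <- stats::rpois(1, lambda * W * H)
  x <- stats::runif(n, 0, W); y <- stats::runif(n, 0, H)
  if (h > 0 && n > 1) {
    keep <- logical(n)
    ax <- numeric(0); ay <- numeric(0)
    for (i in seq_len(n)) {
      if (!length(ax) || min((ax - x[i])^2 + (ay - y[i])^2) >= h^2) {
        keep[i] <- TRUE
        ax <- c(ax, x[i]); ay <- c(ay, y[i])
      }
    }
    if (sum(keep) < 0.5 * n)
      warning("hard-core packing infeasible at this intensity; ",
              "returning achievable pattern")
    x <- x[keep]; y <- y[keep]
  }
  point_pattern(x, y, window)
}

#' Thin small trees near large trees
#'
#' Each small point lying within \code{rho} of any large point is removed
#' independently with probability \code{p}, inducing bivariate repulsion
#' between the two classes at distances below \code{rho}.
#'
#' @param small,large \code{point_pattern}s in the same window.
#' @param rho Segregation radius in meters.
#' @param p Removal probability in [0, 1].
#' @return The thinned small-tree \code{point_pattern}.
#' @export
apply_segregation <- function(small, large, rho, p) {
  stopifnot(p >= 0, p <= 1, rho >= 0)
  if (p == 0 || small$n == 0 || large$n == 0) return(small)
  near <- logical(small$n)
  chunk <- 5000L
  for (s in seq(1, small$n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, small$n)
    d2 <- outer(small$x[idx], large$x, "-")^2 +
          outer(small$y[idx], large$y, "-")^2
    near[idx] <- apply(d2, 1, min) < rho^2
  }
  drop <- near & stats::runif(small$n) < p
  point_pattern(small$x[!drop], small$y[!drop], small$window)
}

#' Sample stem diameters
#'
#' Two diameter models, both truncated below at 1 cm (the census
#' threshold):
#' \describe{
#'   \item{negative_exponential}{1 + Exp(\code{rate}) in cm.}
#'   \item{rotated_sigmoid}{a mixture of the truncated exponential and a
#'     Gaussian "hump" (mean \code{hump_mean}, sd \code{hump_sd}, mixture
#'     weight \code{weight_hump}) truncated at 1 cm, renormalized by
#'     rejection. A stand-in parametric form for mid-diameter plateau
#'     distributions; no canonical parametric family exists.}
#' }
#'
#' @param n Number of draws (>= 0).
#' @param model List with \code{type} and the parameters above.
#' @return Numeric vector of n diameters, all >= 1.
#' @export
sample_dbh <- function(n, model) {
  if (n == 0) return(numeric(0))
  type <- model$type
  if (type == "negative_exponential") {
    if (is.null(model$rate) || model$rate <= 0)
      stop("parameter error: rate must be positive")
    return(1 + stats::rexp(n, model$rate))
  }
  if (type == "rotated_sigmoid") {
    if (model$rate <= 0 || model$hump_sd <= 0)
      stop("parameter error: invalid rotated-sigmoid parameters")
    hump <- stats::runif(n) < model$weight_hump
    out <- numeric(n)
    out[!hump] <- 1 + stats::rexp(sum(!hump), model$rate)
    k <- sum(hump)
    if (k) {
      draws <- numeric(0)
      while (length(draws) < k) {
        cand <- stats::rnorm(2 * k, model$hump_mean, model$hump_sd)
        draws <- c(draws, cand[cand >= 1])
      }
      out[hump] <- draws[seq_len(k)]
    }
    return(out)
  }
  stop("unknown dbh model type: ", type)
}

# Intersections of straight debris segments with a transect line segment.
# segments: data.frame with x0, y0, x1, y1 (m). Returns indices of
# intersecting segments. Exact 2-D segment-segment test (no discretization).
.segment_hits <- function(segments, tx0, ty0, tx1, ty1) {
  if (!nrow(segments)) return(integer(0))
  rx <- tx1 - tx0; ry <- ty1 - ty0
  sx <- segments$x1 - segments$x0; sy <- segments$y1 - segments$y0
  qpx <- segments$x0 - tx0; qpy <- segments$y0 - ty0
  denom <- rx * sy - ry * sx
  ok <- abs(denom) > 1e-12
  t <- (qpx * sy - qpy * sx) / denom
  u <- (qpx * ry - qpy * rx) / denom
  which(ok & t >= 0 & t <= 1 & u >= 0 & u <= 1)
}

#' Intersect a transect with a debris segment field
#'
#' Exact segment-segment geometry: a piece is recorded if the transect
#' line crosses it, and the intercept diameter equals the piece diameter
#' (pieces are straight with constant diameter, so the perpendicular
#' intercept is the piece diameter). With \code{toroidal = TRUE} the field
#' is treated as periodic on the window (the segment set is tiled), which
#' removes edge effects in design-unbiasedness simulations.
#'
#' @param segments \code{data.frame} with \code{x0}, \code{y0}, \code{x1},
#'   \code{y1}, \code{diameter_cm}, \code{decay_class}, \code{species}.
#' @param origin Transect origin \code{c(x, y)} in meters.
#' @param azimuth_deg Compass azimuth (clockwise from north).
#' @param length_m Transect length.
#' @param window A \code{plot_geometry} (needed for toroidal tiling).
#' @param toroidal Tile the field periodically (default \code{FALSE}).
#' @return The intersected rows of \code{segments}.
#' @export
transect_crossings <- function(segments, origin, azimuth_deg, length_m,
                               window = NULL, toroidal = FALSE) {
  a <- azimuth_deg * pi / 180
  tx1 <- origin[1] + length_m * sin(a)
  ty1 <- origin[2] + length_m * cos(a)
  field <- segments
  if (toroidal) {
    if (is.null(window)) stop("toroidal tiling needs the window")
    shifts <- expand.grid(sx = c(-1, 0, 1) * window$width_m,
                          sy = c(-1, 0, 1) * window$height_m)
    field <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
      s <- segments
      s$x0 <- s$x0 + shifts$sx[k]; s$x1 <- s$x1 + shifts$sx[k]
      s$y0 <- s$y0 + shifts$sy[k]; s$y1 <- s$y1 + shifts$sy[k]
      s
    }))
  }
  hit <- .segment_hits(field, origin[1], origin[2], tx1, ty1)
  field[hit, c("diameter_cm", "decay_class", "species"), drop = FALSE]
}

#' Simulate a coarse woody debris segment field
#'
#' Pieces are straight segments with uniformly random orientation, uniform
#' length in \code{[len_min, len_max]}, and lognormal diameters truncated
#' below at \code{min_diam_cm}. Segment midpoints are Poisson on the
#' window.
#'
#' @param debris Debris parameter list (see \code{\link{stand_config}}).
#' @param window A \code{plot_geometry}.
#' @return \code{data.frame} of segments with endpoints, diameter, decay
#'   class and species.
#' @export
sample_debris_field <- function(debris, window) {
  W <- window$width_m; H <- window$height_m
  n <- stats::rpois(1, debris$intensity * W * H)
  if (n == 0)
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), diameter_cm = numeric(0),
                      decay_class = integer(0), species = character(0),
                      stringsAsFactors = FALSE))
  cx <- stats::runif(n, 0, W); cy <- stats::runif(n, 0, H)
  len <- stats::runif(n, debris$len_min, debris$len_max)
  th <- stats::runif(n, 0, pi)
  d <- numeric(0)
  while (length(d) < n) {
    cand <- stats::rlnorm(2 * n, debris$diam_meanlog, debris$diam_sdlog)
    d <- c(d, cand[cand >= debris$min_diam_cm])
  }
  d <- d[seq_len(n)]
  data.frame(
    x0 = cx - len / 2 * cos(th), y0 = cy - len / 2 * sin(th),
    x1 = cx + len / 2 * cos(th), y1 = cy + len / 2 * sin(th),
    diameter_cm = d,
    decay_class = sample(1:5, n, replace = TRUE,
                         prob = c(0.10, 0.20, 0.30, 0.25, 0.15)),
    species = sample(c("ABCO", "PILA", "UNKN"), n, replace = TRUE,
                     prob = c(0.45, 0.35, 0.20)),
    stringsAsFactors = FALSE)
}

# Boolean disc shrub model with non-overlapping discs, added sequentially
# until the summed patch area reaches the cover target. Discs are stored
# as 24-gon polygons; patch area is the exact polygon area.
.sample_shrubs <- function(shrub, window) {
  W <- window$width_m; H <- window$height_m
  target <- shrub$cover_target * W * H
  if (target == 0)
    return(NULL)
  ngon <- 24L
  th <- 2 * pi * (seq_len(ngon) - 1) / ngon
  centers <- list(); radii <- numeric(0)
  cover <- 0; tries <- 0L
  while (cover < target) {
    tries <- tries + 1L
    if (tries > 200000L) stop("infeasible shrub cover target")
    r <- stats::runif(1, shrub$r_min, shrub$r_max)
    cx <- stats::runif(1, r, W - r); cy <- stats::runif(1, r, H - r)
    if (length(radii)) {
      cc <- do.call(rbind, centers)
      if (any((cc[, 1] - cx)^2 + (cc[, 2] - cy)^2 < (radii + r)^2)) next
    }
    centers[[length(centers) + 1L]] <- c(cx, cy)
    radii <- c(radii, r)
    cover <- cover + 0.5 * ngon * r^2 * sin(2 * pi / ngon)
  }
  n <- length(radii)
  sp <- sample(names(shrub$species_weights), n, replace = TRUE,
               prob = shrub$species_weights)
  avg_h <- stats::runif(n, 0.3, 1.5)
  polys <- lapply(seq_len(n), function(i) {
    c0 <- centers[[i]]
    cbind(c0[1] + radii[i] * cos(th), c0[2] + radii[i] * sin(th))
  })
  out <- data.frame(
    patch_id = sprintf("P%04d", seq_len(n)),
    species = sp,
    area_m2 = vapply(polys, polygon_area, 0),
    avg_height_m = avg_h,
    max_height_m = avg_h * stats::runif(n, 1.1, 1.6),
    stringsAsFactors = FALSE)
  out$polygon <- polys
  out
}

# Default layout of planar-intercept fuel transects: east-west lines of
# contiguous 20 m segments on evenly spaced northings (112 transects on
# the default 800 x 320 m window, mirroring four interior sampling lines).
.default_transects <- function(window, n_lines = 4, per_line = NULL,
                               length_m = 20) {
  if (is.null(per_line))
    per_line <- max(1L, min(28L, as.integer(window$width_m / length_m) - 1L))
  ys <- window$height_m * (seq_len(n_lines)) / (n_lines + 1)
  span <- per_line * length_m
  x0 <- (window$width_m - span) / 2
  rows <- expand.grid(seg = seq_len(per_line) - 1, line = seq_len(n_lines))
  data.frame(
    transect_id = sprintf("T%03d", seq_len(nrow(rows))),
    x_m = x0 + rows$seg * length_m,
    y_m = ys[rows$line],
    azimuth_deg = 90,
    length_m = length_m,
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic stand dataset
#'
#' Composes the layer samplers into one validated
#' \code{\link{stand_dataset}}: clustered small trees (Thomas process)
#' thinned near hard-core large trees, diameters from the configured
#' models, a snag layer drawn as a binomial fraction of the live stems
#' >= 10 cm (jittered positions, drawn heights, top diameters and decay
#' classes), non-overlapping Boolean-disc shrub patches hitting the cover
#' target, a coarse debris segment field with exact transect-intersection
#' geometry, and fine-fuel/litter/duff tallies per transect. Each layer
#' re-seeds its own stream (seed + layer index), so identical seeds give
#' byte-identical datasets and layers can be regenerated independently.
#'
#' @param config A \code{\link{stand_config}}.
#' @return A validated \code{stand_dataset}.
#' @export
generate_stand <- function(config) {
  geom <- config$geometry
  seed <- config$rng_seed

  set.seed(seed + 1L)  # layer 1: small-tree pattern
  small <- sample_thomas(config$small$kappa, config$small$mu,
                         config$small$sigma, geom)

  set.seed(seed + 2L)  # layer 2: large-tree pattern
  large <- sample_hardcore(config$large$lambda, config$large$hard_core_m,
                           geom)
  set.seed(seed + 2L + 500L)
  small <- apply_segregation(small, large, config$segregation$rho_m,
                             config$segregation$p)

  set.seed(seed + 3L)  # layer 3: diameters and species
  dbh_s <- sample_dbh(small$n, config$dbh_small)
  dbh_s <- pmin(dbh_s, 99.99)  # small class stays below the 100 cm threshold
  dbh_l <- 100 + stats::rexp(large$n, 1 / config$dbh_large$mean_excess_cm)
  dbh_l <- pmin(dbh_l, config$dbh_large$max_cm)
  n_all <- small$n + large$n
  sp_small <- sample(names(config$species_weights), small$n, replace = TRUE,
                     prob = config$species_weights)
  # large-diameter stems are drawn from the species that actually reach
  # those sizes in mixed-conifer stands
  big_pool <- intersect(c("ABCO", "PILA", "CADE"),
                        names(config$species_weights))
  if (!length(big_pool)) big_pool <- names(config$species_weights)
  sp_large <- sample(big_pool, large$n, replace = TRUE,
                     prob = config$species_weights[big_pool])
  sp <- c(sp_small, sp_large)
  stems <- data.frame(
    tag = sprintf("S%06d", seq_len(n_all)),
    species = sp,
    dbh_cm = c(dbh_s, dbh_l),
    x_m = c(small$x, large$x),
    y_m = c(small$y, large$y),
    status = "live",
    stringsAsFactors = FALSE)

  set.seed(seed + 4L)  # layer 4: snags
  live10 <- which(stems$dbh_cm >= 10)
  n_snag <- stats::rbinom(1, length(live10), config$snag_fraction)
  snags <- NULL
  if (n_snag > 0) {
    src <- sample(live10, n_snag)
    sx <- pmin(pmax(stems$x_m[src] + stats::rnorm(n_snag, 0, 2), 0),
               geom$width_m)
    sy <- pmin(pmax(stems$y_m[src] + stats::rnorm(n_snag, 0, 2), 0),
               geom$height_m)
    dbh <- stems$dbh_cm[src]
    snags <- data.frame(
      tag = sprintf("D%05d", seq_len(n_snag)),
      species = ifelse(stats::runif(n_snag) < 0.05, "UNKN",
                       stems$species[src]),
      dbh_cm = dbh,
      height_m = 1.8 + stats::rexp(n_snag, 1 / 8),
      top_diameter_cm = dbh * stats::runif(n_snag, 0.2, 0.9),
      decay_class = sample(1:5, n_snag, replace = TRUE,
                           prob = c(0.15, 0.25, 0.30, 0.20, 0.10)),
      x_m = sx, y_m = sy,
      stringsAsFactors = FALSE)
  }

  set.seed(seed + 5L)  # layer 5: shrubs
  shrub_patches <- .sample_shrubs(config$shrub, geom)
  demography <- data.frame(
    species = names(config$shrub$species_weights),
    plot_area_m2 = 4,
    stems_per_m2 = round(stats::rexp(
      length(config$shrub$species_weights), 1 / 3), 3),
    biomass_kg_per_m2 = round(stats::rexp(
      length(config$shrub$species_weights), 1 / 4), 3),
    stringsAsFactors = FALSE)

  set.seed(seed + 6L)  # layer 6: debris field
  segments <- sample_debris_field(config$debris, geom)

  set.seed(seed + 7L)  # layer 7: transect tallies
  tr <- .default_transects(geom)
  fl <- config$fuels
  gam <- function(n, mean, sd) {
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  }
  nt <- nrow(tr)
  tr$count_1h <- stats::rpois(nt, fl$mu_1h)
  tr$count_10h <- stats::rpois(nt, fl$mu_10h)
  tr$count_100h <- stats::rpois(nt, fl$mu_100h)
  tr$len_1h_m <- 2; tr$len_10h_m <- 2; tr$len_100h_m <- 4
  tr$litter_cm <- round(gam(nt, fl$litter_mean_cm, fl$litter_sd_cm), 3)
  tr$duff_cm <- round(gam(nt, fl$duff_mean_cm, fl$duff_sd_cm), 3)

  ic_list <- lapply(seq_len(nt), function(i) {
    hits <- transect_crossings(segments, c(tr$x_m[i], tr$y_m[i]),
                               tr$azimuth_deg[i], tr$length_m[i])
    if (!nrow(hits)) return(NULL)
    cbind(data.frame(transect_id = tr$transect_id[i],
                     stringsAsFactors = FALSE), hits)
  })
  ic_list <- ic_list[!vapply(ic_list, is.null, TRUE)]
  intercepts <- if (length(ic_list)) do.call(rbind, ic_list) else NULL
  if (!is.null(intercepts)) {
    intercepts$diameter_cm <- round(intercepts$diameter_cm, 2)
    rownames(intercepts) <- NULL
  }

  stand_dataset(geom, stems = stems, snags = snags,
                shrub_patches = shrub_patches, demography = demography,
                transects = tr[, .stand_columns$transects],
                intercepts = intercepts)
}
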