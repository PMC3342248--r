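#' Plot geometry for a rectangular forest dynamics plot
#'
#' Defines the rectangular study window. Coordinates are in meters with the
#' origin at the southwest corner, x increasing eastward and y northward.
#' Both dimensions must be integer multiples of the quadrat edge length so
#' the plot tiles exactly into square quadrats.
#'
#' @param width_m East-west extent in meters.
#' @param height_m North-south extent in meters.
#' @param quadrat_m Quadrat edge length in meters (default 20).
#' @return An object of class \code{plot_geometry} with fields
#'   \code{width_m}, \code{height_m}, \code{quadrat_m} and the derived
#'   \code{area_ha}.
#' @examples
#' geom <- plot_geometry(800, 320)
#' geom$area_ha  # 25.6
#' @export
plot_geometry <- function(width_m, height_m, quadrat_m = 20) {
  stopifnot(is.numeric(width_m), is.numeric(height_m), is.numeric(quadrat_m))
  if (width_m <= 0 || height_m <= 0)
    stop("plot dimensions must be positive")
  if (quadrat_m <= 0)
    stop("quadrat edge length must be positive")
  if (abs(width_m / quadrat_m - round(width_m / quadrat_m)) > 1e-9 ||
      abs(height_m / quadrat_m - round(height_m / quadrat_m)) > 1e-9)
    stop("plot dimensions must be integer multiples of the quadrat edge")
  structure(
    list(width_m = width_m, height_m = height_m, quadrat_m = quadrat_m,
         area_ha = width_m * height_m / 1e4),
    class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf("Plot window: %g m x %g m (%.2f ha), %g m quadrats\n",
              x$width_m, x$height_m, x$area_ha, x$quadrat_m))
  invisible(x)
}

# Column dictionaries for the delimited census layers. Readers validate
# against these; writers emit them in this order.
.stand_columns <- list(
  stems      = c("tag", "species", "dbh_cm", "x_m", "y_m", "status"),
  snags      = c("tag", "species", "dbh_cm", "height_m", "top_diameter_cm",
                 "decay_class", "x_m", "y_m"),
  demography = c("species", "plot_area_m2", "stems_per_m2",
                 "biomass_kg_per_m2"),
  transects  = c("transect_id", "x_m", "y_m", "azimuth_deg", "length_m",
                 "count_1h", "count_10h", "count_100h",
                 "len_1h_m", "len_10h_m", "len_100h_m",
                 "litter_cm", "duff_cm"),
  intercepts = c("transect_id", "diameter_cm", "decay_class", "species")
)

#' Assemble a stand dataset from its census layers
#'
#' Bundles all census layers of one plot and validates them jointly. Each
#' layer is a \code{data.frame} with the documented columns; missing layers
#' default to empty tables.
#'
#' @param geometry A \code{\link{plot_geometry}}.
#' @param stems Live/dead stem records: \code{tag}, \code{species},
#'   \code{dbh_cm}, \code{x_m}, \code{y_m}, \code{status} (\code{"live"} or
#'   \code{"dead"}).
#' @param snags Standing-dead records: \code{tag}, \code{species},
#'   \code{dbh_cm}, \code{height_m}, \code{top_diameter_cm},
#'   \code{decay_class} (1-5), \code{x_m}, \code{y_m}.
#' @param shrub_patches Mapped shrub polygons: \code{patch_id},
#'   \code{species}, \code{area_m2}, \code{avg_height_m}, \code{max_height_m}
#'   plus a \code{polygon} list-column of two-column vertex matrices.
#' @param demography Shrub demography subplot densities per species.
#' @param transects Fuel transects (20 m planar-intercept lines).
#' @param intercepts Coarse woody debris intercepts keyed by
#'   \code{transect_id}.
#' @param validate Run \code{\link{validate_stand}} (default \code{TRUE}).
#' @return An object of class \code{stand_dataset}.
#' @export
stand_dataset <- function(geometry, stems = NULL, snags = NULL,
                          shrub_patches = NULL, demography = NULL,
                          transects = NULL, intercepts = NULL,
                          validate = TRUE) {
  if (!inherits(geometry, "plot_geometry"))
    stop("geometry must be a plot_geometry object")
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    df
  }
  x <- structure(list(
    geometry = geometry,
    stems = if (is.null(stems)) empty(.stand_columns$stems) else stems,
    snags = if (is.null(snags)) empty(.stand_columns$snags) else snags,
    shrub_patches = shrub_patches,
    demography = if (is.null(demography)) empty(.stand_columns$demography)
                 else demography,
    transects = if (is.null(transects)) empty(.stand_columns$transects)
                else transects,
    intercepts = if (is.null(intercepts)) empty(.stand_columns$intercepts)
                 else intercepts
  ), class = "stand_dataset")
  if (validate) validate_stand(x)
  x
}

#' @export
print.stand_dataset <- function(x, ...) {
  cat("Stand dataset\n")
  print(x$geometry)
  cat(sprintf("  %d stems, %d snags, %d shrub patches, %d demography plots,\n",
              nrow(x$stems), nrow(x$snags),
              if (is.null(x$shrub_patches)) 0L else nrow(x$shrub_patches),
              nrow(x$demography)))
  cat(sprintf("  %d fuel transects with %d coarse intercepts\n",
              nrow(x$transects), nrow(x$intercepts)))
  invisible(x)
}

#' Validate a stand dataset
#'
#' Checks layer schemas and record-level invariants: live stems have
#' dbh >= 1 cm, snags have dbh >= 10 cm, height >= 1.8 m, decay class 1-5
#' and top diameter not exceeding dbh, all coordinates fall inside the plot
#' window, tags are unique within a layer, and coarse intercepts have
#' diameter >= 10 cm. Errors name the offending tags.
#'
#' @param stand A \code{stand_dataset}.
#' @return The dataset, invisibly, if valid; otherwise an error.
#' @export
validate_stand <- function(stand) {
  geom <- stand$geometry
  check_cols <- function(df, layer) {
    need <- .stand_columns[[layer]]
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("schema error in %s: missing column(s) %s",
                   layer, paste(miss, collapse = ", ")))
  }
  in_window <- function(x, y)
    x >= 0 & x <= geom$width_m & y >= 0 & y <= geom$height_m

  st <- stand$stems
  check_cols(st, "stems")
  if (nrow(st)) {
    if (anyDuplicated(st$tag))
      stop("validation error: duplicated stem tag(s): ",
           paste(unique(st$tag[duplicated(st$tag)]), collapse = ", "))
    bad <- !in_window(st$x_m, st$y_m)
    if (any(bad))
      stop("validation error: stem coordinates outside plot window for tag(s): ",
           paste(st$tag[bad], collapse = ", "))
    small <- st$status == "live" & st$dbh_cm < 1
    if (any(small))
      stop("validation error: live stem dbh < 1 cm for tag(s): ",
           paste(st$tag[small], collapse = ", "))
  }

  sn <- stand$snags
  check_cols(sn, "snags")
  if (nrow(sn)) {
    if (anyDuplicated(sn$tag))
      stop("validation error: duplicated snag tag(s)")
    bad <- !in_window(sn$x_m, sn$y_m)
    if (any(bad))
      stop("validation error: snag coordinates outside plot window for tag(s): ",
           paste(sn$tag[bad], collapse = ", "))
    if (any(sn$dbh_cm < 10))
      stop("validation error: snag dbh < 10 cm for tag(s): ",
           paste(sn$tag[sn$dbh_cm < 10], collapse = ", "))
    if (any(sn$height_m < 1.8))
      stop("validation error: snag height < 1.8 m for tag(s): ",
           paste(sn$tag[sn$height_m < 1.8], collapse = ", "))
    if (any(sn$decay_class < 1 | sn$decay_class > 5))
      stop("validation error: snag decay class outside 1-5")
    if (any(sn$top_diameter_cm > sn$dbh_cm + 1e-9))
      stop("validation error: snag top diameter exceeds dbh for tag(s): ",
           paste(sn$tag[sn$top_diameter_cm > sn$dbh_cm + 1e-9],
                 collapse = ", "))
  }

  sp <- stand$shrub_patches
  if (!is.null(sp) && nrow(sp)) {
    if (any(sp$area_m2 < 2))
      stop("validation error: shrub patch area < 2 m2 for patch(es): ",
           paste(sp$patch_id[sp$area_m2 < 2], collapse = ", "))
    if (!is.null(sp$polygon)) {
      for (i in seq_len(nrow(sp))) {
        a <- polygon_area(sp$polygon[[i]])
        if (abs(a - sp$area_m2[i]) > 0.01 * sp$area_m2[i])
          stop(sprintf(
            "validation error: patch %s stored area %.3f disagrees with polygon area %.3f",
            sp$patch_id[i], sp$area_m2[i], a))
      }
    }
  }

  dm <- stand$demography
  check_cols(dm, "demography")
  if (nrow(dm) && (any(dm$stems_per_m2 < 0) || any(dm$biomass_kg_per_m2 < 0)))
    stop("validation error: negative shrub demography densities")

  tr <- stand$transects
  check_cols(tr, "transects")
  if (nrow(tr)) {
    counts <- as.matrix(tr[, c("count_1h", "count_10h", "count_100h")])
    if (any(counts < 0)) stop("validation error: negative fuel tallies")
    if (any(tr$litter_cm < 0) || any(tr$duff_cm < 0))
      stop("validation error: negative litter/duff depth")
    lens <- as.matrix(tr[, c("len_1h_m", "len_10h_m", "len_100h_m")])
    if (any(lens > tr$length_m + 1e-9))
      stop("validation error: sampled sub-length exceeds transect length")
  }

  ic <- stand$intercepts
  check_cols(ic, "intercepts")
  if (nrow(ic)) {
    if (any(ic$diameter_cm < 10))
      stop("validation error: coarse intercept diameter < 10 cm")
    if (nrow(tr) && !all(ic$transect_id %in% tr$transect_id))
      stop("validation error: intercept references unknown transect id")
  }
  invisible(stand)
}

#' Shoelace area of a simple polygon
#'
#' @param verts Two-column matrix of vertices (meters); the ring is closed
#'   implicitly.
#' @return Absolute enclosed area in square meters.
#' @export
polygon_area <- function(verts) {
  verts <- as.matrix(verts)
  x <- verts[, 1]; y <- verts[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Write a stand dataset to a directory of delimited files
#'
#' Emits \code{geometry.csv}, \code{stems.csv}, \code{snags.csv},
#' \code{demography.csv}, \code{transects.csv}, \code{intercepts.csv} and
#' \code{shrub_patches.geojson} (polygons in plot coordinates). Output is
#' bit-stable given a fixed record order: numbers are formatted with
#' \code{format(..., digits = 15)} and UTF-8 '.'-decimal conventions.
#'
#' @param stand A validated \code{stand_dataset}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_stand <- function(stand, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, cols, file) {
    df <- df[, cols, drop = FALSE]
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  geom <- stand$geometry
  wr(data.frame(width_m = geom$width_m, height_m = geom$height_m,
                quadrat_m = geom$quadrat_m),
     c("width_m", "height_m", "quadrat_m"), "geometry.csv")
  wr(stand$stems, .stand_columns$stems, "stems.csv")
  wr(stand$snags, .stand_columns$snags, "snags.csv")
  wr(stand$demography, .stand_columns$demography, "demography.csv")
  wr(stand$transects, .stand_columns$transects, "transects.csv")
  wr(stand$intercepts, .stand_columns$intercepts, "intercepts.csv")

  sp <- stand$shrub_patches
  features <- list()
  if (!is.null(sp) && nrow(sp)) {
    features <- lapply(seq_len(nrow(sp)), function(i) {
      ring <- as.matrix(sp$polygon[[i]])
      ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
      list(
        type = "Feature",
        properties = list(
          patch_id = sp$patch_id[i], species = sp$species[i],
          area_m2 = sp$area_m2[i],
          avg_height_m = sp$avg_height_m[i],
          max_height_m = sp$max_height_m[i]),
        geometry = list(type = "Polygon",
                        coordinates = list(unname(ring))))
    })
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, file.path(dir, "shrub_patches.geojson"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a stand dataset from a directory written by \code{write_stand}
#'
#' Validates headers against the documented column dictionaries and runs
#' full record validation; malformed rows are reported with their source
#' line numbers.
#'
#' @param dir Directory containing the layer files.
#' @return A validated \code{stand_dataset}.
#' @export
read_stand <- function(dir) {
  path <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing layer file: ", p)
    p
  }
  rd <- function(file, layer, classes) {
    df <- utils::read.csv(path(file), stringsAsFactors = FALSE,
                          colClasses = NA)
    need <- .stand_columns[[layer]]
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("schema error in %s: missing column(s) %s",
                   file, paste(miss, collapse = ", ")))
    num <- intersect(names(classes)[classes == "numeric"], names(df))
    for (cn in num) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
      if (length(bad))
        stop(sprintf("malformed %s in %s at data line(s) %s",
                     cn, file, paste(bad + 1L, collapse = ", ")))
      df[[cn]] <- v
    }
    df[, need, drop = FALSE]
  }
  g <- utils::read.csv(path("geometry.csv"))
  geometry <- plot_geometry(g$width_m[1], g$height_m[1], g$quadrat_m[1])

  numcols <- function(...) {
    v <- c(...)
    setNames(rep("numeric", length(v)), v)
  }
  stems <- rd("stems.csv", "stems", numcols("dbh_cm", "x_m", "y_m"))
  snags <- rd("snags.csv", "snags",
              numcols("dbh_cm", "height_m", "top_diameter_cm",
                      "decay_class", "x_m", "y_m"))
  demography <- rd("demography.csv", "demography",
                   numcols("plot_area_m2", "stems_per_m2",
                           "biomass_kg_per_m2"))
  transects <- rd("transects.csv", "transects",
                  numcols("x_m", "y_m", "azimuth_deg", "length_m",
                          "count_1h", "count_10h", "count_100h",
                          "len_1h_m", "len_10h_m", "len_100h_m",
                          "litter_cm", "duff_cm"))
  intercepts <- rd("intercepts.csv", "intercepts",
                   numcols("diameter_cm", "decay_class"))

  gj <- jsonlite::read_json(path("shrub_patches.geojson"))
  shrub_patches <- NULL
  if (length(gj$features)) {
    rows <- lapply(gj$features, function(f) {
      ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                    function(v) unlist(v)))
      ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
      p <- f$properties
      list(patch_id = p$patch_id, species = p$species,
           area_m2 = p$area_m2,
           avg_height_m = p$avg_height_m, max_height_m = p$max_height_m,
           polygon = ring)
    })
    shrub_patches <- data.frame(
      patch_id = vapply(rows, `[[`, "", "patch_id"),
      species = vapply(rows, `[[`, "", "species"),
      area_m2 = vapply(rows, `[[`, 0, "area_m2"),
      avg_height_m = vapply(rows, `[[`, 0, "avg_height_m"),
      max_height_m = vapply(rows, `[[`, 0, "max_height_m"),
      stringsAsFactors = FALSE)
    shrub_patches$polygon <- lapply(rows, `[[`, "polygon")
  }
  stand_dataset(geometry, stems = stems, snags = snags,
                shrub_patches = shrub_patches, demography = demography,
                transects = transects, intercepts = intercepts)
}

#' Partition stems into large- and small-diameter classes
#'
#' The large-diameter threshold follows the convention for old-growth
#' conifer forests of the Pacific Slope: stems with dbh at or above the
#' threshold (default 100 cm) are "large". The partition is exhaustive and
#' disjoint; the boundary value is large.
#'
#' @param stems Stem record \code{data.frame} with a \code{dbh_cm} column.
#' @param threshold_cm Diameter threshold in cm (default 100).
#' @return List with elements \code{large} and \code{small}, each a subset
#'   of \code{stems}.
#' @export
classify_diameter <- function(stems, threshold_cm = 100) {
  if (!is.numeric(threshold_cm) || threshold_cm < 0)
    stop("parameter error: threshold must be non-negative")
  if (any(is.na(stems$dbh_cm)))
    stop("dbh must be present on all records")
  big <- stems$dbh_cm >= threshold_cm
  list(large = stems[big, , drop = FALSE],
       small = stems[!big, , drop = FALSE])
}

#' Basal area of stems
#'
#' Cross-sectional area at breast height, \eqn{\pi (dbh/200)^2} square
#' meters per stem with dbh in cm.
#'
#' @param dbh_cm Diameters in cm.
#' @return Basal areas in square meters.
#' @export
basal_area_m2 <- function(dbh_cm) pi * (dbh_cm / 200)^2

#' Summarize stems by quadrat
#'
#' Assigns every stem to exactly one square quadrat using half-open
#' intervals [k*q, (k+1)*q); a stem exactly on the far plot boundary is
#' mapped into the last quadrat rather than rejected. Returns one row per
#' quadrat (including empty ones) with stem count, basal area and, if
#' supplied, summed biomass.
#'
#' @param stand A \code{stand_dataset}.
#' @param biomass_kg Optional per-stem biomass vector aligned with
#'   \code{stand$stems}.
#' @return \code{data.frame} with \code{qx}, \code{qy} (zero-based quadrat
#'   indices), \code{x0}, \code{y0}, \code{n_stems}, \code{basal_area_m2}
#'   and optionally \code{biomass_kg}.
#' @export
quadratize <- function(stand, biomass_kg = NULL) {
  geom <- stand$geometry
  q <- geom$quadrat_m
  nx <- as.integer(round(geom$width_m / q))
  ny <- as.integer(round(geom$height_m / q))
  st <- stand$stems
  idx <- function(v, k) pmin(as.integer(floor(v / q)), k - 1L)
  grid <- expand.grid(qx = seq_len(nx) - 1L, qy = seq_len(ny) - 1L)
  out <- data.frame(qx = grid$qx, qy = grid$qy,
                    x0 = grid$qx * q, y0 = grid$qy * q,
                    n_stems = 0L, basal_area_m2 = 0)
  if (!is.null(biomass_kg)) out$biomass_kg <- 0
  if (nrow(st)) {
    qx <- idx(st$x_m, nx); qy <- idx(st$y_m, ny)
    cell <- qy * nx + qx + 1L
    cnt <- tabulate(cell, nbins = nx * ny)
    ba <- vapply(split(basal_area_m2(st$dbh_cm), factor(cell, 1:(nx * ny))),
                 sum, 0)
    out$n_stems <- cnt
    out$basal_area_m2 <- unname(ba)
    if (!is.null(biomass_kg)) {
      bm <- vapply(split(biomass_kg, factor(cell, 1:(nx * ny))), sum, 0)
      out$biomass_kg <- unname(bm)
    }
  }
  out
}
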