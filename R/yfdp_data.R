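#' Published plot-level summaries of the Yosemite Forest Dynamics Plot
#'
#' Loads the plot-level summary tables of the 25.6 ha Yosemite Forest
#' Dynamics Plot census (800 x 320 m, old-growth Sierra Nevada
#' mixed-conifer): per-species stem counts at the 1, 10 and 100 cm dbh
#' thresholds for live trees and snags, shrub patch cover with
#' demography-subplot densities, and the plot biomass pool totals. These
#' are the published summary values; the underlying stem map is not
#' distributed, which is why the package ships a synthetic stand
#' generator for everything that needs mapped coordinates.
#'
#' @return List of \code{data.frame}s: \code{trees}, \code{snags},
#'   \code{shrub_cover}, \code{shrub_demography}, \code{biomass_pools},
#'   plus \code{geometry} (the plot window).
#' @examples
#' y <- yfdp_tables()
#' # live stem density, stems/ha
#' tot <- y$trees[y$trees$species == "TOTAL", ]
#' round(tot$n_ge1 / y$geometry$area_ha, 1)
#' @export
yfdp_tables <- function() {
  dir <- system.file("extdata", "yfdp", package = "standforge")
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  list(trees = rd("trees.csv"),
       snags = rd("snags.csv"),
       shrub_cover = rd("shrub_cover.csv"),
       shrub_demography = rd("shrub_demography.csv"),
       biomass_pools = rd("biomass_pools.csv"),
       geometry = plot_geometry(800, 320))
}
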