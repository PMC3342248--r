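# Shared fixtures: everything is built in code at test time.

demo_registry <- function() {
  load_registry(system.file("extdata", "registry", package = "standforge"))
}

# A small, fast synthetic stand configuration for unit tests.
small_config <- function(seed = 7L, width = 200, height = 200) {
  stand_config(geometry = plot_geometry(width, height, 20), rng_seed = seed)
}

# A hand-built four-stem dataset with known contents.
tiny_stand <- function() {
  geom <- plot_geometry(100, 80, 20)
  stems <- data.frame(
    tag = c("a1", "a2", "a3", "a4"),
    species = c("ABCO", "ABCO", "PILA", "CADE"),
    dbh_cm = c(12, 55, 130, 3),
    x_m = c(5, 50, 70, 99),
    y_m = c(5, 40, 20, 79),
    status = "live",
    stringsAsFactors = FALSE)
  stand_dataset(geom, stems = stems)
}

# Uniform wood-density table (all groups/classes the same), for hand
# calculations where the density must be a known constant.
flat_densities <- function(rho = 400) {
  expand.grid(species_group = c("unknown"), decay_class = 1:5,
              density_kg_m3 = rho, stringsAsFactors = FALSE)
}

# Independent union-of-arcs oracle for the isotropic edge weight: for each
# near edge the circle portion beyond it is an angular interval centered on
# the outward normal with half-width acos(e/d); the weight is one minus the
# measure of the union of those intervals over 2*pi. Interval union is
# computed by endpoint sorting, an algorithm independent of the
# inclusion-exclusion closed form in the package.
arc_union_weight <- function(x, y, d, window) {
  W <- window$width_m; H <- window$height_m
  ivals <- list()
  add <- function(center, e) {
    if (e < d) {
      a <- acos(min(max(e / d, -1), 1))
      ivals[[length(ivals) + 1]] <<- c(center - a, center + a)
    }
  }
  add(pi, x); add(0, W - x); add(3 * pi / 2, y); add(pi / 2, H - y)
  if (!length(ivals)) return(1)
  m <- do.call(rbind, ivals) %% (2 * pi)
  segs <- list()
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] <= m[i, 2]) segs[[length(segs) + 1]] <- m[i, ]
    else {  # wraps through 0
      segs[[length(segs) + 1]] <- c(0, m[i, 2])
      segs[[length(segs) + 1]] <- c(m[i, 1], 2 * pi)
    }
  }
  s <- do.call(rbind, segs)
  s <- s[order(s[, 1]), , drop = FALSE]
  total <- 0; cur <- s[1, ]
  for (i in seq_len(nrow(s))[-1]) {
    if (s[i, 1] <= cur[2]) cur[2] <- max(cur[2], s[i, 2])
    else { total <- total + cur[2] - cur[1]; cur <- s[i, ] }
  }
  total <- total + cur[2] - cur[1]
  1 - total / (2 * pi)
}
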