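#' Marked point pattern in a rectangular window
#'
#' @param x,y Point coordinates in meters.
#' @param window A \code{\link{plot_geometry}} (the rectangle
#'   [0, width] x [0, height]).
#' @param mark Optional label per point (e.g. "large"/"small").
#' @return Object of class \code{point_pattern}.
#' @export
point_pattern <- function(x, y, window, mark = NULL) {
  if (!inherits(window, "plot_geometry"))
    stop("window must be a plot_geometry")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) && (any(x < 0 | x > window$width_m) ||
                    any(y < 0 | y > window$height_m)))
    stop("points outside window")
  if (!is.null(mark) && length(mark) != length(x))
    stop("mark length must match point count")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 window = window, mark = mark, n = length(x)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in %g x %g m window\n",
              x$n, x$window$width_m, x$window$height_m))
  invisible(x)
}

#' Subset a point pattern by mark
#' @param pattern A \code{point_pattern} with marks.
#' @param value Mark value to keep.
#' @return The sub-pattern carrying the same window.
#' @export
split_marks <- function(pattern, value) {
  keep <- pattern$mark == value
  point_pattern(pattern$x[keep], pattern$y[keep], pattern$window,
                mark = pattern$mark[keep])
}

# Ripley isotropic edge-correction weights for a rectangle.
# For reference points (x, y) and pair distances d, returns the fraction of
# the circumference of the circle of radius d centered at (x, y) that lies
# inside [0, W] x [0, H]. Closed form: the arc lost beyond each near edge
# subtends 2*acos(e/d); where the circle passes a corner the two edge arcs
# overlap by acos(p/d) + acos(q/d) - pi/2. Valid for d < min(W, H)/2 (the
# circle can never reach two opposite edges), which the default r_max of a
# quarter of the minimum dimension guarantees.
ripley_weight <- function(x, y, d, window) {
  W <- window$width_m; H <- window$height_m
  half <- function(e) {
    out <- numeric(length(d))
    hit <- e < d
    out[hit] <- acos(pmin(pmax(e[hit] / d[hit], -1), 1))
    out
  }
  aL <- half(x);      aR <- half(W - x)
  aD <- half(y);      aU <- half(H - y)
  ov <- function(a, b) pmax(0, a + b - pi / 2)
  exterior <- 2 * (aL + aR + aD + aU) -
    (ov(aL, aD) + ov(aL, aU) + ov(aR, aD) + ov(aR, aU))
  1 - exterior / (2 * pi)
}

# Numeric arc-integration oracle for ripley_weight: fraction of m points on
# the circle falling inside the rectangle. Kept exported for verification.
#' Numeric edge-correction weight by circle discretization
#'
#' Brute-force check of the closed-form isotropic correction: places
#' \code{m} points uniformly on the circle of radius \code{d} around
#' \code{(x, y)} and returns the inside fraction.
#'
#' @param x,y Circle center (scalars), meters.
#' @param d Radius, meters.
#' @param window A \code{plot_geometry}.
#' @param m Number of subdivisions (default 1e4).
#' @return Inside fraction in [0, 1].
#' @export
ripley_weight_numeric <- function(x, y, d, window, m = 1e4) {
  th <- (seq_len(m) - 0.5) / m * 2 * pi
  px <- x + d * cos(th); py <- y + d * sin(th)
  mean(px >= 0 & px <= window$width_m & py >= 0 & py <= window$height_m)
}

# Block-wise search for point pairs with distance <= rmax, avoiding a full
# n x n matrix. Returns ordered pairs (both orientations for the self
# case). idx: two-column index matrix; d: distances.
.close_pairs <- function(x1, y1, x2 = NULL, y2 = NULL, rmax) {
  self <- is.null(x2)
  if (self) { x2 <- x1; y2 <- y1 }
  n1 <- length(x1); n2 <- length(x2)
  block <- max(1L, as.integer(2e6 / max(n2, 1L)))
  idx <- list(); dd <- list(); k <- 0L
  for (s in seq(1, n1, by = block)) {
    rows <- s:min(s + block - 1L, n1)
    D <- sqrt(outer(x1[rows], x2, "-")^2 + outer(y1[rows], y2, "-")^2)
    sel <- if (self) which(D <= rmax & D > 0, arr.ind = TRUE)
           else which(D <= rmax, arr.ind = TRUE)
    if (nrow(sel)) {
      k <- k + 1L
      idx[[k]] <- cbind(rows[sel[, 1]], sel[, 2])
      dd[[k]] <- D[sel]
    }
  }
  if (!k) return(list(idx = matrix(0L, 0, 2), d = numeric(0)))
  list(idx = do.call(rbind, idx), d = unlist(dd, use.names = FALSE))
}

# Shared helper: step-function accumulation of edge-corrected pair counts
# onto an increasing r grid. d and w are aligned vectors of pair distances
# and pair weights (already 1/w_ij contributions).
.accumulate_k <- function(d, contrib, r_grid) {
  if (!length(d)) return(numeric(length(r_grid)))
  o <- order(d)
  d <- d[o]; cs <- cumsum(contrib[o])
  idx <- findInterval(r_grid, d)
  out <- numeric(length(r_grid))
  out[idx > 0] <- cs[idx[idx > 0]]
  out
}

#' Ripley's K function with isotropic edge correction
#'
#' Estimates \deqn{\hat K(r) = \frac{|A|}{n(n-1)} \sum_{i \ne j}
#' w_{ij}^{-1} \, 1(d_{ij} \le r)} where \eqn{w_{ij}} is the fraction of
#' the circle of radius \eqn{d_{ij}} centered on point \eqn{i} that lies
#' inside the rectangular window (Ripley's isotropic correction, closed
#' form for rectangles). Both orderings of each pair contribute with their
#' own weight.
#'
#' @param pattern A \code{point_pattern} with at least 2 points.
#' @param r_grid Increasing radii in meters starting at or above 0. By
#'   default the maximum radius is capped at a quarter of the minimum
#'   window dimension; larger requests warn unless \code{check_rmax} is
#'   \code{FALSE}.
#' @param check_rmax Warn when \code{max(r_grid)} exceeds the quarter-
#'   dimension default (default \code{TRUE}).
#' @return Numeric vector of \eqn{\hat K(r)} aligned with \code{r_grid}.
#' @export
k_hat_isotropic <- function(pattern, r_grid, check_rmax = TRUE) {
  n <- pattern$n
  if (n < 2) stop("estimator error: need at least 2 points")
  win <- pattern$window
  rmax_default <- min(win$width_m, win$height_m) / 4
  if (check_rmax && max(r_grid) > rmax_default + 1e-9)
    warning("r_grid extends beyond one quarter of the minimum window dimension")
  x <- pattern$x; y <- pattern$y
  pairs <- .close_pairs(x, y, rmax = max(r_grid))
  if (!length(pairs$d)) return(numeric(length(r_grid)))
  w <- ripley_weight(x[pairs$idx[, 1]], y[pairs$idx[, 1]], pairs$d, win)
  area <- win$width_m * win$height_m
  area / (n * (n - 1)) * .accumulate_k(pairs$d, 1 / w, r_grid)
}

#' Centered L function
#'
#' Variance-stabilized transform \eqn{\hat L(r) - r =
#' \sqrt{\hat K(r)/\pi} - r}. Positive values indicate clustering, negative
#' values inhibition/regularity; 0 is the expectation under complete
#' spatial randomness.
#'
#' @inheritParams k_hat_isotropic
#' @param centered Subtract r (default \code{TRUE}); set \code{FALSE} for
#'   the raw L.
#' @return Object of class \code{l_result}: a \code{data.frame} with
#'   columns \code{r} and \code{l}, plus attributes recording the
#'   estimator, point count and window.
#' @export
l_hat <- function(pattern, r_grid, centered = TRUE, check_rmax = TRUE) {
  k <- k_hat_isotropic(pattern, r_grid, check_rmax = check_rmax)
  l <- sqrt(k / pi) - if (centered) r_grid else 0
  structure(data.frame(r = r_grid, l = l),
            class = c("l_result", "data.frame"),
            edge_correction = "isotropic", n = pattern$n,
            window = pattern$window, centered = centered)
}

#' Bivariate K function with shared isotropic weighting
#'
#' \deqn{\hat K_{12}(r) = \frac{|A|}{n_1 n_2} \sum_i \sum_j c_{ij} \,
#' 1(d_{ij} \le r)} over type-1 points \eqn{i} and type-2 points \eqn{j},
#' with \eqn{c_{ij} = (w_i^{-1} + w_j^{-1})/2}, the average of the
#' isotropic inverse weights computed at each endpoint. Averaging the two
#' one-sided corrections mirrors the univariate estimator (which counts
#' both orderings of a pair) and makes the estimator exactly symmetric in
#' the two types.
#'
#' @param pattern1,pattern2 \code{point_pattern}s sharing one window.
#' @param r_grid Radii in meters.
#' @param check_rmax See \code{\link{k_hat_isotropic}}.
#' @return Numeric vector of \eqn{\hat K_{12}(r)}.
#' @export
k12_hat_isotropic <- function(pattern1, pattern2, r_grid, check_rmax = TRUE) {
  w1 <- pattern1$window; w2 <- pattern2$window
  if (w1$width_m != w2$width_m || w1$height_m != w2$height_m)
    stop("mismatched windows")
  if (pattern1$n < 1 || pattern2$n < 1)
    stop("estimator error: both patterns must be non-empty")
  rmax_default <- min(w1$width_m, w1$height_m) / 4
  if (check_rmax && max(r_grid) > rmax_default + 1e-9)
    warning("r_grid extends beyond one quarter of the minimum window dimension")
  pairs <- .close_pairs(pattern1$x, pattern1$y, pattern2$x, pattern2$y,
                        rmax = max(r_grid))
  if (!length(pairs$d)) return(numeric(length(r_grid)))
  d <- pairs$d
  wi <- ripley_weight(pattern1$x[pairs$idx[, 1]], pattern1$y[pairs$idx[, 1]],
                      d, w1)
  wj <- ripley_weight(pattern2$x[pairs$idx[, 2]], pattern2$y[pairs$idx[, 2]],
                      d, w1)
  contrib <- (1 / wi + 1 / wj) / 2
  area <- w1$width_m * w1$height_m
  area / (pattern1$n * pattern2$n) * .accumulate_k(d, contrib, r_grid)
}

#' Centered bivariate L function
#'
#' \eqn{\hat L_{12}(r) - r}; positive values indicate attraction between
#' the two types, negative values repulsion.
#'
#' @inheritParams k12_hat_isotropic
#' @param centered Subtract r (default \code{TRUE}).
#' @return An \code{l_result}.
#' @export
l12_hat <- function(pattern1, pattern2, r_grid, centered = TRUE,
                    check_rmax = TRUE) {
  k <- k12_hat_isotropic(pattern1, pattern2, r_grid, check_rmax = check_rmax)
  l <- sqrt(k / pi) - if (centered) r_grid else 0
  structure(data.frame(r = r_grid, l = l),
            class = c("l_result", "data.frame"),
            edge_correction = "isotropic",
            n = c(pattern1$n, pattern2$n),
            window = pattern1$window, centered = centered)
}

#' Simulate complete spatial randomness
#'
#' A binomial process: exactly \code{n} points placed independently and
#' uniformly on the window (the point count is conditioned on the observed
#' count, as in conditional CSR Monte Carlo tests).
#'
#' @param n Number of points.
#' @param window A \code{plot_geometry}.
#' @return A \code{point_pattern}.
#' @export
simulate_csr <- function(n, window) {
  point_pattern(stats::runif(n, 0, window$width_m),
                stats::runif(n, 0, window$height_m), window)
}

#' Toroidal shift of a point pattern
#'
#' Translates the pattern by \code{shift} with wrap-around on the window
#' treated as a torus: \eqn{(x, y) \to ((x + s_x) \bmod W, (y + s_y) \bmod
#' H)}. Preserves point count and all toroidal pairwise distances, hence
#' the internal configuration of the pattern.
#'
#' @param pattern A \code{point_pattern}.
#' @param shift Numeric length-2 vector \code{c(sx, sy)} in meters.
#' @return The shifted \code{point_pattern}.
#' @export
toroidal_shift <- function(pattern, shift) {
  win <- pattern$window
  point_pattern((pattern$x + shift[1]) %% win$width_m,
                (pattern$y + shift[2]) %% win$height_m,
                win, mark = pattern$mark)
}

#' Toroidal pairwise distances
#'
#' Shortest-path distances on the window torus; used to verify shift
#' invariance.
#'
#' @param pattern A \code{point_pattern}.
#' @return Distance matrix.
#' @export
toroidal_dist <- function(pattern) {
  win <- pattern$window
  dx <- abs(outer(pattern$x, pattern$x, "-"))
  dy <- abs(outer(pattern$y, pattern$y, "-"))
  dx <- pmin(dx, win$width_m - dx)
  dy <- pmin(dy, win$height_m - dy)
  sqrt(dx^2 + dy^2)
}

#' Monte Carlo envelope for L statistics
#'
#' Computes the observed centered L (univariate or bivariate) and
#' \code{n_sim} simulated curves under a null model:
#' \describe{
#'   \item{\code{"csr"}}{positions resimulated as a binomial process with
#'     the observed point count; univariate \code{\link{l_hat}}.}
#'   \item{\code{"population_independence"}}{both sub-patterns are held
#'     internally rigid and each receives an independent uniform toroidal
#'     shift before the bivariate statistic is recomputed (set
#'     \code{shift_mode = "relative"} to shift only the second pattern,
#'     which is distributionally equivalent for the relative placement).}
#' }
#' All simulated curves are retained so exploratory comparison against the
#' full null distribution is possible beyond the pointwise bounds.
#'
#' @param pattern A \code{point_pattern}; for population independence it
#'   must carry marks and \code{types} selects the two sub-patterns.
#' @param null_model \code{"csr"} or \code{"population_independence"}.
#' @param n_sim Number of simulated patterns (e.g. 999; 250 and 99 are
#'   common cheaper choices).
#' @param r_grid Radii in meters (default 0 to a quarter of the minimum
#'   window dimension in 0.25 m steps).
#' @param types Length-2 character vector of mark values (bivariate only).
#' @param shift_mode \code{"independent"} (default) or \code{"relative"}.
#' @return Object of class \code{envelope_result}: list with
#'   \code{observed} (an \code{l_result}), \code{simulated} (matrix,
#'   n_sim x length(r_grid)), \code{r_grid} and \code{null_model}.
#' @export
envelope <- function(pattern, null_model = c("csr", "population_independence"),
                     n_sim = 999, r_grid = NULL, types = NULL,
                     shift_mode = c("independent", "relative")) {
  null_model <- match.arg(null_model)
  shift_mode <- match.arg(shift_mode)
  if (n_sim < 1) stop("n_sim must be at least 1")
  win <- pattern$window
  if (is.null(r_grid))
    r_grid <- seq(0, min(win$width_m, win$height_m) / 4, by = 0.25)
  if (null_model == "csr") {
    obs <- l_hat(pattern, r_grid)
    sims <- matrix(0, n_sim, length(r_grid))
    for (s in seq_len(n_sim))
      sims[s, ] <- l_hat(simulate_csr(pattern$n, win), r_grid)$l
  } else {
    if (is.null(pattern$mark) || is.null(types) || length(types) != 2)
      stop("population independence needs a marked pattern and two types")
    p1 <- split_marks(pattern, types[1])
    p2 <- split_marks(pattern, types[2])
    obs <- l12_hat(p1, p2, r_grid)
    sims <- matrix(0, n_sim, length(r_grid))
    for (s in seq_len(n_sim)) {
      q1 <- if (shift_mode == "independent")
        toroidal_shift(p1, stats::runif(2) * c(win$width_m, win$height_m))
      else p1
      q2 <- toroidal_shift(p2, stats::runif(2) * c(win$width_m, win$height_m))
      sims[s, ] <- l12_hat(q1, q2, r_grid)$l
    }
  }
  structure(list(observed = obs, simulated = sims, r_grid = r_grid,
                 null_model = null_model),
            class = "envelope_result")
}

#' Pointwise envelope bounds
#'
#' Lower and upper quantiles of the simulated curves at each radius.
#'
#' @param env An \code{envelope_result}.
#' @param probs Two probabilities (default \code{c(0.025, 0.975)}).
#' @return \code{data.frame} with \code{r}, \code{lo}, \code{hi},
#'   \code{observed}.
#' @export
envelope_bounds <- function(env, probs = c(0.025, 0.975)) {
  qs <- apply(env$simulated, 2, stats::quantile, probs = probs, names = FALSE)
  data.frame(r = env$r_grid, lo = qs[1, ], hi = qs[2, ],
             observed = env$observed$l)
}

#' Loosmore-Ford goodness-of-fit test
#'
#' Rank-based Monte Carlo GoF integrating squared deviations of the
#' summary function over a distance interval. With the observed curve
#' indexed 1 and the simulated curves 2..(n_sim+1), each curve's deviation
#' is \deqn{u_i = \sum_k (\hat H_i(r_k) - \bar H_{(-i)}(r_k))^2 \, \Delta r}
#' where \eqn{\bar H_{(-i)}} is the mean over all other curves and
#' \eqn{\Delta r} the grid step. The p-value is
#' \eqn{(1 + \#\{i \ge 2 : u_i \ge u_1\})/(n_{sim} + 1)}; ties count as
#' extreme (conservative).
#'
#' @param env An \code{envelope_result} (the centered L is the summary
#'   function by default).
#' @param r_min,r_max Integration bounds in meters (defaults 0 and 9, the
#'   neighborhood radius used for Sierra Nevada mixed-conifer stands).
#' @return Object of class \code{gof_result}: list with \code{u_observed},
#'   \code{u_simulated}, \code{p_value}, \code{r_min}, \code{r_max},
#'   \code{n_sim}.
#' @export
gof_loosmore_ford <- function(env, r_min = 0, r_max = 9) {
  r <- env$r_grid
  if (r_min < min(r) - 1e-9 || r_max > max(r) + 1e-9)
    stop("integration bounds outside the r grid")
  if (nrow(env$simulated) < 2) stop("need at least 2 simulated curves")
  keep <- r >= r_min - 1e-9 & r <= r_max + 1e-9
  H <- rbind(env$observed$l[keep],
             env$simulated[, keep, drop = FALSE])
  dr <- if (length(r) > 1) r[2] - r[1] else 1
  m <- nrow(H)
  tot <- colSums(H)
  u <- vapply(seq_len(m), function(i) {
    mbar <- (tot - H[i, ]) / (m - 1)
    sum((H[i, ] - mbar)^2) * dr
  }, 0)
  p <- (1 + sum(u[-1] >= u[1])) / m
  structure(list(u_observed = u[1], u_simulated = u[-1], p_value = p,
                 r_min = r_min, r_max = r_max, n_sim = m - 1L),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Loosmore-Ford GoF over %g-%g m: u = %.4g, p = %.4g (%d simulations)\n",
    x$r_min, x$r_max, x$u_observed, x$p_value, x$n_sim))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m_tests Number of tests (>= 1).
#' @param digits Decimal places for the reported threshold (default 3).
#' @return \code{alpha / m_tests}, rounded to \code{digits}.
#' @examples
#' bonferroni(0.05, 12)  # 0.004
#' @export
bonferroni <- function(alpha, m_tests, digits = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m_tests < 1) stop("m_tests must be >= 1")
  round(alpha / m_tests, digits)
}

#' Distance-class correlogram for transect values
#'
#' Bins pairs of sampling units by the distance between their midpoints
#' and computes, per distance class, the Pearson correlation of the paired
#' values with a permutation p-value (values permuted across units,
#' correlations recomputed per class).
#'
#' @param values Numeric response per transect (e.g. debris volume).
#' @param midpoints Two-column matrix of transect midpoints (m).
#' @param breaks Increasing distance-class breaks in meters.
#' @param n_perm Number of permutations (default 999).
#' @return \code{data.frame} with one row per class: \code{d_lo},
#'   \code{d_hi}, \code{n_pairs}, \code{correlation}, \code{p_value},
#'   \code{estimable}. Classes with fewer than 2 pairs or zero variance are
#'   flagged not estimable.
#' @export
transect_correlogram <- function(values, midpoints, breaks, n_perm = 999) {
  midpoints <- as.matrix(midpoints)
  n <- length(values)
  if (nrow(midpoints) != n) stop("values and midpoints lengths differ")
  D <- as.matrix(stats::dist(midpoints))
  pair <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[pair]
  cls <- cut(d, breaks = breaks, include.lowest = TRUE)
  classcor <- function(v) {
    vapply(levels(cls), function(lv) {
      sel <- which(cls == lv)
      if (length(sel) < 2) return(NA_real_)
      a <- v[pair[sel, 1]]; b <- v[pair[sel, 2]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      # symmetric (both orderings) Pearson correlation of pair values
      stats::cor(c(a, b), c(b, a))
    }, 0)
  }
  obs <- classcor(values)
  exceed <- matrix(0L, n_perm, length(obs))
  for (p in seq_len(n_perm)) {
    perm <- classcor(sample(values))
    exceed[p, ] <- as.integer(!is.na(perm) & !is.na(obs) &
                                abs(perm) >= abs(obs))
  }
  pval <- (1 + colSums(exceed)) / (n_perm + 1)
  pval[is.na(obs)] <- NA_real_
  k <- length(levels(cls))
  data.frame(d_lo = breaks[seq_len(k)], d_hi = breaks[seq_len(k) + 1],
             n_pairs = as.integer(table(cls)),
             correlation = unname(obs), p_value = unname(pval),
             estimable = !is.na(obs))
}
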