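#' Build a wiring-cost field from a labeled template
#'
#' Assigns every voxel a traversal speed expressing how easily a simulated
#' axonal fiber passes through it: white matter is fast (`f_WM`, default 1),
#' gray matter is slow but passable (`f_GM`, default 0.05), and voxels
#' outside the brain are forbidden (speed 0). Geodesics in this field model
#' wiring-cost-minimizing axonal tracts that dive into the white matter.
#'
#' @param tpl a `cw_template`.
#' @param f_WM white-matter speed (> 0).
#' @param f_GM gray-matter speed; must satisfy `0 < f_GM <= f_WM`.
#' @return An object of class `cw_cost` holding the speed grid and geometry.
#' @export
build_cost_field <- function(tpl, f_WM = 1, f_GM = 0.05) {
  stopifnot(inherits(tpl, "cw_template"))
  if (f_GM <= 0) stop("f_GM must be positive")
  if (f_GM > f_WM) stop("f_GM must not exceed f_WM")
  speed <- array(0, dim(tpl$labels))
  speed[tpl$labels == LAB_WM] <- f_WM
  speed[tpl$labels >= 2L] <- f_GM
  structure(list(
    speed = speed,
    voxel_size = tpl$voxel_size,
    origin = tpl$origin,
    f_WM = f_WM, f_GM = f_GM
  ), class = "cw_cost")
}

#' Area centroid as the deepest interior point
#'
#' The centroid of a binary mask is the voxel maximizing the signed distance
#' transform, i.e. the mask voxel farthest from the mask boundary. This point
#' is guaranteed to lie inside the mask (unlike the center of mass). Ties are
#' broken by the lexicographically smallest voxel index.
#'
#' @param mask logical 3D array.
#' @param voxel_size mm per voxel along each axis.
#' @param origin mm coordinate of the center of voxel (1,1,1).
#' @return mm coordinate (length 3) of the centroid voxel center.
#' @export
area_centroid <- function(mask, voxel_size, origin = voxel_size / 2) {
  if (!any(mask)) stop("empty mask")
  obj <- list(voxel_size = voxel_size, origin = origin)
  inside <- which_voxels(mask)
  inside_mm <- voxel_to_world(obj, inside)
  # nearest complement voxel to any mask voxel borders the mask; space beyond
  # the grid also counts as complement
  cand <- dilate_mask(mask) & !mask
  edge_pen <- edge_distances(dim(mask), voxel_size, inside)
  if (any(cand)) {
    tgt_mm <- voxel_to_world(obj, which_voxels(cand))
    nn <- .cw_nearest(inside_mm, tgt_mm)
    sdt <- pmin(nn$dist, edge_pen)
  } else {
    sdt <- edge_pen
  }
  best <- which.max(sdt) # first maximum = lowest linear voxel index
  unname(inside_mm[best, ])
}

# distance from voxel centers to the grid's outer faces (complement beyond
# the grid), per voxel row of `ijk`
edge_distances <- function(d, h, ijk) {
  dd <- cbind(ijk[, 1] * h[1], (d[1] - ijk[, 1] + 1) * h[1],
              ijk[, 2] * h[2], (d[2] - ijk[, 2] + 1) * h[2],
              ijk[, 3] * h[3], (d[3] - ijk[, 3] + 1) * h[3])
  apply(dd, 1, min)
}

#' Solve the Eikonal arrival-time field from a seed point
#'
#' First-order upwind fast marching on the cost field: the returned grid T
#' satisfies |grad T| = 1/speed with T = 0 at the seed. Voxels enclosed by
#' zero-speed regions are unreachable and carry `Inf`.
#'
#' @param cost a `cw_cost` field.
#' @param seed mm coordinate of the seed point; must lie in a voxel with
#'   positive speed.
#' @return An object of class `cw_arrival` (arrival-time array plus
#'   geometry and seed).
#' @export
solve_arrival_time <- function(cost, seed) {
  stopifnot(inherits(cost, "cw_cost"))
  vox <- world_to_voxel(cost, seed)[1, ]
  if (!in_grid(cost, vox) || cost$speed[rbind(vox)] <= 0)
    stop("seed point outside the brain (zero-speed voxel)")
  T <- .cw_fmm(cost$speed, cost$voxel_size, as.integer(vox) - 1L)
  structure(list(
    T = T,
    voxel_size = cost$voxel_size,
    origin = cost$origin,
    seed = as.numeric(seed),
    seed_vox = vox
  ), class = "cw_arrival")
}

arrival_at <- function(at, p) {
  ijk <- world_to_voxel(at, p)
  ok <- in_grid(list(speed = at$T), ijk)
  out <- rep(Inf, nrow(ijk))
  if (any(ok)) out[ok] <- at$T[ijk[ok, , drop = FALSE]]
  out
}

#' Trace a geodesic through an arrival-time field
#'
#' Fixed-step steepest descent on the trilinearly interpolated arrival time,
#' from `start` back to the seed of the field. The step is a tenth of the
#' smallest voxel edge; tracing stops within one voxel of the seed and the
#' remaining straight segment is added to the arclength.
#'
#' @param at a `cw_arrival` field from [solve_arrival_time()].
#' @param start mm coordinate with finite arrival time.
#' @param step_frac descent step as a fraction of the smallest voxel edge.
#' @param smooth_mm moving-average window (mm) applied to the polyline before
#'   measuring its arclength, suppressing sub-voxel zigzag where the arrival
#'   field is nearly flat; 0 disables smoothing.
#' @param keep_path return the polyline as well as its length?
#' @return A list with `length_mm`, `converged`, and (optionally) `path`
#'   (n x 3 mm polyline from `start` to the seed; the raw, unsmoothed trace).
#' @export
trace_geodesic <- function(at, start, step_frac = 0.1, smooth_mm = 0.75,
                           keep_path = TRUE) {
  stopifnot(inherits(at, "cw_arrival"))
  if (!is.finite(arrival_at(at, start)))
    stop("start point is unreachable from the seed (infinite arrival time)")
  step <- step_frac * min(at$voxel_size)
  stop_radius <- max(at$voxel_size)
  res <- .cw_trace(at$T, at$voxel_size,
                   to_grid_mm(at, start)[1, ], to_grid_mm(at, at$seed)[1, ],
                   step, stop_radius, smooth_mm, keep_path)
  out <- list(length_mm = res$length, converged = res$converged)
  if (keep_path) out$path <- from_grid_mm(at, res$path)
  out
}

# vectorized geodesic lengths from many start points to the field's seed
trace_lengths <- function(at, starts, step_frac = 0.1, smooth_mm = 0.75) {
  starts <- rbind(starts)
  step <- step_frac * min(at$voxel_size)
  stop_radius <- max(at$voxel_size)
  reach <- is.finite(arrival_at(at, starts))
  len <- rep(NA_real_, nrow(starts))
  conv <- rep(FALSE, nrow(starts))
  if (any(reach)) {
    res <- .cw_trace_lengths(at$T, at$voxel_size,
                             to_grid_mm(at, starts[reach, , drop = FALSE]),
                             to_grid_mm(at, at$seed)[1, ],
                             step, stop_radius, smooth_mm)
    len[reach] <- res$length
    conv[reach] <- res$converged
  }
  list(length_mm = len, converged = conv)
}

#' Geodesic wiring distance between two points
#'
#' Length (mm) of the simulated axonal tract connecting two brain points:
#' the fast-marching field is seeded at `b` and the geodesic is traced back
#' from `a`. The result is symmetric up to the numerical direction
#' discrepancy of the solver.
#'
#' @param cost a `cw_cost` field.
#' @param a,b mm coordinates inside the brain.
#' @return Geodesic length in mm.
#' @export
point_to_point_distance <- function(cost, a, b) {
  if (sqrt(sum((a - b)^2)) == 0) return(0)
  at <- solve_arrival_time(cost, b)
  if (!is.finite(arrival_at(at, a)))
    stop("point outside the brain or unreachable")
  trace_geodesic(at, a, keep_path = FALSE)$length_mm
}

#' Interareal wiring-distance matrix
#'
#' For every unordered pair of areas, geodesic trajectories between the area
#' centroids are traced in both directions and the distance is their mean,
#' `d_ij = (d_fwd + d_rev) / 2`. The per-pair direction discrepancy
#' `|d_fwd - d_rev| / d_ij` (or the absolute difference in mm) is retained as
#' a numerical-quality diagnostic. Pairs whose centroids are mutually
#' unreachable get distance `Inf` and are excluded from summary means.
#'
#' @param tpl a `cw_template`.
#' @param f_WM,f_GM cost-field parameters, see [build_cost_field()].
#' @param areas area ids to include (default: all areas of the template).
#' @param discrepancy `"relative"` (default) or `"absolute"` (mm).
#' @return An object of class `cw_distmat`: list with symmetric matrix `d`
#'   (mm), matrix `discrepancy`, per-direction matrix `d_dir` (entry \[i, j\]
#'   = length of the trajectory seeded at i and traced from j), `centroids`,
#'   and the cost parameters.
#' @export
pairwise_area_distances <- function(tpl, f_WM = 1, f_GM = 0.05, areas = NULL,
                                    discrepancy = c("relative", "absolute")) {
  stopifnot(inherits(tpl, "cw_template"))
  discrepancy <- match.arg(discrepancy)
  areas <- areas %||% tpl$area_ids
  n <- length(areas)
  key <- as.character(areas)
  cost <- build_cost_field(tpl, f_WM = f_WM, f_GM = f_GM)

  centroids <- matrix(NA_real_, n, 3, dimnames = list(key, c("x", "y", "z")))
  for (i in seq_len(n)) {
    mask <- tpl$labels == areas[i]
    if (!any(mask)) stop("area ", areas[i], " has an empty mask")
    centroids[i, ] <- area_centroid(mask, tpl$voxel_size, tpl$origin)
  }

  d_dir <- matrix(NA_real_, n, n, dimnames = list(key, key))
  for (i in seq_len(n)) {
    at <- solve_arrival_time(cost, centroids[i, ])
    others <- setdiff(seq_len(n), i)
    res <- trace_lengths(at, centroids[others, , drop = FALSE])
    len <- res$length_mm
    len[is.na(len)] <- Inf
    d_dir[i, others] <- len
  }

  d <- (d_dir + t(d_dir)) / 2
  diag(d) <- 0
  disc <- abs(d_dir - t(d_dir))
  if (discrepancy == "relative") disc <- disc / d
  diag(disc) <- NA_real_
  disc[!is.finite(d)] <- NA_real_

  structure(list(
    d = d, discrepancy = disc, d_dir = d_dir, centroids = centroids,
    areas = areas, f_WM = f_WM, f_GM = f_GM,
    discrepancy_type = discrepancy
  ), class = "cw_distmat")
}

#' @export
print.cw_distmat <- function(x, ...) {
  ut <- x$d[upper.tri(x$d)]
  cat("cw_distmat:", length(x$areas), "areas,",
      n_area_pairs(length(x$areas)), "unordered pairs; mean",
      signif(mean(ut[is.finite(ut)]), 4), "mm\n")
  invisible(x)
}

#' Number of unordered area pairs
#'
#' `n * (n - 1) / 2`, the count of informative entries in a symmetric
#' interareal distance matrix over `n` areas.
#'
#' @param n number of areas.
#' @return Integer-valued count of unordered pairs.
#' @export
n_area_pairs <- function(n) {
  n * (n - 1) / 2
}

# mean of the finite informative (upper-triangle) distances
mean_interareal_distance <- function(dmat) {
  ut <- dmat$d[upper.tri(dmat$d)]
  mean(ut[is.finite(ut)])
}

#' Sensitivity of interareal distances to the white/gray cost ratio
#'
#' Recomputes the interareal distance matrix for a set of `f_WM / f_GM`
#' ratios (holding `f_WM` fixed) and reports the mean interareal distance per
#' ratio. Because higher ratios push trajectories deeper into the white
#' matter, the mean trajectory length is monotone non-decreasing in the
#' ratio; over the biologically plausible range (roughly 10-30) it is
#' expected to vary little.
#'
#' @param tpl a `cw_template`.
#' @param ratios numeric vector of `f_WM / f_GM` ratios (>= 1).
#' @param f_WM white-matter speed held fixed across the sweep.
#' @return A data frame with columns `ratio` and `mean_distance_mm`.
#' @export
sensitivity_sweep <- function(tpl, ratios = c(1, 10, 20, 30), f_WM = 1) {
  if (any(ratios < 1)) stop("ratios must be >= 1")
  means <- vapply(ratios, function(r) {
    dm <- pairwise_area_distances(tpl, f_WM = f_WM, f_GM = f_WM / r)
    mean_interareal_distance(dm)
  }, numeric(1))
  data.frame(ratio = ratios, mean_distance_mm = means)
}
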