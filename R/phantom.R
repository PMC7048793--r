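#' Configuration of the synthetic brain phantom
#'
#' The phantom emulates the inputs of the downstream analyses: a closed
#' cortical sheet (a spherical shell of gray matter, split into supra- and
#' infragranular halves at its radial midpoint) around a white-matter core,
#' partitioned into contiguous cortical areas; tracer injections with an
#' exclusion zone; and labeled-cell point clouds whose per-area counts decay
#' with the wiring distance between source and target areas.
#'
#' Cell counts are generated from a per-voxel intensity: for an injection in
#' target area t, every gray voxel of source area s has intensity
#' proportional to `pair_weights[t, s] * exp(-d(t, s) / decay_length)`, so a
#' source area's expected count also scales with its gray-matter volume.
#' Intrinsic (within-area) labeling uses `intrinsic_weight` at distance 0.
#'
#' @param grid_shape integer length-3, voxels per axis (default 80^3).
#' @param voxel_size mm per voxel (default 0.25 mm isotropic).
#' @param n_areas number of cortical areas tiling the shell (>= 2).
#' @param cortex_thickness thickness of the gray shell, mm.
#' @param decay_length exponential decay length (lambda) of projection
#'   strength with interareal wiring distance, mm.
#' @param pair_weights `n_areas x n_areas` nonnegative matrix of relative
#'   projection strengths (target x source); default log-normal draws.
#' @param supra_fraction per-pair probability that an extrinsic labeled cell
#'   is supragranular (scalar or `n_areas x n_areas` matrix in `[0,1]`).
#' @param intrinsic_weight relative weight of intrinsic labeling (>= 0).
#' @param cells_per_injection expected number of labeled cells per injection.
#' @param exclusion_radius_range mm interval from which each injection's
#'   exclusion-zone radius is drawn uniformly.
#' @param no_layer4_areas integer area ids whose cells carry no laminar
#'   assignment (lamina `"none"`).
#' @param seed integer seed governing all phantom randomness.
#' @return A list of class `cw_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(80L, 80L, 80L),
                           voxel_size = c(0.25, 0.25, 0.25),
                           n_areas = 8L,
                           cortex_thickness = 2,
                           decay_length = 3,
                           pair_weights = NULL,
                           supra_fraction = NULL,
                           intrinsic_weight = 2,
                           cells_per_injection = 2000L,
                           exclusion_radius_range = c(0.1, 1.1),
                           no_layer4_areas = integer(0),
                           seed = 1L) {
  if (n_areas < 2) stop("n_areas must be >= 2")
  if (decay_length <= 0) stop("decay_length must be positive")
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (intrinsic_weight < 0) stop("intrinsic_weight must be nonnegative")
  if (length(exclusion_radius_range) != 2 ||
      any(exclusion_radius_range < 0) || diff(exclusion_radius_range) < 0)
    stop("exclusion_radius_range must be a nondecreasing nonnegative interval")
  if (is.null(pair_weights)) {
    pair_weights <- with_seed(seed, {
      matrix(rlnorm(n_areas^2, meanlog = 0, sdlog = 1), n_areas, n_areas)
    })
  }
  pair_weights <- as.matrix(pair_weights)
  if (!all(dim(pair_weights) == n_areas) || any(pair_weights < 0))
    stop("pair_weights must be a nonnegative n_areas x n_areas matrix")
  if (is.null(supra_fraction)) {
    supra_fraction <- with_seed(seed + 1L, {
      matrix(runif(n_areas^2, 0.15, 0.85), n_areas, n_areas)
    })
  }
  if (length(supra_fraction) == 1)
    supra_fraction <- matrix(supra_fraction, n_areas, n_areas)
  supra_fraction <- as.matrix(supra_fraction)
  if (any(supra_fraction < 0 | supra_fraction > 1))
    stop("supra_fraction must lie in [0, 1]")
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_size = as.numeric(voxel_size),
    n_areas = as.integer(n_areas),
    cortex_thickness = cortex_thickness,
    decay_length = decay_length,
    pair_weights = pair_weights,
    supra_fraction = supra_fraction,
    intrinsic_weight = intrinsic_weight,
    cells_per_injection = as.integer(cells_per_injection),
    exclusion_radius_range = as.numeric(exclusion_radius_range),
    no_layer4_areas = as.integer(no_layer4_areas),
    seed = as.integer(seed)
  ), class = "cw_phantom_config")
}

# deterministic, roughly equidistant directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Build the phantom template volume
#'
#' Constructs a spherical-shell cortex of the configured thickness over a
#' white-matter core. The shell is partitioned into `n_areas` contiguous
#' sectors (spherical Voronoi cells of deterministic anchor directions); the
#' outer half of the shell is labeled supragranular and the inner half
#' infragranular, split at the radial midpoint, which also carries the
#' mid-thickness surface sample.
#'
#' @param config a [phantom_config()].
#' @return A [template_volume()] with attributes `shell_radii` (inner, mid,
#'   outer, mm) and `center` (mm).
#' @export
build_template <- function(config) {
  stopifnot(inherits(config, "cw_phantom_config"))
  n <- config$grid_shape
  h <- config$voxel_size
  if (config$cortex_thickness < 2 * max(h))
    stop("degenerate geometry: cortex thickness under 2 voxels")
  extent <- n * h
  center <- extent / 2
  r_out <- 0.4 * min(extent)
  r_in <- r_out - config$cortex_thickness
  if (r_in <= 2 * max(h))
    stop("degenerate geometry: white-matter core too small")

  cx <- (seq_len(n[1]) - 0.5) * h[1] - center[1]
  cy <- (seq_len(n[2]) - 0.5) * h[2] - center[2]
  cz <- (seq_len(n[3]) - 0.5) * h[3] - center[3]
  r2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  r <- sqrt(r2)

  labels <- array(LAB_OUT, n)
  labels[r <= r_in] <- LAB_WM

  gray <- r > r_in & r <= r_out
  gidx <- which(gray)
  garr <- which_voxels(gray)
  gxyz <- cbind((garr[, 1] - 0.5) * h[1] - center[1],
                (garr[, 2] - 0.5) * h[2] - center[2],
                (garr[, 3] - 0.5) * h[3] - center[3])
  gdir <- gxyz / sqrt(rowSums(gxyz^2))
  anchors <- fibonacci_sphere(config$n_areas)
  sector <- max.col(gdir %*% t(anchors), ties.method = "first")
  labels[gidx] <- sector + 1L

  r_mid <- (r_in + r_out) / 2
  lamina <- array(0L, n)
  # supra iff closer to the pial (outer) boundary than to the white boundary
  lamina[gidx] <- ifelse(r[gidx] > r_mid, 1L, 2L)

  on_mid <- abs(r[gidx] - r_mid) <= 0.5 * min(h)
  mid_pts <- sweep(gxyz[on_mid, , drop = FALSE], 2, center, "+")

  tpl <- template_volume(labels, h, lamina = lamina, midthickness = mid_pts)
  attr(tpl, "shell_radii") <- c(inner = r_in, mid = r_mid, outer = r_out)
  attr(tpl, "center") <- center
  tpl
}

#' Place tracer injections in requested areas
#'
#' Each requested area receives one injection at a uniformly chosen
#' gray-matter voxel of that area. The exclusion-zone radius is drawn
#' uniformly from the configured range; the injection site is modeled as a
#' ball of that radius, from which the site volume and the percentage of
#' injected voxels per area are derived. The assigned area is the label at
#' the voxel containing the injection barycenter.
#'
#' @param tpl a `cw_template`.
#' @param areas integer area ids to inject (one injection per entry).
#' @param config a [phantom_config()]; randomness derives from its seed.
#' @return A data frame of class `cw_injections` with columns `id`, `tracer`,
#'   `x_mm`, `y_mm`, `z_mm`, `area`, `volume_mm3`, `exclusion_radius_mm`,
#'   `pct_within`, plus a `percent_by_area` attribute (one named vector per
#'   injection).
#' @export
place_injections <- function(tpl, areas, config) {
  stopifnot(inherits(tpl, "cw_template"))
  missing_areas <- setdiff(areas, tpl$area_ids)
  if (length(missing_areas) > 0)
    stop("area id(s) absent from template: ", paste(missing_areas, collapse = ", "))
  tracers <- c("FB", "DY", "FE", "FR", "CTBgr", "CTBr")
  with_seed(config$seed + 1L, {
    n <- length(areas)
    centers <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      vox <- which_voxels(tpl$labels == areas[i])
      pick <- vox[sample.int(nrow(vox), 1L), , drop = FALSE]
      centers[i, ] <- voxel_to_world(tpl, pick)
    }
    radius <- runif(n, config$exclusion_radius_range[1],
                    config$exclusion_radius_range[2])
    inj <- data.frame(
      id = sprintf("inj%02d", seq_len(n)),
      tracer = tracers[(seq_len(n) - 1L) %% length(tracers) + 1L],
      x_mm = centers[, 1], y_mm = centers[, 2], z_mm = centers[, 3],
      area = label_at(tpl, centers),
      volume_mm3 = 4 / 3 * pi * radius^3,
      exclusion_radius_mm = radius,
      stringsAsFactors = FALSE
    )
    pba <- lapply(seq_len(n), function(i)
      injection_site_composition(tpl, centers[i, ], radius[i]))
    inj$pct_within <- vapply(seq_len(n), function(i) {
      p <- pba[[i]][as.character(inj$area[i])]
      if (is.na(p)) 0 else unname(p)
    }, numeric(1))
    attr(inj, "percent_by_area") <- pba
    class(inj) <- c("cw_injections", "data.frame")
    inj
  })
}

# fraction of injected (gray-matter) voxels per area within a ball around the
# injection center
injection_site_composition <- function(tpl, center, radius) {
  h <- tpl$voxel_size
  d <- dim(tpl$labels)
  lo <- pmax(world_to_voxel(tpl, center - radius)[1, ], 1L)
  hi <- pmin(world_to_voxel(tpl, center + radius)[1, ], d)
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  xyz <- voxel_to_world(tpl, ijk)
  inside <- sqrt(rowSums(sweep(xyz, 2, center)^2)) <= radius
  labs <- tpl$labels[ijk[inside, , drop = FALSE]]
  labs <- labs[labs >= 2L]
  if (length(labs) == 0) {
    # ball smaller than one voxel: the barycenter voxel is the whole site
    labs <- label_at(tpl, center)
  }
  tab <- table(labs)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Simulate labeled-cell point clouds for a set of injections
#'
#' For each injection, labeled cells are drawn from a multinomial over source
#' areas whose per-area weight is `pair_weights[target, source] *
#' exp(-d(target, source) / decay_length) * (gray volume of source)`, with
#' intrinsic labeling weighted by `intrinsic_weight` at distance 0. Cells are
#' placed uniformly within the gray matter of their source area, and each
#' extrinsic cell is supragranular with probability
#' `supra_fraction[target, source]` (intrinsic cells use the diagonal entry).
#' Cells in `no_layer4_areas` carry lamina `"none"`.
#'
#' @param tpl a `cw_template` from [build_template()].
#' @param injections a `cw_injections` data frame.
#' @param config a [phantom_config()].
#' @param dmat optional precomputed [pairwise_area_distances()] for `tpl`;
#'   computed with default cost parameters when omitted, so that the
#'   generator and the analyses share one wiring metric.
#' @return A data frame of class `cw_cells` with columns `injection_id`,
#'   `tracer`, `x_mm`, `y_mm`, `z_mm`, `area`, `lamina`.
#' @export
simulate_cells <- function(tpl, injections, config, dmat = NULL) {
  stopifnot(inherits(tpl, "cw_template"), inherits(injections, "data.frame"))
  if (is.null(dmat)) dmat <- pairwise_area_distances(tpl)
  ids <- tpl$area_ids
  key <- as.character(ids)
  nvox <- table(factor(tpl$labels[tpl$labels >= 2L], levels = ids))
  nvox <- setNames(as.numeric(nvox), key)
  w_pairs <- config$pair_weights
  sf <- config$supra_fraction

  with_seed(config$seed + 2L, {
    rows <- vector("list", nrow(injections))
    for (i in seq_len(nrow(injections))) {
      target <- injections$area[i]
      ti <- match(target, ids)
      d <- dmat$d[key[ti], key]
      w <- w_pairs[ti, ] * exp(-d / config$decay_length) * nvox
      w[ti] <- config$intrinsic_weight * nvox[ti]
      w[!is.finite(w)] <- 0
      if (sum(w) <= 0)
        stop("all pair weights zero for injection ", injections$id[i])
      counts <- as.vector(rmultinom(1, config$cells_per_injection, w / sum(w)))
      area_of_cell <- rep(ids, counts)
      n_cells <- length(area_of_cell)
      pos <- matrix(NA_real_, n_cells, 3)
      lam <- character(n_cells)
      for (a in seq_along(ids)) {
        sel <- which(area_of_cell == ids[a])
        if (length(sel) == 0) next
        vox <- which_voxels(tpl$labels == ids[a])
        pick <- vox[sample.int(nrow(vox), length(sel), replace = TRUE), , drop = FALSE]
        jit <- matrix(runif(3 * length(sel), -0.5, 0.5), ncol = 3)
        pos[sel, ] <- voxel_to_world(tpl, pick) +
          sweep(jit, 2, tpl$voxel_size, "*")
        if (ids[a] %in% config$no_layer4_areas) {
          lam[sel] <- "none"
        } else {
          p_supra <- sf[ti, a]
          lam[sel] <- ifelse(rbinom(length(sel), 1, p_supra) == 1, "supra", "infra")
        }
      }
      rows[[i]] <- data.frame(
        injection_id = injections$id[i],
        tracer = injections$tracer[i],
        x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
        area = area_of_cell,
        lamina = lam,
        stringsAsFactors = FALSE
      )
    }
    cells <- do.call(rbind, rows)
    rownames(cells) <- NULL
    class(cells) <- c("cw_cells", "data.frame")
    cells
  })
}

#' Generate a complete phantom dataset
#'
#' Convenience wrapper building the template, placing one injection into each
#' of `inject_areas` (default: every area), and simulating labeled cells.
#'
#' @inheritParams simulate_cells
#' @param config a [phantom_config()].
#' @param inject_areas area ids to inject; default all areas.
#' @param f_WM,f_GM wiring-cost parameters shared between the generator and
#'   the analyses.
#' @return A list with elements `template`, `injections`, `cells`, `dmat`,
#'   `cost`, `config`.
#' @export
phantom_dataset <- function(config = phantom_config(),
                            inject_areas = NULL,
                            f_WM = 1, f_GM = 0.05) {
  tpl <- build_template(config)
  inject_areas <- inject_areas %||% tpl$area_ids
  inj <- place_injections(tpl, inject_areas, config)
  cost <- build_cost_field(tpl, f_WM = f_WM, f_GM = f_GM)
  dmat <- pairwise_area_distances(tpl, f_WM = f_WM, f_GM = f_GM)
  cells <- simulate_cells(tpl, inj, config, dmat = dmat)
  list(template = tpl, injections = inj, cells = cells,
       dmat = dmat, cost = cost, config = config)
}
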