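#' Named primary-area sets of the marmoset parcellation
#'
#' Three alternative definitions of the "primary" sensory/motor areas used as
#' reference points for the distance-to-primary gradient analyses: the
#' default set (primary visual, somatosensory, auditory core, and motor
#' cortex), a functionally defined sensory set (adds gustatory cortex,
#' drops motor cortex and the rostrotemporal auditory area), and a
#' koniocortex-type set (areas with a prominent granular layer 4).
#'
#' @return Named list of character vectors of area names.
#' @export
primary_area_sets <- function() {
  list(
    default = c("V1", "A3a", "A3b", "AuA1", "AuR", "AuRT", "A4ab", "A4c"),
    functional_sensory = c("V1", "A3a", "A3b", "AuA1", "AuR", "Gu"),
    koniocortex = c("V1", "AuA1", "AuR", "A3b")
  )
}

#' Wiring distance from an injection to the nearest primary area
#'
#' Zero when the injection's barycenter lies inside a primary area; otherwise
#' the minimum wiring (geodesic) distance from the barycenter to any boundary
#' voxel of a primary area. Boundary voxels are primary-area voxels adjacent
#' to a differently labeled voxel; candidates are ranked by arrival time and
#' the shortest traced trajectory among competitive candidates is returned.
#'
#' @param injection one row of a `cw_injections` data frame.
#' @param primaries integer area ids forming the primary set (nonempty).
#' @param tpl a `cw_template`.
#' @param cost a `cw_cost` field.
#' @param at optional precomputed `cw_arrival` seeded at the injection
#'   center.
#' @return Distance in mm (0 for injections inside a primary area).
#' @export
distance_to_nearest_primary <- function(injection, primaries, tpl, cost,
                                        at = NULL) {
  if (length(primaries) == 0) stop("primary area set is empty")
  if (injection$area %in% primaries) return(0)
  center <- c(injection$x_mm, injection$y_mm, injection$z_mm)
  if (is.null(at)) at <- solve_arrival_time(cost, center)
  pmask <- array(tpl$labels %in% primaries, dim(tpl$labels))
  bnd <- boundary_of_mask(pmask)
  bpts <- voxel_to_world(tpl, which_voxels(bnd))
  tt <- arrival_at(at, bpts)
  if (!any(is.finite(tt))) return(Inf)
  # trace the trajectories competitive in arrival time, keep the shortest
  keep <- which(tt <= min(tt) * 2 + 1e-12)
  if (length(keep) > 600) keep <- keep[order(tt[keep])[1:600]]
  res <- trace_lengths(at, bpts[keep, , drop = FALSE])
  min(res$length_mm, na.rm = TRUE)
}

#' Area-based connectivity distance of an injection
#'
#' The labeled-neuron-weighted mean of centroid-to-centroid wiring distances:
#' the sum over source areas of (distance from target to source centroid)
#' times (labeled neurons in the source), divided by the total number of
#' extrinsic labeled neurons. Intrinsic cells are excluded.
#'
#' @param injection one row of a `cw_injections` data frame.
#' @param counts named numeric vector of labeled-cell counts per source area
#'   (names are area ids).
#' @param dmat a `cw_distmat` from [pairwise_area_distances()].
#' @return Connectivity distance in mm.
#' @export
area_based_cd <- function(injection, counts, dmat) {
  target <- as.character(injection$area)
  src <- setdiff(names(counts)[counts > 0], target)
  if (length(src) == 0)
    stop("connectivity distance undefined: no extrinsic labeled cells")
  d <- dmat$d[target, src]
  sum(d * counts[src]) / sum(counts[src])
}

#' Project points to the mid-thickness surface
#'
#' Nearest mid-thickness surface point by Euclidean distance; ties are broken
#' by the lowest vertex index, so the projection is deterministic.
#'
#' @param points n x 3 matrix (or length-3 vector) of mm coordinates.
#' @param tpl a `cw_template` with a non-empty `midthickness` sample.
#' @return n x 3 matrix of projected mm coordinates, with attribute `index`
#'   (the matched vertex indices).
#' @export
project_to_midthickness <- function(points, tpl) {
  if (is.null(tpl$midthickness) || nrow(tpl$midthickness) == 0)
    stop("template has no mid-thickness surface")
  points <- rbind(points)
  nn <- .cw_nearest(points, tpl$midthickness)
  out <- tpl$midthickness[nn$which, , drop = FALSE]
  attr(out, "index") <- nn$which
  out
}

#' Cell-based connectivity distance of an injection
#'
#' Average length of the simulated axonal tracts from each labeled cell to
#' the injection center. Cells and the center are first projected to the
#' mid-thickness surface, removing the bias from different laminar depths;
#' cells whose projected position falls within the injection's exclusion
#' radius of the projected center are discarded (labeling there is
#' unreliable). Both intrinsic and extrinsic cells contribute.
#'
#' @param injection one row of a `cw_injections` data frame (must carry
#'   `exclusion_radius_mm`).
#' @param cells a `cw_cells` table.
#' @param tpl a `cw_template`.
#' @param cost a `cw_cost` field.
#' @param at optional precomputed `cw_arrival` seeded at the projected
#'   injection center (reused across calls for speed).
#' @return List with `cd_cell` (mm), `per_cell` (data frame of surviving
#'   cells: distance, area, lamina), `center_proj`, and `at` (the arrival
#'   field, for reuse).
#' @export
cell_based_cd <- function(injection, cells, tpl, cost, at = NULL) {
  if (is.null(injection$exclusion_radius_mm) ||
      is.na(injection$exclusion_radius_mm))
    stop("injection has no exclusion radius")
  sub <- cells[cells$injection_id == injection$id, , drop = FALSE]
  if (nrow(sub) == 0) stop("no labeled cells for injection ", injection$id)
  center <- c(injection$x_mm, injection$y_mm, injection$z_mm)
  center_proj <- project_to_midthickness(center, tpl)[1, ]
  pts <- project_to_midthickness(as.matrix(sub[, c("x_mm", "y_mm", "z_mm")]), tpl)
  eucl <- sqrt(rowSums(sweep(pts, 2, center_proj)^2))
  keep <- eucl >= injection$exclusion_radius_mm
  if (!any(keep))
    stop("no cells survive the exclusion zone for injection ", injection$id)
  if (is.null(at)) at <- solve_arrival_time(cost, center_proj)
  res <- trace_lengths(at, pts[keep, , drop = FALSE])
  per_cell <- data.frame(
    distance_mm = res$length_mm,
    area = sub$area[keep],
    lamina = sub$lamina[keep],
    stringsAsFactors = FALSE
  )
  list(cd_cell = mean(res$length_mm, na.rm = TRUE),
       per_cell = per_cell, center_proj = center_proj, at = at)
}

#' Laminar split of the cell-based connectivity distance
#'
#' Mean afferent length restricted to supragranular and to infragranular
#' cells, plus their ratio. Cells without a laminar assignment are excluded;
#' if one compartment is empty its mean (and the ratio) is `NA`.
#'
#' @param per_cell the `per_cell` data frame from [cell_based_cd()].
#' @return List with `L_supra`, `L_infra` (mm) and `ratio` (supra / infra).
#' @export
laminar_cd_split <- function(per_cell) {
  ds <- per_cell$distance_mm[per_cell$lamina == "supra"]
  di <- per_cell$distance_mm[per_cell$lamina == "infra"]
  L_supra <- if (length(ds) > 0) mean(ds, na.rm = TRUE) else NA_real_
  L_infra <- if (length(di) > 0) mean(di, na.rm = TRUE) else NA_real_
  list(L_supra = L_supra, L_infra = L_infra, ratio = L_supra / L_infra)
}

#' Per-injection connectivity-distance records
#'
#' Assembles, for every injection, the quantities entering the
#' distance-to-primary analyses: the wiring distance to the nearest primary
#' area, the area-based and cell-based connectivity distances, the laminar
#' split, and the model covariates (location centrality of the injected area
#' = mean wiring distance from its centroid to all other centroids; gray
#' volume of the injected area; injection volume; and the mean wiring
#' distance from the injection center to the cortical sheet, sampled on the
#' mid-thickness surface).
#'
#' @param cells a `cw_cells` table.
#' @param injections a `cw_injections` data frame.
#' @param tpl a `cw_template`.
#' @param dmat a `cw_distmat`.
#' @param cost a `cw_cost` field.
#' @param primaries integer area ids of the primary set.
#' @param max_surface_sample cap on the number of mid-thickness points used
#'   for the mean-distance-to-cortex covariate.
#' @return Data frame of class `cw_cd_records`, one row per injection.
#' @export
connectivity_distance_records <- function(cells, injections, tpl, dmat, cost,
                                          primaries,
                                          max_surface_sample = 1500L) {
  vols <- area_volumes(tpl)
  n <- nrow(injections)
  rows <- vector("list", n)
  surf <- tpl$midthickness
  if (nrow(surf) > max_surface_sample) {
    stride <- ceiling(nrow(surf) / max_surface_sample)
    surf <- surf[seq(1, nrow(surf), by = stride), , drop = FALSE]
  }
  for (i in seq_len(n)) {
    inj <- injections[i, , drop = FALSE]
    counts <- cell_counts(cells, inj$id, tpl$area_ids)
    cbc <- cell_based_cd(inj, cells, tpl, cost)
    lam <- laminar_cd_split(cbc$per_cell)
    surf_d <- trace_lengths(cbc$at, surf)$length_mm
    tkey <- as.character(inj$area)
    rows[[i]] <- data.frame(
      injection_id = inj$id,
      area = inj$area,
      dist_to_primary = distance_to_nearest_primary(inj, primaries, tpl, cost),
      cd_area = area_based_cd(inj, counts, dmat),
      cd_cell = cbc$cd_cell,
      L_supra = lam$L_supra,
      L_infra = lam$L_infra,
      centrality_mm = mean(dmat$d[tkey, setdiff(colnames(dmat$d), tkey)]),
      area_volume_mm3 = unname(vols[tkey]),
      injection_volume_mm3 = inj$volume_mm3,
      mean_dist_to_cortex_mm = mean(surf_d, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cw_cd_records", "data.frame")
  out
}

#' Linear model of connectivity distance against distance to primary areas
#'
#' Ordinary least-squares fit of the connectivity distance on the distance to
#' the nearest primary area plus covariates. For the area-based response the
#' covariates are the location centrality of the injected area and its gray
#' volume; for the cell-based response they are the injection volume and the
#' mean distance from the injection site to the cortical sheet. The reported
#' slope `beta` is for the standardized design (z-scored response and
#' predictors), making it unitless; the raw-scale slope is also returned.
#'
#' @param records a `cw_cd_records` data frame.
#' @param response `"cd_area"` or `"cd_cell"`.
#' @param mode `"per_injection"` fits one observation per injection;
#'   `"per_area_mean"` first averages the records of injections sharing an
#'   injected area.
#' @param predictors optional character vector overriding the default
#'   covariate set (must be columns of `records`; `dist_to_primary` is always
#'   included first).
#' @return An object of class `cw_glm`: list with `beta`, `ci` (95%),
#'   `beta_raw`, `F`, `df1`, `df2`, `p`, `n`, `exact_fit` flag, and the
#'   underlying `lm` fit.
#' @export
fit_cd_glm <- function(records,
                       response = c("cd_area", "cd_cell"),
                       mode = c("per_injection", "per_area_mean"),
                       predictors = NULL) {
  response <- match.arg(response)
  mode <- match.arg(mode)
  predictors <- predictors %||% if (response == "cd_area")
    c("centrality_mm", "area_volume_mm3")
  else c("injection_volume_mm3", "mean_dist_to_cortex_mm")
  vars <- unique(c("dist_to_primary", predictors))
  if (length(vars) < length(c("dist_to_primary", predictors)))
    stop("dist_to_primary duplicated among the covariates")

  df <- records[, c(vars, response, "area")]
  if (mode == "per_area_mean") {
    df <- aggregate(df[, c(vars, response)], by = list(area = df$area), mean)
  }
  df <- df[complete.cases(df[, c(vars, response)]), , drop = FALSE]
  n <- nrow(df)
  if (n < length(vars) + 2)
    stop("need at least ", length(vars) + 2, " observations")

  X <- as.matrix(df[, vars, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("collinear design: predictors are rank deficient")

  zscore <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  zdf <- as.data.frame(lapply(df[, c(vars, response)], zscore))
  fml <- stats::as.formula(paste(response, "~", paste(vars, collapse = " + ")))
  fit_z <- lm(fml, data = zdf)
  fit_raw <- lm(fml, data = df)

  rss <- sum(residuals(fit_z)^2)
  tss <- sum((zdf[[response]] - mean(zdf[[response]]))^2)
  df1 <- length(vars)
  df2 <- n - df1 - 1
  exact <- rss < 1e-12 * max(tss, 1)
  if (exact) {
    Fstat <- Inf
    p <- 0
    ci <- c(coef(fit_z)[["dist_to_primary"]], coef(fit_z)[["dist_to_primary"]])
  } else {
    Fstat <- ((tss - rss) / df1) / (rss / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    ci <- confint(fit_z)["dist_to_primary", ]
  }

  structure(list(
    beta = unname(coef(fit_z)[["dist_to_primary"]]),
    ci = unname(ci),
    beta_raw = unname(coef(fit_raw)[["dist_to_primary"]]),
    F = Fstat, df1 = df1, df2 = df2, p = p, n = n,
    exact_fit = exact, response = response, mode = mode,
    fit = fit_raw
  ), class = "cw_glm")
}

#' @export
print.cw_glm <- function(x, ...) {
  cat(sprintf("cw_glm (%s, %s): F(%d,%d) = %.2f, p = %.3g, beta = %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
              x$response, x$mode, x$df1, x$df2, x$F, x$p, x$beta,
              x$ci[1], x$ci[2], x$n))
  invisible(x)
}
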