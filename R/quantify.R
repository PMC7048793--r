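#' Assign a point to a cortical area
#'
#' Returns the area label of the voxel containing `position`. If that voxel
#' is not a cortical area (white matter or outside), the nearest area voxel
#' within `tolerance` mm is used instead; beyond the tolerance the point is
#' unassignable and an error is raised.
#'
#' @param position mm coordinate.
#' @param tpl a `cw_template`.
#' @param tolerance search radius in mm for points falling outside the
#'   parcellation (>= 0).
#' @return Integer area id.
#' @export
assign_area <- function(position, tpl, tolerance = 0.5) {
  stopifnot(inherits(tpl, "cw_template"), tolerance >= 0)
  lab <- label_at(tpl, position)
  if (!is.na(lab) && lab >= 2L) return(lab)
  # restrict the nearest-voxel search to a tolerance-sized bounding box
  d <- dim(tpl$labels)
  lo <- pmax(world_to_voxel(tpl, position - tolerance)[1, ] - 1L, 1L)
  hi <- pmin(world_to_voxel(tpl, position + tolerance)[1, ] + 1L, d)
  sub <- tpl$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ijk_local <- which_voxels(array(sub >= 2L, dim(sub)))
  if (nrow(ijk_local) == 0)
    stop("point unassignable: no cortical area within ", tolerance, " mm")
  ijk <- sweep(ijk_local, 2, lo - 1L, "+")
  nn <- .cw_nearest(rbind(as.numeric(position)), voxel_to_world(tpl, ijk))
  if (nn$dist[1] > tolerance)
    stop("point unassignable: nearest area is ", signif(nn$dist[1], 3),
         " mm away (tolerance ", tolerance, " mm)")
  tpl$labels[ijk[nn$which[1], , drop = FALSE]]
}

# labeled-cell counts by source area for one injection, over a fixed area set
cell_counts <- function(cells, injection_id, areas) {
  sub <- cells[cells$injection_id == injection_id, , drop = FALSE]
  tab <- table(factor(sub$area, levels = areas))
  setNames(as.numeric(tab), as.character(areas))
}

#' Fraction of labeled neurons, extrinsic (FLNe)
#'
#' For one injection into area A, the FLNe of source area B is the number of
#' labeled neurons in B divided by the total number of labeled neurons in all
#' areas other than A. Entries sum to 1 over extrinsic sources; the injected
#' area's entry is `NA` (intrinsic connections are not evaluated).
#'
#' @param cells a `cw_cells` table (or any data frame with `injection_id` and
#'   `area` columns).
#' @param injection one row of a `cw_injections` data frame.
#' @param areas integer vector fixing the source-area universe.
#' @return Named numeric vector of FLNe values over `areas`.
#' @export
compute_flne <- function(cells, injection, areas) {
  counts <- cell_counts(cells, injection$id, areas)
  target <- as.character(injection$area)
  extr <- counts
  extr[target] <- 0
  total <- sum(extr)
  if (total == 0)
    stop("FLNe undefined: no extrinsic labeled cells for injection ",
         injection$id)
  flne <- extr / total
  flne[target] <- NA_real_
  flne
}

#' Fraction of supragranular labeled neurons (SLN)
#'
#' For one injection, the SLN of source area B is the number of supragranular
#' labeled neurons in B divided by all labeled neurons in B. The value is
#' undefined (`NA`) for projections with no labeled cells and for source
#' areas lacking a discernible layer 4, whose cells carry no laminar
#' assignment.
#'
#' @inheritParams compute_flne
#' @param no_layer4 area ids for which SLN is undefined.
#' @return Named numeric vector of SLN values over `areas`.
#' @export
compute_sln <- function(cells, injection, areas, no_layer4 = integer(0)) {
  sub <- cells[cells$injection_id == injection$id, , drop = FALSE]
  key <- as.character(areas)
  supra <- table(factor(sub$area[sub$lamina == "supra"], levels = areas))
  infra <- table(factor(sub$area[sub$lamina == "infra"], levels = areas))
  supra <- setNames(as.numeric(supra), key)
  infra <- setNames(as.numeric(infra), key)
  tot <- supra + infra
  sln <- ifelse(tot > 0, supra / tot, NA_real_)
  sln[key %in% as.character(no_layer4)] <- NA_real_
  setNames(sln, key)
}

#' Quantify connectivity matrices from cells and injections
#'
#' Computes per-injection raw counts, FLNe and SLN vectors, then aggregates
#' them by injected (target) area: mean FLNe over all injections into the
#' area — counting a projection not observed in an injection as 0, so that
#' means are not biased upward (set `unobserved = "na"` to average over
#' observing injections only) — and pooled SLN, summing supra- and
#' infragranular counts across the injections in which the projection was
#' observed before forming the ratio.
#'
#' @param cells a `cw_cells` table.
#' @param injections a `cw_injections` data frame.
#' @param areas integer vector of all area ids (e.g. `tpl$area_ids`).
#' @param no_layer4 area ids for which SLN is undefined.
#' @param unobserved how the FLNe mean treats projections absent from an
#'   injection: `"zero"` (default) or `"na"`.
#' @return An object of class `cw_connmat`: source x target matrices
#'   `counts`, `flne`, `sln`, logical `observed`, and a `per_injection` list.
#'   Diagonals (intrinsic connections) are `NA` in `flne` and `sln`.
#' @export
quantify_connectivity <- function(cells, injections, areas,
                                  no_layer4 = integer(0),
                                  unobserved = c("zero", "na")) {
  unobserved <- match.arg(unobserved)
  key <- as.character(areas)
  per_injection <- lapply(seq_len(nrow(injections)), function(i) {
    inj <- injections[i, , drop = FALSE]
    sub <- cells[cells$injection_id == inj$id, , drop = FALSE]
    counts <- cell_counts(cells, inj$id, areas)
    supra <- setNames(as.numeric(table(factor(
      sub$area[sub$lamina == "supra"], levels = areas))), key)
    infra <- setNames(as.numeric(table(factor(
      sub$area[sub$lamina == "infra"], levels = areas))), key)
    list(id = inj$id, target = inj$area,
         counts = counts, supra = supra, infra = infra,
         flne = compute_flne(cells, inj, areas),
         sln = compute_sln(cells, inj, areas, no_layer4))
  })
  names(per_injection) <- injections$id

  targets <- sort(unique(injections$area))
  tkey <- as.character(targets)
  counts <- matrix(0, length(areas), length(targets), dimnames = list(key, tkey))
  flne <- matrix(NA_real_, length(areas), length(targets), dimnames = list(key, tkey))
  sln <- matrix(NA_real_, length(areas), length(targets), dimnames = list(key, tkey))
  observed <- matrix(FALSE, length(areas), length(targets), dimnames = list(key, tkey))

  for (t in seq_along(targets)) {
    pis <- per_injection[injections$area == targets[t]]
    cmat <- vapply(pis, `[[`, numeric(length(areas)), "counts")
    fmat <- vapply(pis, `[[`, numeric(length(areas)), "flne")
    smat <- vapply(pis, `[[`, numeric(length(areas)), "supra")
    imat <- vapply(pis, `[[`, numeric(length(areas)), "infra")
    counts[, t] <- rowSums(cmat)
    observed[, t] <- rowSums(cmat) > 0
    if (unobserved == "zero") {
      # absent projection counted as FLNe 0 (intrinsic rows remain NA)
      fmat[is.na(fmat) & cmat == 0] <- 0
      fmat[as.character(targets[t]), ] <- NA_real_
      flne[, t] <- rowMeans(fmat)
    } else {
      # average over the injections in which the projection was observed
      fmat[cmat == 0] <- NA_real_
      flne[, t] <- suppressWarnings(rowMeans(fmat, na.rm = TRUE))
      flne[is.nan(flne[, t]), t] <- NA_real_
    }
    # pooled SLN over injections where the projection was observed
    seen <- cmat > 0
    s_tot <- rowSums(smat * seen)
    i_tot <- rowSums(imat * seen)
    sln[, t] <- ifelse(s_tot + i_tot > 0, s_tot / (s_tot + i_tot), NA_real_)
    sln[key %in% as.character(no_layer4), t] <- NA_real_
    sln[as.character(targets[t]), t] <- NA_real_
  }

  structure(list(
    counts = counts, flne = flne, sln = sln, observed = observed,
    per_injection = per_injection, areas = areas, targets = targets,
    no_layer4 = no_layer4, unobserved = unobserved
  ), class = "cw_connmat")
}

#' @export
print.cw_connmat <- function(x, ...) {
  cat("cw_connmat:", length(x$areas), "source areas x", length(x$targets),
      "injected areas,", length(x$per_injection), "injections\n")
  invisible(x)
}

#' Order areas by hierarchical clustering of connectivity profiles
#'
#' Areas with similar connectivity profiles are placed adjacent to each
#' other: rows of the matrix are log-transformed (`log10(x + 1e-6)`, with
#' missing entries treated as 0 beforehand), their correlation distance
#' (1 - Pearson r) is clustered with average linkage, and the dendrogram
#' leaf order is returned. Deterministic given the matrix.
#'
#' @param m numeric matrix with one row per area (e.g. `t(conn$flne)` or
#'   `conn$flne` depending on which margin is being ordered); row names
#'   identify the areas.
#' @return Integer permutation of row indices, with the row names as names.
#' @export
cluster_order <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 areas to order")
  m[is.na(m)] <- 0
  lm10 <- log10(m + 1e-6)
  cc <- suppressWarnings(cor(t(lm10)))
  cc[!is.finite(cc)] <- 0
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "average")
  setNames(hc$order, rownames(m)[hc$order])
}
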