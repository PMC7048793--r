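#' Labeled template volumes
#'
#' A template volume is a 3D integer label grid in which 0 marks voxels
#' outside the brain, 1 marks white matter, and codes >= 2 mark cortical
#' areas. A parallel laminar grid records, for every gray-matter voxel,
#' whether it lies in the supragranular or infragranular compartment of the
#' cortical sheet. World coordinates are millimetres; the voxel with index
#' (1,1,1) has its center at `origin`, and axes are aligned with the grid.
#'
#' @param labels integer 3D array of label codes.
#' @param voxel_size numeric length-3, mm per voxel along each axis.
#' @param lamina integer 3D array (0 = none, 1 = supra, 2 = infra), same
#'   dimensions as `labels`.
#' @param origin mm coordinate of the center of voxel (1,1,1). Defaults to
#'   `voxel_size / 2` so that world coordinates start at the grid corner.
#' @param midthickness n x 3 matrix of mm points sampling the mid-thickness
#'   surface of the cortical sheet, or `NULL`.
#' @param area_names optional named character vector mapping label codes
#'   (as names) to area names.
#' @return An object of class `cw_template`.
#' @export
template_volume <- function(labels, voxel_size, lamina = NULL, origin = NULL,
                            midthickness = NULL, area_names = NULL) {
  stopifnot(length(dim(labels)) == 3, length(voxel_size) == 3)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  storage.mode(labels) <- "integer"
  if (is.null(lamina)) {
    lamina <- array(0L, dim(labels))
  }
  storage.mode(lamina) <- "integer"
  if (!identical(dim(lamina), dim(labels)))
    stop("lamina grid must match label grid dimensions")
  origin <- origin %||% (voxel_size / 2)
  ids <- sort(unique(as.integer(labels[labels >= 2L])))
  if (is.null(area_names)) {
    area_names <- setNames(paste0("A", ids), as.character(ids))
  }
  structure(list(
    labels = labels,
    lamina = lamina,
    voxel_size = as.numeric(voxel_size),
    origin = as.numeric(origin),
    midthickness = midthickness,
    area_ids = ids,
    area_names = area_names
  ), class = "cw_template")
}

#' @export
print.cw_template <- function(x, ...) {
  cat("cw_template:", paste(dim(x$labels), collapse = " x "),
      "voxels,", length(x$area_ids), "areas, voxel",
      paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  invisible(x)
}

#' @rdname template_volume
#' @param x a `cw_template`.
#' @export
affine_matrix <- function(x) {
  A <- diag(4)
  diag(A)[1:3] <- x$voxel_size
  # maps 0-based voxel indices to world mm
  A[1:3, 4] <- x$origin
  A
}

# world mm -> 1-based voxel indices (matrix in, matrix out)
world_to_voxel <- function(obj, p) {
  p <- rbind(p)
  idx <- sweep(sweep(p, 2, obj$origin, "-"), 2, obj$voxel_size, "/")
  round(idx) + 1L
}

# 1-based voxel indices -> world mm of voxel centers
voxel_to_world <- function(obj, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, obj$voxel_size, "*"), 2, obj$origin, "+")
}

# world mm -> the grid-corner frame assumed by the C++ kernels, in which the
# center of 0-based voxel i is (i + 0.5) * h
to_grid_mm <- function(obj, p) {
  p <- rbind(p)
  sweep(p, 2, obj$origin - obj$voxel_size / 2, "-")
}

from_grid_mm <- function(obj, p) {
  p <- rbind(p)
  sweep(p, 2, obj$origin - obj$voxel_size / 2, "+")
}

in_grid <- function(obj, ijk) {
  d <- dim(obj$labels %||% obj$speed)
  ijk <- rbind(ijk)
  ok <- ijk[, 1] >= 1 & ijk[, 2] >= 1 & ijk[, 3] >= 1 &
    ijk[, 1] <= d[1] & ijk[, 2] <= d[2] & ijk[, 3] <= d[3]
  ok & !is.na(ok)
}

# label at world positions; NA outside the grid
label_at <- function(tpl, p) {
  ijk <- world_to_voxel(tpl, p)
  ok <- in_grid(tpl, ijk)
  out <- rep(NA_integer_, nrow(ijk))
  if (any(ok)) out[ok] <- tpl$labels[ijk[ok, , drop = FALSE]]
  out
}

# 1-based indices (n x 3) of voxels where `what` is TRUE
which_voxels <- function(what) {
  which(what, arr.ind = TRUE)
}

# mm centers of all voxels carrying a given label
voxel_centers_of <- function(tpl, label) {
  ijk <- which_voxels(tpl$labels == label)
  voxel_to_world(tpl, ijk)
}

# logical 3D array marking voxels of `mask` that touch (26-adjacency) a voxel
# outside `mask` (or the grid edge)
# 6-neighbour dilation of a logical mask
dilate_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      if (s == 1L) { src[[a]] <- 1:(d[a] - 1); dst[[a]] <- 2:d[a] }
      else { src[[a]] <- 2:d[a]; dst[[a]] <- 1:(d[a] - 1) }
      shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
      out <- out | shifted
    }
  }
  out
}

boundary_of_mask <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      shifted <- array(FALSE, d)
      src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      if (s == 1L) { src[[a]] <- 1:(d[a] - 1); dst[[a]] <- 2:d[a] }
      else { src[[a]] <- 2:d[a]; dst[[a]] <- 1:(d[a] - 1) }
      shifted[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
      interior <- interior & shifted
    }
  }
  mask & !interior
}

# gray-matter volume (mm^3) per area
area_volumes <- function(tpl) {
  vox <- prod(tpl$voxel_size)
  tab <- table(tpl$labels[tpl$labels >= 2L])
  setNames(as.numeric(tab) * vox, names(tab))
}
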