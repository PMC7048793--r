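#' Write and read label volumes as NIfTI-1
#'
#' The template's integer label grid is stored as a NIfTI-1 volume whose
#' sform affine maps 0-based voxel indices to mm (diagonal scaling by the
#' voxel size, possibly anisotropic). The laminar grid is written alongside
#' as `<stem>_lamina.nii`, and the area dictionary as `<stem>_areas.json`.
#'
#' @param tpl a `cw_template`.
#' @param path output path for the label volume (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(tpl, path) {
  stopifnot(inherits(tpl, "cw_template"))
  aff <- affine_matrix(tpl)
  as_img <- function(arr) {
    attr(arr, "pixdim") <- tpl$voxel_size
    img <- RNifti::asNifti(arr, datatype = "int32")
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    img
  }
  RNifti::writeNifti(as_img(tpl$labels), path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  if (!all(tpl$lamina == 0L)) {
    RNifti::writeNifti(as_img(tpl$lamina), paste0(stem, "_lamina.nii"))
  }
  jsonlite::write_json(as.list(tpl$area_names),
                       paste0(stem, "_areas.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_volume
#' @param mirror_lr flip the first (left-right) axis on import, for data
#'   acquired in the opposite hemisphere. Off by default.
#' @return For `read_label_volume`, a `cw_template`.
#' @export
read_label_volume <- function(path, mirror_lr = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D label volume")
  arr <- array(as.vector(arr), dim(arr)) # strip image attributes
  if (any(arr != round(arr)))
    stop("label volume must contain integer codes (found non-integer data)")
  aff <- RNifti::xform(img)
  # accept axis-aligned affines only; per-axis voxel size from the diagonal
  offdiag <- aff[1:3, 1:3]; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6))
    stop("only axis-aligned (diagonal) affines are supported")
  scales <- diag(aff)[1:3]
  voxel_size <- abs(scales)
  if (any(voxel_size <= 0)) stop("missing or degenerate affine")
  origin <- aff[1:3, 4]
  # fold axis flips (negative scales, as in RAS-converted affines) into the
  # array so that the internal frame always has positive spacing
  for (a in which(scales < 0)) {
    idx <- list(seq_len(dim(arr)[1]), seq_len(dim(arr)[2]), seq_len(dim(arr)[3]))
    idx[[a]] <- rev(idx[[a]])
    arr <- arr[idx[[1]], idx[[2]], idx[[3]]]
    origin[a] <- origin[a] + scales[a] * (dim(arr)[a] - 1)
  }
  if (mirror_lr) {
    arr <- arr[rev(seq_len(dim(arr)[1])), , ]
  }
  storage.mode(arr) <- "integer"

  stem <- sub("\\.nii(\\.gz)?$", "", path)
  lam <- NULL
  lam_path <- paste0(stem, "_lamina.nii")
  if (file.exists(lam_path)) {
    lam <- as.array(RNifti::readNifti(lam_path))
    lam <- array(as.vector(lam), dim(lam))
    storage.mode(lam) <- "integer"
    if (mirror_lr) lam <- lam[rev(seq_len(dim(lam)[1])), , ]
  }
  area_names <- NULL
  dict_path <- paste0(stem, "_areas.json")
  if (file.exists(dict_path)) {
    dict <- jsonlite::read_json(dict_path)
    area_names <- setNames(unlist(dict), names(dict))
  }
  template_volume(arr, voxel_size, lamina = lam, origin = origin,
                  area_names = area_names)
}

CELL_COLUMNS <- c("injection_id", "tracer", "x_mm", "y_mm", "z_mm",
                  "area", "lamina")
LAMINA_TOKENS <- c("supra", "infra", "none")

#' Read and write labeled-cell tables
#'
#' Cell tables are UTF-8 comma-separated files with a mandatory header and
#' columns `injection_id, tracer, x_mm, y_mm, z_mm, area, lamina`
#' (coordinates in mm, `lamina` one of `supra`/`infra`/`none`). Readers
#' reject rather than coerce: missing columns, non-numeric or non-finite
#' coordinates, unknown lamina tokens, and (when an area dictionary is
#' supplied) unknown areas all raise errors naming the offending rows.
#'
#' @param path CSV file path.
#' @param area_dict optional vector of valid area identifiers; rows with
#'   areas outside it are rejected.
#' @param column_map optional named character vector mapping the expected
#'   column names (names) to the file's column names (values), for importing
#'   spreadsheets with a different dialect.
#' @return A `cw_cells` data frame.
#' @export
read_cell_table <- function(path, area_dict = NULL, column_map = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(raw))
        stop("mapped column not found in file: ", column_map[[std]])
      names(raw)[names(raw) == column_map[[std]]] <- std
    }
  }
  missing_cols <- setdiff(CELL_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  cells <- raw[, CELL_COLUMNS]
  for (cc in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(cells[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop("non-numeric or non-finite ", cc, " in row(s): ",
           paste(head(bad, 5), collapse = ", "))
    cells[[cc]] <- v
  }
  bad <- which(!cells$lamina %in% LAMINA_TOKENS)
  if (length(bad) > 0)
    stop("unknown lamina token ", dQuote(cells$lamina[bad[1]]),
         " in row(s): ", paste(head(bad, 5), collapse = ", "))
  if (!is.null(area_dict)) {
    bad <- which(!as.character(cells$area) %in% as.character(area_dict))
    if (length(bad) > 0)
      stop("unknown area ", dQuote(cells$area[bad[1]]), " in row(s): ",
           paste(head(bad, 5), collapse = ", "))
  }
  class(cells) <- c("cw_cells", "data.frame")
  cells
}

#' @rdname read_cell_table
#' @param cells a `cw_cells` data frame.
#' @export
write_cell_table <- function(cells, path) {
  write.csv(as.data.frame(cells)[, CELL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read and write injection lists
#'
#' Injection lists are CSV files with columns `id, tracer, x_mm, y_mm, z_mm,
#' area, volume_mm3, exclusion_radius_mm`. Duplicate injection ids and
#' non-finite coordinates or radii are rejected.
#'
#' @param path CSV file path.
#' @return A `cw_injections` data frame.
#' @export
read_injections <- function(path) {
  inj <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "tracer", "x_mm", "y_mm", "z_mm", "area",
            "volume_mm3", "exclusion_radius_mm")
  missing_cols <- setdiff(need, names(inj))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(inj$id))
    stop("duplicate injection id(s): ",
         paste(unique(inj$id[duplicated(inj$id)]), collapse = ", "))
  num <- c("x_mm", "y_mm", "z_mm", "volume_mm3", "exclusion_radius_mm")
  for (cc in num) {
    v <- suppressWarnings(as.numeric(inj[[cc]]))
    if (any(!is.finite(v))) stop("non-finite values in column ", cc)
    inj[[cc]] <- v
  }
  if (any(inj$exclusion_radius_mm < 0))
    stop("negative exclusion radius")
  class(inj) <- c("cw_injections", "data.frame")
  inj
}

#' @rdname read_injections
#' @param injections a `cw_injections` data frame.
#' @export
write_injections <- function(injections, path) {
  keep <- c("id", "tracer", "x_mm", "y_mm", "z_mm", "area",
            "volume_mm3", "exclusion_radius_mm")
  write.csv(as.data.frame(injections)[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Write a connectivity matrix in portal layout
#'
#' Rows are source areas, columns are injected (target) areas; projections
#' that were not detected are left empty, and the diagonal (intrinsic
#' connections, not evaluated) carries the sentinel `"intrinsic"`.
#'
#' @param conn a `cw_connmat`.
#' @param path output CSV path.
#' @param what which matrix to write: `"flne"`, `"sln"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(conn, path, what = c("flne", "sln", "counts")) {
  what <- match.arg(what)
  m <- conn[[what]]
  out <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  det <- conn$observed
  out[det] <- format(m[det], trim = TRUE, digits = 8)
  out[det & is.na(m)] <- "" # e.g. SLN of a no-layer-4 source
  for (tk in colnames(m)) if (tk %in% rownames(m)) out[tk, tk] <- "intrinsic"
  df <- data.frame(source = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an interareal distance matrix and its QC table
#'
#' The distance matrix is written as an area x area CSV (mm); the companion
#' QC table lists, per unordered pair, the forward and reverse trajectory
#' lengths and the direction discrepancy.
#'
#' @param dmat a `cw_distmat`.
#' @param path output CSV path for the matrix.
#' @param qc_path optional output path for the per-pair QC table.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dmat, path, qc_path = NULL) {
  df <- data.frame(area = rownames(dmat$d), dmat$d, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(qc_path)) {
    ut <- which(upper.tri(dmat$d), arr.ind = TRUE)
    qc <- data.frame(
      area_i = rownames(dmat$d)[ut[, 1]],
      area_j = colnames(dmat$d)[ut[, 2]],
      d_fwd = dmat$d_dir[ut],
      d_rev = t(dmat$d_dir)[ut],
      d_mean = dmat$d[ut],
      discrepancy = dmat$discrepancy[ut]
    )
    write.csv(qc, qc_path, row.names = FALSE)
  }
  invisible(path)
}

# small stable polynomial hash of a string, for provenance fingerprints
config_fingerprint <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a provenance sidecar
#'
#' Every pipeline output directory gets a JSON sidecar recording the full
#' configuration, the seed, the package version, and a fingerprint of the
#' configuration, so a run can be reproduced exactly from its sidecar.
#'
#' @param path output JSON path.
#' @param config the run configuration (a list).
#' @param seed the seed used.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed) {
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(list(
    package = "cortexwire",
    version = as.character(utils::packageVersion("cortexwire")),
    seed = seed,
    config_hash = config_fingerprint(cfg_json),
    config = config
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
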