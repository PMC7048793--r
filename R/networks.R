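#' Default functional-network table of the marmoset cortex
#'
#' Five groups of areas corresponding to functional networks identified by
#' neuroimaging: the primary sensorimotor network (Pri), a higher-order
#' somatomotor network (HOSom), a visuomotor integration network (VisM), the
#' cognitive control network (CON, a putative homolog of default mode network
#' B), and the apex transmodal network (APEX, a putative homolog of default
#' mode network A).
#'
#' @return Named list of character vectors of area names (disjoint).
#' @export
default_network_table <- function() {
  list(
    Pri = c("A3a", "A3b", "A4ab", "A4c"),
    HOSom = c("A6DC", "A6M", "A6Va", "A24d", "PF"),
    VisM = c("LIP", "VIP", "PEC", "A8aV", "A8C"),
    CON = c("A8aD", "A6DR", "PGM", "A23b", "OPt", "PG"),
    APEX = c("A10", "A23a", "TPO", "PGa/IPa", "TE3")
  )
}

validate_network_table <- function(networks) {
  if (length(networks) == 0 || any(lengths(networks) == 0))
    stop("network table must be a nonempty list of nonempty area vectors")
  all_areas <- unlist(networks)
  if (anyDuplicated(all_areas))
    stop("network area lists must be disjoint")
  invisible(networks)
}

#' Local-to-distant connectivity ratio of an injection
#'
#' Fraction of labeled neurons within `thresholds[1]` mm of the injection
#' center (local connections) divided by the fraction beyond `thresholds[2]`
#' mm (distant connections). Distances default to the wiring metric used by
#' [cell_based_cd()] (mid-thickness projection, geodesic tract length);
#' Euclidean distances are selectable. Cells between the two thresholds
#' belong to neither class, so the fractions need not sum to 1. If no cell
#' lies beyond the distant threshold the ratio is infinite and flagged.
#'
#' @param injection one row of a `cw_injections` data frame.
#' @param cells a `cw_cells` table.
#' @param tpl,cost template and cost field (required for the wiring metric).
#' @param metric `"wiring"` (default) or `"euclidean"`.
#' @param thresholds numeric length-2, local and distant cutoffs in mm.
#' @param distances optional precomputed per-cell distances (mm) to the
#'   injection center, bypassing the metric computation.
#' @return One-row data frame: `injection_id`, `area`, `n_cells`,
#'   `frac_local`, `frac_distant`, `ratio`, `infinite`.
#' @export
local_distant_ratio <- function(injection, cells, tpl = NULL, cost = NULL,
                                metric = c("wiring", "euclidean"),
                                thresholds = c(4, 8), distances = NULL) {
  metric <- match.arg(metric)
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  sub <- cells[cells$injection_id == injection$id, , drop = FALSE]
  if (nrow(sub) == 0) stop("no labeled cells for injection ", injection$id)
  center <- c(injection$x_mm, injection$y_mm, injection$z_mm)
  if (is.null(distances)) {
    pts <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
    if (metric == "euclidean") {
      distances <- sqrt(rowSums(sweep(pts, 2, center)^2))
    } else {
      if (is.null(tpl) || is.null(cost))
        stop("wiring metric requires tpl and cost")
      center_proj <- project_to_midthickness(center, tpl)[1, ]
      proj <- project_to_midthickness(pts, tpl)
      at <- solve_arrival_time(cost, center_proj)
      distances <- trace_lengths(at, proj)$length_mm
    }
  }
  distances <- distances[!is.na(distances)]
  n <- length(distances)
  frac_local <- mean(distances <= thresholds[1])
  frac_distant <- mean(distances > thresholds[2])
  inf <- frac_distant == 0
  data.frame(
    injection_id = injection$id,
    area = injection$area,
    n_cells = n,
    frac_local = frac_local,
    frac_distant = frac_distant,
    ratio = if (inf) Inf else frac_local / frac_distant,
    infinite = inf,
    stringsAsFactors = FALSE
  )
}

#' Dunn's post-hoc pairwise rank test
#'
#' All pairwise z-tests on mean ranks following a Kruskal-Wallis test, with
#' the usual tie correction and a multiplicity adjustment (Holm by default).
#'
#' @param x numeric response values.
#' @param g grouping factor.
#' @param method a [stats::p.adjust()] method, or `"none"`.
#' @return Data frame with columns `group1`, `group2`, `z`, `p`, `p_adj`,
#'   `signif` (significance tier: `***` p <= 1e-3, `**` p <= 1e-2,
#'   `*` p <= 0.05).
#' @export
dunn_test <- function(x, g, method = "holm") {
  g <- factor(g)
  ok <- is.finite(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  p_adj <- p.adjust(p, method = method)
  tier <- function(p) ifelse(p <= 1e-3, "***", ifelse(p <= 1e-2, "**",
                      ifelse(p <= 0.05, "*", "")))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = z, p = p, p_adj = p_adj, signif = tier(p_adj),
             stringsAsFactors = FALSE)
}

#' Compare local/distant ratios across functional networks
#'
#' Assigns each injection's ratio record to a network by its injected area,
#' then tests for differences across networks with the tie-corrected
#' Kruskal-Wallis H test, followed by Dunn's pairwise post-hoc tests.
#' Infinite ratios (injections with no distant cells) are excluded and
#' logged; networks with fewer than two finite records are excluded with a
#' warning.
#'
#' @param records data frame of ratio records from [local_distant_ratio()]
#'   (rows bound together); must have columns `area` and `ratio`. Areas may
#'   be ids or names matching the network table entries.
#' @param networks named list mapping network name to area vector; default
#'   [default_network_table()].
#' @param dunn_method multiplicity adjustment for Dunn's test.
#' @return An object of class `cw_network_test`: list with `H`, `df`, `p`,
#'   `dunn` (data frame), `group_sizes`, `excluded_infinite` (injection ids),
#'   `excluded_networks`, and the annotated `records`.
#' @export
compare_networks <- function(records, networks = default_network_table(),
                             dunn_method = "holm") {
  validate_network_table(networks)
  area2net <- rep(names(networks), lengths(networks))
  names(area2net) <- as.character(unlist(networks))
  records$network <- area2net[as.character(records$area)]
  records <- records[!is.na(records$network), , drop = FALSE]
  if (nrow(records) == 0) stop("no records map to any network")

  inf_ids <- records$injection_id[!is.finite(records$ratio)]
  finite <- records[is.finite(records$ratio), , drop = FALSE]

  sizes <- table(finite$network)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0)
    warning("excluding network(s) with fewer than 2 records: ",
            paste(small, collapse = ", "))
  finite <- finite[!finite$network %in% small, , drop = FALSE]
  if (length(unique(finite$network)) < 2)
    stop("need at least 2 networks with at least 2 records each")

  g <- factor(finite$network)
  kw <- kruskal.test(finite$ratio, g)
  dunn <- dunn_test(finite$ratio, g, method = dunn_method)

  structure(list(
    H = unname(kw$statistic),
    df = unname(kw$parameter),
    p = kw$p.value,
    dunn = dunn,
    group_sizes = table(g),
    excluded_infinite = inf_ids,
    excluded_networks = small,
    records = records
  ), class = "cw_network_test")
}

#' @export
print.cw_network_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.2f, df = %d, p = %.3g (%d groups)\n",
              x$H, x$df, x$p, length(x$group_sizes)))
  if (length(x$excluded_infinite) > 0)
    cat("  excluded", length(x$excluded_infinite), "infinite ratio(s)\n")
  print(x$dunn, digits = 3)
  invisible(x)
}
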