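# Independent 26-neighbour Dijkstra oracle (igraph) for validating the
# fast-marching solver. Edge weight = mean slowness along the edge (sampled
# at 5 points so diagonal edges cannot tunnel through slow voxels) times the
# edge length; the oracle geodesic length is the physical length of the
# minimum-time lattice path.

dijkstra_oracle <- function(speed, h, seed_vox) {
  d <- dim(speed)
  nid <- array(seq_len(prod(d)), d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  edges <- NULL; wts <- NULL; lens <- NULL
  idx <- which(speed > 0, arr.ind = TRUE)
  slow <- array(Inf, d); slow[speed > 0] <- 1 / speed[speed > 0]
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- sweep(idx, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    a <- idx[ok, , drop = FALSE]; b <- nb[ok, , drop = FALSE]
    keep <- speed[b] > 0
    a <- a[keep, , drop = FALSE]; b <- b[keep, , drop = FALSE]
    msl <- rep(0, nrow(a))
    for (fr in seq(0, 1, length.out = 5)) {
      sm <- round(a + fr * (b - a))
      msl <- msl + slow[sm]
    }
    msl <- msl / 5
    ok2 <- is.finite(msl)
    a <- a[ok2, , drop = FALSE]; b <- b[ok2, , drop = FALSE]; msl <- msl[ok2]
    el <- sqrt(sum((o * h)^2))
    edges <- rbind(edges, cbind(nid[a], nid[b]))
    wts <- c(wts, el * msl)
    lens <- c(lens, rep(el, nrow(a)))
  }
  g <- igraph::make_graph(t(edges), n = prod(d), directed = FALSE)
  igraph::E(g)$weight <- wts
  igraph::E(g)$len <- lens
  s <- nid[rbind(seed_vox)]
  list(g = g,
       times = as.vector(igraph::distances(g, v = s, algorithm = "dijkstra")),
       nid = nid, seed = s)
}

oracle_time <- function(or, target_vox) {
  or$times[or$nid[rbind(target_vox)]]
}

oracle_path_length <- function(or, target_vox) {
  t <- or$nid[rbind(target_vox)]
  sp <- igraph::shortest_paths(or$g, from = or$seed, to = t, output = "epath")
  sum(igraph::E(or$g)$len[sp$epath[[1]]])
}

# brute-force signed-distance-transform centroid: for every mask voxel, the
# exact distance to the nearest complement voxel center (grid boundary counts
# as complement); returns the mm coordinate of the (first) argmax
brute_centroid <- function(mask, h) {
  d <- dim(mask)
  inside <- which(mask, arr.ind = TRUE)
  outside <- which(!mask, arr.ind = TRUE)
  best <- -Inf; arg <- NULL
  for (r in seq_len(nrow(inside))) {
    v <- inside[r, ]
    d_out <- if (nrow(outside) > 0)
      sqrt(min(colSums((t(outside) - v)^2 * h^2))) else Inf
    d_edge <- min(v * h, (d - v + 1) * h)
    sdt <- min(d_out, d_edge)
    if (sdt > best) { best <- sdt; arg <- v }
  }
  unname((arg - 0.5) * h)
}
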