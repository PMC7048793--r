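uniform_cost <- function(n = 30L, h = 0.5, f = 1) {
  structure(list(speed = array(f, rep(n, 3)), voxel_size = rep(h, 3),
                 origin = rep(h / 2, 3), f_WM = f, f_GM = f),
            class = "cw_cost")
}

test_that("cost field maps tissue classes to the stated speeds", {
  tpl <- tiny_template()
  cost <- build_cost_field(tpl)
  expect_equal(cost$f_WM, 1)
  expect_equal(cost$f_GM, 0.05)
  expect_setequal(unique(as.vector(cost$speed)), c(0, 0.05, 1))
  expect_equal(cost$speed[tpl$labels == 1L][1], 1)
  expect_equal(cost$speed[tpl$labels >= 2L][1], 0.05)
  expect_true(all(cost$speed[tpl$labels == 0L] == 0))

  uni <- build_cost_field(tpl, f_WM = 1, f_GM = 1)
  expect_setequal(unique(as.vector(uni$speed)), c(0, 1))

  expect_error(build_cost_field(tpl, f_GM = 0), "f_GM")
  expect_error(build_cost_field(tpl, f_WM = 0.5, f_GM = 0.9), "f_GM")
})

test_that("area centroid maximizes interior depth", {
  h <- rep(0.5, 3)
  # solid ball: centroid is the center voxel
  d <- c(21, 21, 21)
  ctr <- (d / 2) * h
  ijk <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  r <- sqrt(rowSums(sweep(sweep(ijk - 0.5, 2, h, "*"), 2, ctr)^2))
  ball <- array(r <= 4, d)
  expect_equal(area_centroid(ball, h), c(10.5, 10.5, 10.5) * h)

  # L-shaped slab: deepest voxel of the thicker arm, against brute force
  d2 <- c(20, 14, 7)
  L <- array(FALSE, d2)
  L[1:20, 1:4, 1:7] <- TRUE   # thin arm
  L[1:8, 1:14, 1:7] <- TRUE   # thick arm
  expect_equal(area_centroid(L, h), brute_centroid(L, h))

  expect_error(area_centroid(array(FALSE, c(4, 4, 4)), h), "empty")
})

test_that("arrival times in a uniform medium approximate Euclidean distance", {
  cost <- uniform_cost()
  seed <- c(2.25, 2.25, 2.25)
  at <- solve_arrival_time(cost, seed)
  # a point 5 mm away: arrival within 2 voxel diagonals
  p <- seed + c(5, 0, 0)
  expect_lt(abs(cortexwire:::arrival_at(at, p) - 5),
            2 * sqrt(3) * 0.5)
  set.seed(2)
  pts <- matrix(runif(30, 3, 13), ncol = 3)
  tt <- cortexwire:::arrival_at(at, pts)
  vox <- cortexwire:::world_to_voxel(at, pts)
  ex <- sqrt(rowSums(sweep(sweep(vox - 0.5, 2, cost$voxel_size, "*"),
                           2, seed)^2))
  expect_lt(max(abs(tt - ex)), 2 * sqrt(3) * 0.5)
})

test_that("zero-speed regions are impassable and invalid seeds rejected", {
  cost <- uniform_cost(n = 20L)
  cost$speed[10, , ] <- 0 # a full wall
  at <- solve_arrival_time(cost, c(1.25, 1.25, 1.25))
  expect_true(all(!is.finite(at$T[15, , ])))
  cost$speed[1, 1, 1] <- 0
  expect_error(solve_arrival_time(cost, c(0.25, 0.25, 0.25)), "seed")
})

test_that("geodesics follow corridors and measure their length", {
  # straight white-matter corridor through gray surroundings
  d <- c(40, 11, 11); h <- rep(0.5, 3)
  speed <- array(0.05, d)
  speed[, 5:7, 5:7] <- 1
  cost <- structure(list(speed = speed, voxel_size = h, origin = h / 2,
                         f_WM = 1, f_GM = 0.05), class = "cw_cost")
  a <- c(1.25, 2.75, 2.75); b <- c(18.75, 2.75, 2.75)
  at <- solve_arrival_time(cost, a)
  tr <- trace_geodesic(at, b)
  expect_true(tr$converged)
  expect_lt(abs(tr$length_mm - sqrt(sum((b - a)^2))) / sqrt(sum((b - a)^2)),
            0.05)

  # start at the seed: zero length
  expect_equal(trace_geodesic(at, a, keep_path = FALSE)$length_mm, 0)

  # unreachable start errors
  cost2 <- uniform_cost(n = 20L)
  cost2$speed[10, , ] <- 0
  at2 <- solve_arrival_time(cost2, c(1.25, 1.25, 1.25))
  expect_error(trace_geodesic(at2, c(8.25, 1.25, 1.25)), "unreachable")
})

test_that("a U-shaped white channel bends the geodesic around gray", {
  # gray block with a white U-channel (two vertical legs + bottom rung)
  d <- c(25, 25, 9); h <- rep(0.5, 3)
  speed <- array(0.05, d)
  speed[4:6, 3:22, 4:6] <- 1    # left leg
  speed[20:22, 3:22, 4:6] <- 1  # right leg
  speed[4:22, 3:5, 4:6] <- 1    # bottom rung
  cost <- structure(list(speed = speed, voxel_size = h, origin = h / 2,
                         f_WM = 1, f_GM = 0.05), class = "cw_cost")
  a <- c(2.25, 10.25, 2.25) # top of left leg
  b <- c(10.25, 10.25, 2.25) # top of right leg
  at <- solve_arrival_time(cost, a)
  tr <- trace_geodesic(at, b)
  # the path must run down, across, and up: much longer than the straight gap
  expect_gt(tr$length_mm, 2.5 * sqrt(sum((b - a)^2)))
  # most of its length lies inside the channel
  p <- tr$path
  seg <- sqrt(rowSums(diff(p)^2))
  vox <- cortexwire:::world_to_voxel(cost, p)
  in_ch <- cost$speed[vox[-1, , drop = FALSE]] == 1
  expect_gt(sum(seg[in_ch]) / sum(seg), 0.8)
  # and its length matches the Dijkstra oracle path length
  or <- dijkstra_oracle(cost$speed, h, cortexwire:::world_to_voxel(cost, a)[1, ])
  ld <- oracle_path_length(or, cortexwire:::world_to_voxel(cost, b)[1, ])
  expect_lt(abs(tr$length_mm - ld) / ld, 0.10)
})

test_that("the point metric is nonnegative, near-symmetric and triangular", {
  dat <- tiny_dataset()
  cost <- dat$cost
  gm <- which(dat$template$labels >= 2L, arr.ind = TRUE)
  set.seed(3)
  pts <- sweep(gm[sample(nrow(gm), 4), ] - 0.5, 2, cost$voxel_size, "*")

  expect_equal(point_to_point_distance(cost, pts[1, ], pts[1, ]), 0)

  dab <- point_to_point_distance(cost, pts[1, ], pts[2, ])
  dba <- point_to_point_distance(cost, pts[2, ], pts[1, ])
  expect_lt(abs(dab - dba) / ((dab + dba) / 2), 0.1)

  # never shorter than the straight line (up to trace resolution)
  for (i in 2:4) {
    dij <- point_to_point_distance(cost, pts[1, ], pts[i, ])
    expect_gte(dij, sqrt(sum((pts[1, ] - pts[i, ])^2)) - max(cost$voxel_size))
  }

  # triangle inequality within a 2-voxel slack
  d13 <- point_to_point_distance(cost, pts[1, ], pts[3, ])
  d32 <- point_to_point_distance(cost, pts[3, ], pts[2, ])
  expect_lte(dab, d13 + d32 + 2 * max(cost$voxel_size))
})

test_that("uniform-medium arrival error shrinks at least first-order", {
  err_at <- function(n) {
    h <- 10 / n
    cost <- uniform_cost(n = n, h = h)
    seed <- c(0.5, 0.5, 0.5) * h
    at <- solve_arrival_time(cost, seed)
    pts <- rbind(c(8, 7, 6), c(7, 8, 8), c(8.5, 4, 7)) # fixed physical points
    vox <- cortexwire:::world_to_voxel(at, pts)
    tt <- at$T[vox]
    ex <- sqrt(rowSums(sweep(sweep(vox - 0.5, 2, rep(h, 3), "*"), 2, seed)^2))
    max(abs(tt - ex))
  }
  e20 <- err_at(20L)
  e40 <- err_at(40L)
  expect_lt(e40, 0.75 * e20)
})

test_that("interareal distances average both directions and count pairs", {
  dat <- tiny_dataset()
  dm <- dat$dmat
  n <- length(dm$areas)

  ut_idx <- upper.tri(dm$d)
  expect_equal(dm$d[ut_idx], ((dm$d_dir + t(dm$d_dir)) / 2)[ut_idx])
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  ut <- dm$d[upper.tri(dm$d)]
  expect_equal(sum(is.finite(ut)), n_area_pairs(n))
  expect_true(all(ut >= 0))
  # the atlas-scale pair count
  expect_equal(n_area_pairs(116), 6670)
  # discrepancy is the relative direction difference
  i <- 1; j <- 2
  expect_equal(dm$discrepancy[i, j],
               abs(dm$d_dir[i, j] - dm$d_dir[j, i]) / dm$d[i, j])

  expect_error(pairwise_area_distances(dat$template, areas = c(2L, 99L)),
               "empty mask")
})

test_that("arrival times track the Dijkstra oracle in heterogeneous media", {
  # the lattice oracle is an upper bound on travel time (every lattice path
  # is admissible); its own metrication bias is bounded by ~13%
  dat <- tiny_dataset()
  cost <- dat$cost
  gm <- which(dat$template$labels >= 2L, arr.ind = TRUE)
  set.seed(4)
  seedv <- gm[sample(nrow(gm), 1), ]
  at <- solve_arrival_time(cost, (seedv - 0.5) * cost$voxel_size)
  or <- dijkstra_oracle(cost$speed, cost$voxel_size, seedv)
  tg <- gm[sample(nrow(gm), 30), , drop = FALSE]
  far <- sqrt(rowSums(sweep(sweep(tg, 2, seedv), 2, cost$voxel_size, "*")^2)) >= 5
  tg <- tg[far, , drop = FALSE][1:10, , drop = FALSE]
  tf <- at$T[tg]
  td <- oracle_time(or, tg)
  expect_true(all(tf <= 1.06 * td))
  expect_true(all(tf >= 0.85 * td))
})

test_that("mean wiring length grows from the uniform limit with the ratio", {
  tpl <- tiny_template()
  sw <- sensitivity_sweep(tpl, ratios = c(1, 10))
  expect_lte(sw$mean_distance_mm[1], sw$mean_distance_mm[2])
  expect_error(sensitivity_sweep(tpl, ratios = c(0.5, 2)), "ratios")
})
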