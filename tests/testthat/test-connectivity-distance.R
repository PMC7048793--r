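test_that("distance to the nearest primary area is zero inside, minimal outside", {
  dat <- tiny_dataset()
  tpl <- dat$template
  inj <- dat$injections

  # an injection inside a primary area
  expect_equal(distance_to_nearest_primary(inj[1, ], primaries = inj$area[1],
                                           tpl, dat$cost), 0)
  # every injection, when all areas are primary
  for (i in seq_len(nrow(inj)))
    expect_equal(distance_to_nearest_primary(inj[i, ], tpl$area_ids,
                                             tpl, dat$cost), 0)
  expect_error(distance_to_nearest_primary(inj[1, ], integer(0), tpl,
                                           dat$cost), "empty")

  # against brute force over all boundary voxels of the primary area
  prim <- setdiff(tpl$area_ids, inj$area[2])[1]
  d_pkg <- distance_to_nearest_primary(inj[2, ], prim, tpl, dat$cost)
  center <- c(inj$x_mm[2], inj$y_mm[2], inj$z_mm[2])
  at <- solve_arrival_time(dat$cost, center)
  pmask <- array(tpl$labels == prim, dim(tpl$labels))
  bnd <- which(cortexwire:::boundary_of_mask(pmask), arr.ind = TRUE)
  bpts <- sweep(bnd - 0.5, 2, tpl$voxel_size, "*")
  all_len <- cortexwire:::trace_lengths(at, bpts)$length_mm
  # the implementation traces an arrival-time-pruned candidate subset, so it
  # can never undercut the exhaustive minimum, and must land within 2% of it
  expect_gte(d_pkg, min(all_len, na.rm = TRUE) - 1e-9)
  expect_lte(d_pkg, min(all_len, na.rm = TRUE) * 1.02)
})

test_that("area-based connectivity distance is the count-weighted mean", {
  dat <- tiny_dataset()
  dm <- dat$dmat
  inj <- dat$injections[1, ]
  key <- as.character(dat$template$area_ids)

  # all cells in one source
  counts <- setNames(numeric(length(key)), key)
  src <- setdiff(key, as.character(inj$area))[1]
  counts[src] <- 12
  expect_equal(area_based_cd(inj, counts, dm),
               dm$d[as.character(inj$area), src])

  # 75 cells at 2 mm, 25 cells at 10 mm -> 4 mm (synthetic distances)
  fake <- dm
  tk <- as.character(inj$area)
  s1 <- setdiff(key, tk)[1]; s2 <- setdiff(key, tk)[2]
  fake$d[tk, s1] <- 2; fake$d[tk, s2] <- 10
  counts2 <- setNames(numeric(length(key)), key)
  counts2[s1] <- 75; counts2[s2] <- 25
  expect_equal(area_based_cd(inj, counts2, fake), 4)

  # intrinsic-only counts are an error
  counts3 <- setNames(numeric(length(key)), key)
  counts3[tk] <- 50
  expect_error(area_based_cd(inj, counts3, dm), "extrinsic")

  # bounded by the min and max source distance
  cells1 <- dat$cells[dat$cells$injection_id == inj$id, ]
  counts4 <- cortexwire:::cell_counts(dat$cells, inj$id, dat$template$area_ids)
  cd <- area_based_cd(inj, counts4, dm)
  used <- setdiff(names(counts4)[counts4 > 0], tk)
  expect_gte(cd, min(dm$d[tk, used]))
  expect_lte(cd, max(dm$d[tk, used]))
})

test_that("mid-thickness projection matches exhaustive nearest search", {
  tpl <- tiny_template()
  # a surface point projects to itself
  sp <- tpl$midthickness[10, ]
  expect_equal(project_to_midthickness(sp, tpl)[1, ], sp)

  # arbitrary gray points match brute force
  gm <- which(tpl$labels >= 2L, arr.ind = TRUE)
  set.seed(5)
  pts <- sweep(gm[sample(nrow(gm), 20), ] - 0.5, 2, tpl$voxel_size, "*")
  proj <- project_to_midthickness(pts, tpl)
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(tpl$midthickness) - pts[i, ])^2)
    expect_equal(attr(proj, "index")[i], which.min(d2))
  }

  # deterministic tie-break: the lowest vertex index wins
  tpl2 <- tpl
  tpl2$midthickness <- rbind(c(1, 1, 1), c(3, 1, 1), c(1, 1, 1))
  p <- project_to_midthickness(c(1, 1, 1.5), tpl2)
  expect_equal(attr(p, "index"), 1L)
})

test_that("cell-based connectivity distance applies projection and exclusion", {
  dat <- tiny_dataset()
  inj <- dat$injections[1, ]
  res <- cell_based_cd(inj, dat$cells, dat$template, dat$cost)
  expect_true(is.finite(res$cd_cell))
  expect_equal(res$cd_cell, mean(res$per_cell$distance_mm))
  # both intrinsic and extrinsic cells contribute
  expect_true(inj$area %in% res$per_cell$area)
  expect_true(any(res$per_cell$area != inj$area))

  # duplicating every cell leaves the mean unchanged
  dup <- rbind(dat$cells, dat$cells)
  class(dup) <- c("cw_cells", "data.frame")
  res2 <- cell_based_cd(inj, dup, dat$template, dat$cost, at = res$at)
  expect_equal(res2$cd_cell, res$cd_cell, tolerance = 1e-12)

  # removing the exclusion zone can only lower (or keep) the mean
  inj0 <- inj; inj0$exclusion_radius_mm <- 0
  res0 <- cell_based_cd(inj0, dat$cells, dat$template, dat$cost, at = res$at)
  expect_lte(res0$cd_cell, res$cd_cell + 1e-12)

  # an exclusion radius swallowing every cell is an error
  injX <- inj; injX$exclusion_radius_mm <- 100
  expect_error(cell_based_cd(injX, dat$cells, dat$template, dat$cost),
               "exclusion")
})

test_that("laminar split separates supra and infra afferent lengths", {
  per_cell <- data.frame(distance_mm = c(4, 4, 8, 8, 6),
                         area = 3L,
                         lamina = c("supra", "supra", "infra", "infra", "none"))
  lam <- laminar_cd_split(per_cell)
  expect_equal(lam$L_supra, 4)
  expect_equal(lam$L_infra, 8)
  expect_equal(lam$ratio, 0.5)

  only_supra <- laminar_cd_split(per_cell[per_cell$lamina == "supra", ])
  expect_true(is.na(only_supra$L_infra))
  expect_true(is.na(only_supra$ratio))
})

test_that("supra and infra lengths agree when drawn from one spatial law", {
  # the phantom places supra and infra cells identically, so the laminar
  # ratio must be ~1 up to sampling error
  dat <- tiny_dataset()
  ratios <- vapply(seq_len(nrow(dat$injections)), function(i) {
    res <- cell_based_cd(dat$injections[i, ], dat$cells, dat$template,
                         dat$cost)
    laminar_cd_split(res$per_cell)$ratio
  }, numeric(1))
  expect_true(all(abs(ratios - 1) < 0.15))
})

test_that("the connectivity-distance GLM recovers exact and planted effects", {
  # exact linear response: raw slope 2, flagged perfect fit
  set.seed(8)
  rec <- data.frame(
    injection_id = sprintf("i%02d", 1:20),
    area = rep(2:5, 5),
    dist_to_primary = runif(20, 0, 10),
    centrality_mm = runif(20, 8, 12),
    area_volume_mm3 = runif(20, 100, 200),
    injection_volume_mm3 = runif(20, 0.1, 1),
    mean_dist_to_cortex_mm = runif(20, 8, 12)
  )
  rec$cd_area <- 2 * rec$dist_to_primary + 3
  rec$cd_cell <- rec$cd_area
  class(rec) <- c("cw_cd_records", "data.frame")
  g <- fit_cd_glm(rec, "cd_area")
  expect_true(g$exact_fit)
  expect_equal(g$beta_raw, 2, tolerance = 1e-8)
  expect_identical(g$F, Inf)

  # duplicated predictor is rejected
  expect_error(fit_cd_glm(rec, "cd_area",
                          predictors = c("dist_to_primary", "centrality_mm")),
               "duplicated")
  # collinear design is rejected
  rec2 <- rec
  rec2$centrality_mm <- 2 * rec2$dist_to_primary
  expect_error(fit_cd_glm(rec2, "cd_area"), "collinear")

  # per-area averaging uses one observation per area
  rec$area <- rep(2:11, 2)
  rec$cd_area <- rec$cd_area + rnorm(20, 0, 0.5)
  g2 <- fit_cd_glm(rec, "cd_area", mode = "per_area_mean")
  expect_equal(g2$n, 10)
})

test_that("the GLM slope test is calibrated under the null", {
  # response independent of dist_to_primary: the slope's CI excludes 0
  # at ~5% rate (a = 0.05, 400 simulations, binomial tolerance)
  set.seed(21)
  n <- 60
  rej <- 0
  for (r in 1:400) {
    rec <- data.frame(
      injection_id = as.character(1:n), area = rep(2:7, 10),
      dist_to_primary = runif(n, 0, 10),
      centrality_mm = rnorm(n, 10),
      area_volume_mm3 = runif(n, 100, 200),
      injection_volume_mm3 = runif(n, .1, 1),
      mean_dist_to_cortex_mm = rnorm(n, 10),
      cd_area = rnorm(n), cd_cell = rnorm(n)
    )
    class(rec) <- c("cw_cd_records", "data.frame")
    g <- fit_cd_glm(rec, "cd_area")
    if (g$ci[1] > 0 || g$ci[2] < 0) rej <- rej + 1
  }
  expect_gt(rej / 400, 0.02)
  expect_lt(rej / 400, 0.09)
})
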