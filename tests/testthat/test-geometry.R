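test_that("signed distance field matches the analytic ball and the sign convention", {
  dm <- c(21L, 21L, 21L)
  cw <- as.matrix(expand.grid(1:21, 1:21, 1:21))
  d <- sqrt(rowSums(sweep(cw, 2, c(11, 11, 11))^2))
  m <- array(d <= 5, dm)
  s <- signed_distance_field(volume_grid(m))

  expect_lt(abs(s$data[11, 11, 11] - (-5)), 1)      # centre of a 5 mm ball
  expect_lt(abs(s$data[18, 11, 11] - 2), 1)         # 7 mm from centre
  expect_true(all(s$data[m] < 0))
  expect_true(all(s$data[!m] > 0))

  # complement: equal magnitude, opposite sign (exact for this convention)
  sc <- signed_distance_field(volume_grid(!m))
  expect_equal(sc$data, -s$data)

  expect_error(signed_distance_field(volume_grid(array(FALSE, dm))), "empty")
  expect_error(signed_distance_field(volume_grid(array(TRUE, dm))), "fills")
})

test_that("fast distance transform agrees with exhaustive search on random masks", {
  for (seed in 1:6) {
    dm <- c(sample(10:14, 1), sample(10:14, 1), sample(10:14, 1))
    sp <- if (seed %% 2 == 0) c(1, 1, 1) else c(0.7, 0.9, 1.3)
    m <- random_blob_mask(dm, seed)
    s <- signed_distance_field(volume_grid(m, sp))
    o <- brute_sdf(m, sp)
    expect_equal(s$data, o, tolerance = 1e-8)
  }
})

test_that("the distance field satisfies the eikonal property away from boundary", {
  an <- small_phantom(1L)
  s <- signed_distance_field(an$vessel)
  g <- s$data
  d <- dim(g)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  gx <- (g[ix + 1, iy, iz] - g[ix - 1, iy, iz]) / 2
  gy <- (g[ix, iy + 1, iz] - g[ix, iy - 1, iz]) / 2
  gz <- (g[ix, iy, iz + 1] - g[ix, iy, iz - 1]) / 2
  gmag <- sqrt(gx^2 + gy^2 + gz^2)
  core <- g[ix, iy, iz]
  # away from the boundary and the medial axis: |grad| ~ 1
  gmag_far <- gmag[core > 2 & core < 15]
  expect_gt(mean(abs(gmag_far - 1) < 0.2), 0.95)
})

test_that("local airway diameter interpolates radii and rejects far queries", {
  pts <- cbind(0, 0, seq(0, 10, by = 1))
  tree <- structure(list(branches = list(list(
    id = 1L, parent = 0L, generation = 0L,
    start = c(0, 0, 0), end = c(0, 0, 10), direction = c(0, 0, 1),
    radius_mm = 3, length_mm = 10, points = pts,
    arc_mm = seq(0, 10, 1), vessel_id = 1L,
    radius_points = seq(2, 4, length.out = 11))),
    spacing_mm = c(1, 1, 1)), class = "centerline_tree")

  expect_equal(local_airway_diameter(tree, c(0, 0, 0)), 4)      # node radius 2
  expect_equal(local_airway_diameter(tree, c(0, 0, 10)), 8)     # node radius 4
  expect_equal(local_airway_diameter(tree, c(0, 0, 5)), 6)      # midpoint: radius 3
  # constant-radius branch: diameter = 2 r anywhere on the branch
  an <- small_phantom(1L)
  b <- an$tree$branches[[2]]
  mid <- (b$start + b$end) / 2
  expect_equal(local_airway_diameter(an$tree, mid), 2 * b$radius_mm)
  expect_error(local_airway_diameter(tree, c(50, 50, 50), max_dist_mm = 5),
               "from the nearest branch")
})

test_that("cross-sections measure lumen and plugged areas", {
  toy <- make_toy_anatomy(r_air = 3)
  p <- toy$tree$branches[[1]]
  mid <- (p$start + p$end) / 2

  cs <- cross_section(toy$airway, NULL, mid, c(0, 0, 1))
  expect_equal(cs$plugged_area_mm2, 0)
  expect_equal(cs$occlusion_ratio, 0)
  # digitized disc area within 10% of pi r^2
  expect_lt(abs(cs$lumen_area_mm2 - pi * 9) / (pi * 9), 0.1)

  full <- cross_section(toy$airway, toy$airway, mid, c(0, 0, 1))
  expect_equal(full$occlusion_ratio, 1.0)

  expect_error(cross_section(toy$airway, NULL, c(1, 1, 1), c(0, 0, 1)),
               "not inside the lumen")
  expect_error(cross_section(toy$airway, NULL, mid, c(0, 0, 0)), "nonzero")
})

test_that("cross-section plugged area is monotone under plug growth", {
  toy <- make_toy_anatomy(r_air = 3)
  mid <- (toy$tree$branches[[1]]$start + toy$tree$branches[[1]]$end) / 2
  geom <- lumen_geometry(toy)
  cfg <- plug_config()
  phen <- structure(list(target_length_mm = 8, target_occlusion_ratio = 0.5,
                         eligible_diameter_mm = 6, distribution = "uniform"),
                    class = "plug_phenotype")
  seed_vox <- geom$idx[which.min(abs(geom$s_mm - 15) + geom$radial_mm)]
  small <- grow_plug(toy, seed_vox, phen, geom)
  phen2 <- phen; phen2$target_occlusion_ratio <- 0.9
  big <- grow_plug(toy, seed_vox, phen2, geom)

  to_mask <- function(p) {
    m <- array(FALSE, dim(toy$airway$data)); m[p$voxels] <- TRUE
    volume_grid(m, toy$airway$spacing)
  }
  cs_small <- cross_section(toy$airway, to_mask(small), mid, c(0, 0, 1))
  cs_big <- cross_section(toy$airway, to_mask(big), mid, c(0, 0, 1))
  expect_gte(cs_big$plugged_area_mm2, cs_small$plugged_area_mm2)
})

test_that("plug length is the arc between extreme centerline projections", {
  toy <- make_toy_anatomy(r_air = 3)
  geom <- lumen_geometry(toy)
  # plug filling the segment s in [10, 20]: length ~10 mm
  vox <- geom$idx[geom$s_mm >= 10 & geom$s_mm <= 20]
  expect_lt(abs(plug_length(vox, toy$tree, toy$airway) - 10), 1)

  # single voxel: one voxel spacing, not zero
  expect_equal(plug_length(geom$idx[1], toy$tree, toy$airway), 1)

  # bent centerline: arc length exceeds chord length
  n <- 21
  th <- seq(0, pi / 2, length.out = n)
  pts <- cbind(10 * cos(th), 0, 10 * sin(th))  # quarter circle, radius 10
  seglen <- sqrt(rowSums(diff(pts)^2))
  bent <- structure(list(branches = list(list(
    id = 1L, parent = 0L, generation = 0L,
    start = pts[1, ], end = pts[n, ], direction = c(0, 0, 1),
    radius_mm = 2, length_mm = sum(seglen), points = pts,
    arc_mm = cumsum(c(0, seglen)), vessel_id = 1L)),
    spacing_mm = c(1, 1, 1)), class = "centerline_tree")
  vol <- volume_grid(array(0L, c(24, 4, 24)), c(1, 1, 1))
  ends <- rbind(c(11, 1, 1), c(1, 1, 11))  # voxels at the two arc ends
  lin <- plugsim:::ijk_to_linear(vol, ends)
  arc <- plug_length(lin, bent, vol)
  chord <- sqrt(sum((pts[n, ] - pts[1, ])^2))
  expect_gt(arc, chord)
  expect_lt(abs(arc - 10 * pi / 2), 1.5)
})
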