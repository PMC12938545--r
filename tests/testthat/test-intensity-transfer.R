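toy_with_two_vessels <- function() {
  make_toy_anatomy(dm = c(44L, 44L, 44L), r_air = 3,
                   vessels = list(list(center_xy = c(30, 21), r = 3),    # 8 mm away
                                  list(center_xy = c(38, 21), r = 3.2))) # 16 mm away
}

grow_toy_plug <- function(toy, occlusion = 1.0, length_mm = 10, s0 = 18) {
  geom <- lumen_geometry(toy)
  seed_vox <- geom$idx[which.min(abs(geom$s_mm - s0) + geom$radial_mm)]
  p <- grow_plug(toy, seed_vox, structure(list(
    target_length_mm = length_mm, target_occlusion_ratio = occlusion,
    eligible_diameter_mm = 6, distribution = "uniform"),
    class = "plug_phenotype"), geom)
  p$label_id <- 1L
  p
}

test_that("companion selection picks the nearest caliber-compatible vessel", {
  toy <- toy_with_two_vessels()
  plug <- grow_toy_plug(toy)
  comp <- find_companion_vessel(toy, plug)
  # the 8 mm vessel wins over the 16 mm one
  lab_at <- toy$vessel_map[30, 21, 22]
  expect_equal(sort(unique(toy$vessel_map[comp$voxels])), lab_at)

  # caliber tolerance: a far-too-large vessel is rejected
  toy_big <- make_toy_anatomy(dm = c(48L, 48L, 44L), r_air = 1.5,
                              vessels = list(list(center_xy = c(34, 23), r = 8)))
  plug_b <- grow_toy_plug(toy_big)
  expect_error(find_companion_vessel(toy_big, plug_b),
               class = "plugsim_no_companion")

  # search radius: nothing within 4 mm
  expect_error(find_companion_vessel(toy, plug, search_radius_mm = 1),
               class = "plugsim_no_companion")
})

test_that("intensity transfer matches depths, preserves off-plug voxels, and is seeded", {
  toy <- toy_with_two_vessels()
  plug <- grow_toy_plug(toy)
  asdf <- signed_distance_field(toy$airway, mask_role = "airway")
  vsdf <- signed_distance_field(toy$vessel, mask_role = "vessel")
  res <- transfer_intensities(toy$ct, toy, plug, airway_sdf = asdf,
                              vessel_sdf = vsdf, seed = 5L)

  # locality: off-plug voxels bit-identical
  off <- setdiff(seq_along(toy$ct$data), plug$voxels)
  expect_identical(res$ct$data[off], toy$ct$data[off])

  # depth matching within tolerance for non-fallback entries
  ok <- !res$map$fallback
  expect_gt(mean(ok), 0.9)
  expect_true(all(res$map$residual_mm[ok] <= 0.5 + 1e-9))
  # matched voxels lie in the vessel mask
  expect_true(all(toy$vessel$data[res$map$vessel_voxel]))

  # noise-free constant-HU vessel: transferred plug is exactly vessel HU
  expect_true(all(res$ct$data[plug$voxels] == 40))

  # determinism under a fixed seed
  res2 <- transfer_intensities(toy$ct, toy, plug, airway_sdf = asdf,
                               vessel_sdf = vsdf, seed = 5L)
  expect_identical(res2$ct$data, res$ct$data)
  expect_identical(res2$map$vessel_voxel, res$map$vessel_voxel)
})

test_that("airways deeper than their vessel fall back to nearest-depth sampling", {
  # wide airway (r 4), narrow-ish vessel (r 2.4, within 50% caliber band):
  # core plug voxels are deeper than any vessel voxel
  toy <- make_toy_anatomy(dm = c(48L, 48L, 44L), r_air = 4,
                          vessels = list(list(center_xy = c(33, 23), r = 2.4)))
  plug <- grow_toy_plug(toy)
  res <- transfer_intensities(toy$ct, toy, plug, seed = 2L)
  expect_gt(sum(res$map$fallback), 0)
  # fallback voxels still textured from the vessel pool
  expect_true(all(res$ct$data[plug$voxels] == 40))
})

test_that("depth-stratified plug HU reproduces the vessel depth profile", {
  # smooth the noise-free phantom so HU varies with depth (partial volume),
  # then check the transferred plug reproduces the vessel's depth profile
  toy <- toy_with_two_vessels()
  ct_s <- volume_grid(plugsim:::gaussian_smooth_3d(toy$ct$data, 0.8),
                      toy$ct$spacing)
  toy_s <- toy; toy_s$ct <- ct_s
  plug <- grow_toy_plug(toy_s)
  asdf <- signed_distance_field(toy$airway); vsdf <- signed_distance_field(toy$vessel)
  res <- transfer_intensities(ct_s, toy_s, plug, airway_sdf = asdf,
                              vessel_sdf = vsdf, seed = 9L)
  comp <- find_companion_vessel(toy_s, plug, vsdf)
  vdep <- vsdf$data[comp$voxels]; vhu <- ct_s$data[comp$voxels]
  pdep <- asdf$data[plug$voxels]; phu <- res$ct$data[plug$voxels]
  for (lo in c(-3, -2, -1)) {
    pi_ <- pdep >= lo & pdep < lo + 1
    vi_ <- vdep >= lo & vdep < lo + 1
    if (sum(pi_) > 10 && sum(vi_) > 10) {
      ks <- suppressWarnings(stats::ks.test(phu[pi_], vhu[vi_])$statistic)
      expect_lt(as.numeric(ks), 0.3)
    }
  }
})

test_that("augmentation draws are bounded, seeded, and smoothing reduces variation", {
  x <- volume_grid(array(rnorm(20^3, sd = 30), c(20, 20, 20)))
  # both ranges degenerate at zero: identity
  same <- apply_augmentation(x, c(0, 0), c(0, 0), seed = 1L)
  expect_identical(same$data, x$data)

  # additive noise with sigma = 5: sample SD of the difference in [4, 6]
  noisy <- apply_augmentation(x, c(0, 0), c(5, 5), seed = 2L)
  expect_true(stats::sd(noisy$data - x$data) > 4 &&
                stats::sd(noisy$data - x$data) < 6)

  # smoothing never increases total variation
  sm <- apply_augmentation(x, c(0.8, 0.8), c(0, 0), seed = 3L)
  expect_lte(total_variation(sm), total_variation(x))

  expect_error(apply_augmentation(x, c(-1, 0), c(0, 0)), "non-negative")
  expect_identical(apply_augmentation(x, seed = 7L)$data,
                   apply_augmentation(x, seed = 7L)$data)
})
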