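make_phenotype <- function(length_mm = 8, occlusion = 0.6, diameter = 6) {
  structure(list(target_length_mm = length_mm,
                 target_occlusion_ratio = occlusion,
                 eligible_diameter_mm = diameter,
                 distribution = "uniform"), class = "plug_phenotype")
}

test_that("phenotypes are sampled uniformly within the configured ranges", {
  cfg <- plug_config()
  set.seed(11)
  draws <- sample_phenotype(cfg, n = 10000L)
  expect_true(all(draws$target_length_mm >= 2 & draws$target_length_mm <= 20))
  expect_true(all(draws$target_occlusion_ratio >= 0.35 &
                    draws$target_occlusion_ratio <= 1))
  expect_true(all(draws$eligible_diameter_mm >= 1 &
                    draws$eligible_diameter_mm <= 20))
  # uniformity: KS test not rejected at alpha = 0.01
  expect_gt(stats::ks.test(draws$target_length_mm, "punif", 2, 20)$p.value, 0.01)
  expect_gt(stats::ks.test(draws$target_occlusion_ratio, "punif", 0.35, 1)$p.value, 0.01)

  # degenerate range is a point mass
  cfg5 <- plug_config(length_range_mm = c(5, 5))
  expect_true(all(sample_phenotype(cfg5, n = 50L)$target_length_mm == 5))
  expect_error(plug_config(length_range_mm = c(7, 3)), "lo <= hi")
})

test_that("seed selection respects caliber eligibility and occupancy", {
  an <- small_phantom(1L)
  geom <- lumen_geometry(an)
  cfg <- plug_config()
  phen <- make_phenotype()

  set.seed(3)
  sv <- select_seed(an, phen, NULL, geom, cfg)
  d <- 2 * geom$branch_radius[geom$branch[match(sv, geom$idx)]]
  expect_gte(d, 1); expect_lte(d, 20)

  # no airway of eligible caliber -> condition
  cfg_narrow <- plug_config(diameter_range_mm = c(18, 20))
  expect_error(select_seed(an, phen, NULL, geom, cfg_narrow),
               class = "plugsim_no_eligible_site")

  # both branches of a one-bifurcation phantom receive seeds
  sp1 <- small_spec(seed = 4L, tree_depth = 1L)
  an1 <- generate_phantom(sp1)
  g1 <- lumen_geometry(an1)
  set.seed(5)
  seeds <- replicate(500, select_seed(an1, phen, NULL, g1, cfg))
  hosts <- g1$branch[match(seeds, g1$idx)]
  expect_setequal(unique(hosts), c(1L, 2L, 3L))
})

test_that("grown plugs honor containment, connectivity, occlusion and length targets", {
  toy <- make_toy_anatomy(dm = c(40L, 40L, 60L), r_air = 3)
  geom <- lumen_geometry(toy)
  seed_vox <- geom$idx[which.min(abs(geom$s_mm - 25) + geom$radial_mm)]

  # full occlusion: every covered cross-section completely plugged
  p_full <- grow_plug(toy, seed_vox, make_phenotype(10, 1.0), geom)
  expect_true(all(p_full$section_ratios == 1.0))

  # straight branch: achieved length within one voxel of the 10 mm target
  expect_lt(abs(p_full$achieved_length_mm - 10), 1 + 1e-9)
  expect_lt(abs(plug_length(p_full, toy$tree, toy$airway) - 10), 1.5)

  # containment in lumen
  expect_true(all(toy$airway$data[p_full$voxels]))

  # partial occlusion: every covered section reaches the target ratio
  p_part <- grow_plug(toy, seed_vox, make_phenotype(12, 0.5), geom)
  expect_true(all(p_part$section_ratios >= 0.5))
  expect_true(all(p_part$section_ratios < 1))

  # 26-connectivity of the voxel set
  m <- array(FALSE, dim(toy$airway$data)); m[p_part$voxels] <- TRUE
  lab <- label_components(m, 26L)
  expect_equal(length(unique(lab[lab > 0])), 1L)

  # deterministic: same inputs, same plug
  p2 <- grow_plug(toy, seed_vox, make_phenotype(12, 0.5), geom)
  expect_identical(p2$voxels, p_part$voxels)

  expect_error(grow_plug(toy, 1L, make_phenotype(), geom), "outside the airway lumen")
})

test_that("populate_scan yields the requested number of disjoint labelled plugs", {
  an <- small_phantom(2L)
  geom <- lumen_geometry(an)

  ps0 <- populate_scan(an, 0L, seed = 1L, geom = geom)
  expect_length(ps0$plugs, 0L)
  expect_true(all(ps0$labels$data == 0L))

  ps <- populate_scan(an, 15L, seed = 1L, geom = geom)
  expect_length(ps$plugs, 15L)
  labs <- ps$labels$data
  expect_setequal(sort(unique(as.vector(labs))), 0:15)

  # pairwise disjoint: each voxel belongs to at most one plug
  all_vox <- unlist(lapply(ps$plugs, `[[`, "voxels"))
  expect_false(anyDuplicated(all_vox) > 0)
  # every labelled voxel lies in the lumen
  expect_true(all(an$airway$data[labs > 0]))

  # achieved occlusion never below the floor at any covered section
  tb <- plug_table(ps)
  expect_true(all(tb$min_section_occlusion >= 0.35))
  # achieved length never exceeds target by more than one voxel
  expect_true(all(tb$length_mm <= tb$target_length_mm + 1 + 1e-9))
})

test_that("plug insertion is reproducible and monotone in the request size", {
  an <- small_phantom(2L)
  geom <- lumen_geometry(an)
  a <- populate_scan(an, 12L, seed = 33L, geom = geom)
  b <- populate_scan(an, 12L, seed = 33L, geom = geom)
  expect_identical(a$labels$data, b$labels$data)

  big <- populate_scan(an, 20L, seed = 33L, geom = geom)
  expect_gte(length(big$plugs), length(a$plugs))
  # common prefix: the first 12 plugs of the larger request are the same
  for (i in seq_len(12L))
    expect_identical(big$plugs[[i]]$voxels, a$plugs[[i]]$voxels)
})

test_that("plugs never exceed their target length by more than one voxel", {
  an <- small_phantom(2L)
  geom <- lumen_geometry(an)
  for (corridor in c("seed", "full")) {
    cfg <- plug_config(corridor = corridor)
    set.seed(17)
    for (i in 1:8) {
      phen <- sample_phenotype(cfg)
      sv <- tryCatch(select_seed(an, phen, NULL, geom, cfg),
                     plugsim_no_eligible_site = function(e) NULL)
      if (is.null(sv)) next
      p <- grow_plug(an, sv, phen, geom, NULL, cfg)
      expect_lte(p$achieved_length_mm, phen$target_length_mm + 1 + 1e-9)
      expect_gte(min(p$section_ratios), phen$target_occlusion_ratio - 1e-9)
    }
  }
})

test_that("saturated anatomies yield fewer plugs with a warning, not an error", {
  sp <- phantom_spec(volume_shape = c(32L, 32L, 32L), tree_depth = 0L,
                     root_radius_mm = 2, branch_length_mm = 12,
                     vessel_offset_mm = 6, seed = 3L)
  an <- generate_phantom(sp)
  expect_warning(ps <- populate_scan(an, 200L, seed = 1L), "saturated")
  expect_lt(length(ps$plugs), 200L)
  expect_gt(length(ps$plugs), 0L)
})
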