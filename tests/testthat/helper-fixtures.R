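# Shared fixtures and independent oracles for the test suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast phantom: 48^3, 3 generations
small_spec <- function(seed = 1L, ...) {
  args <- list(volume_shape = c(48L, 48L, 48L), tree_depth = 3L,
               root_radius_mm = 2.5, branch_length_mm = 11,
               vessel_offset_mm = 7, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

small_phantom <- function(seed = 1L) {
  cached(paste0("small_phantom_", seed), generate_phantom(small_spec(seed)))
}

default_phantom <- function(seed = 1L) {
  cached(paste0("default_phantom_", seed),
         generate_phantom(phantom_spec(seed = seed)))
}

# single straight airway along z plus hand-placed vessel cylinders; used to
# test companion selection and intensity transfer against a fully known
# geometry
make_toy_anatomy <- function(dm = c(40L, 40L, 44L), r_air = 3,
                             vessels = list(list(center_xy = c(29, 20), r = 3)),
                             hu_vessel = 40, spacing = c(1, 1, 1)) {
  cw <- list(x = (seq_len(dm[1]) - 1) * spacing[1],
             y = (seq_len(dm[2]) - 1) * spacing[2],
             z = (seq_len(dm[3]) - 1) * spacing[3])
  ax_xy <- c(cw$x[dm[1] %/% 2], cw$y[dm[2] %/% 2])
  rad2 <- outer((cw$x - ax_xy[1])^2, (cw$y - ax_xy[2])^2, "+")
  z0 <- 4; z1 <- max(cw$z) - 4
  in_z <- cw$z >= z0 & cw$z <= z1
  airway <- array(FALSE, dm)
  airway[, , in_z] <- rep(rad2 <= r_air^2, sum(in_z))
  vessel <- array(FALSE, dm)
  vessel_map <- array(0L, dm)
  for (vi in seq_along(vessels)) {
    v <- vessels[[vi]]
    vr2 <- outer((cw$x - v$center_xy[1])^2, (cw$y - v$center_xy[2])^2, "+")
    vm <- array(FALSE, dm)
    vm[, , in_z] <- rep(vr2 <= v$r^2, sum(in_z))
    vessel <- vessel | vm
    vessel_map[vm] <- vi
  }
  ct <- array(-850, dm)
  ct[airway] <- -1000
  ct[vessel] <- hu_vessel
  npts <- ceiling((z1 - z0) / min(spacing)) + 1L
  zs <- seq(z0, z1, length.out = npts)
  pts <- cbind(ax_xy[1], ax_xy[2], zs)
  tree <- structure(list(branches = list(list(
    id = 1L, parent = 0L, generation = 0L,
    start = c(ax_xy, z0), end = c(ax_xy, z1), direction = c(0, 0, 1),
    radius_mm = r_air, length_mm = z1 - z0,
    points = pts, arc_mm = zs - z0, vessel_id = 1L)),
    spacing_mm = spacing), class = "centerline_tree")
  structure(list(ct = volume_grid(ct, spacing),
                 lung = volume_grid(array(TRUE, dm), spacing),
                 airway = volume_grid(airway, spacing),
                 vessel = volume_grid(vessel, spacing),
                 branch_map = array(ifelse(airway, 1L, 0L), dm),
                 vessel_map = vessel_map,
                 tree = tree, spec = NULL), class = "anatomy_model")
}

# brute-force signed distance oracle: distance from every voxel to the
# nearest voxel of the opposite class, minus half the smallest spacing
brute_sdf <- function(mask, spacing = c(1, 1, 1)) {
  dm <- dim(mask)
  idx <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])))
  cw <- sweep(idx - 1, 2, spacing, "*")
  inside <- as.vector(mask)
  off <- 0.5 * min(spacing)
  pin <- cw[inside, , drop = FALSE]
  pout <- cw[!inside, , drop = FALSE]
  min_dist_to <- function(pts, targets) {
    apply(pts, 1, function(p) {
      sqrt(min(colSums((t(targets) - p)^2)))
    })
  }
  vals <- numeric(nrow(cw))
  vals[inside] <- -(min_dist_to(pin, pout) - off)
  vals[!inside] <- min_dist_to(pout, pin) - off
  array(vals, dm)
}

# random smooth blob mask for SDF / labeling stress tests
random_blob_mask <- function(dm, seed, fill = 0.25) {
  set.seed(seed)
  x <- array(stats::rnorm(prod(dm)), dm)
  for (i in 1:2) {
    k <- c(1, 2, 1) / 4
    for (ax in 1:3) x <- plugsim:::convolve_axis(x, k, ax)
  }
  q <- stats::quantile(x, 1 - fill)
  m <- x > q
  if (!any(m)) m[ceiling(dm[1] / 2), ceiling(dm[2] / 2), ceiling(dm[3] / 2)] <- TRUE
  if (all(m)) m[1, 1, 1] <- FALSE
  m
}

# closed-form Wilson score interval, independent of stats::prop.test
wilson_oracle <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

# fabricate a lesion_match_result from bare counts (for rate arithmetic
# tests on published-style integer counts)
fake_match <- function(n_gt, n_tp, n_fp) {
  gt <- if (n_gt > 0)
    data.frame(id = seq_len(n_gt), n_voxels = 1L,
               matched = seq_len(n_gt) <= n_tp)
  else data.frame(id = integer(0), n_voxels = integer(0), matched = logical(0))
  pred <- if (n_fp > 0)
    data.frame(id = seq_len(n_fp), n_voxels = 1L, matched = FALSE)
  else data.frame(id = integer(0), n_voxels = integer(0), matched = logical(0))
  structure(list(TP = n_tp, FN = n_gt - n_tp, FP = n_fp,
                 gt_lesions = gt, pred_lesions = pred,
                 gt_labels = NULL, pred_labels = NULL),
            class = "lesion_match_result")
}

# brute-force lesion matching: enumerate every (gt, pred) component pair and
# test overlap voxel-by-voxel
brute_match_counts <- function(pred_lab, gt_lab) {
  gt_ids <- setdiff(sort(unique(as.vector(gt_lab))), 0)
  pr_ids <- setdiff(sort(unique(as.vector(pred_lab))), 0)
  tp <- 0L
  for (g in gt_ids) {
    hit <- FALSE
    for (p in pr_ids) if (any(gt_lab == g & pred_lab == p)) { hit <- TRUE; break }
    tp <- tp + hit
  }
  fp <- 0L
  for (p in pr_ids) {
    hit <- FALSE
    for (g in gt_ids) if (any(gt_lab == g & pred_lab == p)) { hit <- TRUE; break }
    fp <- fp + !hit
  }
  list(TP = tp, FN = length(gt_ids) - tp, FP = fp)
}
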