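#' Specification of a procedural airway/vessel phantom
#'
#' Describes a CT-like phantom volume containing a bifurcating airway tree
#' (air-attenuation lumen wrapped in a soft-tissue wall), one companion
#' vessel tube per airway branch, parenchymal background and Gaussian
#' acquisition noise. The phantom stands in for a segmented real chest CT:
#' [rasterize_phantom()] emits the image together with exact lung, airway
#' lumen and vessel masks and the centerline tree.
#'
#' Default attenuations are standard CT physics: lumen -1000 HU (air), wall
#' -200 HU, vessel 40 HU (soft tissue / blood, inside the 30-50 HU band
#' typical of non-contrast vessels and mucus), parenchyma -850 HU, noise
#' sigma 15 HU. The default tree spans lumen diameters from 6 mm at the
#' trunk down to under 2 mm at the leaves so that plugs can be hosted across
#' the eligible caliber range, and carries enough total centerline length to
#' host dense plug augmentation.
#'
#' @param volume_shape Integer length-3, voxel counts per axis.
#' @param spacing_mm Numeric length-3 (or scalar), voxel size in mm.
#' @param tree_depth Number of bifurcation generations (0 = single trunk).
#' @param root_radius_mm Lumen radius of the trunk, mm.
#' @param radius_taper Child/parent lumen radius ratio, in (0, 1).
#' @param branch_length_mm Trunk segment length in mm; generation g has
#'   length `branch_length_mm * length_taper^g`. A vector of length
#'   `tree_depth + 1` gives explicit per-generation lengths.
#' @param length_taper Per-generation length decay when `branch_length_mm`
#'   is scalar.
#' @param branch_angle_deg Bifurcation half-angle in degrees.
#' @param wall_thickness_mm Airway wall thickness, mm.
#' @param vessel_offset_mm Centre-to-centre distance from each airway branch
#'   to its companion vessel, mm.
#' @param vessel_radius_ratio Vessel radius as a fraction of the airway
#'   outer radius (lumen + wall).
#' @param hu_lumen,hu_wall,hu_vessel,hu_parenchyma Mean attenuations, HU.
#' @param noise_sigma_hu Gaussian noise scale, HU (0 = noise-free).
#' @param jitter Relative jitter applied per branch to angle and length
#'   (uniform in `[1 - jitter, 1 + jitter]`) so that different seeds give
#'   different anatomies; 0 = fully regular tree.
#' @param seed RNG seed used by [generate_phantom()].
#' @return A `phantom_spec` object (a validated list).
#' @seealso [build_airway_tree()], [rasterize_phantom()], [generate_phantom()]
#' @export
phantom_spec <- function(volume_shape = c(80L, 80L, 80L),
                         spacing_mm = c(1, 1, 1),
                         tree_depth = 5L,
                         root_radius_mm = 3,
                         radius_taper = 0.78,
                         branch_length_mm = 16,
                         length_taper = 0.8,
                         branch_angle_deg = 32,
                         wall_thickness_mm = 0.8,
                         vessel_offset_mm = 8,
                         vessel_radius_ratio = 0.75,
                         hu_lumen = -1000,
                         hu_wall = -200,
                         hu_vessel = 40,
                         hu_parenchyma = -850,
                         noise_sigma_hu = 15,
                         jitter = 0.08,
                         seed = 1L) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  spec <- list(volume_shape = as.integer(volume_shape),
               spacing_mm = as.numeric(spacing_mm),
               tree_depth = as.integer(tree_depth),
               root_radius_mm = root_radius_mm,
               radius_taper = radius_taper,
               branch_length_mm = branch_length_mm,
               length_taper = length_taper,
               branch_angle_deg = branch_angle_deg,
               wall_thickness_mm = wall_thickness_mm,
               vessel_offset_mm = vessel_offset_mm,
               vessel_radius_ratio = vessel_radius_ratio,
               hu_lumen = hu_lumen, hu_wall = hu_wall,
               hu_vessel = hu_vessel, hu_parenchyma = hu_parenchyma,
               noise_sigma_hu = noise_sigma_hu,
               jitter = jitter,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(volume_shape) != 3L || any(volume_shape < 8L))
      stop("phantom_spec: volume_shape must be 3 counts, each >= 8")
    if (any(spacing_mm <= 0)) stop("phantom_spec: spacing_mm must be > 0")
    if (tree_depth < 0L) stop("phantom_spec: tree_depth must be >= 0")
    if (root_radius_mm <= 0) stop("phantom_spec: root_radius_mm must be > 0")
    if (radius_taper <= 0 || radius_taper >= 1)
      stop("phantom_spec: radius_taper must lie in (0, 1)")
    if (any(branch_length_mm <= 0))
      stop("phantom_spec: branch_length_mm must be > 0")
    if (wall_thickness_mm < 0) stop("phantom_spec: wall_thickness_mm must be >= 0")
    if (vessel_radius_ratio <= 0) stop("phantom_spec: vessel_radius_ratio must be > 0")
    if (noise_sigma_hu < 0) stop("phantom_spec: noise_sigma_hu must be >= 0")
    if (vessel_offset_mm <= root_radius_mm + wall_thickness_mm)
      stop("phantom_spec: vessel_offset_mm too small; companion vessel would ",
           "intersect the trunk lumen/wall")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels @ %s mm, depth %d, root r=%.2g mm, taper %.2g\n",
              paste(x$volume_shape, collapse = "x"),
              paste(format(x$spacing_mm, digits = 3), collapse = "x"),
              x$tree_depth, x$root_radius_mm, x$radius_taper))
  invisible(x)
}

branch_generation_lengths <- function(spec) {
  if (length(spec$branch_length_mm) == spec$tree_depth + 1L)
    return(spec$branch_length_mm)
  spec$branch_length_mm[1] * spec$length_taper^(0:spec$tree_depth)
}

norm3 <- function(v) sqrt(sum(v * v))
unit3 <- function(v) v / norm3(v)

# a unit vector perpendicular to t, as parallel as possible to hint
perp_towards <- function(t, hint) {
  p <- hint - sum(hint * t) * t
  n <- norm3(p)
  if (n < 1e-8) {
    hint2 <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- hint2 - sum(hint2 * t) * t
    n <- norm3(p)
  }
  p / n
}

#' Build a bifurcating airway centerline tree
#'
#' Grows a binary tree of straight branches inside the phantom volume. The
#' trunk starts near the low-z face and runs along +z; each bifurcation
#' splits at `branch_angle_deg` in planes alternating between the xz and yz
#' orientations (rotated with the local tangent), with per-branch
#' multiplicative jitter on angle and length. Generation-g branches have
#' lumen radius `root_radius_mm * radius_taper^g`. Every centerline point
#' must stay inside the volume with a margin of at least the local outer
#' radius (lumen + wall); otherwise the spec is rejected.
#'
#' @param spec A [phantom_spec].
#' @param seed RNG seed for the jitter stream (default `spec$seed`).
#' @return A `centerline_tree`: list of branches, each with `id`, `parent`
#'   (0 for the trunk), `generation`, `start`, `end` (world mm), `radius_mm`,
#'   `length_mm`, `points` (m x 3 matrix of samples spaced ~1 voxel along the
#'   branch), `arc_mm` (arc position of each sample) and `vessel_id`.
#' @export
build_airway_tree <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  extent <- (spec$volume_shape - 1) * spec$spacing_mm
  gen_len <- branch_generation_lengths(spec)
  step <- min(spec$spacing_mm)
  theta0 <- spec$branch_angle_deg * pi / 180

  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }

  branches <- list()
  nid <- 0L

  add_branch <- function(start, dir, gen, parent) {
    nid <<- nid + 1L
    id <- nid
    jf <- function() if (spec$jitter > 0) stats::runif(1, 1 - spec$jitter, 1 + spec$jitter) else 1
    len <- gen_len[gen + 1L] * jf()
    r <- spec$root_radius_mm * spec$radius_taper^gen
    end <- start + len * dir
    outer <- r + spec$wall_thickness_mm
    m <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = m)
    pts <- cbind(start[1] + tt * (end[1] - start[1]),
                 start[2] + tt * (end[2] - start[2]),
                 start[3] + tt * (end[3] - start[3]))
    lo <- pmin(pts[1, ], pts[m, ]) - outer
    hi <- pmax(pts[1, ], pts[m, ]) + outer
    if (any(lo < 0) || any(hi > extent))
      stop(sprintf(paste0("build_airway_tree: branch %d (generation %d) exits the ",
                          "volume (outer radius margin %.2f mm); enlarge ",
                          "volume_shape or shorten/shrink the tree"), id, gen, outer))
    branches[[id]] <<- list(id = id, parent = parent, generation = gen,
                            start = start, end = end, direction = dir,
                            radius_mm = r, length_mm = len,
                            points = pts, arc_mm = tt * len, vessel_id = id)
    if (gen < spec$tree_depth) {
      hint <- if (gen %% 2L == 0L) c(1, 0, 0) else c(0, 1, 0)
      p <- perp_towards(dir, hint)
      th <- theta0 * jf()
      d1 <- unit3(cos(th) * dir + sin(th) * p)
      th <- theta0 * jf()
      d2 <- unit3(cos(th) * dir - sin(th) * p)
      add_branch(end, d1, gen + 1L, id)
      add_branch(end, d2, gen + 1L, id)
    }
    id
  }

  centre <- extent / 2
  root_outer <- spec$root_radius_mm + spec$wall_thickness_mm
  start <- c(centre[1], centre[2], root_outer + spec$spacing_mm[3])
  add_branch(start, c(0, 0, 1), 0L, 0L)

  structure(list(branches = branches, spec_shape = spec$volume_shape,
                 spacing_mm = spec$spacing_mm),
            class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  gens <- vapply(x$branches, `[[`, integer(1), "generation")
  lens <- vapply(x$branches, `[[`, numeric(1), "length_mm")
  cat(sprintf("<centerline_tree> %d branches, %d generations, total length %.1f mm\n",
              length(x$branches), max(gens) + 1L, sum(lens)))
  invisible(x)
}

n_branches <- function(tree) length(tree$branches)

tree_segments <- function(tree, wall = 0) {
  do.call(rbind, lapply(tree$branches, function(b)
    c(b$start, b$end, b$radius_mm + wall, b$radius_mm + wall, b$id)))
}

# minimum distances from segment (p0,p1) to each segment (Q0[i,], Q1[i,]);
# clamped closest-point formulation
seg_seg_distances <- function(p0, p1, Q0, Q1) {
  u <- p1 - p0
  v <- Q1 - Q0
  w0 <- matrix(p0, nrow(Q0), 3, byrow = TRUE) - Q0
  a <- sum(u * u)
  b <- as.numeric(v %*% u)
  cc <- rowSums(v * v)
  d <- as.numeric(w0 %*% u)
  e <- rowSums(v * w0)
  D <- a * cc - b * b
  sc <- ifelse(D > 1e-12, (b * e - cc * d) / D, 0)
  sc <- pmin(pmax(sc, 0), 1)
  tc <- ifelse(cc > 1e-12, (e + sc * b) / cc, 0)
  tc <- pmin(pmax(tc, 0), 1)
  sc <- if (a > 1e-12) pmin(pmax((b * tc - d) / a, 0), 1) else rep(0, length(b))
  P <- matrix(p0, length(b), 3, byrow = TRUE) + outer(sc, u)
  Q <- Q0 + v * tc
  sqrt(rowSums((P - Q)^2))
}

# companion vessel axis: branch axis shifted by vessel_offset_mm along a
# perpendicular direction chosen to maximize clearance from all airway tubes
# and already-placed vessels (16 candidate directions; radial-outward from
# the trunk axis preferred on ties)
vessel_segments <- function(tree, spec, n_dirs = 16L) {
  trunk <- tree$branches[[1]]
  axis_pt <- trunk$start
  br <- tree$branches
  A0 <- do.call(rbind, lapply(br, `[[`, "start"))
  A1 <- do.call(rbind, lapply(br, `[[`, "end"))
  a_out <- vapply(br, function(b) b$radius_mm + spec$wall_thickness_mm, numeric(1))

  placed <- matrix(numeric(0), 0, 9)
  for (b in br) {
    mid <- (b$start + b$end) / 2
    radial <- c(mid[1] - axis_pt[1], mid[2] - axis_pt[2], 0)
    if (norm3(radial) < 1e-6) radial <- c(1, 0, 0)
    e1 <- perp_towards(b$direction, radial)
    e2 <- unit3(cross3(b$direction, e1))
    rv <- spec$vessel_radius_ratio * (b$radius_mm + spec$wall_thickness_mm)

    best <- NULL
    for (k in seq_len(n_dirs) - 1L) {
      ang <- 2 * pi * k / n_dirs
      off <- spec$vessel_offset_mm * (cos(ang) * e1 + sin(ang) * e2)
      q0 <- b$start + off
      q1 <- b$end + off
      d_air <- seg_seg_distances(q0, q1, A0, A1) - a_out - rv
      d_air[b$id] <- spec$vessel_offset_mm - a_out[b$id] - rv
      clear <- min(d_air)
      if (nrow(placed)) {
        d_ves <- seg_seg_distances(q0, q1, placed[, 1:3, drop = FALSE],
                                   placed[, 4:6, drop = FALSE]) -
          placed[, 7] - rv
        clear <- min(clear, d_ves)
      }
      if (is.null(best) || clear > best$clear + 1e-9)
        best <- list(clear = clear, q0 = q0, q1 = q1)
    }
    placed <- rbind(placed, c(best$q0, best$q1, rv, rv, b$id))
  }
  placed
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rasterize a phantom into a CT volume with ground-truth masks
#'
#' Voxelizes the airway tree (lumen + wall shell) and one companion vessel
#' tube per branch into the phantom volume, assigns mean attenuations per
#' compartment and adds Gaussian acquisition noise to the CT image only --
#' masks always reflect the exact noiseless geometry. Companion vessels are
#' required not to intersect any airway lumen; a collision aborts with the
#' offending branch named.
#'
#' @param tree A `centerline_tree` from [build_airway_tree()].
#' @param spec The [phantom_spec] used to build it.
#' @param seed RNG seed for the noise draw (default `spec$seed`).
#' @return An `anatomy_model`: list with `ct`, `lung`, `airway`, `vessel`
#'   ([volume_grid]s; masks logical), `branch_map` / `vessel_map` (integer
#'   arrays mapping voxels to branch / companion-vessel ids), `tree`, `spec`.
#' @export
rasterize_phantom <- function(tree, spec, seed = spec$seed) {
  stopifnot(inherits(tree, "centerline_tree"), inherits(spec, "phantom_spec"))
  dm <- spec$volume_shape
  sp <- spec$spacing_mm
  org <- c(0, 0, 0)
  pad <- spec$wall_thickness_mm + 2 * max(sp)

  aw <- cpp_rasterize_tubes(dm, sp, org, tree_segments(tree), pad)
  lumen <- array(aw$excess <= 0, dm)
  wall <- array(aw$excess > 0 & aw$excess <= spec$wall_thickness_mm, dm)
  branch_map <- array(ifelse(lumen, aw$id, 0L), dm)

  vs <- cpp_rasterize_tubes(dm, sp, org, vessel_segments(tree, spec), pad)
  vessel <- array(vs$excess <= 0, dm)
  vessel_map <- array(ifelse(vessel, vs$id, 0L), dm)

  collide <- vessel & lumen
  if (any(collide)) {
    bad <- sort(unique(branch_map[collide]))
    stop("rasterize_phantom: companion vessel intersects airway lumen of branch ",
         paste(bad, collapse = ", "),
         "; increase vessel_offset_mm or shrink vessel_radius_ratio")
  }

  ct <- array(spec$hu_parenchyma, dm)
  ct[wall] <- spec$hu_wall
  ct[vessel] <- spec$hu_vessel
  ct[lumen] <- spec$hu_lumen
  if (spec$noise_sigma_hu > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed + 7L)
    }
    ct <- ct + array(stats::rnorm(prod(dm), 0, spec$noise_sigma_hu), dm)
  }

  anatomy <- structure(list(
    ct = volume_grid(ct, sp, org),
    lung = volume_grid(array(TRUE, dm), sp, org),
    airway = volume_grid(lumen, sp, org),
    vessel = volume_grid(vessel, sp, org),
    branch_map = branch_map,
    vessel_map = vessel_map,
    tree = tree,
    spec = spec), class = "anatomy_model")
  anatomy
}

#' @rdname rasterize_phantom
#' @param spec A [phantom_spec]; `generate_phantom()` builds the tree and
#'   rasterizes it in one call, seeding everything from `spec$seed`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  tree <- build_airway_tree(spec, seed = seed)
  rasterize_phantom(tree, spec, seed = seed)
}

#' @export
print.anatomy_model <- function(x, ...) {
  d <- dim(x$ct$data)
  cat(sprintf("<anatomy_model> %d x %d x %d voxels, %d airway branches\n",
              d[1], d[2], d[3], n_branches(x$tree)))
  cat(sprintf("  lumen %d vox, wall+vessel %d vox, lumen fraction %.3f%%\n",
              sum(x$airway$data), sum(x$vessel$data),
              100 * mean(x$airway$data)))
  invisible(x)
}

#' Check the structural invariants of an anatomy model
#'
#' Asserts that the airway lumen and vessel masks are disjoint, both lie
#' inside the lung mask, and every centerline sample maps to a lumen voxel.
#'
#' @param anatomy An `anatomy_model`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_anatomy <- function(anatomy) {
  a <- anatomy$airway$data; v <- anatomy$vessel$data; l <- anatomy$lung$data
  if (any(a & v)) stop("anatomy invariant violated: airway and vessel masks overlap")
  if (any(a & !l)) stop("anatomy invariant violated: airway outside lung")
  if (any(v & !l)) stop("anatomy invariant violated: vessel outside lung")
  for (b in anatomy$tree$branches) {
    ijk <- round(world_to_voxel(anatomy$airway, b$points))
    ijk <- pmax(pmin(ijk, matrix(dim(a), nrow(ijk), 3, byrow = TRUE)), 1)
    lin <- ijk_to_linear(anatomy$airway, ijk)
    if (!all(a[lin]))
      stop("anatomy invariant violated: centerline of branch ", b$id,
           " leaves the lumen mask")
  }
  invisible(TRUE)
}

# --- RNG scoping helpers -----------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}
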