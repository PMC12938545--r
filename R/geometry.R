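#' Signed Euclidean distance field of a binary mask
#'
#' Computes, for every voxel, the signed distance in mm to the mask's face
#' boundary (the interface between inside and outside voxels): strictly
#' negative inside the mask, strictly positive outside, zero level set lying
#' on the interface. Distances are exact Euclidean distances between voxel
#' centres (anisotropic spacing respected), computed with a separable
#' lower-envelope distance transform, shifted by half the smallest voxel
#' spacing so that an inside/outside voxel pair adjacent across a face gets
#' values -h/2 and +h/2. This makes the sign symmetry exact:
#' `sdf(mask) == -sdf(!mask)`.
#'
#' @param mask A logical [volume_grid] (or 3-D logical array).
#' @param spacing_mm Voxel spacing, used when `mask` is a bare array.
#' @param mask_role Optional tag (`"airway"` or `"vessel"`) carried along
#'   for bookkeeping.
#' @return A [volume_grid] of class `c("sdf_volume", "volume_grid")` with
#'   numeric distances in mm and attribute `mask_role`.
#' @examples
#' m <- array(FALSE, c(11, 11, 11)); m[4:8, 4:8, 4:8] <- TRUE
#' s <- signed_distance_field(volume_grid(m))
#' s$data[6, 6, 6] < 0
#' @export
signed_distance_field <- function(mask, spacing_mm = NULL, mask_role = NULL) {
  if (!is_volume_grid(mask))
    mask <- volume_grid(mask, spacing_mm %||% c(1, 1, 1))
  m <- mask$data
  if (!is.logical(m)) m <- m > 0
  if (!any(m)) stop("signed_distance_field: mask is empty (no boundary)")
  if (all(m)) stop("signed_distance_field: mask fills the volume (no boundary)")
  dm <- dim(m)
  d_to_in <- cpp_edt_sq(as.vector(m), dm, mask$spacing)
  d_to_out <- cpp_edt_sq(as.vector(!m), dm, mask$spacing)
  off <- 0.5 * min(mask$spacing)
  vals <- ifelse(as.vector(m), -(sqrt(d_to_out) - off), sqrt(d_to_in) - off)
  out <- volume_grid(array(vals, dm), mask$spacing, mask$origin)
  class(out) <- c("sdf_volume", class(out))
  attr(out, "mask_role") <- mask_role
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Local airway diameter at a point
#'
#' Projects a world-coordinate point onto the nearest centerline segment and
#' returns twice the linearly interpolated lumen radius there. Branches may
#' carry a per-point radius vector (`radius_points`); otherwise the branch
#' radius is constant.
#'
#' @param tree A `centerline_tree`.
#' @param point_mm Numeric length-3 world coordinate.
#' @param max_dist_mm Maximum allowed distance from the point to the tree;
#'   farther queries are an error.
#' @return Diameter in mm.
#' @export
local_airway_diameter <- function(tree, point_mm, max_dist_mm = 10) {
  best <- list(dist = Inf, radius = NA_real_)
  for (b in tree$branches) {
    pts <- b$points
    m <- nrow(pts)
    radii <- b$radius_points %||% rep(b$radius_mm, m)
    p0 <- pts[-m, , drop = FALSE]
    p1 <- pts[-1, , drop = FALSE]
    v <- p1 - p0
    w <- sweep(-p0, 2, point_mm, "+")
    vv <- rowSums(v * v)
    t <- pmin(pmax(rowSums(w * v) / pmax(vv, 1e-12), 0), 1)
    dvec <- w - v * t
    d <- sqrt(rowSums(dvec * dvec))
    i <- which.min(d)
    if (d[i] < best$dist)
      best <- list(dist = d[i], radius = radii[i] + t[i] * (radii[i + 1] - radii[i]))
  }
  if (best$dist > max_dist_mm)
    stop(sprintf("local_airway_diameter: point is %.2f mm from the nearest branch (limit %.2f mm)",
                 best$dist, max_dist_mm))
  2 * best$radius
}

#' Lumen cross-section at a centerline point
#'
#' Collects the lumen voxels whose centres lie within half a voxel of the
#' plane through `point_mm` with normal `tangent` (a one-voxel slab),
#' restricted to the connected in-slab component containing the point, and
#' measures lumen and plugged areas as voxel count times the in-plane voxel
#' area (voxel volume divided by the voxel extent along the tangent).
#'
#' @param lumen_mask Logical [volume_grid] of the airway lumen.
#' @param plug_mask Logical [volume_grid] of plug voxels (or `NULL`).
#' @param point_mm World coordinate on/near the centerline, inside the lumen.
#' @param tangent Numeric length-3 local centerline direction (nonzero).
#' @return A `cross_section`: list with `point`, `tangent`, `lumen_voxels`
#'   (linear indices), `lumen_area_mm2`, `plug_voxels`, `plugged_area_mm2`
#'   and `occlusion_ratio`.
#' @export
cross_section <- function(lumen_mask, plug_mask = NULL, point_mm, tangent) {
  stopifnot(is_volume_grid(lumen_mask))
  if (norm3(tangent) < 1e-9) stop("cross_section: tangent must be nonzero")
  th <- unit3(tangent)
  sp <- lumen_mask$spacing
  slab_half <- 0.5 * sum(abs(th) * sp)

  pt_ijk <- round(world_to_voxel(lumen_mask, matrix(point_mm, 1)))
  dmv <- dim(lumen_mask$data)
  if (any(pt_ijk < 1) || any(pt_ijk > dmv))
    stop("cross_section: point lies outside the volume")
  pt_lin <- ijk_to_linear(lumen_mask, pt_ijk)
  if (!lumen_mask$data[pt_lin])
    stop("cross_section: point is not inside the lumen mask")

  lum_lin <- which(as.vector(lumen_mask$data))
  cw <- voxel_to_world(lumen_mask, lum_lin)
  dplane <- (cw[, 1] - point_mm[1]) * th[1] + (cw[, 2] - point_mm[2]) * th[2] +
    (cw[, 3] - point_mm[3]) * th[3]
  # half-open slab [-h, h): exactly one voxel layer even when the plane
  # falls midway between two layers
  slab <- lum_lin[dplane >= -slab_half - 1e-9 & dplane < slab_half - 1e-9]

  # connected component (26) of the slab containing the query point
  ijk <- linear_to_ijk(lumen_mask, slab)
  lo <- pmax(apply(ijk, 2, min) - 1L, 1L)
  hi <- pmin(apply(ijk, 2, max) + 1L, dmv)
  sub_dm <- hi - lo + 1L
  sub <- array(FALSE, sub_dm)
  loc <- sweep(ijk, 2, lo, "-") + 1L
  sub[loc[, 1] + sub_dm[1] * ((loc[, 2] - 1L) + sub_dm[2] * (loc[, 3] - 1L))] <- TRUE
  lab <- array(cpp_label_components(as.vector(sub), sub_dm, 26L), sub_dm)
  pt_loc <- as.integer(pt_ijk - lo + 1L)
  seed_lab <- lab[pt_loc[1], pt_loc[2], pt_loc[3]]
  if (seed_lab == 0) stop("cross_section: point not contained in the slab")
  keep <- lab[loc[, 1] + sub_dm[1] * ((loc[, 2] - 1L) + sub_dm[2] * (loc[, 3] - 1L))] == seed_lab
  slab <- slab[keep]

  vox_area <- prod(sp) / sum(abs(th) * sp)
  plug_lin <- integer(0)
  if (!is.null(plug_mask)) {
    stopifnot_same_grid(lumen_mask, plug_mask)
    plug_lin <- slab[plug_mask$data[slab]]
  }
  structure(list(point = point_mm, tangent = th,
                 lumen_voxels = slab,
                 lumen_area_mm2 = length(slab) * vox_area,
                 plug_voxels = plug_lin,
                 plugged_area_mm2 = length(plug_lin) * vox_area,
                 occlusion_ratio = if (length(slab)) length(plug_lin) / length(slab) else NA_real_),
            class = "cross_section")
}

#' Longitudinal extent of a plug along its host centerline
#'
#' Projects every plug voxel onto the centerline of the branch it is nearest
#' to and returns the arc-length between the extreme projections. Voxels may
#' span a parent-child chain of branches (the arc is accumulated along the
#' path); voxels assigned to branches that do not form a single path are an
#' invalid plug. A single-voxel plug is reported as one voxel spacing, not
#' zero, so that length-bin assignment is defined for every plug.
#'
#' @param plug A `synthetic_plug`, or a vector of linear voxel indices.
#' @param tree The `centerline_tree` of the host anatomy.
#' @param vol A [volume_grid] defining the voxel lattice (required when
#'   `plug` is a bare index vector; defaults to the plug's recorded grid).
#' @return Length in mm.
#' @export
plug_length <- function(plug, tree, vol = NULL) {
  if (inherits(plug, "synthetic_plug")) {
    vox <- plug$voxels
    vol <- vol %||% plug$grid
  } else {
    vox <- as.integer(plug)
  }
  if (length(vox) == 0) stop("plug_length: empty plug")
  if (is.null(vol)) stop("plug_length: need a volume_grid to locate voxels")
  coords <- voxel_to_world(vol, vox)

  # nearest branch + sample for every voxel
  all_pts <- do.call(rbind, lapply(tree$branches, `[[`, "points"))
  pt_branch <- rep(vapply(tree$branches, `[[`, integer(1), "id"),
                   vapply(tree$branches, function(b) nrow(b$points), integer(1)))
  pt_local <- unlist(lapply(tree$branches, function(b) seq_len(nrow(b$points))))
  nn <- cpp_nearest_sample(coords, all_pts)
  vb <- pt_branch[nn$index]
  vl <- pt_local[nn$index]

  ids <- sort(unique(vb))
  if (length(ids) > 1) {
    # must form one parent-child path
    parents <- vapply(tree$branches, `[[`, integer(1), "parent")
    path_ok <- all(vapply(ids, function(i) {
      p <- parents[i]
      i == min(ids) || p %in% ids
    }, logical(1)))
    gens <- vapply(tree$branches[ids], `[[`, integer(1), "generation")
    if (!path_ok || any(duplicated(gens)))
      stop("plug_length: plug spans branches that do not form a single ",
           "centerline path (invalid plug)")
    ids <- ids[order(gens)]
  }

  # arc position along the concatenated path, projecting each voxel onto
  # the nearest polyline segment of its branch
  base <- c(0, cumsum(vapply(tree$branches[ids], `[[`, numeric(1), "length_mm")))
  s <- numeric(length(vox))
  for (w in seq_along(ids)) {
    b <- tree$branches[[ids[w]]]
    sel <- vb == b$id
    if (!any(sel)) next
    pts <- b$points
    m <- nrow(pts)
    P0 <- pts[-m, , drop = FALSE]
    P1 <- pts[-1, , drop = FALSE]
    seglen <- sqrt(rowSums((P1 - P0)^2))
    arc0 <- cumsum(c(0, seglen))[seq_len(m - 1L)]
    cs <- coords[sel, , drop = FALSE]
    best_d <- rep(Inf, nrow(cs))
    best_s <- numeric(nrow(cs))
    for (sg in seq_len(m - 1L)) {
      v <- P1[sg, ] - P0[sg, ]
      vv <- max(sum(v * v), 1e-12)
      w0 <- sweep(cs, 2, P0[sg, ])
      t <- pmin(pmax(as.numeric(w0 %*% v) / vv, 0), 1)
      dvec <- w0 - outer(t, v)
      dd <- rowSums(dvec * dvec)
      upd <- dd < best_d
      best_d[upd] <- dd[upd]
      best_s[upd] <- arc0[sg] + t[upd] * seglen[sg]
    }
    s[sel] <- base[w] + best_s
  }
  len <- max(s) - min(s)
  max(len, min(vol$spacing))
}

#' Precomputed lumen geometry of an anatomy model
#'
#' Assigns every airway-lumen voxel to its branch and nearest centerline
#' sample (a one-voxel cross-section slab), with arc position and radial
#' offset. This is the substrate for seed selection, constrained plug
#' growth and occlusion measurement.
#'
#' @param anatomy An `anatomy_model`.
#' @return A `lumen_geometry` object: parallel vectors `idx` (linear voxel
#'   index), `branch`, `sample`, `section` (branch/sample key), `s_mm`
#'   (exact arc position), plus per-voxel radial offset components, branch
#'   diameter lookup and per-section voxel counts.
#' @export
lumen_geometry <- function(anatomy) {
  vol <- anatomy$airway
  lin <- which(as.vector(vol$data))
  br <- anatomy$branch_map[lin]
  coords <- voxel_to_world(vol, lin)

  sample_idx <- integer(length(lin))
  s_mm <- numeric(length(lin))
  off <- matrix(0, length(lin), 3)
  for (b in anatomy$tree$branches) {
    sel <- which(br == b$id)
    if (!length(sel)) next
    nn <- cpp_nearest_sample(coords[sel, , drop = FALSE], b$points)
    sample_idx[sel] <- nn$index
    d <- coords[sel, , drop = FALSE] - b$points[nn$index, , drop = FALSE]
    along <- as.numeric(d %*% b$direction)
    # clamp to the branch arc range: voxels of the rasterized end caps
    # project onto the branch ends, as in plug_length()
    s_mm[sel] <- pmin(pmax(b$arc_mm[nn$index] + along, 0), b$length_mm)
    off[sel, ] <- d - outer(along, b$direction)
  }
  section <- br * 100000 + sample_idx
  radius <- vapply(anatomy$tree$branches, `[[`, numeric(1), "radius_mm")
  structure(list(idx = lin, branch = br, sample = sample_idx,
                 section = section, s_mm = s_mm, offset = off,
                 radial_mm = sqrt(rowSums(off^2)),
                 branch_radius = radius,
                 section_n = table(section),
                 grid = volume_grid(array(0L, dim(vol$data)), vol$spacing, vol$origin)),
            class = "lumen_geometry")
}

#' Estimated vs specified caliber along phantom centerlines
#'
#' For each centerline sample of each branch, estimates the local lumen
#' diameter from the signed distance field of the rasterized lumen mask
#' (twice the interior depth at the centerline voxel) and pairs it with the
#' diameter the spec prescribes. Used to validate that rasterization honors
#' the requested geometry.
#'
#' @param anatomy An `anatomy_model`.
#' @param sdf Optional precomputed SDF of the airway mask.
#' @return data.frame with columns `branch`, `sample`, `spec_diameter_mm`,
#'   `est_diameter_mm`.
#' @export
centerline_caliber_estimates <- function(anatomy, sdf = NULL) {
  sdf <- sdf %||% signed_distance_field(anatomy$airway, mask_role = "airway")
  h <- min(anatomy$airway$spacing)
  geom <- lumen_geometry(anatomy)
  voxvol <- prod(anatomy$airway$spacing)
  out <- lapply(anatomy$tree$branches, function(b) {
    sel <- geom$branch == b$id
    if (!any(sel)) return(NULL)
    # caliber of each one-voxel cross-section slab from its area: the slab
    # holds ~area x sample-step worth of voxel volume, so
    # d = 2 sqrt(A / pi) with A = n voxvol / step. Area is robust to the
    # sub-voxel offset between the axis and the voxel lattice, which biases
    # depth-based estimates.
    step_b <- b$arc_mm[2] - b$arc_mm[1]
    n_bin <- tapply(rep(1L, sum(sel)), geom$sample[sel], sum)
    est <- 2 * sqrt(as.numeric(n_bin) * voxvol / step_b / pi)
    s_ids <- as.integer(names(n_bin))
    arc <- b$arc_mm[s_ids]
    # interior samples: away from the end caps and bifurcation junctions,
    # where the section is not shaped by the merging parent (whose lumen
    # bulges one parent-radius into the child)
    r_par <- if (b$parent > 0) anatomy$tree$branches[[b$parent]]$radius_mm else b$radius_mm
    interior <- arc > max(b$radius_mm, r_par) + h &
      arc < b$length_mm - b$radius_mm - h
    data.frame(branch = b$id, sample = s_ids,
               spec_diameter_mm = 2 * b$radius_mm,
               est_diameter_mm = est,
               interior = interior)
  })
  do.call(rbind, out)
}
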