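#' Identify the companion vessel of a plug's host airway
#'
#' Among the 26-connected components of the vessel mask, selects the one
#' minimizing the distance to the host branch centerline, restricted to
#' vessels whose estimated caliber is within a relative tolerance of the
#' host airway caliber ("adjacent vessel of comparable caliber"). Vessel
#' caliber is estimated as twice the maximum interior depth of the
#' component in the vessel signed distance field.
#'
#' @param anatomy An `anatomy_model`.
#' @param plug A `synthetic_plug` (its `host_branch` is used).
#' @param vessel_sdf Optional precomputed [signed_distance_field()] of the
#'   vessel mask.
#' @param search_radius_mm Maximum centerline-to-vessel distance, mm.
#' @param caliber_tolerance Relative radius tolerance (0.5 = +-50%).
#' @return List with `component` (vessel component id), `voxels` (linear
#'   indices), `distance_mm`, `radius_mm`. Raises a condition of class
#'   `plugsim_no_companion` when no vessel qualifies.
#' @export
find_companion_vessel <- function(anatomy, plug, vessel_sdf = NULL,
                                  search_radius_mm = 20, caliber_tolerance = 0.5) {
  vmask <- anatomy$vessel
  if (!any(vmask$data)) stop("find_companion_vessel: vessel mask is empty")
  labs <- array(cpp_label_components(as.vector(vmask$data), dim(vmask$data), 26L),
                dim(vmask$data))
  vessel_sdf <- vessel_sdf %||% signed_distance_field(vmask, mask_role = "vessel")
  branch <- anatomy$tree$branches[[plug$host_branch]]
  r_air <- branch$radius_mm

  comp_ids <- sort(unique(labs[labs > 0]))
  best <- NULL
  for (cid in comp_ids) {
    vox <- which(as.vector(labs) == cid)
    depth <- -vessel_sdf$data[vox]
    r_ves <- max(depth) + 0.5 * min(vmask$spacing)
    if (abs(r_ves - r_air) / r_air > caliber_tolerance) next
    # distance from host-branch centerline to the component (subsample for speed)
    sub <- vox[seq(1, length(vox), length.out = min(length(vox), 400L))]
    cw <- voxel_to_world(vmask, sub)
    nn <- cpp_nearest_sample(cw, branch$points)
    d <- min(nn$distance)
    if (d > search_radius_mm) next
    if (is.null(best) || d < best$distance_mm)
      best <- list(component = cid, voxels = vox, distance_mm = d, radius_mm = r_ves)
  }
  if (is.null(best))
    stop(errorCondition(
      sprintf("find_companion_vessel: no vessel within %.1f mm and +-%.0f%% caliber of branch %d",
              search_radius_mm, 100 * caliber_tolerance, plug$host_branch),
      class = c("plugsim_no_companion", "error")))
  best
}

#' Transfer vessel intensities onto a plug by depth matching
#'
#' Gives the plug a realistic attenuation texture: each plug voxel's HU is
#' replaced by the HU of a companion-vessel voxel whose signed distance to
#' the vessel wall matches the plug voxel's signed distance to the airway
#' wall within `tolerance_mm` (ties broken uniformly at random). When no
#' vessel voxel matches within tolerance (e.g. the airway is deeper than
#' the vessel), the voxel falls back to a draw from the vessel voxels at
#' the nearest available depth and is flagged. Voxels outside the plug are
#' bit-identical to the input.
#'
#' @param ct CT [volume_grid] to modify.
#' @param anatomy The `anatomy_model` the plug lives in.
#' @param plug A `synthetic_plug`.
#' @param companion Result of [find_companion_vessel()] (computed if `NULL`;
#'   on a no-companion condition every voxel uses the global vessel pool of
#'   the nearest depth and is flagged as fallback).
#' @param airway_sdf,vessel_sdf Signed distance fields of the airway lumen
#'   and vessel masks (computed if missing).
#' @param tolerance_mm Depth-matching tolerance, mm.
#' @param seed Optional RNG seed for tie-breaking draws.
#' @param min_companion_voxels Minimum size of the companion voxel pool;
#'   smaller companions are an error.
#' @return List with `ct` (modified [volume_grid]) and `map`, a
#'   `correspondence_map` data.frame: `plug_voxel`, `vessel_voxel`,
#'   `airway_depth_mm`, `vessel_depth_mm`, `residual_mm`, `fallback`.
#' @export
transfer_intensities <- function(ct, anatomy, plug, companion = NULL,
                                 airway_sdf = NULL, vessel_sdf = NULL,
                                 tolerance_mm = 0.5, seed = NULL,
                                 min_companion_voxels = 8L) {
  stopifnot(is_volume_grid(ct), inherits(plug, "synthetic_plug"))
  airway_sdf <- airway_sdf %||% signed_distance_field(anatomy$airway, mask_role = "airway")
  vessel_sdf <- vessel_sdf %||% signed_distance_field(anatomy$vessel, mask_role = "vessel")
  if (is.null(companion))
    companion <- tryCatch(
      find_companion_vessel(anatomy, plug, vessel_sdf),
      plugsim_no_companion = function(e)
        list(component = NA_integer_, voxels = which(as.vector(anatomy$vessel$data)),
             distance_mm = NA_real_, radius_mm = NA_real_, fallback_pool = TRUE))
  vvox <- companion$voxels
  if (length(vvox) < min_companion_voxels)
    stop("transfer_intensities: companion vessel has fewer than ",
         min_companion_voxels, " voxels")
  pool_is_fallback <- isTRUE(companion$fallback_pool)

  vdepth <- vessel_sdf$data[vvox]
  ord <- order(vdepth)
  vvox <- vvox[ord]
  vdepth <- vdepth[ord]

  pvox <- plug$voxels
  adepth <- airway_sdf$data[pvox]

  out <- ct$data
  with_seed(seed, {
    lo <- findInterval(adepth - tolerance_mm, vdepth) + 1L
    hi <- findInterval(adepth + tolerance_mm, vdepth)
    n_cand <- pmax(hi - lo + 1L, 0L)
    matched <- integer(length(pvox))
    fallback <- logical(length(pvox))
    for (i in seq_along(pvox)) {
      if (n_cand[i] > 0) {
        matched[i] <- vvox[lo[i] + sample.int(n_cand[i], 1L) - 1L]
      } else {
        fallback[i] <- TRUE
        resid <- abs(vdepth - adepth[i])
        pool <- which(resid <= min(resid) + 1e-9)
        matched[i] <- vvox[pool[sample.int(length(pool), 1L)]]
      }
    }
    out[pvox] <- ct$data[matched]
    map <- data.frame(plug_voxel = pvox,
                      vessel_voxel = matched,
                      airway_depth_mm = adepth,
                      vessel_depth_mm = vessel_sdf$data[matched],
                      residual_mm = abs(vessel_sdf$data[matched] - adepth),
                      fallback = fallback | pool_is_fallback)
    class(map) <- c("correspondence_map", "data.frame")
    list(ct = volume_grid(out, ct$spacing, ct$origin), map = map)
  })
}

#' Texture all plugs of a scan
#'
#' Applies [transfer_intensities()] to every plug of a [populate_scan()]
#' result, sharing one airway and one vessel SDF across plugs.
#'
#' @param plug_set A `plug_set`.
#' @param seed Optional RNG seed.
#' @param ... Passed to [transfer_intensities()].
#' @return List with `ct` (textured CT) and `maps` (per-plug
#'   correspondence maps).
#' @export
texture_plugs <- function(plug_set, seed = NULL, ...) {
  anatomy <- plug_set$anatomy
  if (!length(plug_set$plugs))
    return(list(ct = anatomy$ct, maps = list()))
  airway_sdf <- signed_distance_field(anatomy$airway, mask_role = "airway")
  vessel_sdf <- signed_distance_field(anatomy$vessel, mask_role = "vessel")
  ct <- anatomy$ct
  maps <- vector("list", length(plug_set$plugs))
  with_seed(seed, {
    for (i in seq_along(plug_set$plugs)) {
      res <- transfer_intensities(ct, anatomy, plug_set$plugs[[i]],
                                  airway_sdf = airway_sdf,
                                  vessel_sdf = vessel_sdf, seed = NULL, ...)
      ct <- res$ct
      maps[[i]] <- res$map
    }
  })
  list(ct = ct, maps = maps)
}

#' Acquisition-realism augmentation
#'
#' Applies optional Gaussian smoothing and additive Gaussian noise with
#' parameters drawn uniformly per call from the configured ranges,
#' emulating variation in reconstruction kernel sharpness and image noise.
#' With both ranges degenerate at zero, the input is returned unchanged.
#'
#' @param x A [volume_grid] or 3-D array (spacing assumed 1 mm if an array).
#' @param smooth_sigma_range_mm Range of the Gaussian smoothing sigma in mm
#'   (default 0-0.8).
#' @param noise_sigma_range_hu Range of the additive noise sigma in HU
#'   (default 0-10).
#' @param seed Optional RNG seed.
#' @return Same type as `x`.
#' @export
apply_augmentation <- function(x, smooth_sigma_range_mm = c(0, 0.8),
                               noise_sigma_range_hu = c(0, 10), seed = NULL) {
  if (any(smooth_sigma_range_mm < 0) || any(noise_sigma_range_hu < 0))
    stop("apply_augmentation: sigma ranges must be non-negative")
  was_grid <- is_volume_grid(x)
  vol <- if (was_grid) x else volume_grid(x)
  with_seed(seed, {
    s_smooth <- stats::runif(1, smooth_sigma_range_mm[1], smooth_sigma_range_mm[2])
    s_noise <- stats::runif(1, noise_sigma_range_hu[1], noise_sigma_range_hu[2])
    arr <- vol$data
    if (s_smooth > 0) arr <- gaussian_smooth_3d(arr, s_smooth / vol$spacing)
    if (s_noise > 0) arr <- arr + array(stats::rnorm(length(arr), 0, s_noise), dim(arr))
    if (was_grid) volume_grid(arr, vol$spacing, vol$origin) else arr
  })
}

# separable Gaussian filter; sigma in voxels per axis, reflective borders
gaussian_smooth_3d <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3)
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half:half) / s)^2)
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  half <- (length(k) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  x <- aperm(arr, perm)
  dm <- dim(x)
  n <- dm[1]
  m <- matrix(x, nrow = n)
  # reflective padding
  top <- m[pmin(pmax(half:1, 1), n), , drop = FALSE]
  bot <- m[pmin(pmax(n:(n - half + 1), 1), n), , drop = FALSE]
  mp <- rbind(top, m, bot)
  res <- matrix(0, n, ncol(m))
  for (i in seq_along(k))
    res <- res + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
  y <- array(res, dm)
  aperm(y, order(perm))
}

#' Total variation of a volume
#'
#' Sum of absolute finite differences along the three axes; smoothing never
#' increases it.
#'
#' @param x A [volume_grid] or 3-D array.
#' @return Scalar total variation.
#' @export
total_variation <- function(x) {
  a <- if (is_volume_grid(x)) x$data else x
  d <- dim(a)
  sum(abs(a[-1, , ] - a[-d[1], , ])) +
    sum(abs(a[, -1, ] - a[, -d[2], ])) +
    sum(abs(a[, , -1] - a[, , -d[3]]))
}
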