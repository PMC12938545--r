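#' Configuration of plug phenotype sampling and growth
#'
#' Bundles the sampled phenotype ranges (defaults are the simulated cohort's
#' stated ranges: length 2-20 mm, occlusion ratio 0.35-1.0, eligible airway
#' diameter 1-20 mm), the growth geometry and the retry policy.
#'
#' @param length_range_mm Target plug length range (uniform), mm.
#' @param occlusion_range Target occlusion-ratio range (uniform), in
#'   `[0.35, 1]` by default.
#' @param diameter_range_mm Eligible host-airway diameter range, mm.
#' @param distribution Sampling distribution tag; only `"uniform"` is
#'   currently implemented.
#' @param geometry `"mural"` grows the plugged part of each cross-section
#'   from the wall-adjacent side of the seed (mucus adheres to airway
#'   walls); `"centered"` grows radially outward from the centerline.
#' @param corridor `"seed"` requires only the seed's own cross-section to be
#'   free of existing plugs and clips the growth window to the contiguous
#'   free run around it (plugs shorter than target are flagged truncated);
#'   `"full"` requires the entire target-length corridor to be free.
#' @param max_seed_attempts Attempts before [select_seed()] raises a
#'   no-eligible-site condition.
#' @param max_phenotype_resamples How often [populate_scan()] resamples the
#'   phenotype after a no-eligible-site condition before declaring the
#'   anatomy saturated.
#' @return A `plug_config` list.
#' @export
plug_config <- function(length_range_mm = c(2, 20),
                        occlusion_range = c(0.35, 1),
                        diameter_range_mm = c(1, 20),
                        distribution = "uniform",
                        geometry = c("mural", "centered"),
                        corridor = c("seed", "full"),
                        max_seed_attempts = 100L,
                        max_phenotype_resamples = 25L) {
  geometry <- match.arg(geometry)
  corridor <- match.arg(corridor)
  for (rg in list(length_range_mm, occlusion_range, diameter_range_mm)) {
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[1] > rg[2])
      stop("plug_config: ranges must be finite c(lo, hi) with lo <= hi")
  }
  if (!identical(distribution, "uniform"))
    stop("plug_config: only the uniform sampling distribution is implemented")
  structure(list(length_range_mm = length_range_mm,
                 occlusion_range = occlusion_range,
                 diameter_range_mm = diameter_range_mm,
                 distribution = distribution,
                 geometry = geometry, corridor = corridor,
                 max_seed_attempts = as.integer(max_seed_attempts),
                 max_phenotype_resamples = as.integer(max_phenotype_resamples)),
            class = "plug_config")
}

#' Sample a plug phenotype
#'
#' Draws the target length, occlusion ratio and eligible host-airway
#' diameter independently and uniformly from the configured ranges.
#'
#' @param config A [plug_config].
#' @param n Number of phenotypes (1 returns a single `plug_phenotype`;
#'   larger n a data.frame of draws).
#' @return A `plug_phenotype` (list) or data.frame.
#' @export
sample_phenotype <- function(config = plug_config(), n = 1L) {
  draw <- function(rg, k) if (rg[1] == rg[2]) rep(rg[1], k) else stats::runif(k, rg[1], rg[2])
  out <- data.frame(
    target_length_mm = draw(config$length_range_mm, n),
    target_occlusion_ratio = draw(config$occlusion_range, n),
    eligible_diameter_mm = draw(config$diameter_range_mm, n),
    distribution = config$distribution)
  if (n == 1L)
    return(structure(as.list(out[1, ]), class = "plug_phenotype"))
  out
}

no_eligible_site <- function(msg) {
  stop(errorCondition(msg, class = c("plugsim_no_eligible_site", "error")))
}

#' Select a seed voxel for plug growth
#'
#' Draws a uniformly random airway-lumen voxel whose host branch diameter
#' lies within the phenotype's eligible range and whose cross-section is
#' free of existing plugs (with `corridor = "full"`, whose whole
#' target-length corridor is free and within the branch).
#'
#' @param anatomy An `anatomy_model`.
#' @param phenotype A `plug_phenotype`.
#' @param occupancy Integer array of existing plug labels (0 = free), or
#'   `NULL`.
#' @param geom Precomputed [lumen_geometry()] (computed if missing).
#' @param config A [plug_config].
#' @return Linear voxel index of the seed. Raises a condition of class
#'   `plugsim_no_eligible_site` when no voxel qualifies.
#' @export
select_seed <- function(anatomy, phenotype, occupancy = NULL,
                        geom = lumen_geometry(anatomy), config = plug_config()) {
  diam <- 2 * geom$branch_radius[geom$branch]
  ok <- diam >= config$diameter_range_mm[1] & diam <= config$diameter_range_mm[2]
  if (!is.null(occupancy)) {
    occ_vox <- occupancy[geom$idx] > 0
    occ_sections <- unique(geom$section[occ_vox])
    ok <- ok & !(geom$section %in% occ_sections)
  }
  cand <- which(ok)
  if (!length(cand))
    no_eligible_site("select_seed: no eligible lumen voxel for this phenotype")
  for (a in seq_len(config$max_seed_attempts)) {
    pick <- cand[sample.int(length(cand), 1L)]
    if (config$corridor == "seed") return(geom$idx[pick])
    run <- free_section_run(geom, occupancy, pick,
                            phenotype$target_length_mm / 2)
    span <- diff(range(geom$s_mm[geom$branch == geom$branch[pick] &
                                   geom$sample %in% run]))
    if (span + min(geom$grid$spacing) >= phenotype$target_length_mm)
      return(geom$idx[pick])
  }
  no_eligible_site("select_seed: no seed with a free full-length corridor found")
}

# contiguous run of fully free samples (of the picked voxel's branch) within
# +-half_mm of the picked voxel's arc position, containing its sample
free_section_run <- function(geom, occupancy, pick, half_mm) {
  b <- geom$branch[pick]
  in_branch <- geom$branch == b
  samp <- geom$sample[in_branch]
  svox <- geom$s_mm[in_branch]
  s0 <- geom$s_mm[pick]
  occ <- if (is.null(occupancy)) rep(FALSE, sum(in_branch)) else
    occupancy[geom$idx[in_branch]] > 0
  tab <- sort(unique(samp))
  s_of <- vapply(tab, function(s) mean(svox[samp == s]), numeric(1))
  occupied <- vapply(tab, function(s) any(occ[samp == s]), logical(1))
  in_win <- abs(s_of - s0) <= half_mm + 0.5 * min(geom$grid$spacing)
  usable <- in_win & !occupied
  i0 <- which(tab == geom$sample[pick])
  if (!length(i0) || !usable[i0]) return(integer(0))
  lo <- i0; while (lo > 1 && usable[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(tab) && usable[hi + 1]) hi <- hi + 1
  tab[lo:hi]
}

#' Grow a synthetic plug by constrained region growing
#'
#' Deterministically grows a plug from a seed voxel within the airway lumen
#' of the seed's host branch, never crossing a bifurcation. Longitudinal
#' extent is capped at the target length (window of +-length/2 around the
#' seed, clipped to the contiguous run of plug-free cross-sections); in each
#' covered one-voxel cross-section the plugged voxel count is the smallest
#' count whose area ratio reaches the target occlusion ratio, grown from
#' the wall-adjacent side of the seed (or from the centerline with
#' `geometry = "centered"`). The result is a 26-connected voxel set that is
#' disjoint from existing plugs.
#'
#' @param anatomy An `anatomy_model`.
#' @param seed Linear voxel index inside the lumen (from [select_seed()]).
#' @param phenotype A `plug_phenotype`.
#' @param geom Precomputed [lumen_geometry()].
#' @param occupancy Integer array of existing plug labels, or `NULL`.
#' @param config A [plug_config].
#' @return A `synthetic_plug`: `voxels` (sorted linear indices),
#'   `seed_voxel`, `host_branch`, `achieved_length_mm`,
#'   `achieved_occlusion_ratio` (mean over covered sections),
#'   `section_ratios`, `volume_mm3`, `truncated`, `phenotype`, `grid`.
#' @export
grow_plug <- function(anatomy, seed, phenotype,
                      geom = lumen_geometry(anatomy), occupancy = NULL,
                      config = plug_config()) {
  pick <- match(seed, geom$idx)
  if (is.na(pick)) stop("grow_plug: seed voxel is outside the airway lumen")
  b <- geom$branch[pick]
  step <- min(geom$grid$spacing)
  rho <- phenotype$target_occlusion_ratio
  L <- phenotype$target_length_mm

  run <- free_section_run(geom, occupancy, pick, L / 2)
  if (!length(run)) stop("grow_plug: seed cross-section is already occupied")
  cand <- which(geom$branch == b & geom$sample %in% run)
  if (!is.null(occupancy)) cand <- cand[occupancy[geom$idx[cand]] == 0]

  # occlusion denominators: the full lumen voxel count of each section
  full_n <- table(geom$sample[geom$branch == b & geom$sample %in% run])

  # longitudinal window at voxel granularity, so the achieved length can
  # never exceed the target; edge sections that cannot reach their quota
  # inside the window are dropped by the connectivity pass
  s0 <- geom$s_mm[pick]
  cand <- cand[abs(geom$s_mm[cand] - s0) <= L / 2 + 1e-9]

  # per-section quota: smallest count reaching the target occlusion ratio
  samp <- geom$sample[cand]
  n_sec <- full_n[names(full_n) %in% as.character(unique(samp))]
  quota <- pmax(1L, as.integer(ceiling(rho * as.integer(n_sec) - 1e-9)))
  names(quota) <- names(n_sec)

  # in-plane ordering: mural (toward the seed-side wall) or centered
  if (config$geometry == "mural") {
    a_dir <- geom$offset[pick, ]
    if (norm3(a_dir) < 0.25 * step)
      a_dir <- perp_towards(anatomy$tree$branches[[b]]$direction, c(1, 1, 0))
    a_dir <- unit3(a_dir)
    score <- -(geom$offset[cand, , drop = FALSE] %*% a_dir)[, 1]
  } else {
    score <- geom$radial_mm[cand]
  }
  ord <- order(score, geom$idx[cand])

  sel <- logical(length(cand))
  taken <- integer(0)
  cnt <- stats::setNames(integer(length(n_sec)), names(n_sec))
  for (o in ord) {
    key <- as.character(samp[o])
    if (cnt[key] < quota[key]) {
      sel[o] <- TRUE
      cnt[key] <- cnt[key] + 1L
    }
  }
  # the seed itself always belongs to the plug
  seed_pos <- match(pick, cand)
  if (!sel[seed_pos]) {
    key <- as.character(samp[seed_pos])
    worst <- which(sel & samp == samp[seed_pos])
    worst <- worst[which.max(score[worst])]
    sel[worst] <- FALSE
    sel[seed_pos] <- TRUE
  }

  sel <- enforce_connectivity(geom, cand, sel, seed_pos, quota, samp, score)

  vox <- geom$idx[cand[sel]]
  covered <- samp[sel]
  ratios <- as.integer(table(covered)) / as.integer(n_sec[names(table(covered))])
  s_sel <- geom$s_mm[cand[sel]]
  len <- max(s_sel) - min(s_sel)
  if (len <= 0) len <- step
  structure(list(label_id = NA_integer_,
                 seed_voxel = seed,
                 voxels = sort(vox),
                 host_branch = b,
                 achieved_length_mm = len,
                 achieved_occlusion_ratio = mean(ratios),
                 section_ratios = ratios,
                 volume_mm3 = length(vox) * prod(geom$grid$spacing),
                 truncated = len < L - 1.5 * step,
                 phenotype = phenotype,
                 grid = geom$grid),
            class = "synthetic_plug")
}

# Keep the 26-connected component containing the seed; refill sections that
# drop below quota from voxels adjacent to the plug; drop sections that
# cannot be refilled. Iterates to a fixed point.
enforce_connectivity <- function(geom, cand, sel, seed_pos, quota, samp, score) {
  ijk <- linear_to_ijk(geom$grid, geom$idx[cand])
  lo <- pmax(apply(ijk, 2, min) - 1L, 1L)
  sub_dm <- apply(ijk, 2, max) - lo + 1L
  loc <- sweep(ijk, 2, lo, "-") + 1L
  loc_lin <- loc[, 1] + sub_dm[1] * ((loc[, 2] - 1L) + sub_dm[2] * (loc[, 3] - 1L))

  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, ]

  adjacent_to <- function(plug_arr, rows) {
    out <- rep(FALSE, length(rows))
    for (r in seq_len(nrow(neigh))) {
      ii <- loc[rows, 1] + neigh[r, 1]
      jj <- loc[rows, 2] + neigh[r, 2]
      kk <- loc[rows, 3] + neigh[r, 3]
      inb <- ii >= 1 & ii <= sub_dm[1] & jj >= 1 & jj <= sub_dm[2] &
        kk >= 1 & kk <= sub_dm[3]
      lin <- ii[inb] + sub_dm[1] * ((jj[inb] - 1L) + sub_dm[2] * (kk[inb] - 1L))
      out[inb] <- out[inb] | plug_arr[lin]
    }
    out
  }

  for (pass in 1:20) {
    arr <- array(FALSE, sub_dm)
    arr[loc_lin[sel]] <- TRUE
    lab <- cpp_label_components(as.vector(arr), sub_dm, 26L)
    keep_lab <- lab[loc_lin[seed_pos]]
    new_sel <- sel & lab[loc_lin] == keep_lab
    changed <- !identical(new_sel, sel)
    sel <- new_sel

    # refill deficient covered sections from adjacent free candidates
    arr <- array(FALSE, sub_dm)
    arr[loc_lin[sel]] <- TRUE
    for (key in unique(as.character(samp[sel]))) {
      in_sec <- samp == as.integer(key)
      have <- sum(sel & in_sec)
      need <- quota[key] - have
      while (need > 0) {
        free_rows <- which(in_sec & !sel)
        if (!length(free_rows)) break
        adj <- adjacent_to(arr, free_rows)
        free_rows <- free_rows[adj]
        if (!length(free_rows)) break
        add <- free_rows[which.min(score[free_rows])]
        sel[add] <- TRUE
        arr[loc_lin[add]] <- TRUE
        changed <- TRUE
        need <- need - 1L
      }
      if (need > 0 && as.integer(key) != samp[seed_pos] && any(sel & in_sec)) {
        # section cannot reach quota while staying connected: drop it
        sel[in_sec] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # final sweep: seed component only
  arr <- array(FALSE, sub_dm)
  arr[loc_lin[sel]] <- TRUE
  lab <- cpp_label_components(as.vector(arr), sub_dm, 26L)
  sel & lab[loc_lin] == lab[loc_lin[seed_pos]]
}

#' Populate a scan with synthetic plugs
#'
#' Repeats phenotype sampling, seed selection and constrained growth until
#' `n_plugs` pairwise-disjoint plugs exist (labels 1..n), resampling the
#' phenotype when no eligible site is found. If the anatomy saturates before
#' reaching `n_plugs`, fewer plugs are returned with a warning.
#'
#' @param anatomy An `anatomy_model`.
#' @param n_plugs Number of plugs to insert (the simulated cohort default
#'   is 50 per scan).
#' @param config A [plug_config].
#' @param seed Optional RNG seed for the whole insertion stream.
#' @param geom Precomputed [lumen_geometry()] (computed if missing).
#' @return A `plug_set`: list with `plugs` (list of `synthetic_plug`, each
#'   with `label_id` assigned), `labels` (integer [volume_grid], background
#'   0) and `anatomy`.
#' @export
populate_scan <- function(anatomy, n_plugs = 50L, config = plug_config(),
                          seed = NULL, geom = NULL) {
  if (n_plugs < 0) stop("populate_scan: n_plugs must be >= 0")
  if (!any(anatomy$airway$data)) stop("populate_scan: anatomy has no airway mask")
  geom <- geom %||% lumen_geometry(anatomy)
  occupancy <- array(0L, dim(anatomy$airway$data))
  plugs <- vector("list", 0L)
  with_seed(seed, {
    k <- 0L
    while (k < n_plugs) {
      grown <- NULL
      for (r in seq_len(config$max_phenotype_resamples)) {
        phen <- sample_phenotype(config)
        sv <- tryCatch(select_seed(anatomy, phen, occupancy, geom, config),
                       plugsim_no_eligible_site = function(e) NULL)
        if (is.null(sv)) next
        # a failed growth at a degenerate site counts as an ineligible
        # draw: resample the phenotype
        grown <- tryCatch(grow_plug(anatomy, sv, phen, geom, occupancy, config),
                          error = function(e) NULL)
        if (!is.null(grown)) break
      }
      if (is.null(grown)) {
        warning(sprintf("populate_scan: anatomy saturated after %d of %d plugs",
                        k, n_plugs))
        break
      }
      k <- k + 1L
      grown$label_id <- k
      occupancy[grown$voxels] <- k
      plugs[[k]] <- grown
    }
  })
  structure(list(plugs = plugs,
                 labels = volume_grid(occupancy, anatomy$airway$spacing,
                                      anatomy$airway$origin),
                 anatomy = anatomy),
            class = "plug_set")
}

#' @export
print.plug_set <- function(x, ...) {
  n <- length(x$plugs)
  cat(sprintf("<plug_set> %d plugs, %d labelled voxels\n",
              n, sum(x$labels$data > 0)))
  if (n) {
    tb <- plug_table(x)
    cat(sprintf("  length %.1f-%.1f mm (mean %.1f), occlusion %.2f-%.2f, %d truncated\n",
                min(tb$length_mm), max(tb$length_mm), mean(tb$length_mm),
                min(tb$occlusion), max(tb$occlusion), sum(tb$truncated)))
  }
  invisible(x)
}

#' Per-plug summary table
#'
#' @param plug_set A `plug_set` from [populate_scan()] (or a list of
#'   `synthetic_plug`s).
#' @return data.frame with one row per plug: `label_id`, `seed_voxel`,
#'   `branch`, `length_mm`, `occlusion`, `min_section_occlusion`,
#'   `volume_mm3`, `n_voxels`, `truncated`, and the sampled targets.
#' @export
plug_table <- function(plug_set) {
  plugs <- if (inherits(plug_set, "plug_set")) plug_set$plugs else plug_set
  do.call(rbind, lapply(plugs, function(p) data.frame(
    label_id = p$label_id,
    seed_voxel = p$seed_voxel,
    branch = p$host_branch,
    length_mm = p$achieved_length_mm,
    occlusion = p$achieved_occlusion_ratio,
    min_section_occlusion = min(p$section_ratios),
    volume_mm3 = p$volume_mm3,
    n_voxels = length(p$voxels),
    truncated = p$truncated,
    target_length_mm = p$phenotype$target_length_mm,
    target_occlusion = p$phenotype$target_occlusion_ratio,
    eligible_diameter_mm = p$phenotype$eligible_diameter_mm)))
}

#' @export
print.synthetic_plug <- function(x, ...) {
  cat(sprintf("<synthetic_plug> label %s, branch %d: %d voxels, length %.2f mm, occlusion %.2f%s\n",
              ifelse(is.na(x$label_id), "?", x$label_id), x$host_branch,
              length(x$voxels), x$achieved_length_mm,
              x$achieved_occlusion_ratio,
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}
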