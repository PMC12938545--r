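#' Resample a volume to isotropic spacing
#'
#' Interpolates the volume onto an isotropic grid (default 0.8 mm, the
#' training resolution used throughout the pipeline). Images are resampled
#' with trilinear interpolation, masks and label volumes with
#' nearest-neighbour so labels stay integral. The world extent is preserved
#' to within one voxel; the origin (first voxel centre) is kept.
#'
#' @param vol A [volume_grid].
#' @param target_mm Isotropic output spacing in mm (default 0.8).
#' @param method `"linear"` (images) or `"nearest"` (labels/masks); the
#'   default picks `"nearest"` for logical or integer data.
#' @return A [volume_grid] with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(vol, target_mm = 0.8,
                               method = c("auto", "linear", "nearest")) {
  stopifnot(is_volume_grid(vol))
  method <- match.arg(method)
  if (method == "auto")
    method <- if (is.logical(vol$data) || is.integer(vol$data)) "nearest" else "linear"
  sp <- vol$spacing
  d <- dim(vol$data)
  extent <- (d - 1) * sp
  nd <- pmax(2L, as.integer(round(extent / target_mm)) + 1L)

  # continuous source index (1-based) for each output voxel centre
  gx <- (seq_len(nd[1]) - 1) * target_mm / sp[1] + 1
  gy <- (seq_len(nd[2]) - 1) * target_mm / sp[2] + 1
  gz <- (seq_len(nd[3]) - 1) * target_mm / sp[3] + 1
  gx <- pmin(gx, d[1]); gy <- pmin(gy, d[2]); gz <- pmin(gz, d[3])

  src <- vol$data
  is_log <- is.logical(src)
  if (is_log) storage.mode(src) <- "integer"

  if (method == "nearest") {
    ix <- pmin(pmax(round(gx), 1), d[1])
    iy <- pmin(pmax(round(gy), 1), d[2])
    iz <- pmin(pmax(round(gz), 1), d[3])
    out <- src[ix, iy, iz]
  } else {
    x0 <- pmin(floor(gx), d[1] - 1); fx <- gx - x0
    y0 <- pmin(floor(gy), d[2] - 1); fy <- gy - y0
    z0 <- pmin(floor(gz), d[3] - 1); fz <- gz - z0
    out <- array(0, nd)
    for (dz in 0:1) {
      wz <- if (dz == 0) 1 - fz else fz
      slab <- array(0, c(nd[1], nd[2], nd[3]))
      for (dy in 0:1) {
        wy <- if (dy == 0) 1 - fy else fy
        plane <- src[, y0 + dy, z0 + dz, drop = FALSE]
        low <- plane[x0, , , drop = FALSE]
        high <- plane[x0 + 1, , , drop = FALSE]
        interp_x <- low * (1 - fx) + high * fx
        slab <- slab + sweep(interp_x, 2, wy, "*")
      }
      out <- out + sweep(slab, 3, wz, "*")
    }
  }
  if (is_log && method == "nearest") out <- array(as.logical(out), nd)
  volume_grid(out, rep(target_mm, 3), vol$origin)
}

#' Assemble a training case from a textured scan
#'
#' Collapses the instance label volume to a binary plug mask, pairs it with
#' the post-transfer CT, and records provenance.
#'
#' @param case_id Character id (e.g. `"case_0001"`).
#' @param ct Textured CT [volume_grid] (output of [texture_plugs()]).
#' @param labels Instance-label [volume_grid] from [populate_scan()].
#' @param plug_set Optional `plug_set` for the per-plug table.
#' @param seed,config_hash Optional provenance fields.
#' @return A `dataset_case`.
#' @export
dataset_case <- function(case_id, ct, labels, plug_set = NULL,
                         seed = NA_integer_, config_hash = NA_character_) {
  stopifnot_same_grid(ct, labels)
  label_bin <- volume_grid(array(labels$data > 0, dim(labels$data)),
                           labels$spacing, labels$origin)
  structure(list(case_id = case_id, image = ct, label = label_bin,
                 instances = labels,
                 plug_table = if (!is.null(plug_set)) plug_table(plug_set),
                 provenance = list(seed = seed, config_hash = config_hash)),
            class = "dataset_case")
}

parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(is.na(parts)))
      stop("ratio must be numeric length 2 or a string like '1:3'")
    ratio <- parts
  }
  if (any(ratio < 0) || sum(ratio) == 0) stop("invalid patch ratio")
  ratio
}

#' Extract a balanced batch of training patches
#'
#' Samples `n_patches` cubic patches at a fixed positive:negative ratio:
#' positive patches are centred on uniformly chosen plug voxels (each
#' contains at least one plug voxel), negative patches are centred on
#' lumen-containing locations whose patch holds no plug voxel. Patch
#' centres are clamped so patches lie fully inside the volume. Counts
#' follow the ratio exactly when divisible, else within one patch.
#'
#' @param case A `dataset_case`.
#' @param ratio Positive:negative ratio, e.g. `c(1, 1)` or `"1:3"`.
#' @param patch_size Cubic patch edge length in voxels (scalar or length 3).
#' @param n_patches Total number of patches.
#' @param seed Optional RNG seed.
#' @param augment Optional list of [apply_augmentation()] arguments applied
#'   per image patch (`NULL` = no augmentation).
#' @param lumen_mask Optional lumen [volume_grid] restricting negative
#'   patch centres; defaults to anywhere plug-free.
#' @param max_attempts Sampling attempts per negative patch.
#' @return A `patch_batch`: list of `(image, label, positive)` patch
#'   triples plus the realized counts.
#' @export
extract_balanced_patches <- function(case, ratio = c(1, 1), patch_size = 96L,
                                     n_patches = 10L, seed = NULL,
                                     augment = NULL, lumen_mask = NULL,
                                     max_attempts = 200L) {
  ratio <- parse_ratio(ratio)
  if (length(patch_size) == 1L) patch_size <- rep(as.integer(patch_size), 3)
  d <- dim(case$image$data)
  if (any(patch_size > d))
    stop("extract_balanced_patches: patch does not fit inside the volume")
  n_pos <- as.integer(round(n_patches * ratio[1] / sum(ratio)))
  n_neg <- n_patches - n_pos
  plug_lin <- which(as.vector(case$label$data))
  if (n_pos > 0 && !length(plug_lin))
    stop("extract_balanced_patches: positives requested but case has no plug voxels")
  neg_pool <- if (!is.null(lumen_mask)) which(as.vector(lumen_mask$data) &
                                                !as.vector(case$label$data))
  else which(!as.vector(case$label$data))

  half_lo <- (patch_size - 1L) %/% 2L
  clamp_corner <- function(center_ijk) {
    pmin(pmax(center_ijk - half_lo, 1L), d - patch_size + 1L)
  }
  crop <- function(vol, corner) {
    vol$data[corner[1]:(corner[1] + patch_size[1] - 1L),
             corner[2]:(corner[2] + patch_size[2] - 1L),
             corner[3]:(corner[3] + patch_size[3] - 1L)]
  }

  with_seed(seed, {
    patches <- vector("list", n_patches)
    k <- 0L
    for (i in seq_len(n_pos)) {
      center <- linear_to_ijk(case$label, plug_lin[sample.int(length(plug_lin), 1L)])
      corner <- clamp_corner(as.integer(center))
      img <- crop(case$image, corner)
      if (!is.null(augment))
        img <- do.call(apply_augmentation, c(list(img), augment))
      k <- k + 1L
      patches[[k]] <- list(image = img, label = crop(case$label, corner),
                           positive = TRUE)
    }
    for (i in seq_len(n_neg)) {
      found <- FALSE
      for (a in seq_len(max_attempts)) {
        center <- linear_to_ijk(case$label, neg_pool[sample.int(length(neg_pool), 1L)])
        corner <- clamp_corner(as.integer(center))
        lab <- crop(case$label, corner)
        if (!any(lab)) { found <- TRUE; break }
      }
      if (!found)
        stop("extract_balanced_patches: could not find a plug-free patch")
      img <- crop(case$image, corner)
      if (!is.null(augment))
        img <- do.call(apply_augmentation, c(list(img), augment))
      k <- k + 1L
      patches[[k]] <- list(image = img, label = lab, positive = FALSE)
    }
    structure(list(patches = patches, n_positive = n_pos, n_negative = n_neg,
                   ratio = ratio, patch_size = patch_size),
              class = "patch_batch")
  })
}

#' @export
print.patch_batch <- function(x, ...) {
  cat(sprintf("<patch_batch> %d patches (%d positive / %d negative), %s voxels\n",
              length(x$patches), x$n_positive, x$n_negative,
              paste(x$patch_size, collapse = "x")))
  invisible(x)
}

#' Export dataset cases as NIfTI pairs with a manifest
#'
#' Writes `<case_id>_image.nii.gz` / `<case_id>_label.nii.gz` per case, a
#' per-case plug CSV when available, and a JSON manifest recording spacing,
#' counts and provenance. Arrays round-trip bit-exactly through
#' [read_volume_nifti()].
#'
#' @param cases List of `dataset_case` objects.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty `out_dir` (otherwise an error).
#' @return The manifest (invisibly); written to `manifest.json`.
#' @export
export_dataset <- function(cases, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("export_dataset: output directory is not empty (use force = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cases, function(cs) {
    stopifnot(inherits(cs, "dataset_case"))
    img_path <- file.path(out_dir, paste0(cs$case_id, "_image.nii.gz"))
    lab_path <- file.path(out_dir, paste0(cs$case_id, "_label.nii.gz"))
    write_volume_nifti(cs$image, img_path)
    lab <- cs$label
    lab$data <- array(as.integer(lab$data), dim(lab$data))
    write_volume_nifti(lab, lab_path)
    n_plugs <- if (!is.null(cs$plug_table)) nrow(cs$plug_table)
    else length(unique(cs$instances$data[cs$instances$data > 0]))
    if (!is.null(cs$plug_table))
      utils::write.csv(cs$plug_table,
                       file.path(out_dir, paste0(cs$case_id, "_plugs.csv")),
                       row.names = FALSE)
    list(case_id = cs$case_id,
         image = basename(img_path), label = basename(lab_path),
         shape = dim(cs$image$data), spacing_mm = cs$image$spacing,
         n_plugs = n_plugs,
         plug_volume_mm3 = sum(cs$label$data) * prod(cs$label$spacing),
         seed = cs$provenance$seed, config_hash = cs$provenance$config_hash)
  })
  manifest <- list(n_cases = length(cases),
                   total_plugs = sum(vapply(entries, function(e)
                     as.numeric(e$n_plugs %||% 0), numeric(1))),
                   cases = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
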