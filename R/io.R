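#' Write and read a phantom case on disk
#'
#' A case is stored as NIfTI volumes `<case>_ct.nii.gz`, `_lung.nii.gz`,
#' `_airway.nii.gz`, `_vessel.nii.gz` plus the centerline tree as JSON
#' (`<case>_tree.json`). Branch maps are reconstructed on read from the
#' tree and masks.
#'
#' @param anatomy An `anatomy_model`.
#' @param dir Output directory (created if needed).
#' @param case_id Case identifier, e.g. `"case_0001"`.
#' @return `write_phantom_case()`: the file paths invisibly;
#'   `read_phantom_case()`: an `anatomy_model` (without branch/vessel maps
#'   unless recomputed).
#' @export
write_phantom_case <- function(anatomy, dir, case_id = "case_0001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ct = file.path(dir, paste0(case_id, "_ct.nii.gz")),
             lung = file.path(dir, paste0(case_id, "_lung.nii.gz")),
             airway = file.path(dir, paste0(case_id, "_airway.nii.gz")),
             vessel = file.path(dir, paste0(case_id, "_vessel.nii.gz")),
             tree = file.path(dir, paste0(case_id, "_tree.json")))
  write_volume_nifti(anatomy$ct, paths["ct"])
  for (nm in c("lung", "airway", "vessel")) {
    v <- anatomy[[nm]]
    v$data <- array(as.integer(v$data), dim(v$data))
    write_volume_nifti(v, paths[nm])
  }
  write_centerline_json(anatomy$tree, paths["tree"])
  invisible(paths)
}

#' @rdname write_phantom_case
#' @export
read_phantom_case <- function(dir, case_id = "case_0001") {
  p <- function(sfx) file.path(dir, paste0(case_id, "_", sfx))
  to_mask <- function(v) { v$data <- array(v$data > 0, dim(v$data)); v }
  ct <- read_volume_nifti(p("ct.nii.gz"))
  structure(list(ct = ct,
                 lung = to_mask(read_volume_nifti(p("lung.nii.gz"))),
                 airway = to_mask(read_volume_nifti(p("airway.nii.gz"))),
                 vessel = to_mask(read_volume_nifti(p("vessel.nii.gz"))),
                 branch_map = NULL, vessel_map = NULL,
                 tree = read_centerline_json(p("tree.json")),
                 spec = NULL), class = "anatomy_model")
}

#' Serialize a centerline tree to JSON
#'
#' @param tree A `centerline_tree`.
#' @param path Output JSON path.
#' @return `path` invisibly.
#' @export
write_centerline_json <- function(tree, path) {
  branches <- lapply(tree$branches, function(b) list(
    id = b$id, parent = b$parent, generation = b$generation,
    start = b$start, end = b$end, direction = b$direction,
    radius_mm = b$radius_mm, length_mm = b$length_mm,
    points = lapply(seq_len(nrow(b$points)), function(r) unname(b$points[r, ])),
    arc_mm = b$arc_mm, vessel_id = b$vessel_id))
  jsonlite::write_json(list(branches = branches,
                            spacing_mm = tree$spacing_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerline_json
#' @export
read_centerline_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  branches <- lapply(raw$branches, function(b) list(
    id = as.integer(b$id), parent = as.integer(b$parent),
    generation = as.integer(b$generation),
    start = as.numeric(unlist(b$start)), end = as.numeric(unlist(b$end)),
    direction = as.numeric(unlist(b$direction)),
    radius_mm = as.numeric(b$radius_mm), length_mm = as.numeric(b$length_mm),
    points = do.call(rbind, lapply(b$points, function(p) as.numeric(unlist(p)))),
    arc_mm = as.numeric(unlist(b$arc_mm)),
    vessel_id = as.integer(b$vessel_id)))
  structure(list(branches = branches,
                 spacing_mm = as.numeric(raw$spacing_mm)),
            class = "centerline_tree")
}

#' Run the full synthesis pipeline for one case
#'
#' Phantom generation, plug population at the configured density, intensity
#' transfer, and assembly into a [dataset_case()].
#'
#' @param config A `run_config` from [load_run_config()].
#' @param case_seed Seed for this case (phantom geometry, noise, plug
#'   stream, transfer draws all derive from it).
#' @param case_id Case identifier.
#' @return List with `case` (a `dataset_case`), `plug_set`, `anatomy`.
#' @export
simulate_case <- function(config = load_run_config(), case_seed = 1L,
                          case_id = sprintf("case_%04d", case_seed)) {
  sp <- config$phantom
  sp$seed <- case_seed
  anatomy <- generate_phantom(sp)
  ps <- populate_scan(anatomy, config$n_plugs_per_scan, config$plugs,
                      seed = case_seed)
  tx <- texture_plugs(ps, seed = case_seed,
                      tolerance_mm = config$transfer$tolerance_mm %||% 0.5)
  case <- dataset_case(case_id, tx$ct, ps$labels, ps,
                       seed = case_seed, config_hash = config$hash)
  list(case = case, plug_set = ps, anatomy = anatomy, maps = tx$maps)
}
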