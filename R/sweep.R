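#' Built-in reference detectors for pipeline experiments
#'
#' `detector_oracle()` returns the ground-truth labels unchanged (an upper
#' bound on performance). `detector_noisy_oracle()` degrades the oracle to
#' exercise the metrics without any trained network: lesions smaller than
#' `min_voxels` are missed, each remaining lesion is dropped independently
#' with probability `miss_rate`, and `fp_rate` spurious small lesions per
#' scan are added at random lumen-free locations.
#'
#' @param min_voxels Lesions below this voxel count are never detected.
#' @param miss_rate Per-lesion miss probability.
#' @param fp_rate Expected number of spurious lesions per scan (Poisson).
#' @return A detector: `function(labels, anatomy)` returning a predicted
#'   binary [volume_grid].
#' @export
detector_oracle <- function() {
  function(labels, anatomy) labels
}

#' @rdname detector_oracle
#' @export
detector_noisy_oracle <- function(min_voxels = 2L, miss_rate = 0.1,
                                  fp_rate = 2) {
  function(labels, anatomy) {
    la <- labels$data
    ids <- sort(unique(la[la > 0]))
    keep <- vapply(ids, function(i) {
      n <- sum(la == i)
      n >= min_voxels && stats::runif(1) > miss_rate
    }, logical(1))
    out <- array(la %in% ids[keep], dim(la))
    n_fp <- stats::rpois(1, fp_rate)
    if (n_fp > 0) {
      bg <- which(!as.vector(anatomy$airway$data) & as.vector(anatomy$lung$data))
      d <- dim(la)
      for (f in seq_len(n_fp)) {
        c0 <- linear_to_ijk(labels, bg[sample.int(length(bg), 1L)])
        sz <- sample(1:2, 3, replace = TRUE)
        i <- pmin(c0[1] + 0:(sz[1]), d[1]); j <- pmin(c0[2] + 0:(sz[2]), d[2])
        k <- pmin(c0[3] + 0:(sz[3]), d[3])
        out[i, j, k] <- TRUE
      }
    }
    volume_grid(out, labels$spacing, labels$origin)
  }
}

#' Augmentation-density sweep over phantom cohorts
#'
#' Reproduces the shape of the density-calibration experiment: for each
#' plug count, populates a small cohort of phantoms at that density, runs a
#' detector, and scores it at the lesion level. With the built-in oracle
#' detectors this demonstrates the full loop (synthesis, scoring,
#' reporting) without any trained network; absolute values are phantom
#' properties, not clinical results.
#'
#' @param counts Plugs-per-scan values to test (default 10 to 100 by 10).
#' @param detector A detector `function(labels, anatomy) -> prediction`
#'   (see [detector_oracle()]); required.
#' @param n_scans Phantoms per count.
#' @param spec [phantom_spec()] template for the cohort.
#' @param config [plug_config()] for synthesis.
#' @param seed RNG seed for the whole sweep.
#' @param csv Optional path to write the sweep table as CSV.
#' @return data.frame with one row per count: `n_plugs_per_scan`,
#'   `sensitivity`, `fp_per_scan`, `dice`, plus backing counts.
#' @export
run_density_sweep <- function(counts = seq(10L, 100L, 10L), detector,
                              n_scans = 3L, spec = phantom_spec(),
                              config = plug_config(), seed = 1L, csv = NULL) {
  if (missing(detector) || !is.function(detector))
    stop("run_density_sweep: a detector callback is required")
  rows <- lapply(seq_along(counts), function(ci) {
    cnt <- counts[ci]
    matches <- list(); gt_len <- list(); pr_len <- list(); dc <- numeric(n_scans)
    for (s in seq_len(n_scans)) {
      sc_seed <- seed + 1000L * ci + s
      sp <- spec; sp$seed <- sc_seed
      anatomy <- generate_phantom(sp)
      ps <- populate_scan(anatomy, cnt, config, seed = sc_seed)
      pred <- with_seed(sc_seed + 1L, detector(ps$labels, anatomy))
      m <- match_lesions(pred, ps$labels)
      matches[[s]] <- m
      gt_len[[s]] <- stats::setNames(
        vapply(ps$plugs, `[[`, numeric(1), "achieved_length_mm"),
        vapply(ps$plugs, `[[`, integer(1), "label_id"))
      pr_len[[s]] <- lesion_lengths(volume_grid(m$pred_labels,
                                                ps$labels$spacing))
      dc[s] <- dice(pred$data > 0, ps$labels$data > 0)
    }
    rep_ <- stratify_and_summarize(matches, gt_len, pr_len, dice_per_scan = dc)
    all_row <- rep_$table[rep_$table$bin == "all", ]
    data.frame(n_plugs_per_scan = cnt,
               n_gt = all_row$n_gt, TP = all_row$TP, FP = all_row$FP,
               sensitivity = all_row$sensitivity,
               fp_per_scan = all_row$fp_per_scan,
               dice = mean(dc))
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
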