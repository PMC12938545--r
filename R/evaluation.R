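#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. When both masks are empty the
#' coefficient is defined as 1.0 (perfect agreement on absence; the raw
#' formula is 0/0 there) and the result carries attribute
#' `both_empty = TRUE`.
#'
#' @param mask_a,mask_b Logical/numeric [volume_grid]s or arrays of equal
#'   shape; nonzero = foreground.
#' @return Numeric in `[0, 1]`.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' dice(a, a)
#' @export
dice <- function(mask_a, mask_b) {
  a <- if (is_volume_grid(mask_a)) mask_a$data else mask_a
  b <- if (is_volume_grid(mask_b)) mask_b$data else mask_b
  if (!identical(dim(a), dim(b)))
    stop("dice: mask shapes differ")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0)
    return(structure(1.0, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Label connected components of a binary volume
#'
#' 26-connectivity by default, matching the growth connectivity of the
#' synthesis pipeline.
#'
#' @param mask Logical/numeric [volume_grid] or array.
#' @param connectivity 6 or 26.
#' @return Integer array (or [volume_grid] if the input was one) of
#'   component labels, background 0.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  grid <- if (is_volume_grid(mask)) mask else NULL
  a <- if (is.null(grid)) mask else grid$data
  lab <- array(cpp_label_components(as.vector(a > 0), dim(a), as.integer(connectivity)),
               dim(a))
  if (is.null(grid)) lab else volume_grid(lab, grid$spacing, grid$origin)
}

as_label_array <- function(x, connectivity = 26L) {
  a <- if (is_volume_grid(x)) x$data else x
  if (is.logical(a) || all(a %in% c(0, 1)))
    a <- if (is_volume_grid(x)) label_components(x, connectivity)$data
  else label_components(a, connectivity)
  storage.mode(a) <- "integer"
  a
}

#' Match predicted lesions against ground truth by voxel overlap
#'
#' A ground-truth lesion counts as detected (TP) if at least one predicted
#' voxel overlaps it; an undetected GT lesion is an FN; a predicted lesion
#' overlapping no GT lesion is an FP. A single prediction overlapping
#' several GT lesions credits each of them. Binary inputs are instance-
#' labelled first (26-connectivity).
#'
#' @param pred Predicted segmentation: binary or instance-label
#'   [volume_grid]/array.
#' @param gt Ground truth, same grid.
#' @param connectivity Connectivity used to instance binary inputs.
#' @return A `lesion_match_result`: counts `TP`, `FP`, `FN`, per-GT-lesion
#'   data.frame `gt_lesions` (id, n_voxels, matched, matched_pred ids) and
#'   per-prediction data.frame `pred_lesions` (id, n_voxels, matched).
#' @export
match_lesions <- function(pred, gt, connectivity = 26L) {
  pa <- if (is_volume_grid(pred)) pred$data else pred
  ga <- if (is_volume_grid(gt)) gt$data else gt
  if (!identical(dim(pa), dim(ga))) stop("match_lesions: grids differ in shape")
  pl <- as_label_array(pred, connectivity)
  gl <- as_label_array(gt, connectivity)

  gt_ids <- sort(unique(gl[gl > 0]))
  pred_ids <- sort(unique(pl[pl > 0]))
  both <- pl > 0 & gl > 0
  pairs <- unique(cbind(gt = gl[both], pred = pl[both]))

  gt_matched <- gt_ids %in% pairs[, "gt"]
  pred_matched <- pred_ids %in% pairs[, "pred"]
  gt_tab <- data.frame(id = gt_ids,
                       n_voxels = as.integer(table(factor(gl[gl > 0], levels = gt_ids))),
                       matched = gt_matched)
  gt_tab$matched_pred <- lapply(gt_ids, function(i) pairs[pairs[, "gt"] == i, "pred"])
  pred_tab <- data.frame(id = pred_ids,
                         n_voxels = as.integer(table(factor(pl[pl > 0], levels = pred_ids))),
                         matched = pred_matched)
  structure(list(TP = sum(gt_matched), FN = sum(!gt_matched),
                 FP = sum(!pred_matched),
                 gt_lesions = gt_tab, pred_lesions = pred_tab,
                 gt_labels = gl, pred_labels = pl),
            class = "lesion_match_result")
}

#' @export
print.lesion_match_result <- function(x, ...) {
  cat(sprintf("<lesion_match_result> TP %d, FN %d, FP %d (GT lesions %d, predictions %d)\n",
              x$TP, x$FN, x$FP, nrow(x$gt_lesions), nrow(x$pred_lesions)))
  invisible(x)
}

#' Measure lesion lengths from a label volume
#'
#' Length of each labelled lesion as its extent along the principal axis of
#' its voxel cloud (plus one voxel spacing, so a single voxel has length
#' one spacing). Used to bin ground-truth lesions when no centerline is
#' available and to bin false positives by their own size.
#'
#' @param labels Instance-label [volume_grid] or array.
#' @param spacing_mm Spacing when `labels` is a bare array.
#' @return Named numeric vector of lengths (mm), names = label ids.
#' @export
lesion_lengths <- function(labels, spacing_mm = c(1, 1, 1)) {
  grid <- if (is_volume_grid(labels)) labels else volume_grid(labels, spacing_mm)
  la <- grid$data
  ids <- sort(unique(la[la > 0]))
  out <- vapply(ids, function(i) {
    lin <- which(as.vector(la) == i)
    cw <- voxel_to_world(grid, lin)
    if (length(lin) == 1L) return(min(grid$spacing))
    cc <- sweep(cw, 2, colMeans(cw), "-")
    v1 <- svd(cc, nu = 0, nv = 1)$v[, 1]
    proj <- cc %*% v1
    diff(range(proj)) + min(grid$spacing)
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Successes. @param n Trials.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"wilson"` (score interval, via [stats::prop.test()]
#'   without continuity correction) or `"clopper-pearson"` (exact, via
#'   [stats::binom.test()]).
#' @return Numeric length-2 `c(lower, upper)`.
#' @export
proportion_ci <- function(x, n, conf_level = 0.95,
                          method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (method == "wilson")
    as.numeric(suppressWarnings(
      stats::prop.test(x, n, conf.level = conf_level,
                       correct = FALSE))$conf.int)
  else
    as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' Size-stratified detection report
#'
#' Pools per-scan lesion match results and stratifies them by lesion length
#' into the bins (0,3), [3,6), [6,15), [15,Inf) mm: per bin and overall,
#' sensitivity = TP/GT with a 95% score CI, false positives per scan
#' (FPs binned by the predicted lesion's own length), and optional Dice
#' summaries. Counts always accompany the rates. With no GT lesions at all
#' the sensitivity is reported as NA and flagged, never silently 0.
#'
#' @param matches List of `lesion_match_result`, one per scan.
#' @param gt_lengths List (same order) of numeric vectors: per-GT-lesion
#'   lengths in mm, aligned with `gt_lesions$id`. Computed with
#'   [lesion_lengths()] when `NULL` (requires volume grids with spacing).
#' @param pred_lengths Like `gt_lengths` for predicted lesions (used to bin
#'   FPs); computed when `NULL`.
#' @param dice_per_scan Optional numeric vector of per-scan Dice values.
#' @param bin_edges Lower edges of the length bins, mm.
#' @param conf_level CI level.
#' @param ci_method Passed to [proportion_ci()].
#' @return A `detection_report`: data.frame `table` with one row per bin
#'   plus `"all"`, and fields `n_scans`, `undefined_sensitivity`.
#' @export
stratify_and_summarize <- function(matches, gt_lengths = NULL,
                                   pred_lengths = NULL, dice_per_scan = NULL,
                                   bin_edges = c(0, 3, 6, 15),
                                   conf_level = 0.95,
                                   ci_method = "wilson") {
  n_scans <- length(matches)
  if (!n_scans) stop("stratify_and_summarize: no scans")
  if (is.null(gt_lengths))
    gt_lengths <- lapply(matches, function(m) lesion_lengths(m$gt_labels))
  if (is.null(pred_lengths))
    pred_lengths <- lapply(matches, function(m) lesion_lengths(m$pred_labels))

  edges <- c(bin_edges, Inf)
  bin_of <- function(len) findInterval(len, edges, left.open = FALSE)
  nb <- length(bin_edges)
  bin_label <- c(sprintf("(%g, %g)", bin_edges[1], bin_edges[2]),
                 sprintf("[%g, %g)", bin_edges[-c(1, nb)], edges[-(1:2)][seq_len(nb - 2)]),
                 sprintf("[%g, Inf)", bin_edges[nb]))

  tp <- fn <- fp <- integer(nb)
  for (s in seq_len(n_scans)) {
    m <- matches[[s]]
    gl <- gt_lengths[[s]]
    if (nrow(m$gt_lesions)) {
      b <- bin_of(lengths_for_ids(gl, m$gt_lesions$id))
      for (i in seq_len(nb)) {
        tp[i] <- tp[i] + sum(m$gt_lesions$matched & b == i)
        fn[i] <- fn[i] + sum(!m$gt_lesions$matched & b == i)
      }
    }
    if (nrow(m$pred_lesions)) {
      bp <- bin_of(lengths_for_ids(pred_lengths[[s]], m$pred_lesions$id))
      for (i in seq_len(nb))
        fp[i] <- fp[i] + sum(!m$pred_lesions$matched & bp == i)
    }
  }
  rows <- lapply(seq_len(nb), function(i)
    report_row(bin_label[i], tp[i], fn[i], fp[i], n_scans, conf_level, ci_method))
  rows[[nb + 1]] <- report_row("all", sum(tp), sum(fn), sum(fp), n_scans,
                               conf_level, ci_method)
  tab <- do.call(rbind, rows)
  if (!is.null(dice_per_scan)) {
    tab$dice_mean <- NA_real_; tab$dice_sd <- NA_real_
    tab$dice_mean[nb + 1] <- mean(dice_per_scan)
    tab$dice_sd[nb + 1] <- stats::sd(dice_per_scan)
  }
  structure(list(table = tab, n_scans = n_scans,
                 undefined_sensitivity = sum(tp) + sum(fn) == 0,
                 conf_level = conf_level),
            class = "detection_report")
}

# align a per-lesion length vector with lesion ids: by name when named,
# positionally otherwise
lengths_for_ids <- function(lens, ids) {
  if (!is.null(names(lens))) {
    v <- lens[as.character(ids)]
    if (!anyNA(v)) return(as.numeric(v))
  }
  if (length(lens) < length(ids))
    stop("stratify_and_summarize: fewer lengths than lesions")
  as.numeric(lens)[seq_along(ids)]
}

report_row <- function(bin, tp, fn, fp, n_scans, conf_level, ci_method) {
  n_gt <- tp + fn
  ci <- if (n_gt > 0) proportion_ci(tp, n_gt, conf_level, ci_method)
  else c(NA_real_, NA_real_)
  data.frame(bin = bin, n_gt = n_gt, TP = tp, FN = fn, FP = fp,
             sensitivity = if (n_gt > 0) tp / n_gt else NA_real_,
             ci_lower = ci[1], ci_upper = ci[2],
             fp_per_scan = fp / n_scans)
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %d scans%s\n", x$n_scans,
              if (x$undefined_sensitivity) " [no GT lesions: sensitivity undefined]" else ""))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    cat(sprintf("  %-10s sens %s (%d/%d; %d%% CI %s-%s)  FP/scan %.3g (%d/%d)\n",
                r$bin,
                ifelse(is.na(r$sensitivity), "NA", sprintf("%.3f", r$sensitivity)),
                r$TP, r$n_gt, round(100 * x$conf_level),
                ifelse(is.na(r$ci_lower), "NA", sprintf("%.3f", r$ci_lower)),
                ifelse(is.na(r$ci_upper), "NA", sprintf("%.3f", r$ci_upper)),
                r$fp_per_scan, r$FP, x$n_scans))
  }
  invisible(x)
}

#' Paired two-sided comparison of per-scan metrics
#'
#' Classical paired Student t-test on two equal-length vectors of per-scan
#' metric values. Degenerate inputs are reported explicitly rather than
#' silently: identical vectors give t = 0, p = 1; nonzero constant
#' differences (zero variance) give a flagged degenerate result.
#'
#' @param metric_a,metric_b Numeric vectors, paired by scan.
#' @return List with `t`, `df`, `p_value`, `mean_diff`, `degenerate`,
#'   `reason`.
#' @export
paired_compare <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b))
    stop("paired_compare: vectors differ in length")
  n <- length(metric_a)
  if (n < 2) stop("paired_compare: need at least 2 pairs")
  d <- metric_a - metric_b
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1, p_value = 1, mean_diff = 0,
                  degenerate = TRUE, reason = "identical vectors"))
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p_value = NA_real_,
                mean_diff = mean(d), degenerate = TRUE,
                reason = "zero variance of nonzero differences"))
  }
  ht <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate),
       degenerate = FALSE, reason = NULL)
}
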