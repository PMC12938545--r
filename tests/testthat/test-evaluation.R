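test_that("dice follows the overlap formula and its conventions", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1.0)

  b <- array(FALSE, c(4, 4, 4)); b[3:4, 4, 4] <- TRUE
  expect_equal(dice(a, b), 0.0)

  # |A| = 8, |B| = 8, |A^B| = 4 -> 0.5
  A <- array(FALSE, c(4, 4, 4)); A[1:8] <- TRUE
  B <- array(FALSE, c(4, 4, 4)); B[5:12] <- TRUE
  expect_equal(dice(A, B), 0.5)

  # symmetry
  expect_equal(dice(A, B), dice(B, A))

  # both empty: defined as 1, flagged
  e <- array(FALSE, c(3, 3, 3))
  d <- dice(e, e)
  expect_equal(as.numeric(d), 1.0)
  expect_true(attr(d, "both_empty"))

  expect_error(dice(a, array(FALSE, c(5, 4, 4))), "shapes differ")
})

test_that("lesion matching implements the one-voxel-overlap rule", {
  dm <- c(12L, 12L, 6L)
  gt <- array(0L, dm); gt[2:3, 2:3, 2] <- 1L; gt[8:9, 8:9, 2] <- 2L
  pred <- array(0L, dm); pred[3:4, 3:4, 2] <- 1L  # overlaps GT 1 only
  m <- match_lesions(pred, gt)
  expect_equal(m$TP, 1L); expect_equal(m$FN, 1L); expect_equal(m$FP, 0L)

  # exactly one voxel of contact still counts
  pred1 <- array(0L, dm); pred1[3, 3, 2] <- 1L; pred1[11, 11, 5] <- 2L
  m1 <- match_lesions(pred1, gt)
  expect_equal(m1$TP, 1L); expect_equal(m1$FP, 1L)

  # empty prediction: all GT missed, no FPs
  m0 <- match_lesions(array(0L, dm), gt)
  expect_equal(m0$TP, 0L); expect_equal(m0$FN, 2L); expect_equal(m0$FP, 0L)

  # one prediction spanning both GT lesions credits each once
  pred2 <- array(0L, dm); pred2[2:9, 2:9, 2] <- 1L
  m2 <- match_lesions(pred2, gt)
  expect_equal(m2$TP, 2L); expect_equal(m2$FP, 0L)
  expect_equal(sum(m2$pred_lesions$matched), 1L)

  expect_error(match_lesions(array(0L, c(4, 4, 4)), gt), "shape")
})

test_that("matching agrees with brute-force pair enumeration on random volumes", {
  for (seed in 1:40) {
    set.seed(seed)
    dm <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
    gt <- array(runif(prod(dm)) < 0.12, dm)
    pred <- array(runif(prod(dm)) < 0.12, dm)
    gl <- label_components(gt)
    pl <- label_components(pred)
    m <- match_lesions(pl, gl)
    o <- brute_match_counts(pl, gl)
    expect_equal(m$TP, o$TP)
    expect_equal(m$FN, o$FN)
    expect_equal(m$FP, o$FP)
    # conservation
    expect_equal(m$TP + m$FN, nrow(m$gt_lesions))
  }
})

test_that("stratified summary reproduces published-style count-to-rate conversions", {
  # pooled counts 1375/1643 TP and 188 FP over 98 scans, with the per-bin
  # GT/TP/FP splits of the size-stratified table
  bins_gt <- c(770L, 459L, 280L, 134L)
  bins_tp <- c(608L, 387L, 254L, 126L)
  bins_fp <- c(131L, 37L, 20L, 0L)
  gt_len <- rep(c(1.5, 4, 9, 20), bins_gt)
  matched <- unlist(lapply(1:4, function(i)
    c(rep(TRUE, bins_tp[i]), rep(FALSE, bins_gt[i] - bins_tp[i]))))
  fp_len <- rep(c(1.5, 4, 9, 20), bins_fp)

  one <- fake_match(sum(bins_gt), sum(bins_tp), sum(bins_fp))
  one$gt_lesions$matched <- matched
  scans <- c(list(one), replicate(97, fake_match(0L, 0L, 0L), simplify = FALSE))
  gl <- c(list(gt_len), replicate(97, numeric(0), simplify = FALSE))
  pl <- c(list(fp_len), replicate(97, numeric(0), simplify = FALSE))

  rep_ <- stratify_and_summarize(scans, gl, pl)
  tab <- rep_$table
  all_row <- tab[tab$bin == "all", ]
  expect_equal(all_row$TP, 1375L)
  expect_equal(all_row$n_gt, 1643L)
  expect_equal(round(all_row$sensitivity, 3), 0.837)     # 1375/1643
  expect_equal(all_row$fp_per_scan, 188 / 98)
  expect_lt(abs(all_row$fp_per_scan - 1.91), 0.01)       # printed precision
  expect_equal(tab$sensitivity[1:4],
               c(608 / 770, 387 / 459, 254 / 280, 126 / 134))
  expect_equal(tab$FP[1:4], bins_fp)
  # score CI brackets the published pooled interval
  expect_equal(round(all_row$ci_lower, 3), 0.818, tolerance = 2e-3)
  expect_equal(round(all_row$ci_upper, 3), 0.854, tolerance = 2e-3)
  # conservation within bins
  expect_equal(sum(tab$n_gt[1:4]), all_row$n_gt)
  expect_equal(sum(tab$FP[1:4]), all_row$FP)
})

test_that("empty ground truth is flagged rather than scored as zero sensitivity", {
  scans <- replicate(3, fake_match(0L, 0L, 2L), simplify = FALSE)
  pl <- replicate(3, c(2, 2), simplify = FALSE)
  rep_ <- stratify_and_summarize(scans, replicate(3, numeric(0), simplify = FALSE), pl)
  expect_true(rep_$undefined_sensitivity)
  expect_true(is.na(rep_$table$sensitivity[rep_$table$bin == "all"]))
  expect_equal(rep_$table$fp_per_scan[rep_$table$bin == "all"], 2)
})

test_that("the proportion CI matches the closed-form score interval and covers", {
  for (x in c(3, 50, 1375)) for (n in c(10, 98, 1643)) {
    if (x > n) next
    expect_equal(proportion_ci(x, n), wilson_oracle(x, n), tolerance = 1e-9)
  }
  # empirical coverage >= 93% across operating points
  set.seed(60)
  for (p in c(0.7, 0.85, 0.95)) for (n in c(100, 1600)) {
    xs <- stats::rbinom(2000, n, p)
    ci <- vapply(xs, function(x) wilson_oracle(x, n), numeric(2))
    cover <- mean(ci[1, ] <= p & p <= ci[2, ])
    expect_gte(cover, 0.93)
  }
})

test_that("paired comparison handles regular and degenerate inputs explicitly", {
  set.seed(9)
  a <- rnorm(30); b <- a + rnorm(30, 0.2)
  res <- paired_compare(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_false(res$degenerate)

  same <- paired_compare(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)

  const <- paired_compare(a + 0.1, a)
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))

  expect_error(paired_compare(a, b[1:10]), "length")
  expect_error(paired_compare(1, 2), "at least 2")
})

test_that("lesion lengths measure principal-axis extent", {
  lab <- array(0L, c(20, 8, 8))
  lab[3:12, 4, 4] <- 1L          # 10 voxels along x -> ~10 mm
  lab[1, 1, 1] <- 2L             # single voxel -> one spacing
  len <- lesion_lengths(lab, c(1, 1, 1))
  expect_equal(unname(len["1"]), 10)
  expect_equal(unname(len["2"]), 1)
})
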