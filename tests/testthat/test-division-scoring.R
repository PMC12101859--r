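eval_parts <- function(gt, res, alpha = 0.5) {
  sim <- compute_similarity(gt, res)
  al <- global_alignment(sim)
  m <- match_at_alpha(sim, al, alpha)
  gtf <- build_forest(gt$tracks)
  rsf <- build_forest(res$tracks)
  list(sim = sim, m = m, gtf = gtf, rsf = rsf,
       verdicts = classify_divisions(gtf, rsf, m, alpha))
}

test_that("a matching division with matched parents is a TPD", {
  gt <- dividing_seq()
  res <- as_role(gt, "tracker")
  v <- eval_parts(gt, res)$verdicts
  expect_equal(v$kind, "TPD")
  expect_equal(v$mean_daughter_iou, 1)
  expect_equal(v$gt_frame, 3L)
})

test_that("an unmatched tracker division is an FPD, gt division an FND", {
  gt <- dividing_seq()
  # tracker never divides: parent mask continues to the end
  frames <- replicate(4, gt$frames[[1]], simplify = FALSE)
  res <- cell_sequence(frames, tibble::tibble(label = 1L, begin = 1L, end = 4L,
                                              parent = 0L), "tracker")
  v <- eval_parts(gt, res)$verdicts
  expect_setequal(v$kind, "FND")

  # and the mirror: tracker divides, gt does not
  v2 <- eval_parts(as_role(res, "ground_truth"), as_role(gt, "tracker"))$verdicts
  expect_setequal(v2$kind, "FPD")
})

test_that("daughters that fail the per-cell IOU threshold break the division", {
  gt <- dividing_seq()
  # erode one 12-px daughter to 4 px (IOU 1/3): below alpha = 0.5 it cannot match
  res <- perturb(gt, "erode", label = 3L, keep = 4L)
  parts <- eval_parts(gt, res, alpha = 0.5)
  expect_setequal(parts$verdicts$kind, c("FPD", "FND"))
  # at a permissive alpha the same division is a TPD with the mean daughter IOU
  parts2 <- eval_parts(gt, res, alpha = 0.3)
  expect_equal(parts2$verdicts$kind, "TPD")
  expect_equal(parts2$verdicts$mean_daughter_iou, (1 + 1 / 3) / 2)
})

test_that("a division one frame off is rescued as TPD_early/TPD_late", {
  gt <- dividing_seq(n = 5L, div_frame = 3L)
  early <- perturb(gt, "shift_division_early", label = 1L)
  late <- perturb(gt, "shift_division_late", label = 1L)

  p <- eval_parts(gt, early)
  fx <- detect_flexible(p$gtf, p$rsf, p$m, p$verdicts)
  expect_equal(fx$verdicts$kind, "TPD_early")
  expect_equal(fx$adjustments$type, "early")
  expect_equal(fx$adjustments$t1, 2L)

  p <- eval_parts(gt, late)
  fx <- detect_flexible(p$gtf, p$rsf, p$m, p$verdicts)
  expect_equal(fx$verdicts$kind, "TPD_late")
  expect_equal(fx$adjustments$t1, 3L)
})

test_that("a division two frames off stays an error", {
  gt <- dividing_seq(n = 6L, div_frame = 4L)
  res <- perturb(perturb(gt, "shift_division_early", label = 1L),
                 "shift_division_early", label = 1L)  # now divides at frame 2
  p <- eval_parts(gt, res)
  fx <- detect_flexible(p$gtf, p$rsf, p$m, p$verdicts)
  expect_setequal(fx$verdicts$kind, c("FPD", "FND"))
  r <- suppressWarnings(evaluate_tracking(gt, res))
  expect_lt(r$integrated$CellHOTA, 1)
})

test_that("flexibility cannot cross the movie boundary", {
  gt <- dividing_seq(n = 4L, div_frame = 4L)  # gt divides at the final frame
  frames <- replicate(4, gt$frames[[1]], simplify = FALSE)
  res <- cell_sequence(frames, tibble::tibble(label = 1L, begin = 1L, end = 4L,
                                              parent = 0L), "tracker")
  p <- eval_parts(gt, res)
  fx <- detect_flexible(p$gtf, p$rsf, p$m, p$verdicts)
  expect_equal(fx$verdicts$kind, "FND")
  expect_equal(nrow(fx$adjustments), 0L)
})

test_that("flex adjustments rewrite the shifted frame's detection outcomes", {
  gt <- dividing_seq(n = 5L, div_frame = 3L)
  early <- perturb(gt, "shift_division_early", label = 1L)
  p <- eval_parts(gt, early)
  fx <- detect_flexible(p$gtf, p$rsf, p$m, p$verdicts)
  adj <- apply_flex_adjustments(p$m, gt, early, fx$adjustments)
  expect_true(all(adj$kept))
  # one matched daughter replaced by one merged TP; the spurious daughter FP
  # and the daughter match disappear
  tp <- nrow(p$m$matches) + adj$tp_delta
  fp <- nrow(p$m$unmatched_res) + adj$fp_delta
  fn <- nrow(p$m$unmatched_gt) + adj$fn_delta
  n_gt_cells <- nrow(sequence_detections(gt))
  expect_equal(tp, n_gt_cells)
  expect_equal(fp, 0L)
  expect_equal(fn, 0L)
  # the association list now links the gt cell to the tracker parent at t1
  expect_true(any(adj$assoc_matches$frame == 2L &
                    adj$assoc_matches$gt_label == 1L &
                    adj$assoc_matches$res_label == 1L))

  # late: the merged ground-truth union counts twice
  late <- perturb(gt, "shift_division_late", label = 1L)
  p <- eval_parts(gt, late)
  fx <- detect_flexible(p$gtf, p$rsf, p$m, p$verdicts)
  adj <- apply_flex_adjustments(p$m, gt, late, fx$adjustments)
  expect_equal(nrow(p$m$matches) + adj$tp_delta, n_gt_cells)

  # no adjustments: identity
  none <- apply_flex_adjustments(p$m, gt, late, fx$adjustments[0, ])
  expect_equal(none$assoc_matches,
               p$m$matches[, c("frame", "gt_label", "res_label")])
  expect_equal(none$tp_delta + none$fp_delta + none$fn_delta, 0L)
})

test_that("gt/tracker swap turns early into late and preserves all scores", {
  gt <- dividing_seq(n = 5L, div_frame = 3L)
  for (kind in c("shift_division_early", "shift_division_late")) {
    res <- perturb(gt, kind, label = 1L)
    fwd <- suppressWarnings(evaluate_tracking(gt, res))
    rev <- suppressWarnings(evaluate_tracking(as_role(res, "ground_truth"),
                                              as_role(gt, "tracker")))
    expect_scores_equal(fwd, rev)
    fwd_off <- suppressWarnings(evaluate_tracking(gt, res, flex = FALSE))
    rev_off <- suppressWarnings(evaluate_tracking(as_role(res, "ground_truth"),
                                                  as_role(gt, "tracker"),
                                                  flex = FALSE))
    expect_scores_equal(fwd_off, rev_off)
    expect_equal(fwd_off$per_alpha$FPD, rev_off$per_alpha$FND)
  }
})

test_that("TPD/FPD/FND tallies account for every division at every alpha", {
  gt <- dividing_seq(n = 5L, div_frame = 3L)
  cases <- list(
    as_role(gt, "tracker"),
    perturb(gt, "shift_division_early", label = 1L),
    perturb(gt, "erode", label = 2L, keep = 0.5)
  )
  n_gt_div <- nrow(build_forest(gt$tracks)$divisions)
  for (res in cases) {
    n_res_div <- nrow(build_forest(res$tracks)$divisions)
    pa <- suppressWarnings(evaluate_tracking(gt, res))$per_alpha
    expect_true(all(pa$TPD + pa$FND == n_gt_div))
    expect_true(all(pa$TPD + pa$FPD == n_res_div))
  }
})

test_that("the early-division rescue is invariant to daughter labelling", {
  gt <- dividing_seq(n = 5L, div_frame = 3L)
  early <- perturb(gt, "shift_division_early", label = 1L)
  # relabel the two tracker daughters (2<->3) so the other one is removed
  swapped <- early
  for (t in 2:5) {
    f <- swapped$frames[[t]]
    p2 <- f == 2L; p3 <- f == 3L
    f[p2] <- 3L; f[p3] <- 2L
    swapped$frames[[t]] <- f
  }
  a <- suppressWarnings(evaluate_tracking(gt, early))
  b <- suppressWarnings(evaluate_tracking(gt, swapped))
  expect_scores_equal(a, b)
  expect_equal(a$integrated$CellHOTA, 1)
})
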