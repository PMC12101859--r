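test_that("compute_similarity is exact pixel-set Jaccard", {
  gt <- two_cell_seq(2)
  res <- as_role(gt, "tracker")
  sim <- compute_similarity(gt, res)
  expect_equal(sim$pairs$iou, rep(1, 4))

  # 10-px gt cell overlapping 5 px of a 10-px tracker cell: 5 / 15
  gtm <- frame_with(6, 10, list(list(label = 1, rows = 2:3, cols = 2:6)))
  rsm <- frame_with(6, 10, list(list(label = 7, rows = 3:4, cols = 2:6)))
  g <- cell_sequence(list(gtm), tibble::tibble(label = 1L, begin = 1L, end = 1L,
                                               parent = 0L), "ground_truth")
  r <- cell_sequence(list(rsm), tibble::tibble(label = 7L, begin = 1L, end = 1L,
                                               parent = 0L), "tracker")
  p <- compute_similarity(g, r)$pairs
  expect_equal(p$iou, 5 / 15)

  # disjoint masks produce an empty table
  rsm2 <- frame_with(6, 10, list(list(label = 7, rows = 5:6, cols = 2:6)))
  r2 <- cell_sequence(list(rsm2), r$tracks, "tracker")
  expect_equal(nrow(compute_similarity(g, r2)$pairs), 0L)

  expect_error(compute_similarity(gt, cell_sequence(list(gtm), g$tracks, "tracker")),
               "frame counts")
})

test_that("global alignment follows the frame-count Jaccard formula", {
  # gt track exists 4 frames; tracker exists 2, overlapping 2 of them
  frames <- list(
    frame_with(6, 6, list(list(label = 1, rows = 2:4, cols = 2:4))),
    frame_with(6, 6, list(list(label = 1, rows = 2:4, cols = 2:4))),
    frame_with(6, 6, list(list(label = 1, rows = 2:4, cols = 2:4))),
    frame_with(6, 6, list(list(label = 1, rows = 2:4, cols = 2:4)))
  )
  gt <- cell_sequence(frames, tibble::tibble(label = 1L, begin = 1L, end = 4L,
                                             parent = 0L), "ground_truth")
  rframes <- list(
    frame_with(6, 6, list()),
    frame_with(6, 6, list()),
    frame_with(6, 6, list(list(label = 5, rows = 2:4, cols = 2:4))),
    frame_with(6, 6, list(list(label = 5, rows = 2:4, cols = 2:4)))
  )
  res <- cell_sequence(rframes, tibble::tibble(label = 5L, begin = 3L, end = 4L,
                                               parent = 0L), "tracker")
  al <- global_alignment(compute_similarity(gt, res))
  expect_equal(al$align, 2 / (4 + 2 - 2))

  # co-existing and overlapping everywhere: alignment 1
  al2 <- global_alignment(compute_similarity(gt, as_role(gt, "tracker")))
  expect_equal(al2$align, 1)
})

test_that("matching respects the strict IOU > alpha rule", {
  gtm <- frame_with(6, 10, list(list(label = 1, rows = 2:3, cols = 2:6)))
  rsm <- frame_with(6, 10, list(list(label = 1, rows = 2:3, cols = 4:8)))  # iou 6/14
  g <- cell_sequence(list(gtm), tibble::tibble(label = 1L, begin = 1L, end = 1L,
                                               parent = 0L), "ground_truth")
  r <- cell_sequence(list(rsm), g$tracks, "tracker")
  sim <- compute_similarity(g, r)
  al <- global_alignment(sim)
  expect_equal(sim$pairs$iou, 6 / 14)

  m_lo <- match_at_alpha(sim, al, 0.3)
  expect_equal(nrow(m_lo$matches), 1L)
  m_hi <- match_at_alpha(sim, al, 0.5)
  expect_equal(nrow(m_hi$matches), 0L)
  expect_equal(nrow(m_hi$unmatched_gt), 1L)
  expect_equal(nrow(m_hi$unmatched_res), 1L)
  # IOU exactly equal to alpha is NOT a match
  m_eq <- match_at_alpha(sim, al, 6 / 14)
  expect_equal(nrow(m_eq$matches), 0L)
})

test_that("a 2x2 crossing frame is resolved like the exhaustive oracle", {
  # two adjacent gt cells; tracker cells shifted sideways so one tracker cell
  # overlaps both gt cells and the assignment has real alternatives
  gtm <- frame_with(6, 11, list(list(label = 1, rows = 2:4, cols = 2:5),
                                list(label = 2, rows = 2:4, cols = 6:9)))
  rsm <- frame_with(6, 11, list(list(label = 1, rows = 2:4, cols = 3:6),
                                list(label = 2, rows = 2:4, cols = 7:10)))
  tracks <- tibble::tibble(label = 1:2, begin = 1L, end = 2L, parent = 0L)
  gt <- cell_sequence(list(gtm, gtm), tracks, "ground_truth")
  res <- cell_sequence(list(rsm, rsm), tracks, "tracker")
  ours <- suppressWarnings(evaluate_tracking(gt, res))$per_alpha
  orc <- oracle_hota(gt, res, ours$alpha)
  expect_equal(ours$CellHOTA, orc, tolerance = 1e-9)
})

test_that("the TP count is non-increasing in alpha", {
  for (seed in c(2, 5, 9)) {
    sc <- random_scenario(seed)
    tp <- suppressWarnings(evaluate_tracking(sc$gt, sc$res))$per_alpha$TP
    expect_true(all(diff(tp) <= 0))
  }
})

test_that("swapping gt and tracker roles transposes the matching", {
  sc <- random_scenario(3)
  sim <- compute_similarity(sc$gt, sc$res)
  sim_t <- compute_similarity(as_role(sc$res, "ground_truth"),
                              as_role(sc$gt, "tracker"))
  for (a in c(0.2, 0.5, 0.8)) {
    m <- match_at_alpha(sim, global_alignment(sim), a)$matches
    mt <- match_at_alpha(sim_t, global_alignment(sim_t), a)$matches
    expect_equal(
      dplyr::arrange(m[c("frame", "gt_label", "res_label")],
                     frame, gt_label),
      dplyr::arrange(
        dplyr::rename(mt[c("frame", "res_label", "gt_label")],
                      gt_label = res_label, res_label = gt_label),
        frame, gt_label)
    )
  }
})
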