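# Tiny hand-built sequences used across the unit tests. All fixtures are
# constructed in code; masks are small integer matrices.

# stamp rectangular cells into a blank frame: cells is a list of
# list(label, rows, cols)
frame_with <- function(h, w, cells = list()) {
  m <- matrix(0L, h, w)
  for (cl in cells) m[cl$rows, cl$cols] <- as.integer(cl$label)
  m
}

# two cells tracked over `n` frames, cell 1 in rows 2:4, cell 2 in rows 7:9
two_cell_seq <- function(n = 4L, role = "ground_truth") {
  frames <- replicate(n, frame_with(10, 6, list(
    list(label = 1, rows = 2:4, cols = 2:5),
    list(label = 2, rows = 7:9, cols = 2:5)
  )), simplify = FALSE)
  cell_sequence(frames,
                tibble::tibble(label = 1:2, begin = 1L, end = n, parent = 0L),
                role = role)
}

# one cell that divides: parent (rows 2:7) until frame `div_frame` - 1, then
# daughters 2 (rows 2:4) and 3 (rows 5:7), exactly partitioning the parent
dividing_seq <- function(n = 4L, div_frame = 3L, role = "ground_truth") {
  parent <- list(label = 1, rows = 2:7, cols = 2:5)
  d1 <- list(label = 2, rows = 2:4, cols = 2:5)
  d2 <- list(label = 3, rows = 5:7, cols = 2:5)
  frames <- lapply(seq_len(n), function(t) {
    if (t < div_frame) frame_with(9, 6, list(parent))
    else frame_with(9, 6, list(d1, d2))
  })
  tracks <- tibble::tibble(
    label = 1:3,
    begin = c(1L, div_frame, div_frame),
    end = c(div_frame - 1L, n, n),
    parent = c(0L, 1L, 1L)
  )
  cell_sequence(frames, tracks, role = role)
}

# role-flipped copy (for symmetry tests)
as_role <- function(seq, role) {
  cell_sequence(seq$frames, seq$tracks, role = role)
}

expect_scores_equal <- function(a, b, tol = 1e-12) {
  cols <- c("DetA", "AssA", "DivA", "AssDivA", "CellHOTA", "HOTA")
  expect_equal(a$per_alpha[cols], b$per_alpha[cols], tolerance = tol)
  expect_equal(a$integrated[cols], b$integrated[cols], tolerance = tol)
}
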