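#' Per-frame mask IOU between ground truth and tracker detections
#'
#' Exact pixel-set Jaccard index for every (ground truth, tracker) pair of
#' detections that overlap by at least one pixel; non-overlapping pairs are
#' not stored. Both sequences must share frame count and image dimensions; no
#' resampling is ever performed.
#'
#' @param gt,res `cell_sequence` objects (ground truth / tracker).
#' @return a `similarity_table`: list with `pairs` (tibble `frame`,
#'   `gt_label`, `res_label`, `intersection`, `iou`), `gt_detections` and
#'   `res_detections` (per-frame areas, see [sequence_detections()]) and
#'   `n_frames`.
#' @export
compute_similarity <- function(gt, res) {
  stopifnot(inherits(gt, "cell_sequence"), inherits(res, "cell_sequence"))
  if (n_frames(gt) != n_frames(res)) {
    stop("frame counts differ: ", n_frames(gt), " vs ", n_frames(res), call. = FALSE)
  }
  if (!identical(dim(gt$frames[[1]]), dim(res$frames[[1]]))) {
    stop("image dimensions differ between sequences", call. = FALSE)
  }
  gt_det <- sequence_detections(gt)
  res_det <- sequence_detections(res)

  pairs <- lapply(seq_len(n_frames(gt)), function(t) {
    a <- gt$frames[[t]]; b <- res$frames[[t]]
    sel <- a > 0L & b > 0L
    if (!any(sel)) return(NULL)
    inter <- as.data.frame(table(gt_label = a[sel], res_label = b[sel]),
                           stringsAsFactors = FALSE)
    inter <- inter[inter$Freq > 0L, ]
    tibble(frame = t,
           gt_label = as.integer(inter$gt_label),
           res_label = as.integer(inter$res_label),
           intersection = as.integer(inter$Freq))
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0L) {
    pairs <- tibble(frame = integer(), gt_label = integer(), res_label = integer(),
                    intersection = integer(), iou = double())
  } else {
    pairs <- pairs |>
      dplyr::left_join(dplyr::rename(gt_det, gt_label = "label", gt_area = "area"),
                       by = c("frame", "gt_label")) |>
      dplyr::left_join(dplyr::rename(res_det, res_label = "label", res_area = "area"),
                       by = c("frame", "res_label")) |>
      dplyr::mutate(iou = .data$intersection /
                      (.data$gt_area + .data$res_area - .data$intersection)) |>
      dplyr::select("frame", "gt_label", "res_label", "intersection", "iou")
  }
  structure(list(pairs = pairs, gt_detections = gt_det, res_detections = res_det,
                 n_frames = n_frames(gt)),
            class = "similarity_table")
}

#' Global track-pair alignment scores
#'
#' For every (ground-truth track, tracker track) pair that ever overlaps, a
#' Jaccard-style alignment over frames:
#' (frames both exist and overlap) / (frames gt exists + frames tracker
#' exists - frames both exist and overlap). Used to bias the per-frame
#' assignment toward globally consistent matches, the standard realisation of
#' matching that maximises the final HOTA score.
#'
#' @param sim a `similarity_table` from [compute_similarity()].
#' @return tibble with `gt_label`, `res_label`, `align`.
#' @export
global_alignment <- function(sim) {
  stopifnot(inherits(sim, "similarity_table"))
  gt_n <- dplyr::count(sim$gt_detections, .data$label, name = "gt_frames")
  res_n <- dplyr::count(sim$res_detections, .data$label, name = "res_frames")
  if (nrow(sim$pairs) == 0L) {
    return(tibble(gt_label = integer(), res_label = integer(), align = double()))
  }
  sim$pairs |>
    dplyr::count(.data$gt_label, .data$res_label, name = "both") |>
    dplyr::left_join(dplyr::rename(gt_n, gt_label = "label"), by = "gt_label") |>
    dplyr::left_join(dplyr::rename(res_n, res_label = "label"), by = "res_label") |>
    dplyr::mutate(align = .data$both /
                    (.data$gt_frames + .data$res_frames - .data$both)) |>
    dplyr::select("gt_label", "res_label", "align")
}

#' One-to-one per-frame matching at a similarity threshold
#'
#' Within each frame, a maximum-score one-to-one assignment (Hungarian
#' algorithm) over the detection pairs with IOU strictly greater than
#' `alpha`; the assignment score is the global alignment plus a small IOU
#' bonus (`align + 1e-6 * iou`), with deterministic tie-breaking toward the
#' lowest label pair. The strict inequality follows the metric's matching
#' rule: an IOU exactly equal to alpha is not a match.
#'
#' @param sim a `similarity_table`.
#' @param align alignment scores from [global_alignment()].
#' @param alpha similarity threshold in (0, 1).
#' @return an `alpha_matching`: list with `alpha`, `matches` (tibble `frame`,
#'   `gt_label`, `res_label`, `iou`), `unmatched_gt` and `unmatched_res`
#'   (tibbles `frame`, `label`).
#' @export
match_at_alpha <- function(sim, align, alpha) {
  stopifnot(inherits(sim, "similarity_table"), alpha > 0, alpha < 1)
  elig <- sim$pairs[sim$pairs$iou > alpha, ]
  elig <- dplyr::left_join(elig, align, by = c("gt_label", "res_label"))
  elig$score <- elig$align + 1e-6 * elig$iou

  match_rows <- vector("list", sim$n_frames)
  for (t in unique(elig$frame)) {
    e <- elig[elig$frame == t, ]
    gl <- sort(unique(e$gt_label)); rl <- sort(unique(e$res_label))
    ni <- length(gl); nj <- length(rl)
    S <- matrix(0, ni, nj)
    i <- match(e$gt_label, gl); j <- match(e$res_label, rl)
    # lexicographic objective: every eligible match contributes a unit, so the
    # assignment maximises the number of matches first; the scaled alignment
    # score (plus IOU bonus and a tiny low-label tie-break) decides between
    # matchings of equal size. 0 = forbidden pair.
    pref <- e$score +
      1e-12 * (2 - (i - 1) / max(ni, 1) - (j - 1) / (max(ni, 1) * max(nj, 1)))
    S[cbind(i, j)] <- 1 + pref / (4 * max(ni, nj))
    if (ni <= nj) {
      sol <- clue::solve_LSAP(S, maximum = TRUE)
      ii <- seq_len(ni); jj <- as.integer(sol)
    } else {
      sol <- clue::solve_LSAP(t(S), maximum = TRUE)
      jj <- seq_len(nj); ii <- as.integer(sol)
    }
    keep <- S[cbind(ii, jj)] > 0
    if (any(keep)) {
      me <- tibble(frame = t, gt_label = gl[ii[keep]], res_label = rl[jj[keep]])
      me <- dplyr::left_join(me, e[, c("gt_label", "res_label", "iou")],
                             by = c("gt_label", "res_label"))
      match_rows[[t]] <- me
    }
  }
  matches <- dplyr::bind_rows(match_rows)
  if (nrow(matches) == 0L) {
    matches <- tibble(frame = integer(), gt_label = integer(),
                      res_label = integer(), iou = double())
  }
  unmatched <- function(det, matched, col) {
    key_d <- paste(det$frame, det$label)
    key_m <- paste(matched$frame, matched[[col]])
    det[!(key_d %in% key_m), c("frame", "label")]
  }
  structure(
    list(alpha = alpha, matches = matches,
         unmatched_gt = unmatched(sim$gt_detections, matches, "gt_label"),
         unmatched_res = unmatched(sim$res_detections, matches, "res_label")),
    class = "alpha_matching"
  )
}
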