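#' Detection accuracy at one threshold
#'
#' Jaccard similarity of detections: `TP / (TP + FP + FN)`. With an empty
#' universe (no detections on either side) the two sequences agree perfectly
#' and 1 is returned with a warning.
#'
#' @param tp,fp,fn detection counts at one alpha.
#' @param warn emit the empty-universe warning (default `TRUE`).
#' @return detection accuracy in \[0, 1\].
#' @export
detection_accuracy <- function(tp, fp, fn, warn = TRUE) {
  denom <- tp + fp + fn
  if (denom == 0) {
    if (warn) warning("no detections in either sequence; DetA defined as 1", call. = FALSE)
    return(1)
  }
  tp / denom
}

#' Association accuracy at one threshold
#'
#' For each detected true positive `c` (one matched detection in one frame),
#' the association score is `A(c) = TPA(c) / (TPA(c) + FPA(c) + FNA(c))`,
#' where for the track pair behind `c`: TPA counts the frames the pair is
#' matched to each other, FPA the frames the tracker track is matched to a
#' different ground-truth track, and FNA the frames the ground-truth track is
#' matched to a different tracker track. The accuracy is the mean of `A(c)`
#' over all detected true positives. With no true positives it is defined as
#' 0 (with a warning).
#'
#' @param matches tibble of matched detections with columns `frame`,
#'   `gt_label`, `res_label` (e.g. `m$matches` of an `alpha_matching`, or the
#'   rewired list from [apply_flex_adjustments()]).
#' @param warn emit the no-TP warning (default `TRUE`).
#' @return association accuracy in \[0, 1\].
#' @seealso [association_scores()] for the per-pair table.
#' @export
association_accuracy <- function(matches, warn = TRUE) {
  if (nrow(matches) == 0L) {
    if (warn) warning("no true positives; AssA defined as 0", call. = FALSE)
    return(0)
  }
  p <- association_scores(matches)
  sum(p$TPA * p$A) / sum(p$TPA)
}

#' Per-pair association counts and scores
#'
#' @inheritParams association_accuracy
#' @return tibble with one row per matched (ground truth, tracker) track pair:
#'   `gt_label`, `res_label`, `TPA`, `FPA`, `FNA` and `A`.
#' @export
association_scores <- function(matches) {
  if (nrow(matches) == 0L) {
    return(tibble(gt_label = integer(), res_label = integer(), TPA = integer(),
                  FPA = integer(), FNA = integer(), A = double()))
  }
  gt_tot <- dplyr::count(matches, .data$gt_label, name = "gt_tot")
  res_tot <- dplyr::count(matches, .data$res_label, name = "res_tot")
  matches |>
    dplyr::count(.data$gt_label, .data$res_label, name = "TPA") |>
    dplyr::left_join(gt_tot, by = "gt_label") |>
    dplyr::left_join(res_tot, by = "res_label") |>
    dplyr::mutate(
      FPA = .data$res_tot - .data$TPA,
      FNA = .data$gt_tot - .data$TPA,
      A = .data$TPA / (.data$TPA + .data$FPA + .data$FNA)
    ) |>
    dplyr::select("gt_label", "res_label", "TPA", "FPA", "FNA", "A")
}

#' Division accuracy at one threshold
#'
#' Jaccard similarity over division events: `TPD / (TPD + FPD + FND)`.
#' Undefined (`NA`) when no divisions exist on either side.
#'
#' @param tpd,fpd,fnd division counts at one alpha.
#' @return division accuracy in \[0, 1\], or `NA` when undefined.
#' @export
division_accuracy <- function(tpd, fpd, fnd) {
  denom <- tpd + fpd + fnd
  if (denom == 0) return(NA_real_)
  tpd / denom
}

#' Combine the per-alpha sub-scores
#'
#' `AssDivA` is the geometric mean of association and division accuracy (the
#' two are weighted equally); `CellHOTA` is the geometric mean of detection
#' accuracy and `AssDivA`; `HOTA` the geometric mean of detection and
#' association accuracy. On division-free data (`DivA` undefined) `AssDivA`
#' falls back to `AssA`, so Cell-HOTA reduces exactly to HOTA.
#'
#' @param deta,assa detection and association accuracy in \[0, 1\].
#' @param diva division accuracy in \[0, 1\], or `NA` when undefined.
#' @return one-row tibble with `DetA`, `AssA`, `DivA`, `AssDivA`, `CellHOTA`,
#'   `HOTA`.
#' @export
combine_alpha <- function(deta, assa, diva = NA_real_) {
  assdiva <- if (is.na(diva)) assa else sqrt(assa * diva)
  tibble(
    DetA = deta, AssA = assa, DivA = diva, AssDivA = assdiva,
    CellHOTA = sqrt(deta * assdiva), HOTA = sqrt(deta * assa)
  )
}

#' Integrate per-alpha scores over the threshold grid
#'
#' Each integrated score is the arithmetic mean of its per-alpha values over
#' exactly the grid used (default 0.05 to 0.95 in steps of 0.05, 19 values).
#' Alphas where `DivA` is undefined are excluded from the `DivA` (and only
#' the `DivA`) mean.
#'
#' @param per_alpha tibble with one row per grid value: `alpha` plus the
#'   [combine_alpha()] columns.
#' @param alpha_grid the grid the rows belong to.
#' @return one-row tibble of integrated `DetA`, `AssA`, `DivA`, `AssDivA`,
#'   `CellHOTA`, `HOTA`.
#' @export
integrate_alpha <- function(per_alpha, alpha_grid = per_alpha$alpha) {
  if (nrow(per_alpha) != length(alpha_grid) ||
      !isTRUE(all.equal(per_alpha$alpha, alpha_grid))) {
    stop("per-alpha table does not line up with the alpha grid", call. = FALSE)
  }
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x[!is.na(x)])
  tibble(
    DetA = mean(per_alpha$DetA), AssA = mean(per_alpha$AssA),
    DivA = mean_def(per_alpha$DivA), AssDivA = mean(per_alpha$AssDivA),
    CellHOTA = mean(per_alpha$CellHOTA), HOTA = mean(per_alpha$HOTA)
  )
}

#' Evaluate a tracking result with Cell-HOTA
#'
#' Runs the full pipeline: pixel IOU similarity, per-alpha Hungarian
#' matching, division classification (with optional one-frame early/late
#' flexibility), detection/association/division counting, per-alpha scores
#' and integration over the alpha grid. Deterministic for fixed inputs.
#'
#' @param gt ground-truth `cell_sequence`.
#' @param res tracker `cell_sequence`.
#' @param alpha_grid similarity thresholds, strictly increasing in (0, 1);
#'   default `seq(0.05, 0.95, by = 0.05)` (19 values).
#' @param flex accept divisions predicted one frame early or late, adjusting
#'   detection and association tallies as if on time (default `TRUE`).
#' @param link_gaps treat single-child parent links as track continuations
#'   (merge the child into the parent identity) instead of new identities
#'   (default `FALSE`).
#' @return a `cell_hota` object: list with `per_alpha` (tibble of scores and
#'   counts per alpha), `integrated` (one-row tibble), `alpha_grid`, `flex`,
#'   `link_gaps`. Scores are kept in \[0, 1\]; printing and report files
#'   scale by 100.
#' @examples
#' gt <- generate_scenario(scenario_config(n_frames = 4,
#'                                         divisions = list(c(1, 3))))
#' evaluate_tracking(gt, gt)
#' @export
evaluate_tracking <- function(gt, res,
                              alpha_grid = seq(0.05, 0.95, by = 0.05),
                              flex = TRUE, link_gaps = FALSE) {
  stopifnot(inherits(gt, "cell_sequence"), inherits(res, "cell_sequence"))
  if (length(alpha_grid) == 0L || any(alpha_grid <= 0) || any(alpha_grid >= 1) ||
      is.unsorted(alpha_grid, strictly = TRUE)) {
    stop("alpha_grid must be strictly increasing within (0, 1)", call. = FALSE)
  }
  gt <- resolve_gap_links(gt, link_gaps)
  res <- resolve_gap_links(res, link_gaps)
  gt_forest <- build_forest(gt$tracks)
  res_forest <- build_forest(res$tracks)
  sim <- compute_similarity(gt, res)
  align <- global_alignment(sim)

  rows <- vector("list", length(alpha_grid))
  for (k in seq_along(alpha_grid)) {
    alpha <- alpha_grid[k]
    m <- match_at_alpha(sim, align, alpha)
    verdicts <- classify_divisions(gt_forest, res_forest, m, alpha)
    tp <- nrow(m$matches)
    fp <- nrow(m$unmatched_res)
    fn <- nrow(m$unmatched_gt)
    assoc <- m$matches[, c("frame", "gt_label", "res_label")]
    if (flex) {
      fx <- detect_flexible(gt_forest, res_forest, m, verdicts)
      if (nrow(fx$adjustments) > 0L) {
        adj <- apply_flex_adjustments(m, gt, res, fx$adjustments)
        verdicts <- upgrade_verdicts(verdicts, fx$adjustments[adj$kept, ])
        tp <- tp + adj$tp_delta
        fp <- fp + adj$fp_delta
        fn <- fn + adj$fn_delta
        assoc <- adj$assoc_matches
      }
    }
    tpd <- sum(startsWith(verdicts$kind, "TPD"))
    fpd <- sum(verdicts$kind == "FPD")
    fnd <- sum(verdicts$kind == "FND")
    warn <- k == 1L
    sc <- combine_alpha(
      detection_accuracy(tp, fp, fn, warn = warn),
      association_accuracy(assoc, warn = warn),
      division_accuracy(tpd, fpd, fnd)
    )
    rows[[k]] <- dplyr::bind_cols(
      tibble(alpha = alpha), sc,
      tibble(TP = tp, FP = fp, FN = fn, TPD = tpd, FPD = fpd, FND = fnd)
    )
  }
  per_alpha <- dplyr::bind_rows(rows)
  structure(
    list(per_alpha = per_alpha,
         integrated = integrate_alpha(per_alpha, alpha_grid),
         alpha_grid = alpha_grid, flex = flex, link_gaps = link_gaps,
         n_frames = n_frames(gt)),
    class = "cell_hota"
  )
}

# single-child parent links: merge the child into the parent identity
# (link_gaps = TRUE) or sever the link so the child is a new identity.
resolve_gap_links <- function(seq, link_gaps) {
  tr <- seq$tracks
  kids <- tr[tr$parent != 0L, ]
  singles <- kids$label[kids$parent %in% names(which(table(kids$parent) == 1L))]
  if (length(singles) == 0L) return(seq)
  if (!link_gaps) {
    tr$parent[tr$label %in% singles] <- 0L
    seq$tracks <- tr
    return(seq)
  }
  # walk chains child -> parent so labels collapse to the chain root
  for (child in singles) {
    parent <- tr$parent[tr$label == child]
    for (t in seq_along(seq$frames)) {
      f <- seq$frames[[t]]
      f[f == child] <- parent
      seq$frames[[t]] <- f
    }
    i <- match(parent, tr$label); j <- match(child, tr$label)
    tr$end[i] <- tr$end[j]
    tr$parent[tr$parent == child] <- parent
    # re-point any later single-child chains through the merged label
    tr <- tr[-j, ]
  }
  seq$tracks <- tr
  seq
}
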