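# Independent brute-force HOTA oracle for tiny division-free instances.
# Deliberately shares no code path with the package: naive per-label IOU and
# exhaustive enumeration of every per-frame one-to-one matching, picking the
# combination that maximises HOTA_alpha.

oracle_iou_table <- function(gt, res) {
  out <- list()
  for (t in seq_along(gt$frames)) {
    a <- gt$frames[[t]]; b <- res$frames[[t]]
    for (gl in setdiff(unique(as.vector(a)), 0L)) {
      for (rl in setdiff(unique(as.vector(b)), 0L)) {
        inter <- sum(a == gl & b == rl)
        if (inter > 0L) {
          uni <- sum(a == gl | b == rl)
          out[[length(out) + 1L]] <- data.frame(
            frame = t, gt_label = gl, res_label = rl, iou = inter / uni)
        }
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(frame = integer(), gt_label = integer(), res_label = integer(),
               iou = double())
  } else {
    do.call(rbind, out)
  }
}

# all maximum-cardinality one-to-one matchings over an eligible pair list of
# one frame, as integer vectors of row indices into `pairs`. The HOTA matching
# is defined lexicographically — maximise the true-positive count first, then
# the association score — so lower-cardinality matchings are never candidates.
oracle_frame_matchings <- function(pairs) {
  gts <- unique(pairs$gt_label)
  recurse <- function(i, used_res, chosen) {
    if (i > length(gts)) return(list(chosen))
    out <- recurse(i + 1L, used_res, chosen)  # leave gts[i] unmatched
    rows <- which(pairs$gt_label == gts[i] & !(pairs$res_label %in% used_res))
    for (r in rows) {
      out <- c(out, recurse(i + 1L, c(used_res, pairs$res_label[r]), c(chosen, r)))
    }
    out
  }
  all <- recurse(1L, integer(), integer())
  sizes <- lengths(all)
  all[sizes == max(sizes)]
}

oracle_hota_alpha <- function(gt, res, alpha, iou_tab = oracle_iou_table(gt, res)) {
  n_gt <- sum(vapply(gt$frames, function(m) length(setdiff(unique(as.vector(m)), 0L)),
                     integer(1)))
  n_res <- sum(vapply(res$frames, function(m) length(setdiff(unique(as.vector(m)), 0L)),
                      integer(1)))
  elig <- iou_tab[iou_tab$iou > alpha, ]
  frames <- seq_along(gt$frames)
  per_frame <- lapply(frames, function(t) {
    p <- elig[elig$frame == t, ]
    list(pairs = p, matchings = oracle_frame_matchings(p))
  })
  best <- -Inf
  combo_eval <- function(t, acc) {
    if (t > length(frames)) {
      tp <- nrow(acc)
      deta <- if (n_gt + n_res == 0L) 1 else tp / (n_gt + n_res - tp)
      if (tp == 0L) {
        assa <- 0
      } else {
        key <- paste(acc$gt_label, acc$res_label)
        tpa <- table(key)
        tot_g <- table(acc$gt_label)
        tot_r <- table(acc$res_label)
        pg <- sub(" .*", "", names(tpa)); pr <- sub(".* ", "", names(tpa))
        a <- as.vector(tpa) /
          (as.vector(tot_g[pg]) + as.vector(tot_r[pr]) - as.vector(tpa))
        assa <- sum(as.vector(tpa) * a) / tp
      }
      best <<- max(best, sqrt(deta * assa))
      return(invisible())
    }
    for (mi in per_frame[[t]]$matchings) {
      combo_eval(t + 1L, rbind(acc, per_frame[[t]]$pairs[mi, ]))
    }
    invisible()
  }
  combo_eval(1L, elig[0, ])
  best
}

oracle_hota <- function(gt, res, alphas) {
  iou_tab <- oracle_iou_table(gt, res)
  # the optimum only changes where the eligible-pair set changes, so cache by
  # eligibility pattern rather than recomputing per alpha
  cache <- new.env(parent = emptyenv())
  vapply(alphas, function(a) {
    key <- paste0("k", paste(which(iou_tab$iou > a), collapse = ","))
    if (is.null(cache[[key]])) {
      cache[[key]] <- oracle_hota_alpha(gt, res, a, iou_tab)
    }
    cache[[key]]
  }, double(1))
}
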