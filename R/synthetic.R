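#' Configuration for a synthetic tracking scenario
#'
#' Describes a ground-truth movie of labelled cell masks with a known binary
#' lineage. Two layouts are available: `mother_machine_1d` stacks cells in a
#' single microfluidic-style channel (divisions split a cell along the
#' channel axis), `open_2d` arranges cells on a grid as for freely growing
#' mammalian cells. Cell masks are static over time and daughters exactly
#' partition the parent mask, so every IOU the metric sees is an exact
#' pixel-count ratio. Non-sibling cells are separated by background, giving
#' perturbations unambiguous effects.
#'
#' @param mode `"mother_machine_1d"` or `"open_2d"`.
#' @param n_initial_cells number of cells present in frame 1.
#' @param n_frames number of frames (>= 1).
#' @param divisions division schedule: list of `c(track, frame)` pairs (or a
#'   two-column matrix/data frame); `track` divides so its daughters first
#'   appear at `frame`.
#' @param cell_shape `"rectangle"` or `"ellipse"`.
#' @param seed integer recorded with the scenario (generation itself is
#'   deterministic).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(mode = c("mother_machine_1d", "open_2d"),
                            n_initial_cells = 1L, n_frames = 4L,
                            divisions = list(),
                            cell_shape = c("rectangle", "ellipse"),
                            seed = 1L) {
  mode <- match.arg(mode)
  cell_shape <- match.arg(cell_shape)
  if (is.data.frame(divisions) || is.matrix(divisions)) {
    divisions <- lapply(seq_len(nrow(divisions)),
                        function(i) as.integer(divisions[i, 1:2]))
  }
  stopifnot(n_initial_cells >= 1L, n_frames >= 1L)
  divisions <- lapply(divisions, function(d) {
    if (length(d) != 2L || d[2] < 2L || d[2] > n_frames) {
      stop("each division must be c(track, frame) with 2 <= frame <= n_frames",
           call. = FALSE)
    }
    as.integer(d)
  })
  structure(list(mode = mode, n_initial_cells = as.integer(n_initial_cells),
                 n_frames = as.integer(n_frames), divisions = divisions,
                 cell_shape = cell_shape, seed = as.integer(seed)),
            class = "scenario_config")
}

# root cell pixel sets (linear indices) and the image dimensions
scenario_layout <- function(config) {
  n <- config$n_initial_cells
  if (config$mode == "mother_machine_1d") {
    # one vertical channel; cell i occupies 30 rows x 8 cols inside a 36-row slot
    H <- 36L * n + 14L; W <- 16L
    cells <- lapply(seq_len(n), function(i) {
      r0 <- (i - 1L) * 36L + 3L
      shape_pixels(config$cell_shape, r0, 5L, 30L, 8L, H)
    })
  } else {
    # grid of 36x36 slots; cell 24 rows x 24 cols inside each
    k <- ceiling(sqrt(n))
    H <- 36L * k + 4L; W <- 36L * k + 4L
    cells <- lapply(seq_len(n), function(i) {
      gr <- (i - 1L) %/% k; gc <- (i - 1L) %% k
      shape_pixels(config$cell_shape, gr * 36L + 7L, gc * 36L + 7L, 24L, 24L, H)
    })
  }
  list(cells = cells, H = H, W = W)
}

shape_pixels <- function(shape, r0, c0, h, w, H) {
  rows <- seq.int(r0, r0 + h - 1L); cols <- seq.int(c0, c0 + w - 1L)
  grid <- expand.grid(row = rows, col = cols)
  if (shape == "ellipse") {
    cy <- r0 + (h - 1) / 2; cx <- c0 + (w - 1) / 2
    keep <- ((grid$row - cy) / (h / 2))^2 + ((grid$col - cx) / (w / 2))^2 <= 1
    grid <- grid[keep, ]
  }
  sort(as.integer((grid$col - 1L) * H + grid$row))
}

# split a pixel set into two halves along its longer axis; the halves
# exactly partition the parent, so the daughters' union equals the parent.
split_pixels <- function(px, H) {
  row <- (px - 1L) %% H + 1L
  col <- (px - 1L) %/% H + 1L
  along <- if (diff(range(row)) >= diff(range(col))) row else col
  o <- order(along, px)
  half <- length(px) %/% 2L
  list(sort(px[o[seq_len(half)]]), sort(px[o[-seq_len(half)]]))
}

#' Generate a ground-truth sequence from a scenario configuration
#'
#' @param config a [scenario_config()].
#' @return a validated ground-truth [cell_sequence()].
#' @examples
#' gt <- generate_scenario(scenario_config(n_frames = 4,
#'                                         divisions = list(c(1, 3))))
#' build_forest(gt)
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lay <- scenario_layout(config)
  n <- config$n_initial_cells
  state <- list(
    pixels = lay$cells,
    tracks = tibble(label = seq_len(n), begin = 1L, end = config$n_frames,
                    parent = 0L),
    divided = rep(FALSE, n)
  )
  divs <- config$divisions
  if (length(divs) > 0L) {
    o <- order(vapply(divs, `[`, integer(1), 2L),
               vapply(divs, `[`, integer(1), 1L))
    for (d in divs[o]) {
      lab <- d[1]; f <- d[2]
      i <- match(lab, state$tracks$label)
      if (is.na(i)) stop("division schedule names unknown track ", lab, call. = FALSE)
      if (state$divided[i] || state$tracks$begin[i] > f - 1L) {
        stop("track ", lab, " cannot divide at frame ", f,
             " (not alive or already divided)", call. = FALSE)
      }
      halves <- split_pixels(state$pixels[[i]], lay$H)
      state$tracks$end[i] <- f - 1L
      state$divided[i] <- TRUE
      for (h in 1:2) {
        state$tracks <- dplyr::add_row(state$tracks,
                                       label = max(state$tracks$label) + 1L,
                                       begin = f, end = config$n_frames,
                                       parent = lab)
        state$pixels[[nrow(state$tracks)]] <- halves[[h]]
        state$divided <- c(state$divided, FALSE)
      }
    }
  }
  frames <- lapply(seq_len(config$n_frames), function(t) {
    m <- matrix(0L, lay$H, lay$W)
    for (i in seq_len(nrow(state$tracks))) {
      if (state$tracks$begin[i] <= t && t <= state$tracks$end[i]) {
        m[state$pixels[[i]]] <- state$tracks$label[i]
      }
    }
    m
  })
  out <- cell_sequence(frames, state$tracks, role = "ground_truth")
  attr(out, "config") <- config
  out
}

#' Apply a controlled perturbation to a sequence
#'
#' Returns a tracker-role copy of `seq` differing only by the requested edit.
#' Each kind targets one error family of the metric:
#' \describe{
#'   \item{`erode`}{shrink a cell to `keep` pixels (or fraction); nested
#'     masks make the IOU exactly `keep / area` (localisation error).}
#'   \item{`dilate`}{grow a cell by `amount` background pixels.}
#'   \item{`translate`}{shift a cell's mask by `by = c(rows, cols)`.}
#'   \item{`drop_detection`}{remove a cell from its first or last frame
#'     (false negative).}
#'   \item{`drop_track`}{remove a childless track entirely.}
#'   \item{`add_spurious`}{stamp a new one-frame cell at `at = c(row, col)`
#'     of size `size = c(h, w)` (false positive).}
#'   \item{`id_switch`}{from `frame` on, each track in `labels` continues
#'     under a fresh identity (the classic tracking ID switch; association
#'     error only).}
#'   \item{`id_swap`}{exchange the identities of two tracks from `frame` on
#'     (crossing tracks; association error only).}
#'   \item{`shift_division_early`/`shift_division_late`}{move the division of
#'     parent `label` so the daughters first appear one frame earlier/later,
#'     replacing the parent mask by the two daughter masks (or vice versa) in
#'     the shifted frame; all other masks stay bit-identical.}
#'   \item{`merge_cells`}{relabel `labels[2]`'s pixels to `labels[1]` in one
#'     boundary frame (under-segmentation).}
#' }
#'
#' @param seq a `cell_sequence` (usually ground truth).
#' @param kind perturbation kind, see above.
#' @param label,labels target track label(s).
#' @param frame,frames target frame(s); default all frames of the track where
#'   that makes sense.
#' @param keep,amount,by,at,size kind-specific parameters.
#' @return a validated tracker-role `cell_sequence`.
#' @export
perturb <- function(seq, kind, label = NULL, labels = NULL, frame = NULL,
                    frames = NULL, keep = NULL, amount = NULL, by = NULL,
                    at = NULL, size = NULL) {
  stopifnot(inherits(seq, "cell_sequence"))
  fr <- seq$frames
  tr <- seq$tracks
  H <- nrow(fr[[1]])
  span_frames <- function(l) {
    i <- match(l, tr$label)
    if (is.na(i)) stop("unknown label ", l, call. = FALSE)
    seq.int(tr$begin[i], tr$end[i])
  }
  has_children <- function(l) any(tr$parent == l)

  switch(
    kind,
    erode = {
      tfs <- if (is.null(frames)) span_frames(label) else frames
      for (t in tfs) {
        px <- which(fr[[t]] == label)
        k <- if (keep < 1) round(keep * length(px)) else keep
        if (k < 1L || k > length(px)) stop("erode: keep out of range", call. = FALSE)
        fr[[t]][px[-seq_len(k)]] <- 0L
      }
    },
    dilate = {
      tfs <- if (is.null(frames)) span_frames(label) else frames
      for (t in tfs) {
        m <- fr[[t]]
        need <- amount
        while (need > 0L) {
          px <- which(m == label)
          nb <- unique(c(px - 1L, px + 1L, px - H, px + H))
          nb <- nb[nb >= 1L & nb <= length(m)]
          nb <- sort(nb[m[nb] == 0L])
          if (length(nb) == 0L) stop("dilate: no room to grow", call. = FALSE)
          take <- nb[seq_len(min(need, length(nb)))]
          m[take] <- label
          need <- need - length(take)
        }
        fr[[t]] <- m
      }
    },
    translate = {
      tfs <- if (is.null(frames)) span_frames(label) else frames
      for (t in tfs) {
        m <- fr[[t]]
        px <- which(m == label)
        row <- (px - 1L) %% H + 1L; col <- (px - 1L) %/% H + 1L
        nr <- row + by[1]; nc <- col + if (length(by) > 1L) by[2] else 0L
        if (any(nr < 1L | nr > H | nc < 1L | nc > ncol(m))) {
          stop("translate: mask leaves the image", call. = FALSE)
        }
        np <- (nc - 1L) * H + nr
        m[px] <- 0L
        if (any(m[np] != 0L)) stop("translate: target pixels occupied", call. = FALSE)
        m[np] <- label
        fr[[t]] <- m
      }
    },
    drop_detection = {
      i <- match(label, tr$label)
      if (is.na(i)) stop("unknown label ", label, call. = FALSE)
      if (frame == tr$begin[i]) tr$begin[i] <- tr$begin[i] + 1L
      else if (frame == tr$end[i]) {
        if (has_children(label)) {
          stop("cannot drop the pre-division frame of parent ", label, call. = FALSE)
        }
        tr$end[i] <- tr$end[i] - 1L
      } else stop("drop_detection only at a track's first or last frame", call. = FALSE)
      fr[[frame]][fr[[frame]] == label] <- 0L
      if (tr$begin[i] > tr$end[i]) {
        if (has_children(label)) stop("cannot remove parent track ", label, call. = FALSE)
        tr <- tr[-i, ]
      }
    },
    drop_track = {
      i <- match(label, tr$label)
      if (is.na(i)) stop("unknown label ", label, call. = FALSE)
      if (has_children(label)) stop("cannot remove parent track ", label, call. = FALSE)
      for (t in span_frames(label)) fr[[t]][fr[[t]] == label] <- 0L
      tr <- tr[-i, ]
    },
    add_spurious = {
      new_lab <- max(tr$label) + 1L
      rows <- seq.int(at[1], at[1] + size[1] - 1L)
      cols <- seq.int(at[2], at[2] + size[2] - 1L)
      if (max(rows) > H || max(cols) > ncol(fr[[1]])) {
        stop("add_spurious: region leaves the image", call. = FALSE)
      }
      px <- as.integer(outer((cols - 1L) * H, rows, `+`))
      if (any(fr[[frame]][px] != 0L)) {
        stop("add_spurious: region overlaps an existing cell", call. = FALSE)
      }
      fr[[frame]][px] <- new_lab
      tr <- dplyr::add_row(tr, label = new_lab, begin = frame, end = frame,
                           parent = 0L)
    },
    id_switch = {
      for (l in labels) {
        i <- match(l, tr$label)
        if (is.na(i)) stop("unknown label ", l, call. = FALSE)
        if (frame <= tr$begin[i] || frame > tr$end[i]) {
          stop("id_switch frame must lie strictly inside the track span", call. = FALSE)
        }
        new_lab <- max(tr$label) + 1L
        for (t in seq.int(frame, tr$end[i])) {
          fr[[t]][fr[[t]] == l] <- new_lab
        }
        tr <- dplyr::add_row(tr, label = new_lab, begin = frame,
                             end = tr$end[i], parent = 0L)
        tr$end[i] <- frame - 1L
        tr$parent[tr$parent == l & tr$begin >= frame] <- new_lab
      }
    },
    id_swap = {
      a <- labels[1]; b <- labels[2]
      ia <- match(a, tr$label); ib <- match(b, tr$label)
      if (is.na(ia) || is.na(ib)) stop("unknown label(s)", call. = FALSE)
      if (tr$end[ia] != tr$end[ib] || frame <= max(tr$begin[ia], tr$begin[ib]) ||
          has_children(a) || has_children(b)) {
        stop("id_swap needs two childless tracks both spanning the swap frame ",
             "to a common end", call. = FALSE)
      }
      for (t in seq.int(frame, tr$end[ia])) {
        m <- fr[[t]]
        pa <- m == a; pb <- m == b
        m[pa] <- b; m[pb] <- a
        fr[[t]] <- m
      }
    },
    shift_division_early = {
      d <- division_of(tr, label)
      f <- d$frame
      i <- match(label, tr$label)
      if (f - 2L < tr$begin[i]) {
        stop("shift_division_early: parent would vanish (movie/track boundary)",
             call. = FALSE)
      }
      m <- fr[[f - 1L]]
      m[m == label] <- 0L
      for (dl in c(d$d1, d$d2)) {
        px <- which(fr[[f]] == dl)
        if (any(m[px] != 0L)) stop("shifted daughter overlaps another cell", call. = FALSE)
        m[px] <- dl
      }
      fr[[f - 1L]] <- m
      tr$end[i] <- f - 2L
      tr$begin[match(c(d$d1, d$d2), tr$label)] <- f - 1L
    },
    shift_division_late = {
      d <- division_of(tr, label)
      f <- d$frame
      i <- match(label, tr$label)
      j1 <- match(d$d1, tr$label); j2 <- match(d$d2, tr$label)
      if (f + 1L > length(fr) || tr$end[j1] < f + 1L || tr$end[j2] < f + 1L) {
        stop("shift_division_late: no room after the division (movie/track boundary)",
             call. = FALSE)
      }
      m <- fr[[f]]
      m[m == d$d1 | m == d$d2] <- 0L
      px <- which(fr[[f - 1L]] == label)
      if (any(m[px] != 0L)) stop("shifted parent overlaps another cell", call. = FALSE)
      m[px] <- label
      fr[[f]] <- m
      tr$end[i] <- f
      tr$begin[c(j1, j2)] <- f + 1L
    },
    merge_cells = {
      a <- labels[1]; b <- labels[2]
      ib <- match(b, tr$label)
      if (is.na(match(a, tr$label)) || is.na(ib)) stop("unknown label(s)", call. = FALSE)
      if (frame == tr$begin[ib]) tr$begin[ib] <- tr$begin[ib] + 1L
      else if (frame == tr$end[ib] && !has_children(b)) tr$end[ib] <- tr$end[ib] - 1L
      else stop("merge_cells only at the absorbed track's first or last frame",
                call. = FALSE)
      fr[[frame]][fr[[frame]] == b] <- a
      if (tr$begin[ib] > tr$end[ib]) tr <- tr[-ib, ]
    },
    stop("unknown perturbation kind: ", kind, call. = FALSE)
  )
  cell_sequence(fr, tr, role = "tracker")
}

division_of <- function(tr, parent_label) {
  ch <- tr[tr$parent == parent_label, ]
  if (nrow(ch) != 2L) stop("label ", parent_label, " has no binary division",
                           call. = FALSE)
  list(d1 = ch$label[1], d2 = ch$label[2], frame = ch$begin[1])
}

#' Named benchmark scenarios
#'
#' A catalog of ground truth + tracker pairs, each isolating one metric
#' behaviour with a hand-computable expected score:
#' \describe{
#'   \item{`perfect`}{tracker identical to ground truth (one division).}
#'   \item{`erode`}{one cell eroded to exactly 60% of its area in every
#'     frame (IOU 0.6): a TP below alpha 0.6, an FP+FN above.}
#'   \item{`id_swap`}{two tracks both handed over to fresh identities at the
#'     movie midpoint: AssA 0.5 at every alpha, DetA 1.}
#'   \item{`shift_division_early` / `shift_division_late`}{the one division
#'     predicted one frame early/late with otherwise identical masks.}
#'   \item{`drop_detection`}{one cell missing from the final frame.}
#'   \item{`add_spurious`}{one extra one-frame cell.}
#' }
#'
#' @param name scenario name.
#' @param seed recorded in the configuration.
#' @return list with `gt`, `res` (both `cell_sequence`) and `name`.
#' @export
synthetic_scenario <- function(name = c("perfect", "erode", "id_swap",
                                        "shift_division_early",
                                        "shift_division_late",
                                        "drop_detection", "add_spurious"),
                               seed = 1L) {
  name <- match.arg(name)
  div2 <- scenario_config(n_initial_cells = 2L, n_frames = 5L,
                          divisions = list(c(1L, 3L)), seed = seed)
  flat2 <- scenario_config(n_initial_cells = 2L, n_frames = 4L, seed = seed)
  res <- switch(
    name,
    perfect = {
      gt <- generate_scenario(div2)
      list(gt = gt, res = cell_sequence(gt$frames, gt$tracks, role = "tracker"))
    },
    erode = {
      gt <- generate_scenario(flat2)
      list(gt = gt, res = perturb(gt, "erode", label = 2L, keep = 144L))
    },
    id_swap = {
      gt <- generate_scenario(flat2)
      list(gt = gt, res = perturb(gt, "id_switch", labels = c(1L, 2L), frame = 3L))
    },
    shift_division_early = {
      gt <- generate_scenario(div2)
      list(gt = gt, res = perturb(gt, "shift_division_early", label = 1L))
    },
    shift_division_late = {
      gt <- generate_scenario(div2)
      list(gt = gt, res = perturb(gt, "shift_division_late", label = 1L))
    },
    drop_detection = {
      gt <- generate_scenario(flat2)
      list(gt = gt, res = perturb(gt, "drop_detection", label = 2L, frame = 4L))
    },
    add_spurious = {
      gt <- generate_scenario(flat2)
      list(gt = gt, res = perturb(gt, "add_spurious", frame = 2L,
                                  at = c(2L, 2L), size = c(3L, 3L)))
    }
  )
  res$name <- name
  res
}

#' Random division-free scenario for cross-validation against brute force
#'
#' Draws a small movie (1-3 cells, 3 frames, mother-machine layout) and a
#' random mix of erosion, dropped tracks, identity switches and mask
#' translations — the error families whose optimal matching a brute-force
#' enumeration can still verify. Fully determined by `seed`.
#'
#' @param seed integer seed.
#' @param n_frames number of frames (default 3).
#' @return list with `gt` and `res`.
#' @export
random_scenario <- function(seed, n_frames = 3L) {
  old <- .Random.seed_exists()
  on.exit(old())
  set.seed(seed)
  n <- sample(1:3, 1)
  gt <- generate_scenario(scenario_config(n_initial_cells = n,
                                          n_frames = n_frames, seed = seed))
  res <- cell_sequence(gt$frames, gt$tracks, role = "tracker")
  dropped <- integer()
  for (l in seq_len(n)) {
    act <- sample(c("keep", "erode", "drop"), 1, prob = c(0.5, 0.35, 0.15))
    if (act == "erode") {
      res <- perturb(res, "erode", label = l,
                     keep = sample(c(120L, 144L, 180L, 216L), 1))
    } else if (act == "drop" && length(dropped) < n - 0L && n > 1L) {
      res <- perturb(res, "drop_track", label = l)
      dropped <- c(dropped, l)
    }
  }
  alive <- setdiff(seq_len(n), dropped)
  if (length(alive) >= 2L && stats::runif(1) < 0.4) {
    res <- perturb(res, "id_switch", labels = alive[1:2], frame = 2L)
  }
  # occasionally slide a cell toward a dropped neighbour's slot so several
  # ground-truth cells overlap one tracker cell (exercises the assignment)
  if (length(dropped) > 0L && length(alive) > 0L && stats::runif(1) < 0.5) {
    tgt <- dropped[1]; src <- alive[which.min(abs(alive - tgt))]
    if (src %in% res$tracks$label) {
      res <- perturb(res, "translate", label = src,
                     by = c(10L * sign(tgt - src), 0L))
    }
  }
  list(gt = gt, res = res)
}

# restore the RNG state on exit so generators don't disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
}
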