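#' Construct a cell tracking sequence
#'
#' Bundles a label movie (one integer label matrix per frame, background 0)
#' with its track table. Frames are indexed 1..T internally; the track table
#' uses the Cell Tracking Challenge columns: `label`, first frame `begin`,
#' last frame `end` (inclusive) and `parent` (0 for none).
#'
#' @param frames list of integer matrices of identical dimensions.
#' @param tracks data frame with columns `label`, `begin`, `end`, `parent`.
#' @param role `"ground_truth"` or `"tracker"`.
#' @param validate check invariants and error on violations (default `TRUE`).
#' @return A `cell_sequence` object.
#' @seealso [read_ctc_sequence()], [validate_sequence()]
#' @export
cell_sequence <- function(frames, tracks, role = c("ground_truth", "tracker"),
                          validate = TRUE) {
  role <- match.arg(role)
  if (!is.list(frames) || length(frames) == 0L) {
    stop("a sequence needs at least one frame", call. = FALSE)
  }
  frames <- lapply(frames, function(m) {
    if (!is.matrix(m)) stop("each frame must be a matrix", call. = FALSE)
    if (is.double(m)) {
      if (any(m != floor(m))) stop("non-integer pixel values in mask", call. = FALSE)
      storage.mode(m) <- "integer"
    }
    m
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must share the same height and width", call. = FALSE)
  }
  tracks <- as_tibble(tracks)[, c("label", "begin", "end", "parent")]
  tracks[] <- lapply(tracks, as.integer)
  tracks <- dplyr::arrange(tracks, .data$label)
  x <- structure(
    list(frames = frames, tracks = tracks, role = role),
    class = "cell_sequence"
  )
  if (validate) {
    d <- validate_sequence(x)
    err <- d[d$severity == "error", ]
    if (nrow(err) > 0L) {
      stop("invalid sequence:\n  ", paste(err$message, collapse = "\n  "),
           call. = FALSE)
    }
  }
  x
}

#' @export
print.cell_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cell_sequence: %s, %d frame(s), %dx%d px, %d track(s), %d division(s)>\n",
              x$role, length(x$frames), d[1], d[2], nrow(x$tracks),
              sum(table(x$tracks$parent[x$tracks$parent != 0]) == 2L)))
  invisible(x)
}

n_frames <- function(seq) length(seq$frames)

#' Per-frame detections of a sequence
#'
#' One row per (frame, label) with the pixel area of the detection.
#'
#' @param seq a `cell_sequence`.
#' @return tibble with columns `frame`, `label`, `area`.
#' @export
sequence_detections <- function(seq) {
  res <- lapply(seq_along(seq$frames), function(t) {
    m <- seq$frames[[t]]
    v <- m[m > 0L]
    if (length(v) == 0L) return(NULL)
    tab <- table(v)
    tibble(frame = t, label = as.integer(names(tab)), area = as.integer(tab))
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(frame = integer(), label = integer(), area = integer())
  }
  out
}

#' Validate a sequence against its structural invariants
#'
#' Checks the track table (unique labels, spans, parent links) against the
#' label movie (every mask label covered by a track spanning that frame and
#' vice versa). Division structure is checked too: a parent with two children
#' must have both daughters begin at the parent's last frame + 1; a parent
#' with a single child (the CTC gap-closing idiom) is flagged as a warning;
#' three or more children are an error.
#'
#' @param seq a `cell_sequence`.
#' @return tibble of diagnostics with columns `severity` ("error"/"warning"),
#'   `kind`, `frame`, `label`, `message`; zero rows when all invariants hold.
#' @export
validate_sequence <- function(seq) {
  diags <- list()
  add <- function(severity, kind, frame, label, message) {
    diags[[length(diags) + 1L]] <<- tibble(
      severity = severity, kind = kind,
      frame = as.integer(frame), label = as.integer(label), message = message
    )
  }
  tr <- seq$tracks
  T <- n_frames(seq)

  if (anyDuplicated(tr$label)) {
    for (l in unique(tr$label[duplicated(tr$label)])) {
      add("error", "duplicate_label", NA, l, sprintf("duplicate track label %d", l))
    }
  }
  for (i in seq_len(nrow(tr))) {
    l <- tr$label[i]
    if (l < 1L) add("error", "bad_label", NA, l, sprintf("track label %d is not positive", l))
    if (tr$begin[i] > tr$end[i]) {
      add("error", "bad_span", NA, l, sprintf("label %d: begin %d > end %d", l, tr$begin[i], tr$end[i]))
    }
    if (tr$begin[i] < 1L || tr$end[i] > T) {
      add("error", "span_outside_movie", NA, l,
          sprintf("label %d: span [%d,%d] outside movie 1..%d", l, tr$begin[i], tr$end[i], T))
    }
    p <- tr$parent[i]
    if (p != 0L) {
      if (p == l) add("error", "self_parent", NA, l, sprintf("label %d is its own parent", l))
      j <- match(p, tr$label)
      if (is.na(j)) {
        add("error", "dangling_parent", NA, l,
            sprintf("label %d names parent %d which has no track record", l, p))
      } else if (tr$end[j] >= tr$begin[i]) {
        add("error", "parent_overlap", NA, l,
            sprintf("label %d begins at %d but parent %d ends at %d", l, tr$begin[i], p, tr$end[j]))
      }
    }
  }

  kids <- tr[tr$parent != 0L, ]
  if (nrow(kids) > 0L) {
    for (p in unique(kids$parent)) {
      ch <- kids[kids$parent == p, ]
      if (nrow(ch) == 1L) {
        add("warning", "single_child_parent", NA, ch$label[1],
            sprintf("parent %d has a single child %d (gap link?)", p, ch$label[1]))
      } else if (nrow(ch) >= 3L) {
        add("error", "too_many_children", NA, p,
            sprintf("parent %d has %d simultaneous children", p, nrow(ch)))
      } else {
        j <- match(p, tr$label)
        if (!is.na(j) && (length(unique(ch$begin)) != 1L || ch$begin[1] != tr$end[j] + 1L)) {
          add("error", "division_timing", NA, p,
              sprintf("daughters of parent %d do not both begin at parent end + 1", p))
        }
      }
    }
  }

  det <- sequence_detections(seq)
  for (i in seq_len(nrow(det))) {
    l <- det$label[i]; t <- det$frame[i]
    j <- match(l, tr$label)
    if (is.na(j)) {
      add("error", "untracked_label", t, l,
          sprintf("label %d appears in frame %d but has no track record", l, t))
    } else if (t < tr$begin[j] || t > tr$end[j]) {
      add("error", "label_outside_span", t, l,
          sprintf("label %d appears in frame %d outside its span [%d,%d]", l, t, tr$begin[j], tr$end[j]))
    }
  }
  for (i in seq_len(nrow(tr))) {
    l <- tr$label[i]
    span <- seq.int(max(1L, tr$begin[i]), min(T, tr$end[i]))
    present <- det$frame[det$label == l]
    missing <- setdiff(span, present)
    for (t in missing) {
      add("error", "label_missing_in_span", t, l,
          sprintf("label %d missing from frame %d inside its span [%d,%d]", l, t, tr$begin[i], tr$end[i]))
    }
  }

  if (length(diags) == 0L) {
    tibble(severity = character(), kind = character(), frame = integer(),
           label = integer(), message = character())
  } else {
    dplyr::bind_rows(diags)
  }
}

# pixel linear indices of one label in one frame (integer vector, may be empty)
label_pixels <- function(seq, frame, label) {
  which(seq$frames[[frame]] == label)
}
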