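#' Build the lineage forest of a track table
#'
#' Derives the parent/daughter structure and the list of division events. A
#' division is a parent with exactly two children; both daughters begin at the
#' parent's last frame + 1, and the event is timestamped at the daughters'
#' first frame. Single-child parent links (the CTC gap-closing idiom) carry no
#' division and are dropped from the forest edges — by default the child is a
#' new identity (see `link_gaps` in [evaluate_tracking()]).
#'
#' @param tracks track table (tibble with `label`, `begin`, `end`, `parent`)
#'   or a `cell_sequence`.
#' @return a `lineage_forest`: list with `nodes` (labels), `edges`
#'   (tibble `parent`, `child`) and `divisions`
#'   (tibble `parent`, `daughter1`, `daughter2`, `frame`).
#' @export
build_forest <- function(tracks) {
  if (inherits(tracks, "cell_sequence")) tracks <- tracks$tracks
  tracks <- as_tibble(tracks)
  kids <- tracks[tracks$parent != 0L, ]

  # cycle check on parent links
  parent_of <- stats::setNames(kids$parent, kids$label)
  for (l in kids$label) {
    seen <- integer(); cur <- l
    while (!is.na(parent_of[as.character(cur)])) {
      if (cur %in% seen) stop("cycle in parent links at label ", cur, call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent_of[[as.character(cur)]]
    }
  }

  divisions <- tibble(parent = integer(), daughter1 = integer(),
                      daughter2 = integer(), frame = integer())
  edges <- tibble(parent = integer(), child = integer())
  if (nrow(kids) > 0L) {
    for (p in sort(unique(kids$parent))) {
      ch <- kids[kids$parent == p, ]
      if (nrow(ch) >= 3L) {
        stop("parent ", p, " has ", nrow(ch), " simultaneous children; ",
             "only binary divisions are supported", call. = FALSE)
      }
      if (nrow(ch) == 2L) {
        pe <- tracks$end[match(p, tracks$label)]
        if (length(unique(ch$begin)) != 1L || ch$begin[1] != pe + 1L) {
          stop("daughters of parent ", p, " do not both begin at parent end + 1",
               call. = FALSE)
        }
        d <- sort(ch$label)
        divisions <- dplyr::add_row(divisions, parent = p, daughter1 = d[1],
                                    daughter2 = d[2], frame = ch$begin[1])
        edges <- dplyr::add_row(edges, parent = p, child = d[1])
        edges <- dplyr::add_row(edges, parent = p, child = d[2])
      }
      # single child: gap link, no division, no edge
    }
  }
  structure(
    list(nodes = sort(tracks$label), edges = edges,
         divisions = dplyr::arrange(divisions, .data$frame, .data$parent)),
    class = "lineage_forest"
  )
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("<lineage_forest: %d track(s), %d division(s)>\n",
              length(x$nodes), nrow(x$divisions)))
  invisible(x)
}

#' Division events at one frame
#'
#' @param forest a `lineage_forest` from [build_forest()].
#' @param frame frame index.
#' @return the rows of `forest$divisions` whose daughters first appear at
#'   `frame`, ordered by parent label.
#' @export
divisions_at <- function(forest, frame) {
  d <- forest$divisions[forest$divisions$frame == frame, ]
  dplyr::arrange(d, .data$parent)
}
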