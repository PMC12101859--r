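#' Read a Cell Tracking Challenge formatted sequence
#'
#' Reads per-frame integer label masks (single-channel TIFF, background 0)
#' plus the four-column lineage table (`label begin end parent`, whitespace
#' separated, no header). Frame numbers parsed from the mask filenames must be
#' contiguous; they are mapped to internal 1-based frames, labels are kept
#' verbatim.
#'
#' @param mask_dir directory holding the mask TIFFs (`*.tif`).
#' @param track_file path to the lineage table; defaults to `man_track.txt`
#'   (ground truth) or `res_track.txt` (tracker) inside `mask_dir`.
#' @param role `"ground_truth"` or `"tracker"`.
#' @return a validated [cell_sequence()].
#' @export
read_ctc_sequence <- function(mask_dir, track_file = NULL,
                              role = c("ground_truth", "tracker")) {
  role <- match.arg(role)
  if (!dir.exists(mask_dir)) stop("mask directory not found: ", mask_dir, call. = FALSE)
  files <- list.files(mask_dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (length(files) == 0L) stop("no TIFF masks in ", mask_dir, call. = FALSE)
  nums <- suppressWarnings(as.integer(sub(".*?(\\d+)\\.tiff?$", "\\1", basename(files))))
  if (anyNA(nums)) stop("mask filenames must end in a frame number", call. = FALSE)
  o <- order(nums)
  files <- files[o]; nums <- nums[o]
  if (anyDuplicated(nums)) stop("duplicate frame numbers in mask filenames", call. = FALSE)
  expected <- seq.int(nums[1], nums[length(nums)])
  if (!identical(nums, expected)) {
    stop("missing frame(s): ", paste(setdiff(expected, nums), collapse = ", "), call. = FALSE)
  }

  frames <- lapply(files, function(f) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (length(dim(m)) != 2L) stop("mask ", basename(f), " is not single-channel", call. = FALSE)
    if (is.double(m) && any(m != floor(m))) {
      stop("non-integer pixel values in ", basename(f), call. = FALSE)
    }
    storage.mode(m) <- "integer"
    m
  })

  if (is.null(track_file)) {
    track_file <- file.path(mask_dir,
                            if (role == "ground_truth") "man_track.txt" else "res_track.txt")
  }
  if (!file.exists(track_file)) stop("track table not found: ", track_file, call. = FALSE)
  tab <- utils::read.table(track_file, header = FALSE,
                           col.names = c("label", "begin", "end", "parent"),
                           colClasses = "integer")
  tracks <- tibble(
    label = tab$label,
    begin = tab$begin - nums[1] + 1L,
    end = tab$end - nums[1] + 1L,
    parent = tab$parent
  )
  cell_sequence(frames, tracks, role = role, validate = TRUE)
}

#' Write a sequence in Cell Tracking Challenge format
#'
#' Emits 16-bit label TIFFs named `man_trackNNN.tif` plus `man_track.txt`
#' (ground truth) or `maskNNN.tif` plus `res_track.txt` (tracker). On-disk
#' frame numbering is normalised to 0-based, so
#' `read_ctc_sequence(write_ctc_sequence(s))` reproduces `s` exactly.
#'
#' @param seq a `cell_sequence`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_ctc_sequence <- function(seq, out_dir) {
  stopifnot(inherits(seq, "cell_sequence"))
  if (length(seq$frames) == 0L) stop("sequence has no frames", call. = FALSE)
  top <- max(0L, vapply(seq$frames, max, integer(1)))
  if (top > 65535L) {
    stop("label ", top, " exceeds the 16-bit range of CTC masks", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- if (seq$role == "ground_truth") "man_track" else "mask"
  width <- max(3L, nchar(as.character(length(seq$frames) - 1L)))
  for (t in seq_along(seq$frames)) {
    f <- file.path(out_dir, sprintf("%s%0*d.tif", prefix, width, t - 1L))
    tiff::writeTIFF(seq$frames[[t]] / 65535, f, bits.per.sample = 16L)
  }
  tab_name <- if (seq$role == "ground_truth") "man_track.txt" else "res_track.txt"
  tr <- seq$tracks
  utils::write.table(
    data.frame(tr$label, tr$begin - 1L, tr$end - 1L, tr$parent),
    file.path(out_dir, tab_name),
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(out_dir)
}
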