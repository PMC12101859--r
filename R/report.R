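#' @export
print.cell_hota <- function(x, ...) {
  g <- x$integrated
  fmt <- function(v) ifelse(is.na(v), "  --  ", sprintf("%6.2f", 100 * v))
  cat(sprintf("Cell-HOTA over %d alpha value(s) (flex %s)\n",
              length(x$alpha_grid), if (x$flex) "on" else "off"))
  cat(sprintf("  Cell-HOTA %s   HOTA %s\n", fmt(g$CellHOTA), fmt(g$HOTA)))
  cat(sprintf("  DetA %s   AssA %s   DivA %s   AssDivA %s\n",
              fmt(g$DetA), fmt(g$AssA), fmt(g$DivA), fmt(g$AssDivA)))
  invisible(x)
}

#' Tidy the per-alpha score table of a Cell-HOTA evaluation
#'
#' @param x a `cell_hota` object from [evaluate_tracking()].
#' @param ... unused.
#' @return tibble with one row per alpha: scores in \[0, 1\] plus the
#'   detection (`TP`, `FP`, `FN`) and division (`TPD`, `FPD`, `FND`) counts.
#' @method tidy cell_hota
#' @export
tidy.cell_hota <- function(x, ...) {
  x$per_alpha
}

#' One-row summary of a Cell-HOTA evaluation
#'
#' @param x a `cell_hota` object.
#' @param ... unused.
#' @return one-row tibble of integrated scores (in \[0, 1\]) plus `n_alpha`,
#'   `flex` and `n_frames`.
#' @method glance cell_hota
#' @export
glance.cell_hota <- function(x, ...) {
  dplyr::bind_cols(
    x$integrated,
    tibble(n_alpha = length(x$alpha_grid), flex = x$flex, n_frames = x$n_frames)
  )
}

#' Plot Cell-HOTA sub-scores across the similarity threshold sweep
#'
#' @param object a `cell_hota` object.
#' @param ... unused.
#' @return a ggplot: one line per sub-metric versus alpha.
#' @method autoplot cell_hota
#' @export
autoplot.cell_hota <- function(object, ...) {
  d <- object$per_alpha |>
    dplyr::select("alpha", "DetA", "AssA", "DivA", "CellHOTA") |>
    tidyr::pivot_longer(-"alpha", names_to = "metric", values_to = "score") |>
    dplyr::filter(!is.na(.data$score))
  ggplot2::ggplot(d, ggplot2::aes(.data$alpha, 100 * .data$score,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(alpha), y = "score", colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Write a Cell-HOTA report to JSON (and optionally CSV)
#'
#' Scores are scaled by 100 and rounded to 2 decimals at serialisation only;
#' the in-memory object keeps full precision in \[0, 1\].
#'
#' @param x a `cell_hota` object.
#' @param json path for the JSON report.
#' @param csv optional path for a flat CSV (one row per alpha).
#' @return `json`, invisibly.
#' @export
write_report <- function(x, json, csv = NULL) {
  stopifnot(inherits(x, "cell_hota"))
  scale2 <- function(d) {
    sc <- intersect(c("DetA", "AssA", "DivA", "AssDivA", "CellHOTA", "HOTA"),
                    names(d))
    d[sc] <- lapply(d[sc], function(v) round(100 * v, 2))
    d
  }
  per_alpha <- scale2(x$per_alpha)
  rep <- list(
    config = list(flex = x$flex, link_gaps = x$link_gaps,
                  n_frames = x$n_frames),
    alpha_grid = x$alpha_grid,
    per_alpha = per_alpha[, c("alpha", "DetA", "AssA", "DivA", "AssDivA",
                              "CellHOTA", "HOTA")],
    counts_per_alpha = x$per_alpha[, c("alpha", "TP", "FP", "FN",
                                       "TPD", "FPD", "FND")],
    integrated = as.list(scale2(x$integrated))
  )
  jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  if (!is.null(csv)) {
    utils::write.csv(per_alpha, csv, row.names = FALSE)
  }
  invisible(json)
}
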