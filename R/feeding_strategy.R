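#' Coordinates for the modified Costello (Amundsen) diagram
#'
#' One point per prey category: frequency of occurrence on the x axis,
#' prey-specific abundance on the y axis. The diagram reads along its
#' diagonals and axes — dominant prey sit at the top right, rare prey at
#' the lower left, prey eaten heavily by few individuals (high
#' between-phenotype component) at the upper left, and prey eaten lightly
#' by many (high within-phenotype component) at the lower right.
#'
#' @param importance a prey-importance table from [prey_importance()].
#' @return a tibble with `prey_category`, `frequency_occurrence` (x) and
#'   `prey_specific_abundance` (y), carrying the group key as attribute.
#' @export
costello_points <- function(importance) {
  needed <- c("prey_category", "frequency_occurrence", "prey_specific_abundance")
  if (!is.data.frame(importance) || !all(needed %in% names(importance))) {
    abort_data("expected a prey-importance table with F and P columns")
  }
  if (nrow(importance) == 0) {
    abort_data("empty prey-importance table: no points to plot")
  }
  out <- tibble::as_tibble(importance[, needed])
  attr(out, "group") <- attr(importance, "group")
  out
}

#' Classify feeding-strategy points
#'
#' Labels each prey point of a Costello diagram by the quadrant it falls
#' in, and the group by its overall feeding strategy:
#' \itemize{
#'   \item importance — `"dominant"` (top right: both coordinates at or
#'     above their thresholds), `"rare"` (bottom left: both below),
#'     `"intermediate"` otherwise, plus a continuous `importance_score`
#'     \eqn{(F_i + P_i)/2} ranking prey along the main diagonal;
#'   \item axis tendency — `"specialization"` for points in the upper half,
#'     `"generalization"` below;
#'   \item phenotype component — `"BPC"` for upper-left points (different
#'     individuals specialise on different prey), `"WPC"` for lower-right
#'     points (all individuals take the prey in small amounts), `"mixed"`
#'     otherwise;
#'   \item group strategy — `"specialized"` if any prey reaches the y
#'     threshold, `"generalized"` if all points lie below it.
#' }
#' Points exactly on a threshold line are assigned to the upper/dominant
#' side, so classification is deterministic.
#'
#' @param points a tibble from [costello_points()].
#' @param x_threshold,y_threshold quadrant boundaries in (0, 100); default
#'   midpoints 50.
#' @return a `strategy_report`: list with the labelled `points` tibble,
#'   the group-level `strategy`, the thresholds, and the group key.
#' @export
classify_points <- function(points, x_threshold = 50, y_threshold = 50) {
  if (!all(is.finite(c(x_threshold, y_threshold))) ||
      x_threshold <= 0 || x_threshold >= 100 ||
      y_threshold <= 0 || y_threshold >= 100) {
    abort_config("quadrant thresholds must lie strictly inside (0, 100)")
  }
  if (nrow(points) == 0) abort_data("no feeding-strategy points to classify")
  x <- points$frequency_occurrence
  y <- points$prey_specific_abundance
  hi_x <- x >= x_threshold
  hi_y <- y >= y_threshold
  labelled <- dplyr::mutate(
    points,
    importance_score = (x + y) / 2,
    importance = dplyr::case_when(hi_x & hi_y ~ "dominant",
                                  !hi_x & !hi_y ~ "rare",
                                  TRUE ~ "intermediate"),
    tendency = ifelse(hi_y, "specialization", "generalization"),
    phenotype_component = dplyr::case_when(hi_y & !hi_x ~ "BPC",
                                           !hi_y & hi_x ~ "WPC",
                                           TRUE ~ "mixed")
  )
  structure(
    list(points = labelled,
         strategy = if (any(hi_y)) "specialized" else "generalized",
         x_threshold = x_threshold,
         y_threshold = y_threshold,
         group = attr(points, "group")),
    class = "strategy_report"
  )
}

#' @export
print.strategy_report <- function(x, ...) {
  grp <- if (is.null(x$group)) "ungrouped" else
    paste(unlist(x$group), collapse = " / ")
  cat(sprintf("<strategy_report> %s: %s feeding strategy, %d prey\n",
              grp, x$strategy, nrow(x$points)))
  print(x$points)
  invisible(x)
}

#' Export feeding-strategy diagrams
#'
#' Writes the point coordinates and labels of one or more strategy reports
#' to a TSV file (deterministic: same report, same bytes) and, optionally,
#' renders the Costello diagram — a scatter on fixed \[0, 100\] x \[0, 100\]
#' axes with dashed reference lines at the thresholds, one panel per
#' group.
#'
#' @param reports a `strategy_report` or a list of them.
#' @param tsv_path path for the coordinates TSV.
#' @param plot_path optional path for a rendered figure (extension decides
#'   the device, e.g. `.png` or `.svg`).
#' @param digits decimals for coordinates written to the TSV (half-up).
#' @return invisibly, the coordinates tibble that was written.
#' @export
export_diagram <- function(reports, tsv_path, plot_path = NULL, digits = 2) {
  if (inherits(reports, "strategy_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "strategy_report")))
  coords <- dplyr::bind_rows(lapply(reports, function(r) {
    pts <- r$points
    grp <- if (is.null(r$group)) "all" else paste(unlist(r$group), collapse = " / ")
    tibble::add_column(pts, group = grp, strategy = r$strategy, .before = 1)
  }))
  num <- vapply(coords, is.numeric, logical(1))
  coords[num] <- lapply(coords[num], round_half_up, digits = digits)
  dir.create(dirname(tsv_path), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(coords, tsv_path, progress = FALSE)

  if (!is.null(plot_path)) {
    thr_x <- reports[[1]]$x_threshold
    thr_y <- reports[[1]]$y_threshold
    p <- ggplot2::ggplot(coords, ggplot2::aes(
      x = .data$frequency_occurrence,
      y = .data$prey_specific_abundance)) +
      ggplot2::geom_hline(yintercept = thr_y, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_vline(xintercept = thr_x, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_point(ggplot2::aes(shape = .data$importance), size = 2) +
      ggplot2::geom_text(ggplot2::aes(label = .data$prey_category),
                         size = 2.5, vjust = -0.8, check_overlap = TRUE) +
      ggplot2::facet_wrap(~group) +
      ggplot2::coord_cartesian(xlim = c(0, 100), ylim = c(0, 100)) +
      ggplot2::labs(x = "Frequency of occurrence (%)",
                    y = "Prey-specific abundance (%)") +
      ggplot2::theme_bw()
    ggplot2::ggsave(plot_path, p, width = 7, height = 6, dpi = 150)
  }
  invisible(coords)
}
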