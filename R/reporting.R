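#' Packaged summary tables from a four-gudgeon diet study
#'
#' Transcriptions of the published specimen and diet-composition summary
#' tables from a gut-content study of four sympatric gudgeon species
#' (*Coreius guichenoti*, *C. heterodon*, *Rhinogobio ventralis*,
#' *R. cylindricus*) in the upper Yangtze River, sampled in spring and
#' autumn. `gudgeon_specimens()` gives per-group specimen counts and
#' standard-length summaries; `gudgeon_diet_composition()` gives per-prey
#' frequency of occurrence and relative abundance (percent, 2 decimals as
#' printed). The composition table is the input for overlap and breadth
#' recomputation — the underlying individual-level records were not
#' deposited.
#'
#' @return a tibble.
#' @export
gudgeon_diet_composition <- function() {
  readr::read_tsv(system.file("extdata", "gudgeon_diet_composition.tsv",
                              package = "gutdiet", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname gudgeon_diet_composition
#' @export
gudgeon_specimens <- function() {
  readr::read_tsv(system.file("extdata", "gudgeon_specimens.tsv",
                              package = "gutdiet", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

group_label <- function(df, group_by) {
  do.call(paste, c(lapply(group_by, function(g) df[[g]]), sep = "|"))
}

#' Split a composition table into per-group proportion vectors
#'
#' Turns a long table of relative abundances (one row per group x prey,
#' as produced by [importance_table()] or shipped in
#' [gudgeon_diet_composition()]) into a named list of
#' [diet_proportions()] vectors, ready for [overlap_matrix()] and
#' [levins_breadth()].
#'
#' @param composition a data frame with group columns, `prey_category`
#'   and `relative_abundance`.
#' @param group_by grouping columns.
#' @param renormalize passed to [diet_proportions()].
#' @return a named list of proportion vectors; names join the group keys
#'   with `"|"`.
#' @export
proportions_by_group <- function(composition,
                                 group_by = c("species", "season"),
                                 renormalize = TRUE) {
  key <- group_label(composition, group_by)
  lapply(split(composition, key), diet_proportions, renormalize = renormalize)
}

#' Prey-importance table for every group
#'
#' Runs [build_diet_matrix()] and [prey_importance()] over a record table
#' and stacks the per-group results into one long table.
#'
#' @inheritParams build_diet_matrix
#' @return a tibble, one row per group x prey.
#' @export
importance_table <- function(records, group_by = c("species", "season")) {
  mats <- build_diet_matrix(records, group_by)
  dplyr::bind_rows(lapply(mats, prey_importance))
}

#' Levins breadth for every group
#'
#' @param proportions a named list of proportion vectors, as from
#'   [proportions_by_group()].
#' @return a tibble with columns `group`, `B` and `S`.
#' @export
breadth_table <- function(proportions) {
  rows <- lapply(names(proportions), function(g) {
    nb <- levins_breadth(proportions[[g]])
    tibble::tibble(group = g, B = nb$B, S = nb$S)
  })
  dplyr::bind_rows(rows)
}

round_table <- function(df, digits) {
  if (is.na(digits)) return(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  df
}

#' Write report tables
#'
#' TSV writers matching the customary layouts of diet studies: a long
#' prey-importance table (group, prey, F, A, P), a square overlap matrix
#' with significance flags, and a breadth table. Numeric columns are
#' rounded half-up to `digits` decimals as published tables are; pass
#' `digits = NA` to keep full precision (machine-readable sidecar).
#'
#' @param x the table or [overlap_matrix()] to write.
#' @param path output file path.
#' @param digits decimals (half-up); `NA` for full precision.
#' @return the path, invisibly.
#' @export
write_importance_tsv <- function(x, path, digits = 2) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(round_table(x, digits), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_importance_tsv
#' @export
write_breadth_tsv <- write_importance_tsv

#' @rdname write_importance_tsv
#' @export
write_overlap_tsv <- function(x, path, digits = 2) {
  stopifnot(inherits(x, "overlap_matrix"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  m <- round_table(as.data.frame(unclass(x)), digits)
  sig <- attr(x, "significant")
  flags <- apply(sig, 1, function(r) paste(names(r)[!is.na(r) & r],
                                           collapse = ", "))
  out <- tibble::add_column(tibble::as_tibble(m), group = rownames(x),
                            .before = 1)
  out$significant_overlap_with <- unname(flags)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

resolve_records <- function(input) {
  if (is.character(input)) read_diet_records(input) else
    validate_diet_records(input)
}

#' Pipeline drivers
#'
#' One-call wrappers chaining the filtering, index, overlap and strategy
#' stages and writing their report tables, for use from analysis scripts.
#' `run_indices()` filters records (when a policy is given), computes the
#' prey-importance and breadth tables and writes them; `run_overlap()`
#' writes the pairwise overlap matrix; `run_strategy()` classifies the
#' Costello points of every group and exports the diagram coordinates
#' (and optionally the figure).
#'
#' @param input a diet-record tibble or a path to a delimited record file.
#' @param out_dir directory for output tables (created if needed).
#' @param policy optional [exclusion_policy()]; when given, prey
#'   exclusions and the juvenile length filter are applied first.
#' @param group_by grouping columns.
#' @param threshold overlap significance threshold (percent).
#' @param x_threshold,y_threshold Costello quadrant thresholds.
#' @param plot also render the strategy diagram (PNG)?
#' @param digits decimals for written tables (half-up).
#' @return a named list of output paths (and the computed objects,
#'   invisibly in the list element `result`).
#' @export
run_indices <- function(input, out_dir, policy = NULL,
                        group_by = c("species", "season"), digits = 2) {
  records <- resolve_records(input)
  if (!is.null(policy)) {
    records <- filter_juveniles(apply_exclusions(records, policy), policy)
  }
  if (nrow(records) == 0) {
    abort_data("no records left after filtering; nothing to report")
  }
  imp <- importance_table(records, group_by)
  if (nrow(imp) == 0) {
    abort_data("no analysable prey in any group after filtering")
  }
  props <- proportions_by_group(imp, group_by)
  breadth <- breadth_table(props)
  paths <- list(
    importance = file.path(out_dir, "prey_importance.tsv"),
    breadth = file.path(out_dir, "niche_breadth.tsv"))
  write_importance_tsv(imp, paths$importance, digits)
  write_breadth_tsv(breadth, paths$breadth, digits)
  paths$result <- list(importance = imp, breadth = breadth)
  invisible(paths)
}

#' @rdname run_indices
#' @export
run_overlap <- function(input, out_dir, policy = NULL,
                        group_by = c("species", "season"),
                        threshold = 60, digits = 2) {
  records <- resolve_records(input)
  if (!is.null(policy)) {
    records <- filter_juveniles(apply_exclusions(records, policy), policy)
  }
  props <- proportions_by_group(importance_table(records, group_by), group_by)
  D <- overlap_matrix(props, threshold = threshold)
  path <- file.path(out_dir, "diet_overlap.tsv")
  write_overlap_tsv(D, path, digits)
  invisible(list(overlap = path, result = D))
}

#' @rdname run_indices
#' @export
run_strategy <- function(input, out_dir, policy = NULL,
                         group_by = c("species", "season"),
                         x_threshold = 50, y_threshold = 50,
                         plot = FALSE, digits = 2) {
  records <- resolve_records(input)
  if (!is.null(policy)) {
    records <- filter_juveniles(apply_exclusions(records, policy), policy)
  }
  mats <- build_diet_matrix(records, group_by)
  reports <- lapply(mats, function(m) {
    classify_points(costello_points(prey_importance(m)),
                    x_threshold = x_threshold, y_threshold = y_threshold)
  })
  tsv <- file.path(out_dir, "feeding_strategy.tsv")
  png <- if (plot) file.path(out_dir, "feeding_strategy.png") else NULL
  export_diagram(reports, tsv, plot_path = png, digits = digits)
  invisible(list(coordinates = tsv, figure = png, result = reports))
}

#' @rdname run_indices
#' @param design a [study_design()] (for `run_simulate`).
#' @export
run_simulate <- function(design, out_dir, digits = 4) {
  records <- generate_study(design)
  path <- file.path(out_dir, "simulated_diet_records.tsv")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- records
  out$prey_weight <- round_half_up(out$prey_weight, digits)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(list(records = path, result = records))
}
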