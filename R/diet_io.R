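#' Read individual-level diet records from a delimited text file
#'
#' Reads a long-format gut-content table: one row per fish x prey category,
#' with specimen metadata repeated on each row. An empty gut is represented
#' by a single marker row whose `prey_category` is missing (empty string or
#' NA) and whose `prey_weight` is 0 or missing; the specimen then stays in
#' the table for size summaries but contributes nothing to diet indices.
#'
#' Required columns: `fish_id`, `species`, `season`, `standard_length`,
#' `prey_category`, `prey_weight`. Optional: `body_weight`, `prey_count`.
#'
#' @param path path to a delimited UTF-8 text file with a header row.
#' @param delim field delimiter; `NULL` (default) guesses tab for `.tsv`
#'   files and comma otherwise.
#' @return a validated diet-record tibble (see [validate_diet_records()]).
#' @export
read_diet_records <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort_data(paste0("diet record file does not exist: ", path))
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  validate_diet_records(raw)
}

#' Validate a diet-record table
#'
#' Checks the schema and row-level invariants of a long-format diet table:
#' required columns present, `standard_length` strictly positive,
#' `prey_weight` non-negative, `prey_count` (if given) a non-negative whole
#' number, and no duplicated (fish_id, prey_category) pair. Offending rows
#' are reported by row number.
#'
#' @param records a data frame of diet records.
#' @return the records as a tibble, with `prey_weight` of empty-gut marker
#'   rows coerced to 0 and optional columns added as NA when absent.
#' @export
validate_diet_records <- function(records) {
  required <- c("fish_id", "species", "season", "standard_length",
                "prey_category", "prey_weight")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort_data(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "gutdiet_schema_error")
  }
  out <- tibble::as_tibble(records)
  if (!"body_weight" %in% names(out)) out$body_weight <- NA_real_
  if (!"prey_count" %in% names(out)) out$prey_count <- NA_integer_
  out$fish_id <- as.character(out$fish_id)
  out$prey_category <- as.character(out$prey_category)
  out$prey_category[!is.na(out$prey_category) &
                      trimws(out$prey_category) == ""] <- NA_character_
  empty_marker <- is.na(out$prey_category)
  out$prey_weight[empty_marker & is.na(out$prey_weight)] <- 0

  bad <- function(cond) which(!is.na(cond) & cond)
  problems <- list(
    "standard_length must be > 0" = bad(out$standard_length <= 0),
    "standard_length is missing"  = which(is.na(out$standard_length)),
    "prey_weight must be >= 0"    = bad(out$prey_weight < 0),
    "prey_weight is missing"      = which(!empty_marker & is.na(out$prey_weight)),
    "prey_count must be a non-negative whole number" =
      bad(out$prey_count < 0 | out$prey_count != floor(out$prey_count)),
    "empty-gut marker row must have prey_weight 0" =
      bad(empty_marker & out$prey_weight != 0),
    "duplicated (fish_id, prey_category) pair" =
      which(!empty_marker &
              duplicated(paste(out$fish_id, out$prey_category, sep = "\r")))
  )
  problems <- problems[lengths(problems) > 0]
  if (length(problems) > 0) {
    msgs <- vapply(seq_along(problems), function(i) {
      rows <- problems[[i]]
      shown <- paste(utils::head(rows, 5), collapse = ", ")
      if (length(rows) > 5) shown <- paste0(shown, ", ...")
      paste0(names(problems)[i], " (row ", shown, ")")
    }, character(1))
    abort_data(c("invalid diet records:", msgs),
               class = "gutdiet_validation_error")
  }
  out
}

#' Specimen-filtering policy
#'
#' Bundles the specimen-handling rules applied before diet indices are
#' computed: prey categories treated as unidentifiable material (weighed but
#' not analysed), categories treated as parasites rather than prey, and the
#' per-species minimum standard length that excludes age-0 juveniles.
#'
#' @param unidentifiable_labels character vector of prey labels to drop as
#'   unidentifiable material.
#' @param parasite_labels character vector of prey labels to drop as
#'   probable parasites.
#' @param min_length_by_species named numeric vector, mm; a fish is retained
#'   only when its standard length is strictly greater than its species'
#'   threshold.
#' @return an `exclusion_policy` object.
#' @seealso [default_exclusion_policy()] for the thresholds used in the
#'   four-gudgeon study this package was built around.
#' @export
exclusion_policy <- function(unidentifiable_labels = character(),
                             parasite_labels = character(),
                             min_length_by_species = numeric()) {
  unidentifiable_labels <- as.character(unidentifiable_labels)
  parasite_labels <- as.character(parasite_labels)
  if (length(intersect(unidentifiable_labels, parasite_labels)) > 0) {
    abort_config("unidentifiable and parasite label sets must be disjoint")
  }
  if (length(min_length_by_species) > 0) {
    if (is.null(names(min_length_by_species)) ||
        any(names(min_length_by_species) == "")) {
      abort_config("min_length_by_species must be a named vector (species -> mm)")
    }
    if (any(!is.finite(min_length_by_species) | min_length_by_species <= 0)) {
      abort_config("length thresholds must be strictly positive")
    }
  }
  structure(
    list(unidentifiable_labels = unidentifiable_labels,
         parasite_labels = parasite_labels,
         min_length_by_species = min_length_by_species),
    class = "exclusion_policy"
  )
}

#' Default policy for the four Yangtze gudgeon species
#'
#' Minimum standard lengths (strict, mm) separating age-0 juveniles from
#' analysable specimens: 96 for *Coreius guichenoti*, 139 for *C.
#' heterodon*, 79 for *Rhinogobio ventralis*, 114 for *R. cylindricus*.
#' Unidentifiable material and cestodes (potential parasites) are excluded
#' from analysis.
#'
#' @return an [exclusion_policy()].
#' @export
default_exclusion_policy <- function() {
  exclusion_policy(
    unidentifiable_labels = "Unidentified",
    parasite_labels = "Cestoda",
    min_length_by_species = c(
      "Coreius guichenoti"     =  96,
      "Coreius heterodon"      = 139,
      "Rhinogobio ventralis"   =  79,
      "Rhinogobio cylindricus" = 114
    )
  )
}

#' Drop unidentifiable and parasite prey rows
#'
#' Removes rows whose prey category the policy marks as unidentifiable
#' material or as a parasite. A fish whose only contents were excluded
#' categories is kept as a specimen but becomes an empty gut (a marker row
#' with missing `prey_category` and zero weight), so it still appears in
#' specimen summaries while contributing nothing to diet indices.
#' Surviving rows are never altered.
#'
#' @param records a validated diet-record tibble.
#' @param policy an [exclusion_policy()].
#' @param verbose if `TRUE`, report how many rows each label set removed.
#' @return the filtered diet-record tibble.
#' @export
apply_exclusions <- function(records, policy, verbose = FALSE) {
  records <- validate_diet_records(records)
  stopifnot(inherits(policy, "exclusion_policy"))
  drop_unident <- records$prey_category %in% policy$unidentifiable_labels
  drop_parasite <- records$prey_category %in% policy$parasite_labels
  if (verbose) {
    rlang::inform(sprintf(
      "apply_exclusions: dropping %d unidentifiable and %d parasite row(s)",
      sum(drop_unident), sum(drop_parasite)))
  }
  kept <- records[!(drop_unident | drop_parasite), , drop = FALSE]

  # Re-seed emptied fish with a marker row carrying their metadata.
  emptied <- setdiff(unique(records$fish_id), unique(kept$fish_id))
  if (length(emptied) > 0) {
    meta <- records[match(emptied, records$fish_id), , drop = FALSE]
    meta$prey_category <- NA_character_
    meta$prey_weight <- 0
    meta$prey_count <- NA_integer_
    kept <- dplyr::bind_rows(kept, meta)
  }
  kept
}

#' Exclude juveniles by species-specific length thresholds
#'
#' Retains only fish whose standard length is strictly greater than the
#' threshold configured for their species ("bigger than" read literally).
#' Every species present in the table must have a threshold.
#'
#' @inheritParams apply_exclusions
#' @return the filtered diet-record tibble (possibly empty).
#' @export
filter_juveniles <- function(records, policy) {
  records <- validate_diet_records(records)
  stopifnot(inherits(policy, "exclusion_policy"))
  species <- unique(records$species)
  missing <- setdiff(species, names(policy$min_length_by_species))
  if (length(missing) > 0) {
    abort_config(paste0("no length threshold configured for species: ",
                        paste(missing, collapse = ", ")))
  }
  thr <- policy$min_length_by_species[records$species]
  records[records$standard_length > thr, , drop = FALSE]
}

#' Build per-group fish-by-prey weight matrices
#'
#' Aggregates a filtered diet-record table into one weight matrix per group
#' (by default species x season): rows are fish, columns are the prey
#' categories observed in that group, cells are grams. Fish with zero total
#' content are kept as all-zero rows but flagged empty; the number of
#' non-empty guts `N` — the denominator of the frequency of occurrence — is
#' stored alongside.
#'
#' @param records a validated diet-record tibble.
#' @param group_by character vector of grouping columns.
#' @return a named list of `diet_matrix` objects (names are the group keys,
#'   e.g. `"Coreius guichenoti|spring"`).
#' @export
build_diet_matrix <- function(records, group_by = c("species", "season")) {
  records <- validate_diet_records(records)
  missing <- setdiff(group_by, names(records))
  if (length(missing) > 0) {
    abort_config(paste0("grouping column(s) not in table: ",
                        paste(missing, collapse = ", ")))
  }
  key <- do.call(paste, c(lapply(group_by, function(g) records[[g]]), sep = "|"))
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    grp <- records[idx, , drop = FALSE]
    fish <- unique(grp$fish_id)
    prey_rows <- grp[!is.na(grp$prey_category), , drop = FALSE]
    prey <- sort(unique(prey_rows$prey_category))
    W <- matrix(0, nrow = length(fish), ncol = length(prey),
                dimnames = list(fish, prey))
    if (nrow(prey_rows) > 0) {
      W[cbind(match(prey_rows$fish_id, fish),
              match(prey_rows$prey_category, prey))] <- prey_rows$prey_weight
    }
    group_key <- as.list(grp[1, group_by, drop = FALSE])
    new_diet_matrix(W, group_key)
  })
  out[order(names(out))]
}

new_diet_matrix <- function(W, group_key) {
  stopifnot(is.matrix(W), all(W >= 0))
  totals <- rowSums(W)
  structure(
    list(group = group_key,
         weights = W,
         fish_totals = totals,
         n_fish = nrow(W),
         n_nonempty = sum(totals > 0)),
    class = "diet_matrix"
  )
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat(sprintf("<diet_matrix> %s: %d fish (%d with contents), %d prey, %.4f g total\n",
              paste(unlist(x$group), collapse = " / "),
              x$n_fish, x$n_nonempty, ncol(x$weights), sum(x$weights)))
  invisible(x)
}

#' Summarise specimens per group
#'
#' Per-group count, mean, standard error, and range of standard length,
#' computed over distinct fish (empty-gut specimens included). The standard
#' error is the sample standard deviation over the square root of n; for a
#' single-fish group it is reported as 0 with a warning.
#'
#' @inheritParams build_diet_matrix
#' @return a tibble with columns `group_by`, `n`, `mean_length_mm`,
#'   `se_length_mm`, `min_length_mm`, `max_length_mm`.
#' @export
summarize_specimens <- function(records, group_by = c("species", "season")) {
  records <- validate_diet_records(records)
  per_fish <- dplyr::distinct(
    records, dplyr::pick(dplyr::all_of(c(group_by, "fish_id", "standard_length"))))
  out <- dplyr::summarise(
    dplyr::group_by(per_fish, dplyr::pick(dplyr::all_of(group_by))),
    n = dplyr::n(),
    mean_length_mm = mean(.data$standard_length),
    se_length_mm = ifelse(dplyr::n() > 1,
                          stats::sd(.data$standard_length) / sqrt(dplyr::n()),
                          0),
    min_length_mm = min(.data$standard_length),
    max_length_mm = max(.data$standard_length),
    .groups = "drop"
  )
  if (any(out$n == 1)) {
    rlang::warn("standard error reported as 0 for group(s) with a single fish")
  }
  out
}
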