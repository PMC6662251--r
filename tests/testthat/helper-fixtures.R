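# Worked toy group used throughout: fish1 {A: 2 g}; fish2 {A: 1 g, B: 1 g};
# fish3 {B: 3 g}; fish4 empty. N = 3, S_t = 7 g.
fixture_w_records <- function() {
  tibble::tibble(
    fish_id = c("fish1", "fish2", "fish2", "fish3", "fish4"),
    species = "sp", season = "spring", standard_length = 150,
    prey_category = c("A", "A", "B", "B", NA),
    prey_weight = c(2, 1, 1, 3, 0))
}

# Random long-format record table for property tests; some empty guts, some
# unidentifiable rows. Caller controls the RNG state.
random_diet_records <- function(n_fish = 6, prey = LETTERS[1:4],
                                p_present = 0.6) {
  rows <- lapply(seq_len(n_fish), function(j) {
    present <- runif(length(prey)) < p_present
    if (!any(present)) {
      tibble::tibble(prey_category = NA_character_, prey_weight = 0)
    } else {
      tibble::tibble(prey_category = prey[present],
                     prey_weight = round(stats::rlnorm(sum(present)), 4))
    }
  })
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(
    out,
    fish_id = rep(sprintf("f%02d", seq_len(n_fish)),
                  vapply(rows, nrow, integer(1))),
    species = "sp", season = "spring",
    standard_length = rep(round(runif(n_fish, 100, 300)),
                          vapply(rows, nrow, integer(1))),
    .before = 1)
  out
}

# A random percent-scale proportion vector over k prey, summing to 100.
random_simplex <- function(k, names = paste0("prey", seq_len(k))) {
  x <- -log(runif(k))
  stats::setNames(x / sum(x) * 100, names)
}

# Published pairwise-overlap values (percent) the composition fixture is
# checked against, keyed as "<species>|<season>" pairs.
published_overlaps <- function() {
  tibble::tribble(
    ~a, ~b, ~season, ~D,
    "Coreius guichenoti", "Coreius heterodon",      "spring", 87.08,
    "Coreius guichenoti", "Rhinogobio ventralis",   "spring", 78.72,
    "Coreius guichenoti", "Rhinogobio cylindricus", "spring", 78.93,
    "Coreius heterodon",  "Rhinogobio ventralis",   "spring", 82.65,
    "Coreius heterodon",  "Rhinogobio cylindricus", "spring", 84.48,
    "Rhinogobio ventralis", "Rhinogobio cylindricus", "spring", 89.68,
    "Coreius guichenoti", "Coreius heterodon",      "autumn", 74.13,
    "Coreius guichenoti", "Rhinogobio ventralis",   "autumn", 72.51,
    "Coreius guichenoti", "Rhinogobio cylindricus", "autumn", 65.61,
    "Coreius heterodon",  "Rhinogobio ventralis",   "autumn", 98.38,
    "Coreius heterodon",  "Rhinogobio cylindricus", "autumn", 57.80,
    "Rhinogobio ventralis", "Rhinogobio cylindricus", "autumn", 56.18)
}

fixture_pair_overlap <- function(a, b, season, renormalize = FALSE) {
  comp <- gudgeon_diet_composition()
  pick <- function(sp) {
    diet_proportions(comp[comp$species == sp & comp$season == season, ],
                     renormalize = renormalize)
  }
  schoener_overlap(pick(a), pick(b))
}
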