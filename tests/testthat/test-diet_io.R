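test_that("reading a well-formed file round-trips the records", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- fixture_w_records()[1:4, ]
  readr::write_csv(recs, path)
  got <- read_diet_records(path)
  expect_equal(nrow(got), 4)
  expect_equal(got$prey_weight, recs$prey_weight)
  expect_true(all(c("body_weight", "prey_count") %in% names(got)))
})

test_that("schema and validation failures are reported with row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(fixture_w_records()[, setdiff(names(fixture_w_records()),
                                                 "prey_weight")], path)
  expect_error(read_diet_records(path), class = "gutdiet_schema_error")

  bad <- fixture_w_records()
  bad$prey_weight[2] <- -1
  expect_error(validate_diet_records(bad), regexp = "row 2",
               class = "gutdiet_validation_error")

  dup <- fixture_w_records()
  dup$prey_category[4] <- "A"
  dup$fish_id[4] <- "fish2"
  expect_error(validate_diet_records(dup), regexp = "duplicated",
               class = "gutdiet_validation_error")
  expect_error(validate_diet_records(transform(fixture_w_records(),
                                               standard_length = 0)),
               class = "gutdiet_validation_error")
})

test_that("prey exclusions drop rows but keep specimens, never touching survivors", {
  policy <- exclusion_policy(unidentifiable_labels = "Unidentified",
                             parasite_labels = "Cestoda")
  recs <- fixture_w_records()
  recs$prey_category[1] <- "Unidentified"
  out <- apply_exclusions(recs, policy)
  expect_equal(nrow(out), 5)  # dropped row replaced by fish1's empty marker
  expect_true(is.na(out$prey_category[out$fish_id == "fish1"]))
  kept <- out[!is.na(out$prey_category), ]
  orig <- recs[recs$prey_category %in% c("A", "B"), ]
  expect_equal(sort(kept$prey_weight), sort(orig$prey_weight))

  # no excluded labels present -> table unchanged
  same <- apply_exclusions(fixture_w_records(), policy)
  expect_equal(dplyr::arrange(same, fish_id, prey_category),
               dplyr::arrange(validate_diet_records(fixture_w_records()),
                              fish_id, prey_category))
})

test_that("a fish whose only content was a parasite becomes an empty gut, excluded from N", {
  policy <- exclusion_policy(parasite_labels = "Cestoda")
  recs <- tibble::tibble(
    fish_id = c("f1", "f2"), species = "sp", season = "spring",
    standard_length = 150,
    prey_category = c("A", "Cestoda"), prey_weight = c(1, 0.2))
  out <- apply_exclusions(recs, policy)
  expect_setequal(unique(out$fish_id), c("f1", "f2"))       # specimen kept
  expect_equal(summarize_specimens(out)$n, 2)
  dm <- build_diet_matrix(out)[[1]]
  expect_equal(dm$n_fish, 2)
  expect_equal(dm$n_nonempty, 1)                            # f2 empty now
  expect_equal(attr(prey_importance(dm), "N"), 1)
})

test_that("juvenile filtering is strict and demands a threshold per species", {
  policy <- default_exclusion_policy()
  recs <- tibble::tibble(
    fish_id = c("a", "b"), species = "Coreius guichenoti", season = "spring",
    standard_length = c(96, 97), prey_category = "A", prey_weight = 1)
  out <- filter_juveniles(recs, policy)
  expect_equal(out$fish_id, "b")  # 96 mm removed, 97 mm retained

  # one specimen each side of its species threshold -> exactly 3 of 6 kept
  thr <- c("s1" = 100, "s2" = 150, "s3" = 200)
  mixed <- tibble::tibble(
    fish_id = sprintf("f%d", 1:6),
    species = rep(names(thr), each = 2), season = "spring",
    standard_length = c(100, 101, 150, 151, 200, 201),
    prey_category = "A", prey_weight = 1)
  kept <- filter_juveniles(mixed, exclusion_policy(min_length_by_species = thr))
  expect_equal(kept$fish_id, c("f2", "f4", "f6"))

  expect_error(
    filter_juveniles(transform(recs, species = "unknown sp"), policy),
    class = "gutdiet_config_error")
  empty <- recs[0, ]
  expect_equal(nrow(filter_juveniles(empty, policy)), 0)
})

test_that("diet matrices carry row totals, N, and group totals", {
  dm <- build_diet_matrix(fixture_w_records())[[1]]
  expect_equal(dm$n_fish, 4)
  expect_equal(dm$n_nonempty, 3)
  expect_equal(sum(dm$weights), 7)
  expect_equal(unname(dm$fish_totals),
               unname(rowSums(dm$weights)))
  expect_equal(dm$fish_totals[["fish2"]], 2)

  # all-empty group: N = 0 and downstream indices refuse it
  empties <- tibble::tibble(
    fish_id = c("f1", "f2"), species = "sp", season = "spring",
    standard_length = 150, prey_category = NA_character_, prey_weight = 0)
  dm0 <- build_diet_matrix(empties)[[1]]
  expect_equal(dm0$n_nonempty, 0)
  expect_error(prey_importance(dm0), class = "gutdiet_empty_group")
})

test_that("specimen summaries match distinct fish and the published totals", {
  s <- summarize_specimens(fixture_w_records())
  expect_equal(s$n, 4)

  two <- tibble::tibble(fish_id = c("a", "b"), species = "sp",
                        season = "spring", standard_length = c(100, 200),
                        prey_category = "A", prey_weight = 1)
  s2 <- summarize_specimens(two)
  expect_equal(s2$mean_length_mm, 150)
  expect_equal(s2$min_length_mm, 100)
  expect_equal(s2$max_length_mm, 200)
  expect_equal(s2$se_length_mm, stats::sd(c(100, 200)) / sqrt(2))

  one <- two[1, ]
  expect_warning(s1 <- summarize_specimens(one), "single fish")
  expect_equal(s1$se_length_mm, 0)
  expect_equal(s1$mean_length_mm, 100)

  # packaged specimen fixture: groups sum to the published 936 individuals
  expect_equal(sum(gudgeon_specimens()$n), 936)
})

test_that("filtering is idempotent and summaries count distinct fish", {
  policy <- exclusion_policy(unidentifiable_labels = "Unidentified",
                             parasite_labels = "Cestoda",
                             min_length_by_species = c(sp = 120))
  withr::local_seed(404)
  for (i in 1:20) {
    recs <- random_diet_records(n_fish = 8,
                                prey = c("A", "B", "Unidentified", "Cestoda"))
    once <- filter_juveniles(apply_exclusions(recs, policy), policy)
    twice <- filter_juveniles(apply_exclusions(once, policy), policy)
    expect_equal(dplyr::arrange(twice, fish_id, prey_category),
                 dplyr::arrange(once, fish_id, prey_category))
    s <- summarize_specimens(recs)
    expect_equal(s$n, length(unique(recs$fish_id)))
  }
})
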