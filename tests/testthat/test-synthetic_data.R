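test_that("profiles validate their parameters", {
  expect_error(species_profile("s", c("A", "B"), occupancy = c(0.5, 1.2),
                               mean_weight_g = 1),
               class = "gutdiet_config_error")
  expect_error(species_profile("s", "A", 0.5, mean_weight_g = -1),
               class = "gutdiet_config_error")
  expect_error(
    species_profile("s", c("A", "B"), 0.5, 1,
                    phenotypes = list(list(fraction = 0.6, occupancy = 0.5),
                                      list(fraction = 0.6, occupancy = 0.5))),
    class = "gutdiet_config_error")
  expect_error(make_archetype("generalist", prey = "A"),
               class = "gutdiet_config_error")
  expect_error(make_archetype("specialist", c("A", "B"), strength = 2),
               class = "gutdiet_config_error")
})

test_that("generation is seed-deterministic and honours degenerate profiles", {
  prof <- make_archetype("specialist", c("A", "B"))
  t1 <- generate_gut_contents(prof, 50, seed = 9)
  t2 <- generate_gut_contents(prof, 50, seed = 9)
  expect_identical(t1, t2)
  t3 <- generate_gut_contents(prof, 50, seed = 10)
  expect_false(identical(t1, t3))

  # single prey with certain occupancy: every gut holds it, F = A = P = 100
  sure <- species_profile("s", "A", occupancy = 1, mean_weight_g = 0.5)
  tab <- generate_gut_contents(sure, 40, seed = 1)
  imp <- importance_table(tab)
  expect_equal(imp$frequency_occurrence, 100)
  expect_equal(imp$relative_abundance, 100)
  expect_equal(imp$prey_specific_abundance, 100)

  # zero occupancy everywhere: all guts empty, indices refuse the group
  none <- species_profile("s", c("A", "B"), occupancy = 0, mean_weight_g = 1)
  tab0 <- generate_gut_contents(none, 20, seed = 1)
  expect_true(all(is.na(tab0$prey_category)))
  expect_error(prey_importance(build_diet_matrix(tab0)[[1]]),
               class = "gutdiet_empty_group")

  expect_equal(nrow(generate_gut_contents(sure, 0)), 0)
})

test_that("analytic expected frequencies follow inclusion-exclusion", {
  one <- species_profile("s", "A", occupancy = 0.5, mean_weight_g = 1)
  e1 <- expected_indices(one, mc_n = 2000, seed = 1)
  expect_equal(e1$F_expected, 100)     # only non-empty guts can be examined

  two <- species_profile("s", c("A", "B"), occupancy = 0.5, mean_weight_g = 1)
  e2 <- expected_indices(two, mc_n = 2000, seed = 1)
  expect_equal(e2$F_expected, rep(100 * 0.5 / 0.75, 2))   # 66.67 by hand

  # Monte-Carlo abundances carry finite standard errors and respect P >= A
  expect_true(all(is.finite(e2$A_se)))
  expect_true(all(e2$P_expected >= e2$A_expected - 4 * (e2$P_se + e2$A_se)))
})

test_that("the pipeline recovers generative frequencies within Monte-Carlo error", {
  prof <- species_profile(
    "mix", c("A", "B", "C"),
    occupancy = c(0.7, 0.4, 0.2), mean_weight_g = c(1, 0.3, 0.1),
    phenotypes = list(list(fraction = 0.6, occupancy = c(0.9, 0.2, 0.2)),
                      list(fraction = 0.4, occupancy = c(0.4, 0.7, 0.2))))
  oracle <- expected_indices(prof, mc_n = 4e4, seed = 2)
  tab <- generate_gut_contents(prof, 500, seed = 3)
  imp <- importance_table(tab)
  dm <- build_diet_matrix(tab)[[1]]
  for (i in seq_along(prof$prey)) {
    f_hat <- imp$frequency_occurrence[imp$prey_category == prof$prey[i]]
    if (length(f_hat) == 0) f_hat <- 0
    f_exp <- oracle$F_expected[i]
    se <- 100 * sqrt(f_exp / 100 * (1 - f_exp / 100) / dm$n_nonempty)
    expect_lt(abs(f_hat - f_exp), 3 * se + 1e-9)
  }
})

test_that("archetypes produce their regimes at scale", {
  # specialist: breadth near 1, dominant prey top-right, group specialized
  sp <- make_archetype("specialist", c("A", "B", "C"), strength = 1)
  tab <- generate_gut_contents(sp, 500, seed = 11)
  imp <- importance_table(tab)
  nb <- levins_breadth(diet_proportions(build_diet_matrix(tab)[[1]]))
  expect_lt(nb$B, 1.5)
  rep <- classify_points(costello_points(imp))
  expect_equal(rep$strategy, "specialized")
  focal <- rep$points[rep$points$prey_category == "A", ]
  expect_equal(focal$importance, "dominant")

  # generalist over 4 prey: breadth above k/2, all points in the lower half
  ge <- make_archetype("generalist", LETTERS[1:4], strength = 1)
  tabg <- generate_gut_contents(ge, 500, seed = 12)
  nbg <- levins_breadth(diet_proportions(build_diet_matrix(tabg)[[1]]))
  expect_gt(nbg$B, 2)
  repg <- classify_points(costello_points(importance_table(tabg)))
  expect_equal(repg$strategy, "generalized")

  # between-phenotype mixture: focal prey eaten heavily (high P) by about
  # half the population (F near 50)
  bp <- make_archetype("bpc_mixture", LETTERS[1:4], strength = 1)
  tabb <- generate_gut_contents(bp, 1000, seed = 13)
  impb <- importance_table(tabb)
  for (prey in c("A", "B")) {
    row <- impb[impb$prey_category == prey, ]
    expect_gt(row$prey_specific_abundance, 60)
    expect_gt(row$frequency_occurrence, 35)
    expect_lt(row$frequency_occurrence, 65)
  }
})

test_that("multi-group studies are reproducible and sized as designed", {
  design <- gudgeon_study_design(seed = 21)
  study <- generate_study(design)
  expect_equal(length(unique(study$fish_id)), 936)
  expect_identical(study, generate_study(gudgeon_study_design(seed = 21)))
  expect_false(identical(study, generate_study(gudgeon_study_design(seed = 22))))

  sizes <- summarize_specimens(study)
  published <- gudgeon_specimens()
  joined <- dplyr::inner_join(sizes, published, by = c("species", "season"))
  expect_equal(nrow(joined), 8)
  expect_equal(joined$n.x, joined$n.y)
  expect_true(all(joined$min_length_mm.x >= joined$min_length_mm.y - 0.5))
  expect_true(all(joined$max_length_mm.x <= joined$max_length_mm.y + 0.5))

  prof <- make_archetype("generalist", c("A", "B"))
  empty_design <- study_design(list(list(profile = prof, season = "spring",
                                         n = 0)), seed = 1)
  expect_equal(nrow(generate_study(empty_design)), 0)
  expect_error(study_design(list(list(profile = prof, season = "s", n = 5))),
               class = "gutdiet_config_error")
})

test_that("seasonal diversification of two groups lowers mean overlap", {
  prey <- c("mussel", "caddisfly", "crab", "detritus")
  shared <- species_profile("base", prey, occupancy = c(0.85, 0.1, 0.1, 0.15),
                            mean_weight_g = c(1, 0.05, 0.1, 0.08))
  diversified <- species_profile("base", prey,
                                 occupancy = c(0.45, 0.5, 0.3, 0.45),
                                 mean_weight_g = c(0.8, 0.15, 0.5, 0.5))
  mk_design <- function(profiles, seed) {
    study_design(lapply(seq_along(profiles), function(i) {
      p <- profiles[[i]]
      p$species <- paste0("sp", i)
      list(profile = p, season = "autumn", n = 150)
    }), seed = seed)
  }
  overlap_mean <- function(design) {
    props <- proportions_by_group(importance_table(generate_study(design)))
    M <- overlap_matrix(props)
    mean(M[upper.tri(M)])
  }
  same <- overlap_mean(mk_design(rep(list(shared), 4), seed = 41))
  shifted <- overlap_mean(mk_design(list(shared, shared, diversified,
                                         diversified), seed = 41))
  expect_lt(shifted, same)
})
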