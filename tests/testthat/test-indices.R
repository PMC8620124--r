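test_that("respondent use value counts distinct (use, part) citations", {
  resp <- rbind(make_respondent("R1"), make_respondent("R2"),
                make_respondent("R3", owns_trees = FALSE))
  reps <- rbind(
    make_report("R1"),
    make_report("R1", "malaria", "medicinal", "general_health", "leaf"),
    make_report("R1", "lucky_charm", "magico_spiritual", "non_medicinal",
                "root"),
    make_report("R2"),
    make_report("R2"))  # exact duplicate citation
  ds <- survey_dataset(resp, reps)
  expect_equal(respondent_use_value(ds, "R1"), 3)
  expect_equal(respondent_use_value(ds, "R2"), 1)
  expect_equal(respondent_use_value(ds, "R3"), 0)
  expect_error(respondent_use_value(ds, "R9"), "R9")
})

test_that("total use value is the mean of per-respondent values", {
  resp <- rbind(make_respondent("R1"), make_respondent("R2"))
  reps <- rbind(
    make_report("R1"),
    make_report("R1", "malaria", "medicinal", "general_health", "leaf"),
    make_report("R2"),
    make_report("R2", "malaria", "medicinal", "general_health", "leaf"),
    make_report("R2", "lucky_charm", "magico_spiritual", "non_medicinal",
                "root"),
    make_report("R2", "chewing_stick", "social", "non_medicinal", "twig"))
  tv <- total_use_value(survey_dataset(resp, reps))
  expect_equal(tv$uv, 3)        # UVj = {2, 4}
  expect_equal(tv$sem, 1)       # sd = sqrt(2), /sqrt(2)

  one_each <- survey_dataset(resp, rbind(make_report("R1"),
                                         make_report("R2")))
  tv <- total_use_value(one_each)
  expect_equal(tv$uv, 1)
  expect_equal(tv$sem, 0)
})

test_that("category use values partition the overall use value", {
  gender_ds <- local({
    resp <- rbind(make_respondent("R1", gender = "man"),
                  make_respondent("R2", gender = "man"),
                  make_respondent("R3", gender = "woman"),
                  make_respondent("R4", gender = "woman"))
    reps <- rbind(make_report("R1"),
                  make_report("R1", "malaria", "medicinal",
                              "general_health", "leaf"),
                  make_report("R2"),
                  make_report("R3"),
                  make_report("R3", "chewing_stick", "social",
                              "non_medicinal", "twig"),
                  make_report("R3", "lucky_charm", "magico_spiritual",
                              "non_medicinal", "root"))
    survey_dataset(resp, reps)
  })
  by_gender <- use_value_by(gender_ds, "gender")
  expect_equal(by_gender$uv[by_gender$scope == "man"], 1.5)  # (2 + 1)/2
  expect_equal(by_gender$uv[by_gender$scope == "woman"], 1.5) # (3 + 0)/2

  by_cat <- use_value_by(gender_ds, "category")
  expect_equal(sum(by_cat$uv), total_use_value(gender_ds)$uv)
  expect_equal(by_cat$uv[by_cat$scope == "food"], 3 / 4)

  for (s in c(1, 2, 3)) {
    ds <- generate_dataset(small_config(seed = s))
    expect_equal(sum(use_value_by(ds, "category")$uv),
                 total_use_value(ds)$uv, tolerance = 1e-12)
    expect_equal(sum(use_value_by(ds, "plant_part")$uv),
                 total_use_value(ds)$uv, tolerance = 1e-12)
  }
})

test_that("informant agreement ratio follows its closed form and bounds", {
  expect_equal(round_half_up(informant_agreement_ratio(112, 5)), 0.96)
  expect_equal(informant_agreement_ratio(2, 2), 0)
  expect_true(is.na(informant_agreement_ratio(1, 1)))
  for (k in c(2, 5, 100)) {
    expect_equal(informant_agreement_ratio(k, 1), 1)
  }
  expect_error(informant_agreement_ratio(3, 4), "na <= nr")
  expect_error(informant_agreement_ratio(3, 0), "na <= nr")

  set.seed(1)
  for (i in 1:50) {
    nr <- sample(2:200, 1)
    na <- sample(seq_len(min(nr, 7)), 1)
    iar <- informant_agreement_ratio(nr, na)
    expect_gte(iar, 0)
    expect_lte(iar, 1)
    expect_equal(iar == 1, na == 1)
    expect_equal(iar == 0, na == nr)
  }
})

test_that("the agreement table tallies citations and distinct parts", {
  resp <- do.call(rbind, lapply(sprintf("R%d", 1:9), make_respondent))
  reps <- do.call(rbind, lapply(1:9, function(i) {
    make_report(sprintf("R%d", i), "female_genital_remedy", "medicinal",
                "female_genital", if (i <= 5) "leaf" else "root")
  }))
  reps <- rbind(reps, make_report("R1", "firewood", "firewood",
                                  "non_medicinal", "twig"))
  ds <- survey_dataset(resp, reps)

  tab <- iar_table(ds, "body_system")
  expect_equal(tab$nr, 9)
  expect_equal(tab$na, 2)
  expect_equal(tab$iar, 0.875)

  bycat <- iar_table(ds, "category")
  expect_true(is.na(bycat$iar[bycat$scope == "firewood"]))
  expect_setequal(bycat$scope, c("medicinal", "firewood"))
})

test_that("agreement table on the generator recovers the part-list sizes", {
  ds <- generate_dataset(generator_config(seed = 31))
  tab <- iar_table(ds, "body_system")
  cat_tab <- use_catalogue()
  med <- cat_tab[cat_tab$category == "medicinal", ]
  for (i in seq_len(nrow(med))) {
    row <- tab[tab$scope == med$body_system[i], ]
    n_parts <- length(strsplit(med$parts[i], ",")[[1]])
    if (nrow(row) == 1 && row$nr >= 20) {
      expect_equal(row$na, n_parts)
    }
  }
})

test_that("use-value/tree-count correlations match direct formulas", {
  resp <- do.call(rbind, lapply(1:6, function(i) {
    make_respondent(sprintf("R%d", i), n_trees = i)
  }))
  labels <- c("sweetener", "commercialization", "chewing_stick",
              "lucky_charm", "malaria", "cough", "protection", "ritualistic")
  reps <- do.call(rbind, lapply(1:6, function(i) {
    do.call(rbind, lapply(seq_len(i), function(j) {
      make_report(sprintf("R%d", i), labels[j], "social", "non_medicinal",
                  survey_levels()$plant_part[j])
    }))
  }))
  ds <- survey_dataset(resp, reps)  # UVj = n_trees = 1..6
  res <- uv_trees_correlation(ds, method = "spearman")
  expect_equal(res$r, 1)
  res <- uv_trees_correlation(ds, method = "pearson")
  expect_equal(res$r, 1)

  # anti-monotone: reverse tree counts
  r2 <- resp
  r2$n_trees <- rev(r2$n_trees)
  ds2 <- survey_dataset(r2, reps)
  expect_equal(uv_trees_correlation(ds2, method = "spearman")$r, -1)

  ds3 <- generate_dataset(small_config(seed = 2))
  res <- uv_trees_correlation(ds3, method = "spearman")
  uv <- vapply(ds3$respondents$respondent_id,
               function(id) respondent_use_value(ds3, id), numeric(1))
  expect_equal(res$r, spearman_oracle(uv, ds3$respondents$n_trees),
               tolerance = 1e-12)
  expect_error(uv_trees_correlation(ds, subset = c(TRUE, TRUE, TRUE,
                                                   rep(FALSE, 3))),
               "fewer than 4")
})

test_that("Fisher r-to-z comparison follows the closed form", {
  res <- compare_correlations_fisher_z(0.3, 40, 0.3, 60)
  expect_equal(res$Z, 0)
  expect_equal(res$p, 1)

  z_hand <- (atanh(0.5) - atanh(0)) / sqrt(1 / 47 + 1 / 47)
  res <- compare_correlations_fisher_z(0.5, 50, 0.0, 50)
  expect_equal(res$Z, z_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)

  swapped <- compare_correlations_fisher_z(0.0, 50, 0.5, 50)
  expect_equal(swapped$Z, -res$Z)
  expect_error(compare_correlations_fisher_z(1, 10, 0, 10), "< 1")
  expect_error(compare_correlations_fisher_z(0.2, 3, 0, 10), "exceed 3")
})
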