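test_that("knowledge events classify to their KMTO paths", {
  p <- classify_kmto("father", "man", "man")
  expect_equal(p[, 1:4], data.frame(kernel = "internal",
                                    mutation = "transition",
                                    type = "vertical", order = 1L))
  p <- classify_kmto("grandmother", "woman", "man")
  expect_equal(p[, 1:4], data.frame(kernel = "internal",
                                    mutation = "transversion",
                                    type = "vertical", order = 2L))
  p <- classify_kmto("friend", "man", "man")
  expect_equal(p[, 1:4], data.frame(kernel = "external",
                                    mutation = "transition",
                                    type = "horizontal", order = 0L))
  p <- classify_kmto("self_learning", "not_applicable", "woman")
  expect_equal(p[, 1:4], data.frame(kernel = "internal",
                                    mutation = "transition",
                                    type = "transversal", order = 0L))
  expect_error(classify_kmto("self_learning", "man", "man"),
               "not_applicable")
  expect_error(classify_kmto("father", "not_applicable", "man"),
               "not_applicable")
})

test_that("the path space has 36 unconstrained and 16 valid members", {
  full <- enumerate_paths(FALSE)
  expect_equal(nrow(full), 36)
  expect_equal(nrow(unique(full[, 1:4])), 36)
  constrained <- enumerate_paths(TRUE)
  expect_equal(nrow(constrained), 16)
  expect_true(all(constrained$structurally_valid))

  # brute-force recount of the valid region
  n_valid <- sum(apply(full, 1, function(row) {
    (row[["type"]] == "vertical" && row[["order"]] %in% c("1", "2")) ||
      (row[["type"]] %in% c("horizontal", "transversal") &&
         row[["order"]] == "0")
  }))
  expect_equal(n_valid, 16)

  key <- function(d) paste(d$kernel, d$mutation, d$type, d$order)
  expect_true(all(key(constrained) %in% key(full)))
})

test_that("classifier outputs are structurally valid except uncle/aunt", {
  lv <- survey_levels()
  valid_key <- with(enumerate_paths(TRUE),
                    paste(kernel, mutation, type, order))
  for (rel in setdiff(lv$source_relation, c("uncle_aunt", "self_learning"))) {
    for (sg in c("man", "woman")) {
      for (rg in c("man", "woman")) {
        p <- classify_kmto(rel, sg, rg)
        expect_true(paste(p$kernel, p$mutation, p$type, p$order) %in%
                      valid_key, label = rel)
      }
    }
  }
  p <- classify_kmto("self_learning", "not_applicable", "man")
  expect_true(paste(p$kernel, p$mutation, p$type, p$order) %in% valid_key)

  # the framework reserves orders 1-2 for parents/grandparents while binning
  # uncles/aunts as another generation: that one path is vertical order 0
  p <- classify_kmto("uncle_aunt", "man", "man")
  expect_equal(p$type, "vertical")
  expect_equal(p$order, 0L)
  expect_false(p$structurally_valid)
})

test_that("path tallies match hand counts and normalize per grouping", {
  resp <- rbind(make_respondent("R1", gender = "man"),
                make_respondent("R2", gender = "man"))
  all_father <- rbind(make_report("R1"), make_report("R2"),
                      make_report("R1", "malaria", "medicinal",
                                  "general_health", "leaf"))
  tal <- path_frequencies(survey_dataset(resp, all_father))
  expect_equal(nrow(tal), 1)
  expect_equal(tal$proportion, 1)
  expect_equal(tal[, c("kernel", "mutation", "type", "order")],
               data.frame(kernel = "internal", mutation = "transition",
                          type = "vertical", order = 1L))

  mixed <- rbind(
    make_report("R1", source_relation = "father", source_gender = "man"),
    make_report("R1", "u2", "food", "non_medicinal", "fruit", "direct",
                "mother", "woman"),
    make_report("R1", "u3", "food", "non_medicinal", "fruit", "direct",
                "mother", "woman"),
    make_report("R2", "u4", "food", "non_medicinal", "fruit", "direct",
                "friend", "woman"),
    make_report("R2", "u5", "food", "non_medicinal", "fruit", "direct",
                "self_learning", "not_applicable"))
  tal <- path_frequencies(survey_dataset(resp, mixed))
  expect_equal(sum(tal$count), 5)
  expect_equal(sum(tal$proportion), 1)
  mother_row <- tal[tal$order == 1 & tal$mutation == "transversion", ]
  expect_equal(mother_row$count, 2)
  expect_equal(mother_row$proportion, 0.4)

  by_cat <- path_frequencies(survey_dataset(resp, mixed),
                             by_category = TRUE)
  for (cc in unique(by_cat$category)) {
    expect_equal(sum(by_cat$proportion[by_cat$category == cc]), 1)
  }
})

test_that("the default generator's modal path is first-order paternal", {
  ds <- generate_dataset(generator_config(seed = 17))
  tal <- path_frequencies(ds)
  top <- tal[which.max(tal$count), ]
  expect_equal(top$kernel, "internal")
  expect_equal(top$mutation, "transition")
  expect_equal(top$type, "vertical")
  expect_equal(top$order, 1L)
})

test_that("attribute tests delegate to the statistical harness", {
  resp <- rbind(make_respondent("R1"), make_respondent("R2"))
  all_father <- rbind(make_report("R1"), make_report("R2"))
  res <- attribute_state_tests(survey_dataset(resp, all_father))
  expect_equal(nrow(res), 4)
  # one state holds all mass: the goodness-of-fit statistic is maximal (= n
  # for two-state attributes, by the closed form)
  kernel <- res[res$attribute == "kernel", ]
  expect_equal(kernel$statistic, 2)
  expect_equal(kernel$df, 1)

  balanced <- rbind(
    make_report("R1", source_relation = "father", source_gender = "man"),
    make_report("R2", "u2", "food", "non_medicinal", "fruit", "direct",
                "friend", "man"))
  res <- attribute_state_tests(survey_dataset(resp, balanced))
  kernel <- res[res$attribute == "kernel", ]
  expect_equal(kernel$statistic, 0)
  expect_equal(kernel$p_value, 1)

  ds <- generate_dataset(small_config(seed = 23))
  res <- kmto_category_tests(ds, seed = 99)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
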