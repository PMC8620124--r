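make_tp <- function(min_split = 4, min_bucket = 2, ...) {
  tree_params(min_split = min_split, min_bucket = min_bucket,
              complexity = 1e-9, seed = 1, ...)
}

test_that("a perfectly separating binary feature yields a pure depth-1 tree", {
  set.seed(2)
  x <- data.frame(flag = sample(c("a", "b"), 100, replace = TRUE))
  y <- x$flag == "a"
  tr <- fit_classification_tree(x, y, tree_params())
  expect_equal(tr$root$split$feature, "flag")
  expect_null(tr$root$children$left$children)
  expect_null(tr$root$children$right$children)
  probs <- c(tr$root$children$left$prediction$prob_positive,
             tr$root$children$right$prediction$prob_positive)
  expect_setequal(probs, c(0, 1))

  const <- fit_classification_tree(x, rep(TRUE, 100), tree_params())
  expect_null(const$root$children)
  expect_equal(const$root$prediction$class, "yes")
  expect_equal(const$root$prediction$prob_positive, 1)

  expect_error(fit_classification_tree(data.frame(), y), "ncol")
})

test_that("categorical splits equal the exhaustive bipartition oracle", {
  set.seed(7)
  rates <- c(a = 0.9, b = 0.1, c = 0.8)
  x <- data.frame(grp = sample(names(rates), 300, replace = TRUE))
  y <- runif(300) < rates[x$grp]
  tr <- fit_classification_tree(x, y, make_tp(max_depth = 1))
  oracle <- best_bipartition_oracle(x$grp, as.numeric(y))
  side <- tr$root$split$left_levels
  expect_true(setequal(side, oracle$left) ||
                setequal(setdiff(names(rates), side), oracle$left))
  expect_true("b" %in% side && length(side) == 1 ||
                setequal(side, c("a", "c")))

  for (k in c(4, 6, 8)) {
    for (rep_i in 1:3) {
      lev <- letters[1:k]
      x <- data.frame(g = sample(lev, 60 + 20 * k, replace = TRUE))
      y <- runif(nrow(x)) < (seq_len(k) / (k + 1))[match(x$g, lev)]
      if (length(unique(y)) < 2) next
      tr <- fit_classification_tree(x, y, make_tp(max_depth = 1,
                                                  min_bucket = 1,
                                                  min_split = 2))
      oracle <- best_bipartition_oracle(x$g, as.numeric(y))
      got <- tr$root$split$left_levels
      present <- sort(unique(x$g))
      same <- setequal(got, oracle$left) ||
        setequal(setdiff(present, got), oracle$left)
      expect_true(same, label = sprintf("k=%d rep=%d", k, rep_i))
    }
  }
})

test_that("regression splits recover exact strata and the SSE oracle", {
  x <- data.frame(schooling = rep(c("university", "none"), each = 30))
  y <- ifelse(x$schooling == "university", 1.8, 0.2)
  tr <- fit_regression_tree(x, y, tree_params())
  leaves <- predict_tree(tr, data.frame(schooling = c("university", "none")))
  expect_equal(leaves$mean, c(1.8, 0.2))

  const <- fit_regression_tree(x, rep(0.43, 60), tree_params())
  expect_null(const$root$children)
  expect_equal(const$root$prediction$mean, 0.43)

  set.seed(13)
  for (rep_i in 1:5) {
    x <- data.frame(g = sample(letters[1:6], 200, replace = TRUE),
                    h = sample(c("u", "v"), 200, replace = TRUE))
    y <- rnorm(200, ifelse(x$g %in% c("a", "b"), 2, 0) +
                 ifelse(x$h == "u", 0.5, 0))
    tr <- fit_regression_tree(x, y, make_tp(max_depth = 1, min_bucket = 1,
                                            min_split = 2))
    o_g <- best_bipartition_sse_oracle(x$g, y)
    o_h <- best_bipartition_sse_oracle(x$h, y)
    best_oracle <- max(o_g$gain, o_h$gain)
    expect_equal(tr$root$split$gain, best_oracle, tolerance = 1e-9)
  }
})

test_that("with two informative features the larger SS reduction splits first", {
  set.seed(4)
  n <- 400
  x <- data.frame(strong = sample(c("s1", "s2"), n, replace = TRUE),
                  weak = sample(c("w1", "w2"), n, replace = TRUE))
  y <- ifelse(x$strong == "s1", 3, 0) + ifelse(x$weak == "w1", 0.3, 0) +
    rnorm(n, sd = 0.2)
  tr <- fit_regression_tree(x, y, tree_params())
  expect_equal(tr$root$split$feature, "strong")
})

test_that("leaf shares sum to one and training predictions are leaf means", {
  ds <- generate_dataset(generator_config(seed = 6))
  r <- ds$respondents
  w <- r$willing_to_cultivate
  feats <- r[w, c("schooling", "perceived_growth")]
  tr <- fit_regression_tree(feats, r$max_acreage_ha[w], tree_params())

  leaves <- ethnosurvey:::tree_leaves(tr$root)
  expect_equal(sum(vapply(leaves, function(l) l$n_share, numeric(1))), 1,
               tolerance = 1e-12)

  pred <- predict_tree(tr, feats)
  agg <- tapply(r$max_acreage_ha[w], pred$mean, mean)
  expect_equal(as.numeric(names(agg)), unname(as.numeric(agg)),
               tolerance = 1e-9)

  # SSE non-increasing along the pruning sequence
  alphas <- ethnosurvey:::alpha_sequence(tr)
  risks <- vapply(c(0, alphas + 1e-9), function(a) {
    sub <- ethnosurvey:::prune_at_alpha(tr, a)
    sum((r$max_acreage_ha[w] - predict_tree(sub, feats)$mean)^2)
  }, numeric(1))
  expect_true(all(diff(risks) >= -1e-9))
})

test_that("pruning endpoints and cross-validated pruning behave", {
  set.seed(21)
  x <- data.frame(g = sample(letters[1:4], 300, replace = TRUE),
                  z = runif(300))
  y <- ifelse(x$g %in% c("a", "b"), 2, 0) + rnorm(300, sd = 0.3)
  tr <- fit_regression_tree(x, y, make_tp())

  same <- prune_tree(tr, x, y, alpha = 0)
  expect_equal(tree_to_text(same), tree_to_text(tr))

  root_only <- prune_tree(tr, x, y, alpha = Inf)
  expect_null(root_only$root$children)
  expect_equal(root_only$root$prediction$mean, mean(y), tolerance = 1e-12)

  # real structure survives CV pruning
  cv <- prune_tree(tr, x, y)
  expect_false(is.null(cv$root$children))

  # pure noise prunes to the root in nearly every replicate
  at_root <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    xn <- data.frame(g = sample(letters[1:5], 500, replace = TRUE),
                     z = runif(500))
    yn <- rnorm(500)
    trn <- fit_regression_tree(xn, yn, tree_params(seed = s))
    pr <- prune_tree(trn, xn, yn, tree_params(seed = s))
    if (is.null(pr$root$children)) at_root <- at_root + 1
  }
  expect_gte(at_root, 19)
})

test_that("prediction routes unseen categories by the majority direction", {
  x <- data.frame(g = rep(c("a", "b", "c"), times = c(50, 30, 20)))
  y <- ifelse(x$g == "a", 1, 0) + rnorm(100, sd = 0.01)
  tr <- fit_regression_tree(x, y, tree_params())
  pred <- predict_tree(tr, data.frame(g = c("a", "b", "zz")))
  expect_equal(pred$mean[1], mean(y[x$g == "a"]), tolerance = 1e-9)
  # "zz" lands somewhere deterministic
  expect_equal(predict_tree(tr, data.frame(g = "zz"))$mean, pred$mean[3])
  expect_error(predict_tree(tr, data.frame(h = "a")), "missing feature")
})

test_that("the text rendering lists the depth-1 tree with its shares", {
  x <- data.frame(flag = rep(c("a", "b"), each = 50))
  y <- x$flag == "a"
  tr <- fit_classification_tree(x, y, tree_params())
  txt <- tree_to_text(tr)
  expect_length(txt, 3)
  expect_match(txt[1], "n%=100.0", fixed = TRUE)
  expect_match(txt[1], "flag in \\{b\\}")  # lower positive rate goes left
  expect_match(txt[2], "n%=50.0", fixed = TRUE)
})

test_that("fits agree with rpart on a strongly structured fixture", {
  set.seed(33)
  n <- 600
  x <- data.frame(
    schooling = sample(c("none", "primary", "secondary", "university"),
                       n, replace = TRUE, prob = c(0.35, 0.25, 0.3, 0.1)),
    growth = sample(c("slow", "moderate", "fast"), n, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1)))
  mu <- ifelse(x$schooling == "university", 1.8,
               ifelse(x$schooling == "none", 0.2,
                      ifelse(x$growth == "fast", 0.83, 0.4)))
  y <- rgamma(n, shape = 4, rate = 4 / mu)
  mine <- fit_regression_tree(x, y, tree_params())
  rp <- rpart::rpart(y ~ ., data = cbind(x, y = y), method = "anova",
                     control = rpart::rpart.control(minsplit = 20, cp = 0.01,
                                                    xval = 0))
  mine_leaves <- sort(unique(predict_tree(mine, x)$mean))
  rp_leaves <- sort(unique(unname(predict(rp, x))))
  expect_equal(mine_leaves, rp_leaves, tolerance = 1e-9)
})

test_that("willingness tree puts a driver variable at the first split", {
  hits <- 0
  for (s in 1:10) {
    ds <- generate_dataset(generator_config(seed = 200 + s))
    r <- ds$respondents
    feats <- r[, c("group", "knows_taboo", "perceives_market", "schooling",
                   "perceived_time_to_fruiting_years", "knows_superstition")]
    tr <- fit_classification_tree(feats, r$willing_to_cultivate,
                                  tree_params(seed = s))
    if (!is.null(tr$root$split) &&
        tr$root$split$feature %in% c("group", "knows_taboo",
                                     "perceives_market")) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})
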