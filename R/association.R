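## Statistical harness: equal-proportion tests, independence tests with a
## small-expected-count fallback, and Poisson / quasi-Poisson count
## regression with a dispersion diagnostic. Standard machinery is
## delegated to stats (chisq.test, fisher.test, glm); this module fixes
## the decision rules - fallback trigger, Monte-Carlo settings,
## overdispersion threshold - used consistently across the pipeline.

#' Chi-square multiple proportion comparison test
#'
#' Goodness-of-fit test of the observed category counts against equal
#' expected proportions; df = k - 1.
#'
#' @param counts Vector of category counts (>= 2 categories, total > 0).
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{method}.
#' @export
#' @examples
#' equal_proportions_test(c(430, 31, 45))
equal_proportions_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least 2 categories", call. = FALSE)
  if (sum(counts) <= 0) stop("total count must be positive", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, method = "chi-square goodness of fit")
}

#' Independence test with small-expected-count fallback
#'
#' Pearson chi-square (no continuity correction) when every expected cell
#' count is at least 5; otherwise Fisher's exact test - exact for 2 x 2
#' tables, Monte-Carlo with 1e5 seeded table draws for larger tables. Rows
#' and columns with zero margin are dropped with a note.
#'
#' @param table Matrix of non-negative integer counts (>= 2 x 2).
#' @param seed Seed for the Monte-Carlo fallback.
#' @param fallback_B Number of Monte-Carlo draws.
#' @return List with \code{statistic} (NA for exact Fisher), \code{df},
#'   \code{p_value}, \code{method}, \code{note}.
#' @export
independence_test <- function(table, seed = 1, fallback_B = 1e5) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integer counts", call. = FALSE)
  }
  note <- NULL
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    note <- sprintf("dropped %d zero-margin row(s) and %d column(s)",
                    sum(!keep_r), sum(!keep_c))
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least a 2 x 2 table after dropping zero margins",
         call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(list(statistic = unname(res$statistic),
                df = unname(res$parameter), p_value = res$p.value,
                method = "chi-square", note = note))
  }
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    res <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, df = NA_real_, p_value = res$p.value,
                method = "fisher_exact", note = note))
  }
  res <- withr_seed(seed, stats::fisher.test(
    tab, simulate.p.value = TRUE, B = as.integer(fallback_B)))
  list(statistic = NA_real_, df = NA_real_, p_value = res$p.value,
       method = "fisher_monte_carlo", note = note)
}

## evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit a Poisson or quasi-Poisson count model
#'
#' Log-link generalized linear model of counts on a design of categorical
#' (or numeric) predictors. The Pearson dispersion statistic
#' sum(pearson residual^2) / (n - p) is computed after the Poisson fit;
#' when it exceeds \code{dispersion_threshold} the standard errors are
#' scaled by its square root and the family recorded as quasi-Poisson
#' (point estimates are identical by construction).
#'
#' @param counts Non-negative integer response vector.
#' @param design data.frame (or vector) of predictors.
#' @param dispersion_threshold Switch point for the quasi family
#'   (default 1.5).
#' @return Object of class \code{count_model_fit}: list with
#'   \code{coefficients}, \code{std_errors}, \code{dispersion},
#'   \code{family_used}, \code{fitted_means}, \code{glm_fit}.
#' @export
fit_count_model <- function(counts, design, dispersion_threshold = 1.5) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (all(counts == 0)) stop("all-zero response", call. = FALSE)
  if (is.null(dim(design))) design <- data.frame(x = design)
  design <- as.data.frame(design)
  for (j in names(design)) {
    if (is.character(design[[j]]) || is.logical(design[[j]])) {
      design[[j]] <- factor(design[[j]])
    }
  }
  ## single-level factors carry no information; drop them (an all-constant
  ## design collapses to the intercept-only model)
  keep <- vapply(design, function(col) {
    if (is.factor(col)) nlevels(droplevels(col)) >= 2 else TRUE
  }, logical(1))
  design <- design[, keep, drop = FALSE]
  dat <- cbind(.y = counts, design)
  form <- if (ncol(design) == 0) .y ~ 1 else .y ~ .
  fit <- stats::glm(form, data = dat, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) stop("count model did not converge", call. = FALSE)
  p <- length(stats::coef(fit))
  disp <- sum(stats::residuals(fit, type = "pearson")^2) /
    (length(counts) - p)
  family_used <- if (is.finite(disp) && disp > dispersion_threshold) {
    "quasipoisson"
  } else "poisson"
  se <- sqrt(diag(stats::vcov(fit)))
  if (family_used == "quasipoisson") se <- se * sqrt(disp)
  structure(
    list(coefficients = stats::coef(fit), std_errors = se,
         dispersion = disp, family_used = family_used,
         fitted_means = stats::fitted(fit), glm_fit = fit),
    class = "count_model_fit")
}

#' @export
print.count_model_fit <- function(x, ...) {
  cat(sprintf("count model (%s), Pearson dispersion %.3f\n",
              x$family_used, x$dispersion))
  print(data.frame(estimate = x$coefficients, se = x$std_errors))
  invisible(x)
}

#' Pearson dispersion of a fitted count model
#'
#' Pure function of the fit's residuals: values near 1 indicate
#' equidispersion, values above the threshold overdispersion.
#'
#' @param fit A \code{count_model_fit}.
#' @return Dispersion statistic.
#' @export
dispersion_check <- function(fit) {
  stopifnot(inherits(fit, "count_model_fit"))
  p <- length(fit$coefficients)
  n <- length(fit$fitted_means)
  y <- fit$glm_fit$y
  sum((y - fit$fitted_means)^2 / fit$fitted_means) / (n - p)
}
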