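## Ethnobotanical indices: per-respondent and total use value
## (Phillips & Gentry), disaggregated use values, the informant agreement
## ratio, and correlation comparisons.
##
## The counting unit of the use value is the distinct
## (use_label, plant_part) citation per respondent: duplicated rows
## collapse, so the index is reproducible from any row ordering.

distinct_reports <- function(ds, extra_keys = character(0)) {
  keys <- c("respondent_id", "use_label", "plant_part", extra_keys)
  u <- ds$use_reports
  u[!duplicated(u[, keys, drop = FALSE]), , drop = FALSE]
}

#' Use value of one respondent
#'
#' The number of distinct (use, plant part) citations the respondent made;
#' the per-respondent term of the Phillips & Gentry use-value index.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param respondent_id Respondent identifier.
#' @return Non-negative integer count.
#' @export
respondent_use_value <- function(ds, respondent_id) {
  stopifnot(inherits(ds, "survey_dataset"))
  if (!respondent_id %in% ds$respondents$respondent_id) {
    stop("unknown respondent_id: ", respondent_id, call. = FALSE)
  }
  u <- distinct_reports(ds)
  sum(u$respondent_id == respondent_id)
}

## vector of UVj over all respondents (zero for non-citing respondents)
respondent_uv_vector <- function(ds, reports = distinct_reports(ds)) {
  counts <- table(factor(reports$respondent_id,
                         levels = ds$respondents$respondent_id))
  as.numeric(counts)
}

#' Total use value of the species
#'
#' Mean per-respondent use value over all N respondents, with the standard
#' error of the mean.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @return data.frame (one row) with \code{scope}, \code{n_respondents},
#'   \code{uv}, \code{sem}.
#' @export
total_use_value <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  n <- nrow(ds$respondents)
  if (n == 0) stop("empty dataset", call. = FALSE)
  uv <- respondent_uv_vector(ds)
  data.frame(scope = "overall", n_respondents = n, uv = mean(uv),
             sem = if (n > 1) stats::sd(uv) / sqrt(n) else 0,
             stringsAsFactors = FALSE)
}

#' Use value disaggregated by category, plant part or respondent factor
#'
#' For \code{category} and \code{plant_part} axes the numerator is
#' restricted to qualifying citations while the denominator stays the full
#' respondent count, so category use values add up to the overall use
#' value. For a respondent factor, respondents are partitioned by level and
#' the per-level mean use value reported.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param axis \code{"category"}, \code{"plant_part"}, or the name of a
#'   categorical respondent field (e.g. \code{"gender"}, \code{"group"}).
#' @return data.frame of per-level rows with \code{scope},
#'   \code{n_respondents}, \code{uv}, \code{sem}.
#' @export
use_value_by <- function(ds, axis) {
  stopifnot(inherits(ds, "survey_dataset"))
  n <- nrow(ds$respondents)
  if (axis %in% c("category", "plant_part")) {
    reports <- distinct_reports(ds, extra_keys = axis)
    levels_ <- survey_levels()[[if (axis == "category") "category" else
      "plant_part"]]
    out <- lapply(levels_, function(lv) {
      sub <- reports[reports[[axis]] == lv, , drop = FALSE]
      uv <- as.numeric(table(factor(sub$respondent_id,
                                    levels = ds$respondents$respondent_id)))
      data.frame(scope = lv, n_respondents = n, uv = mean(uv),
                 sem = if (n > 1) stats::sd(uv) / sqrt(n) else 0,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }
  ok <- c(respondent_factor_fields(), respondent_logical_fields())
  if (!axis %in% ok) {
    stop("unknown axis '", axis, "'; use category, plant_part or one of: ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  uv_all <- respondent_uv_vector(ds)
  fac <- ds$respondents[[axis]]
  if (is.logical(fac)) fac <- ifelse(fac, "yes", "no")
  out <- lapply(sort(unique(fac[!is.na(fac)])), function(lv) {
    sel <- !is.na(fac) & fac == lv
    uv <- uv_all[sel]
    data.frame(scope = lv, n_respondents = sum(sel), uv = mean(uv),
               sem = if (sum(sel) > 1) stats::sd(uv) / sqrt(sum(sel)) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Informant agreement ratio
#'
#' IAR = (nr - na) / (nr - 1), where nr is the number of citations in a
#' scope and na the number of distinct plant parts cited there. Equals 1
#' at full consensus on a single part, 0 when every citation names a
#' different part, and is undefined (NA) for a single citation.
#'
#' @param nr Citation count (integer >= 1).
#' @param na Distinct plant-part count (1 <= na <= nr).
#' @return Numeric in [0, 1], or NA when nr = 1.
#' @export
#' @examples
#' informant_agreement_ratio(112, 5)  # 0.963...
informant_agreement_ratio <- function(nr, na) {
  stopifnot(length(nr) == 1, length(na) == 1)
  if (nr < 1 || na < 1 || na > nr) {
    stop("require 1 <= na <= nr (got nr=", nr, ", na=", na, ")",
         call. = FALSE)
  }
  if (na > length(survey_levels()$plant_part)) {
    stop("na exceeds the number of distinct plant parts", call. = FALSE)
  }
  if (nr == 1) return(NA_real_)
  (nr - na) / (nr - 1)
}

#' Round half away from zero
#'
#' Display rounding used for agreement ratios (0.875 -> 0.88 at two
#' decimals), as opposed to R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Informant agreement table
#'
#' Tallies citations and distinct plant parts per use category or per
#' medicinal body system and computes the agreement ratio for each scope.
#' Scopes with no citations are omitted; a single-citation scope has an
#' undefined (NA) ratio.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param level \code{"category"} or \code{"body_system"} (body systems
#'   exclude the non-medicinal sentinel).
#' @return data.frame with \code{scope}, \code{nr}, \code{na}, \code{iar},
#'   sorted by scope label.
#' @export
iar_table <- function(ds, level = c("category", "body_system")) {
  stopifnot(inherits(ds, "survey_dataset"))
  level <- match.arg(level)
  u <- ds$use_reports
  if (level == "body_system") u <- u[u$body_system != "non_medicinal", ]
  if (nrow(u) == 0) {
    return(data.frame(scope = character(), nr = integer(), na = integer(),
                      iar = numeric(), stringsAsFactors = FALSE))
  }
  scopes <- sort(unique(u[[level]]))
  out <- lapply(scopes, function(sc) {
    sub <- u[u[[level]] == sc, , drop = FALSE]
    nr <- nrow(sub)
    na_ <- length(unique(sub$plant_part))
    data.frame(scope = sc, nr = nr, na = na_,
               iar = informant_agreement_ratio(nr, na_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between use value and number of trees owned
#'
#' Spearman (default) or Pearson correlation between the per-respondent
#' use value and the number of trees owned, over an optional respondent
#' subset. Spearman p-values are exact for n <= 10 and use the
#' large-sample approximation otherwise.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param subset Logical vector over respondents, or NULL for all.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return List with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
uv_trees_correlation <- function(ds, subset = NULL,
                                 method = c("spearman", "pearson")) {
  stopifnot(inherits(ds, "survey_dataset"))
  method <- match.arg(method)
  uv <- respondent_uv_vector(ds)
  trees <- ds$respondents$n_trees
  if (!is.null(subset)) {
    stopifnot(is.logical(subset), length(subset) == nrow(ds$respondents))
    uv <- uv[subset]
    trees <- trees[subset]
  }
  n <- length(uv)
  if (n < 4) stop("subset yields fewer than 4 respondents", call. = FALSE)
  if (stats::sd(uv) == 0 || stats::sd(trees) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, method = method,
                note = "constant vector; correlation undefined"))
  }
  ct <- suppressWarnings(stats::cor.test(
    uv, trees, method = method, exact = (method == "spearman" && n <= 10)))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, method = method)
}

#' Compare two correlations via Fisher's r-to-z transformation
#'
#' Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)) with a two-sided
#' normal p-value.
#'
#' @param r1,r2 Correlations (|r| < 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List with \code{Z} and \code{p}.
#' @export
compare_correlations_fisher_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("|r| must be < 1 for the z-transform", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = z, p = 2 * stats::pnorm(-abs(z)))
}
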