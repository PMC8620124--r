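## KMTO knowledge-acquisition framework. Each citation's knowledge-source
## descriptor is coded as a four-attribute path:
##   Kernel   - internal (family line) or external source
##   Mutation - transition (same-sex transfer) or transversion (cross-sex)
##   Type     - vertical (another generation), horizontal (same
##              generation) or transversal (self-learning)
##   Order    - 1 parent, 2 grandparent, 0 otherwise
##
## Coding conventions for cases the framework leaves open: spouses are
## internal-horizontal; uncles/aunts internal-vertical with order 0 (orders
## 1 and 2 are reserved for parents and grandparents); cousins
## internal-horizontal; self-learning internal-transition-transversal;
## friends, community members and healers external-horizontal with the
## gender the informant reports. The uncle/aunt path is the one classifier
## output that is not structurally valid (vertical with order 0) - a direct
## consequence of the framework reserving orders 1-2 for progenitors while
## binning other generations as vertical; see the methods vignette.

kmto_relation_table <- function() {
  data.frame(
    relation = c("father", "mother", "grandfather", "grandmother",
                 "uncle_aunt", "sibling", "cousin", "spouse",
                 "friend", "community", "healer", "self_learning"),
    kernel = c(rep("internal", 8), "external", "external", "external",
               "internal"),
    type = c("vertical", "vertical", "vertical", "vertical", "vertical",
             "horizontal", "horizontal", "horizontal",
             "horizontal", "horizontal", "horizontal", "transversal"),
    order = c(1, 1, 2, 2, 0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Classify a knowledge-acquisition event into its KMTO path
#'
#' @param source_relation Knowledge source relation (see
#'   \code{survey_levels()$source_relation}).
#' @param source_gender \code{"man"}, \code{"woman"}, or
#'   \code{"not_applicable"} (self-learning only).
#' @param respondent_gender \code{"man"} or \code{"woman"}.
#' @return data.frame (one row) with \code{kernel}, \code{mutation},
#'   \code{type}, \code{order} and the \code{structurally_valid} flag.
#' @export
#' @examples
#' classify_kmto("father", "man", "man")    # internal transition vertical 1
#' classify_kmto("friend", "man", "man")    # external transition horizontal 0
classify_kmto <- function(source_relation, source_gender, respondent_gender) {
  lv <- survey_levels()
  stopifnot(source_relation %in% lv$source_relation,
            source_gender %in% lv$source_gender,
            respondent_gender %in% lv$gender)
  if (xor(source_relation == "self_learning",
          source_gender == "not_applicable")) {
    stop("source_gender must be 'not_applicable' iff source_relation is ",
         "'self_learning'", call. = FALSE)
  }
  tab <- kmto_relation_table()
  row <- tab[tab$relation == source_relation, ]
  mutation <- if (source_relation == "self_learning") "transition" else
    if (source_gender == respondent_gender) "transition" else "transversion"
  kmto_path(row$kernel, mutation, row$type, row$order)
}

kmto_path <- function(kernel, mutation, type, order) {
  valid <- (type == "vertical" & order %in% c(1, 2)) |
    (type %in% c("horizontal", "transversal") & order == 0)
  data.frame(kernel = kernel, mutation = mutation, type = type,
             order = as.integer(order), structurally_valid = valid,
             stringsAsFactors = FALSE)
}

#' Enumerate the KMTO path space
#'
#' The full product of the four attributes has 2 x 2 x 3 x 3 = 36 paths.
#' Under the framework's own structural rule (vertical paths carry order 1
#' or 2; horizontal and transversal paths carry order 0) only 16 of them
#' are attainable.
#'
#' @param constrained If TRUE, return only structurally valid paths.
#' @return data.frame of paths with the \code{structurally_valid} flag.
#' @export
enumerate_paths <- function(constrained = FALSE) {
  grid <- expand.grid(kernel = c("internal", "external"),
                      mutation = c("transition", "transversion"),
                      type = c("vertical", "horizontal", "transversal"),
                      order = c(0L, 1L, 2L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- kmto_path(grid$kernel, grid$mutation, grid$type, grid$order)
  if (constrained) out <- out[out$structurally_valid, , drop = FALSE]
  rownames(out) <- NULL
  out
}

classify_reports <- function(ds) {
  u <- ds$use_reports
  rg <- ds$respondents$gender[match(u$respondent_id,
                                    ds$respondents$respondent_id)]
  tab <- kmto_relation_table()
  m <- match(u$source_relation, tab$relation)
  mutation <- ifelse(u$source_relation == "self_learning", "transition",
                     ifelse(u$source_gender == rg, "transition",
                            "transversion"))
  cbind(u[, c("respondent_id", "category"), drop = FALSE],
        kmto_path(tab$kernel[m], mutation, tab$type[m], tab$order[m]))
}

#' Tally observed KMTO paths
#'
#' Counts and proportions of each observed knowledge-acquisition path over
#' all use reports, optionally within each use category. Zero-count paths
#' are omitted; proportions are normalized within each grouping.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param by_category Tally per use category rather than overall.
#' @return data.frame with the path attributes, \code{count} and
#'   \code{proportion} (and \code{category} when \code{by_category}).
#' @export
path_frequencies <- function(ds, by_category = FALSE) {
  stopifnot(inherits(ds, "survey_dataset"))
  paths <- classify_reports(ds)
  keys <- c(if (by_category) "category", "kernel", "mutation", "type",
            "order")
  agg <- stats::aggregate(list(count = rep(1L, nrow(paths))),
                          by = paths[, keys, drop = FALSE], FUN = sum)
  if (by_category) {
    totals <- tapply(agg$count, agg$category, sum)
    agg$proportion <- agg$count / as.numeric(totals[agg$category])
  } else {
    agg$proportion <- agg$count / sum(agg$count)
  }
  ord <- do.call(order, c(agg[, keys, drop = FALSE], list(method = "radix")))
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Equal-proportion tests of each KMTO attribute's states
#'
#' For each of the four attributes, tests whether its observed states are
#' equally represented across all use reports (chi-square goodness of
#' fit).
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @return data.frame with \code{attribute}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{method}.
#' @export
attribute_state_tests <- function(ds) {
  paths <- classify_reports(ds)
  states <- list(kernel = c("internal", "external"),
                 mutation = c("transition", "transversion"),
                 type = c("vertical", "horizontal", "transversal"),
                 order = c(0L, 1L, 2L))
  out <- lapply(c("kernel", "mutation", "type", "order"), function(a) {
    counts <- table(factor(paths[[a]], levels = states[[a]]))
    res <- equal_proportions_test(as.numeric(counts))
    data.frame(attribute = a, statistic = res$statistic, df = res$df,
               p_value = res$p_value, method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Independence of KMTO attribute states and use category
#'
#' Cross-tabulates each attribute's states against the use category and
#' runs the independence test with its small-expected-count fallback.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param seed Seed for the Monte-Carlo fallback of large sparse tables.
#' @return data.frame with \code{attribute}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{method}.
#' @export
kmto_category_tests <- function(ds, seed = 1) {
  paths <- classify_reports(ds)
  out <- lapply(c("kernel", "mutation", "type", "order"), function(a) {
    tab <- table(paths[[a]], paths$category)
    res <- independence_test(unclass(tab), seed = seed)
    data.frame(attribute = a, statistic = res$statistic,
               df = ifelse(is.null(res$df), NA_real_, res$df),
               p_value = res$p_value, method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
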