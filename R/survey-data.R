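#' Construct a survey dataset
#'
#' Bundles the two survey tables — one row per respondent and one row per
#' respondent-by-use citation — into a validated container used by every
#' downstream analysis.
#'
#' @param respondents data.frame with the respondent schema (see
#'   \code{\link{survey_levels}} and the package vignette).
#' @param use_reports data.frame with the use-report schema.
#' @param provenance Free-text metadata (source file, generator seed, ...).
#' @return An object of class \code{survey_dataset}: a list with elements
#'   \code{respondents}, \code{use_reports}, \code{provenance}.
#' @export
survey_dataset <- function(respondents, use_reports,
                           provenance = "unspecified") {
  stopifnot(is.data.frame(respondents), is.data.frame(use_reports))
  miss <- setdiff(respondent_columns(), names(respondents))
  if (length(miss) > 0) {
    stop("respondents table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(report_columns(), names(use_reports))
  if (length(miss) > 0) {
    stop("use_reports table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- respondents$respondent_id[duplicated(respondents$respondent_id)]
  if (length(dup) > 0) {
    stop("duplicate respondent_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(use_reports$respondent_id, respondents$respondent_id)
  if (length(orphan) > 0) {
    stop("use report references unknown respondent(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(
    list(respondents = respondents[, respondent_columns()],
         use_reports = use_reports[, report_columns()],
         provenance = provenance),
    class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("survey_dataset: %d respondents, %d use reports\n",
              nrow(x$respondents), nrow(x$use_reports)))
  cat(sprintf("  groups: %s\n",
              paste(sort(unique(x$respondents$group)), collapse = ", ")))
  cat(sprintf("  provenance: %s\n", x$provenance))
  invisible(x)
}

bool_from_chr <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a survey dataset from delimiter-separated files
#'
#' Reads the respondents and use-reports tables (comma-separated, UTF-8,
#' header row mandatory), normalizes all categorical labels to the canonical
#' vocabulary via the codebook, and validates referential integrity.
#' Optional fields are empty strings on disk and \code{NA} in memory.
#'
#' @param respondents_path,reports_path File paths.
#' @param codebook Codebook list (default \code{\link{default_codebook}()}),
#'   or a path to a YAML codebook.
#' @param delim Field delimiter, default comma.
#' @return A \code{\link{survey_dataset}}.
#' @export
read_dataset <- function(respondents_path, reports_path,
                         codebook = default_codebook(), delim = ",") {
  stopifnot(file.exists(respondents_path), file.exists(reports_path))
  if (is.character(codebook) && length(codebook) == 1) {
    codebook <- read_codebook(codebook)
  }
  lv <- survey_levels()
  resp <- utils::read.table(respondents_path, header = TRUE, sep = delim,
                            colClasses = "character", fileEncoding = "UTF-8",
                            stringsAsFactors = FALSE, check.names = TRUE)
  rep_ <- utils::read.table(reports_path, header = TRUE, sep = delim,
                            colClasses = "character", fileEncoding = "UTF-8",
                            stringsAsFactors = FALSE, check.names = TRUE)
  miss <- setdiff(respondent_columns(), names(resp))
  if (length(miss) > 0) {
    stop("respondents file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(report_columns(), names(rep_))
  if (length(miss) > 0) {
    stop("use-reports file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  for (f in c("country", "group", "gender", "age_category", "schooling",
              "activity", "religion", "migratory_status", "ownership_mode",
              "habitat", "perceived_growth", "perceived_availability")) {
    resp[[f]] <- normalize_labels(resp[[f]], f, lv[[f]], codebook)
  }
  for (f in c("age_years", "n_trees", "land_area_ha",
              "perceived_time_to_fruiting_years", "max_acreage_ha",
              "max_price_usd")) {
    resp[[f]] <- suppressWarnings(as.numeric(resp[[f]]))
  }
  for (f in respondent_logical_fields()) resp[[f]] <- bool_from_chr(resp[[f]])

  for (f in c("category", "body_system", "plant_part", "preparation",
              "source_relation", "source_gender")) {
    rep_[[f]] <- normalize_labels(rep_[[f]], f, lv[[f]], codebook)
  }
  rep_$use_label <- trimws(rep_$use_label)

  survey_dataset(resp, rep_,
                 provenance = sprintf("read from %s", respondents_path))
}

#' Write a survey dataset to delimiter-separated files
#'
#' Emits \code{respondents.csv} and \code{use_reports.csv} under
#' \code{out_dir}; optional fields are written as empty strings. The result
#' round-trips through \code{\link{read_dataset}} field for field.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(ds, out_dir) {
  stopifnot(inherits(ds, "survey_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, c("respondents.csv", "use_reports.csv"))
  fmt <- function(df) {
    out <- df
    for (f in names(out)) {
      if (is.logical(out[[f]])) out[[f]] <- tolower(as.character(out[[f]]))
      out[[f]] <- as.character(out[[f]])
      out[[f]][is.na(df[[f]])] <- ""
    }
    out
  }
  utils::write.table(fmt(ds$respondents), paths[1], sep = ",", row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  utils::write.table(fmt(ds$use_reports), paths[2], sep = ",", row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Validate a survey dataset against the schema invariants
#'
#' Checks every respondent and report row against the survey invariants:
#' the age category is recomputed from age in years (young < 30,
#' adult 30--59, old >= 60) and the stored label checked against it;
#' ownership fields (mode, habitat, positive tree count) must be present
#' exactly when the respondent owns trees; cultivation-intent fields
#' (acreage, price) exactly when the respondent is willing to cultivate;
#' the medicinal body system is \code{non_medicinal} exactly for
#' non-medicinal categories; and self-learning is the only knowledge source
#' with a \code{not_applicable} gender. Violations are returned as data,
#' not raised as errors.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @return data.frame with columns \code{respondent_id}, \code{rule},
#'   \code{detail}; zero rows when the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  r <- ds$respondents
  u <- ds$use_reports
  v <- list()
  add <- function(id, rule, detail) {
    v[[length(v) + 1]] <<- data.frame(respondent_id = id, rule = rule,
                                      detail = detail,
                                      stringsAsFactors = FALSE)
  }
  expect_cat <- age_category(r$age_years)
  bad <- which(r$age_category != expect_cat)
  for (i in bad) {
    add(r$respondent_id[i], "age_category",
        sprintf("age %g stored as '%s', expected '%s'",
                r$age_years[i], r$age_category[i], expect_cat[i]))
  }
  bad <- which(r$owns_trees & r$n_trees == 0 | !r$owns_trees & r$n_trees != 0)
  for (i in bad) {
    add(r$respondent_id[i], "n_trees",
        sprintf("owns_trees=%s but n_trees=%g", r$owns_trees[i], r$n_trees[i]))
  }
  for (f in c("ownership_mode", "habitat")) {
    bad <- which(r$owns_trees != !is.na(r[[f]]))
    for (i in bad) {
      add(r$respondent_id[i], f,
          sprintf("%s must be present iff owns_trees (owns_trees=%s)",
                  f, r$owns_trees[i]))
    }
  }
  for (f in c("max_acreage_ha", "max_price_usd")) {
    bad <- which(r$willing_to_cultivate != !is.na(r[[f]]))
    for (i in bad) {
      add(r$respondent_id[i], f,
          sprintf("%s must be present iff willing_to_cultivate (=%s)",
                  f, r$willing_to_cultivate[i]))
    }
  }
  bad <- which((u$category == "medicinal") != (u$body_system != "non_medicinal"))
  for (i in bad) {
    add(u$respondent_id[i], "body_system",
        sprintf("category '%s' with body_system '%s'",
                u$category[i], u$body_system[i]))
  }
  bad <- which((u$source_relation == "self_learning") !=
                 (u$source_gender == "not_applicable"))
  for (i in bad) {
    add(u$respondent_id[i], "source_gender",
        sprintf("source_relation '%s' with source_gender '%s'",
                u$source_relation[i], u$source_gender[i]))
  }
  if (length(v) == 0) {
    return(data.frame(respondent_id = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Write a validation report as JSON lines
#'
#' @param report data.frame from \code{\link{validate_dataset}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_validation_report <- function(report, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(report) > 0) {
    for (i in seq_len(nrow(report))) {
      writeLines(jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Cross-tabulate a respondent factor by sociolinguistic group
#'
#' Per-group percentage of each level of a categorical respondent field,
#' plus a Total column over all respondents; every column sums to 100.
#' Mirrors the descriptive-statistics summaries of the survey's demographic
#' table.
#'
#' @param ds A \code{\link{survey_dataset}}.
#' @param factor Name of a categorical or logical respondent field.
#' @return Numeric matrix, rows = factor levels, columns = groups + "Total".
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(seed = 1))
#' demographic_crosstab(ds, "gender")
demographic_crosstab <- function(ds, factor) {
  stopifnot(inherits(ds, "survey_dataset"))
  ok <- c(respondent_factor_fields(), respondent_logical_fields())
  if (!factor %in% ok) {
    stop("'", factor, "' is not a categorical respondent field; one of: ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  r <- ds$respondents
  x <- r[[factor]]
  if (is.logical(x)) x <- ifelse(x, "yes", "no")
  keep <- !is.na(x)
  x <- x[keep]
  g <- r$group[keep]
  lv <- survey_levels()[[factor]]
  if (is.null(lv)) lv <- c("no", "yes")
  lv <- lv[lv %in% unique(x)]
  tab <- table(factor(x, levels = lv), g)
  pct <- sweep(tab, 2, colSums(tab), "/") * 100
  total <- as.numeric(table(factor(x, levels = lv))) / length(x) * 100
  out <- cbind(as.matrix(pct), Total = total)
  rownames(out) <- lv
  out
}
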