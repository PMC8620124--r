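## One-call orchestration: simulate (or load) -> validate -> indices ->
## kmto -> associations -> drivers, writing JSON artifacts plus a manifest
## with checksums. All randomness flows from one root seed split per stage
## by stable labels, so identical configs reproduce byte-identical output.

#' Run configuration for the analysis pipeline
#'
#' Exactly one input source: either a generator config (synthetic run) or
#' the paths of an existing respondents/use-reports pair.
#'
#' @param out_dir Output directory for the stage artifacts.
#' @param generator A \code{\link{generator_config}}, or NULL.
#' @param respondents_path,reports_path Input files, or NULL.
#' @param stages Character subset of
#'   \code{c("validate", "indices", "kmto", "associations", "drivers")}.
#' @param seed Root seed for stage-level randomness (Monte-Carlo tests,
#'   tree cross-validation).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(out_dir, generator = NULL, respondents_path = NULL,
                       reports_path = NULL,
                       stages = c("validate", "indices", "kmto",
                                  "associations", "drivers"),
                       seed = 1) {
  from_files <- !is.null(respondents_path)
  if (from_files == !is.null(generator)) {
    stop("exactly one input source: generator config or input files",
         call. = FALSE)
  }
  if (from_files) {
    for (p in c(respondents_path, reports_path)) {
      if (normalizePath(dirname(p), mustWork = FALSE) ==
          normalizePath(out_dir, mustWork = FALSE)) {
        stop("output directory must be distinct from the input directory",
             call. = FALSE)
      }
    }
  }
  bad <- setdiff(stages, c("validate", "indices", "kmto", "associations",
                           "drivers"))
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  structure(list(out_dir = out_dir, generator = generator,
                 respondents_path = respondents_path,
                 reports_path = reports_path, stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on the configured input,
#' writes one JSON artifact per stage under \code{out_dir}, and returns a
#' manifest listing every artifact with an md5 checksum, the seed and the
#' completed stages. Identical configurations and seeds reproduce
#' byte-identical artifacts.
#'
#' @param cfg A \code{\link{run_config}}.
#' @return List with \code{dataset}, \code{artifacts} (named paths),
#'   \code{manifest}.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- if (!is.null(cfg$generator)) {
    generate_dataset(cfg$generator)
  } else {
    read_dataset(cfg$respondents_path, cfg$reports_path)
  }
  artifacts <- character(0)
  completed <- character(0)
  emit <- function(name, obj, stage = name) {
    p <- write_json_artifact(obj, file.path(cfg$out_dir,
                                            paste0(name, ".json")))
    artifacts[[name]] <<- p
    completed <<- c(completed, stage)
  }

  if ("validate" %in% cfg$stages) {
    emit("validation", validate_dataset(ds), stage = "validate")
  }
  if ("indices" %in% cfg$stages) {
    emit("indices", list(
      uv_overall = total_use_value(ds),
      uv_by_category = use_value_by(ds, "category"),
      uv_by_part = use_value_by(ds, "plant_part"),
      iar_category = iar_table(ds, "category"),
      iar_body_system = iar_table(ds, "body_system")))
  }
  if ("kmto" %in% cfg$stages) {
    emit("kmto", list(
      paths = path_frequencies(ds),
      paths_by_category = path_frequencies(ds, by_category = TRUE),
      attribute_tests = attribute_state_tests(ds),
      category_tests = kmto_category_tests(
        ds, seed = derive_seed(cfg$seed, "kmto_tests"))))
  }
  if ("associations" %in% cfg$stages) {
    r <- ds$respondents
    owners <- r$owns_trees
    emit("associations", list(
      ownership_mode_proportions = equal_proportions_test(
        as.numeric(table(r$ownership_mode[owners]))),
      availability_proportions = equal_proportions_test(
        as.numeric(table(r$perceived_availability))),
      mode_by_age = independence_test(
        unclass(table(r$ownership_mode[owners], r$age_category[owners])),
        seed = derive_seed(cfg$seed, "assoc_mode_age")),
      trees_by_group = {
        fit <- fit_count_model(r$n_trees[owners],
                               data.frame(group = r$group[owners]))
        list(coefficients = as.list(fit$coefficients),
             std_errors = as.list(fit$std_errors),
             dispersion = fit$dispersion, family_used = fit$family_used)
      }))
  }
  if ("drivers" %in% cfg$stages) {
    r <- ds$respondents
    feats <- r[, c("group", "knows_taboo", "perceives_market", "schooling",
                   "perceived_time_to_fruiting_years", "knows_superstition")]
    ct <- fit_classification_tree(
      feats, r$willing_to_cultivate,
      tree_params(seed = derive_seed(cfg$seed, "tree_willing")))
    w <- r$willing_to_cultivate
    rt <- fit_regression_tree(
      r[w, c("schooling", "perceived_growth")], r$max_acreage_ha[w],
      tree_params(seed = derive_seed(cfg$seed, "tree_acreage")))
    pt <- fit_regression_tree(
      r[w, c("activity", "owns_trees", "age_category", "group",
             "perceived_time_to_fruiting_years", "schooling")],
      r$max_price_usd[w],
      tree_params(seed = derive_seed(cfg$seed, "tree_price")))
    emit("drivers", list(
      willingness_tree = tree_to_text(ct),
      acreage_tree = tree_to_text(rt),
      price_tree = tree_to_text(pt)))
  }
  manifest <- list(
    seed = cfg$seed,
    provenance = ds$provenance,
    stages_completed = completed,
    files = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  mp <- write_json_artifact(manifest, file.path(cfg$out_dir,
                                                "manifest.json"))
  list(dataset = ds, artifacts = c(artifacts, manifest = mp),
       manifest = manifest)
}
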