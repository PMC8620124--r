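#' @keywords internal
"_PACKAGE"

## Canonical vocabulary for the two survey tables. Levels are ASCII codes;
## accented display forms (Sahouè, Wémé) are handled by the codebook.

#' Canonical category levels used by the survey schema
#'
#' Named list of the admissible levels for every categorical field of the
#' respondents and use-reports tables: sociolinguistic groups, gender,
#' age category, schooling (ordered none < literate < primary < secondary <
#' university), main activity, religion, migratory status, ownership mode,
#' habitat, perception scales, use categories, the 15 ICPC2-derived body
#' systems plus the \code{non_medicinal} sentinel, plant parts, preparation
#' modes, and knowledge-source descriptors.
#'
#' @return A named list of character vectors.
#' @export
#' @examples
#' survey_levels()$group
survey_levels <- function() {
  list(
    country     = c("Benin", "Ghana"),
    group       = c("Adja", "Aizo", "Fon", "Holli", "Sahoue", "Weme",
                    "Akan", "Ewe", "Ga-adangbe"),
    gender      = c("man", "woman"),
    age_category = c("young", "adult", "old"),
    schooling   = c("none", "literate", "primary", "secondary", "university"),
    activity    = c("farming", "handcraft", "teaching", "trading",
                    "traditional_healing"),
    religion    = c("christian", "indigenous", "muslim"),
    migratory_status = c("autochthon", "allochthon"),
    ownership_mode = c("legacy", "self", "legacy_and_self", "spontaneous"),
    habitat     = c("home_garden", "farm"),
    perceived_growth = c("slow", "moderate", "fast"),
    perceived_availability = c("decline", "stable", "increase"),
    category    = c("food", "medicinal", "magico_spiritual", "sales",
                    "social", "firewood"),
    body_system = c("blood", "circulatory", "digestive",
                    "endocrine_metabolic_nutritional", "eye",
                    "female_genital", "general_health", "male_genital",
                    "musculoskeletal", "neurological",
                    "pregnancy_childbearing", "psychological", "respiratory",
                    "skin", "urinary", "non_medicinal"),
    plant_part  = c("flower", "fruit", "seed", "leaf", "twig", "bark", "root"),
    preparation = c("decoction", "grinding", "direct", "infusion", "other"),
    source_relation = c("father", "mother", "grandfather", "grandmother",
                        "uncle_aunt", "sibling", "cousin", "spouse",
                        "friend", "community", "healer", "self_learning"),
    source_gender = c("man", "woman", "not_applicable")
  )
}

#' Country of a sociolinguistic group
#'
#' @param group Character vector of canonical group codes.
#' @return Character vector, "Benin" or "Ghana".
#' @export
group_country <- function(group) {
  ghana <- c("Akan", "Ewe", "Ga-adangbe")
  ifelse(group %in% ghana, "Ghana", "Benin")
}

#' Age category from age in years
#'
#' Young is under 30, adult 30 to 59, old 60 and above.
#'
#' @param age_years Numeric vector of ages.
#' @return Character vector of categories.
#' @export
#' @examples
#' age_category(c(18, 30, 59, 60))
age_category <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years > 0))
  ifelse(age_years < 30, "young", ifelse(age_years < 60, "adult", "old"))
}

respondent_columns <- function() {
  c("respondent_id", "country", "group", "gender", "age_years",
    "age_category", "schooling", "activity", "religion", "migratory_status",
    "owns_trees", "n_trees", "ownership_mode", "habitat", "land_area_ha",
    "perceived_growth", "perceived_time_to_fruiting_years",
    "perceived_availability", "knows_taboo", "knows_superstition",
    "perceives_market", "willing_to_cultivate", "max_acreage_ha",
    "max_price_usd")
}

report_columns <- function() {
  c("respondent_id", "use_label", "category", "body_system", "plant_part",
    "preparation", "source_relation", "source_gender")
}

## categorical respondent fields usable in crosstabs / UV stratification
respondent_factor_fields <- function() {
  c("country", "group", "gender", "age_category", "schooling", "activity",
    "religion", "migratory_status", "ownership_mode", "habitat",
    "perceived_growth", "perceived_availability")
}

respondent_logical_fields <- function() {
  c("owns_trees", "knows_taboo", "knows_superstition", "perceives_market",
    "willing_to_cultivate")
}
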