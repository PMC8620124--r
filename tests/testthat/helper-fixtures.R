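# Fixture builders: every fixture is constructed in code at test time.

make_respondent <- function(id, group = "Fon", gender = "man",
                            age_years = 45, schooling = "primary",
                            activity = "farming", religion = "christian",
                            migratory_status = "autochthon",
                            owns_trees = TRUE, n_trees = 3,
                            ownership_mode = if (owns_trees) "legacy" else NA,
                            habitat = if (owns_trees) "farm" else NA,
                            land_area_ha = 2,
                            perceived_growth = "slow",
                            perceived_time_to_fruiting_years = 5.5,
                            perceived_availability = "decline",
                            knows_taboo = FALSE, knows_superstition = FALSE,
                            perceives_market = TRUE,
                            willing_to_cultivate = FALSE,
                            max_acreage_ha = if (willing_to_cultivate) 0.4 else NA,
                            max_price_usd = if (willing_to_cultivate) 0.5 else NA,
                            age_category = NULL) {
  data.frame(
    respondent_id = id, country = group_country(group), group = group,
    gender = gender, age_years = age_years,
    age_category = if (is.null(age_category)) {
      ethnosurvey::age_category(age_years)
    } else age_category,
    schooling = schooling, activity = activity, religion = religion,
    migratory_status = migratory_status, owns_trees = owns_trees,
    n_trees = if (owns_trees) n_trees else 0,
    ownership_mode = as.character(ownership_mode),
    habitat = as.character(habitat), land_area_ha = land_area_ha,
    perceived_growth = perceived_growth,
    perceived_time_to_fruiting_years = perceived_time_to_fruiting_years,
    perceived_availability = perceived_availability,
    knows_taboo = knows_taboo, knows_superstition = knows_superstition,
    perceives_market = perceives_market,
    willing_to_cultivate = willing_to_cultivate,
    max_acreage_ha = as.numeric(max_acreage_ha),
    max_price_usd = as.numeric(max_price_usd),
    stringsAsFactors = FALSE)
}

make_report <- function(respondent_id, use_label = "sweetener",
                        category = "food", body_system = "non_medicinal",
                        plant_part = "fruit", preparation = "direct",
                        source_relation = "father",
                        source_gender = if (source_relation == "self_learning") {
                          "not_applicable"
                        } else "man") {
  data.frame(respondent_id = respondent_id, use_label = use_label,
             category = category, body_system = body_system,
             plant_part = plant_part, preparation = preparation,
             source_relation = source_relation,
             source_gender = source_gender, stringsAsFactors = FALSE)
}

## three respondents, five reports
tiny_dataset <- function() {
  resp <- rbind(make_respondent("R1", gender = "man"),
                make_respondent("R2", group = "Akan", gender = "woman",
                                age_years = 25),
                make_respondent("R3", group = "Ewe", owns_trees = FALSE))
  reps <- rbind(
    make_report("R1"),
    make_report("R1", "malaria", "medicinal", "general_health", "leaf",
                "decoction"),
    make_report("R2"),
    make_report("R2", "lucky_charm", "magico_spiritual", "non_medicinal",
                "root", "grinding", "grandmother", "woman"),
    make_report("R3", "chewing_stick", "social", "non_medicinal", "twig"))
  survey_dataset(resp, reps, provenance = "fixture")
}

## small config: same nine groups, ~60 respondents, for fast property loops
small_config <- function(seed, scale = 8L) {
  sizes <- setNames(pmax(4L, round(table1_groups() / scale)),
                    names(table1_groups()))
  generator_config(seed = seed, group_sizes = sizes)
}
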