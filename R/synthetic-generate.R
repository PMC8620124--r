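## Synthetic survey generation. Each generator stage derives its own seed
## from the config seed via derive_seed(), so stages are individually
## reproducible and insensitive to one another's draw counts.

sample_level <- function(n, levels, probs) {
  stopifnot(length(levels) == length(probs))
  if (n == 0) return(character(0))
  sample(levels, n, replace = TRUE, prob = probs)
}

## mean of a zero-truncated negative binomial at location mu
ztnb_mean <- function(mu, size) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  mu / (1 - p0)
}

## calibrate mu so the zero-truncated mean hits `target` (> 1)
ztnb_calibrate <- function(target, size) {
  if (target <= 1.01) return(1e-6)
  stats::uniroot(function(m) ztnb_mean(m, size) - target,
                 lower = 1e-8, upper = target * 2 + 10,
                 tol = 1e-10)$root
}

## inverse-CDF draw from the zero-truncated negative binomial
rztnb <- function(n, mu, size) {
  if (n == 0) return(integer(0))
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, mu = mu, size = size)
}

rgamma_mean <- function(n, mean, shape) {
  if (n == 0) return(numeric(0))
  if (shape <= 0) return(rep(mean, n))
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

age_bounds <- function(cat) {
  switch(cat, young = c(18, 29), adult = c(30, 59), old = c(60, 90))
}

#' Generate synthetic respondents
#'
#' Draws one respondent table with group sizes matched exactly and every
#' categorical field drawn from its per-group marginal; ages are uniform
#' integers within the drawn category's bounds (young 18--29, adult 30--59,
#' old 60--90); owners' tree counts follow a zero-truncated negative
#' binomial whose truncated mean equals the configured per-group mean.
#' Cultivation-intent fields are left unset (see
#' \code{\link{generate_cultivation_outcomes}}).
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return data.frame with the respondent schema.
#' @export
generate_respondents <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(cfg$seed, "respondents"))
  marg <- cfg$demographic_marginals
  pc <- cfg$perception
  groups <- names(cfg$group_sizes)
  rows <- vector("list", length(groups))
  offset <- 0
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- cfg$group_sizes[[gi]]
    draw <- function(field) {
      tab <- marg[[field]]
      sample_level(n, rownames(tab), tab[, g])
    }
    cat_ <- draw("age_category")
    age <- vapply(cat_, function(cc) {
      b <- age_bounds(cc)
      sample(seq(b[1], b[2]), 1)
    }, numeric(1))
    owns <- stats::runif(n) < cfg$ownership_rate
    n_tr <- integer(n)
    if (any(owns)) {
      mu <- ztnb_calibrate(cfg$tree_count_means[[g]], cfg$noise$nb_size)
      n_tr[owns] <- rztnb(sum(owns), mu, cfg$noise$nb_size)
    }
    sch <- draw("schooling")
    land_mean <- ifelse(sch == "university",
                        pc$land_mean_ha[["university"]],
                        pc$land_mean_ha[["default"]])
    rows[[gi]] <- data.frame(
      respondent_id = sprintf("R%04d", offset + seq_len(n)),
      country = group_country(g),
      group = g,
      gender = draw("gender"),
      age_years = age,
      age_category = cat_,
      schooling = sch,
      activity = draw("activity"),
      religion = draw("religion"),
      migratory_status = draw("migratory_status"),
      owns_trees = owns,
      n_trees = n_tr,
      ownership_mode = ifelse(owns, sample_level(
        n, names(pc$ownership_mode), pc$ownership_mode), NA_character_),
      habitat = ifelse(owns, sample_level(
        n, names(pc$habitat), pc$habitat), NA_character_),
      land_area_ha = rgamma_mean(n, 1, 2) * land_mean,
      perceived_growth = sample_level(n, names(pc$growth), pc$growth),
      perceived_time_to_fruiting_years =
        rgamma_mean(n, pc$fruiting_mean_years[[g]], 25),
      perceived_availability = sample_level(
        n, names(pc$availability), pc$availability),
      knows_taboo = stats::runif(n) < pc$taboo_prob[[g]],
      knows_superstition = stats::runif(n) < pc$superstition_prob[[g]],
      perceives_market = stats::runif(n) < pc$market_prob,
      willing_to_cultivate = FALSE,
      max_acreage_ha = NA_real_,
      max_price_usd = NA_real_,
      stringsAsFactors = FALSE)
    offset <- offset + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic use reports
#'
#' For every catalogue use, each eligible respondent (honouring country and
#' group restrictions) cites it independently with probability
#' citations / (eligible respondents in the reference 510-respondent
#' survey); the plant part is drawn uniformly from the use's admissible part
#' list and knowledge-source fields from the configured source-relation
#' weights (father-dominant by default; parents and grandparents carry
#' their own gender, spouses the opposite of the respondent's,
#' self-learning has no source gender).
#'
#' @param respondents data.frame from \code{\link{generate_respondents}}.
#' @param cfg A \code{\link{generator_config}}.
#' @return data.frame with the use-report schema.
#' @export
generate_use_reports <- function(respondents, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(cfg$seed, "use_reports"))
  ref_sizes <- table1_groups()
  cat_tab <- cfg$catalogue
  prep_levels <- survey_levels()$preparation
  prep_probs <- c(0.35, 0.25, 0.25, 0.10, 0.05)
  out <- vector("list", nrow(cat_tab))
  for (i in seq_len(nrow(cat_tab))) {
    row <- cat_tab[i, ]
    eligible <- rep(TRUE, nrow(respondents))
    ref_groups <- names(ref_sizes)
    if (nzchar(row$restrict_country)) {
      eligible <- eligible & respondents$country == row$restrict_country
      ref_groups <- ref_groups[group_country(ref_groups) == row$restrict_country]
    }
    if (nzchar(row$restrict_group)) {
      eligible <- eligible & respondents$group == row$restrict_group
      ref_groups <- intersect(ref_groups, row$restrict_group)
    }
    p <- min(1, row$citations / sum(ref_sizes[ref_groups]))
    idx <- which(eligible)
    cites <- idx[stats::runif(length(idx)) < p]
    if (length(cites) == 0) next
    parts <- strsplit(row$parts, ",", fixed = TRUE)[[1]]
    rel <- sample_level(length(cites), names(cfg$kmto_weights),
                        cfg$kmto_weights)
    rgender <- respondents$gender[cites]
    sg <- ifelse(
      rel %in% c("father", "grandfather"), "man",
      ifelse(rel %in% c("mother", "grandmother"), "woman",
        ifelse(rel == "spouse", ifelse(rgender == "man", "woman", "man"),
          ifelse(rel == "self_learning", "not_applicable",
            ifelse(stats::runif(length(cites)) < cfg$source_man_prob,
                   "man", "woman")))))
    out[[i]] <- data.frame(
      respondent_id = respondents$respondent_id[cites],
      use_label = row$use_label,
      category = row$category,
      body_system = row$body_system,
      plant_part = sample(parts, length(cites), replace = TRUE),
      preparation = if (row$use_label == "sweetener") "direct" else
        sample_level(length(cites), prep_levels, prep_probs),
      source_relation = rel,
      source_gender = sg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

## raw willingness probability of the tree-structured rule, before
## logit-scale calibration of the marginal
willingness_raw_prob <- function(r) {
  ifelse(r$group %in% c("Akan", "Ga-adangbe"), 0.10,
    ifelse(r$knows_taboo, 0.85,
      ifelse(r$perceives_market & r$schooling == "secondary", 0.80,
        ifelse(r$perceives_market, 0.35, 0.15))))
}

#' Generate cultivation-intent outcomes
#'
#' Willingness to cultivate follows a tree-structured rule (sociolinguistic
#' group, taboo knowledge, market perception, schooling) whose
#' probabilities are shifted on the logit scale so the expected marginal
#' equals \code{willingness_rate}. For willing respondents the maximum
#' acreage is drawn from a gamma with the (schooling, perceived growth)
#' stratum mean, and the maximum seedling price from the ordered
#' activity/ownership/age/group price rules; unwilling respondents carry
#' neither.
#'
#' @param respondents data.frame from \code{\link{generate_respondents}}.
#' @param cfg A \code{\link{generator_config}}.
#' @return The respondent data.frame with \code{willing_to_cultivate},
#'   \code{max_acreage_ha} and \code{max_price_usd} filled.
#' @export
generate_cultivation_outcomes <- function(respondents, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(derive_seed(cfg$seed, "cultivation"))
  r <- respondents
  p_raw <- willingness_raw_prob(r)
  shift <- stats::uniroot(
    function(d) mean(stats::plogis(stats::qlogis(p_raw) + d)) -
      cfg$willingness_rate,
    lower = -12, upper = 12, tol = 1e-12)$root
  p <- stats::plogis(stats::qlogis(p_raw) + shift)
  r$willing_to_cultivate <- stats::runif(nrow(r)) < p

  stratum <- acreage_stratum(r$schooling, r$perceived_growth)
  means <- cfg$acreage_leaf_means[stratum]
  w <- which(r$willing_to_cultivate)
  r$max_acreage_ha <- NA_real_
  r$max_acreage_ha[w] <- rgamma_mean(length(w), 1, cfg$noise$gamma_shape) *
    means[w]

  pmeans <- price_stratum_mean(r, cfg$price_rules)
  r$max_price_usd <- NA_real_
  r$max_price_usd[w] <- rgamma_mean(length(w), 1, cfg$noise$gamma_shape) *
    pmeans[w]
  r
}

#' Acreage stratum of a respondent
#'
#' @param schooling,perceived_growth Character vectors.
#' @return Stratum labels keying \code{acreage_leaf_means}.
#' @export
acreage_stratum <- function(schooling, perceived_growth) {
  ifelse(schooling == "none", "none",
    ifelse(schooling == "university", "university",
      ifelse(perceived_growth == "fast", "intermediate_fast",
             "intermediate_slow_moderate")))
}

price_stratum_mean <- function(r, rules) {
  m <- stats::setNames(rules$mean_usd, rules$rule)
  need <- setdiff(c("handcraft_no_trees", "handcraft_owner", "old",
                    "prime_group_intermediate", "prime_group_extreme",
                    "fallback"), names(m))
  if (length(need) > 0) {
    stop("price_rules missing stratum: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  prime <- r$age_category %in% c("young", "adult") &
    r$group %in% c("Adja", "Aizo", "Akan", "Weme") &
    r$perceived_time_to_fruiting_years <= 5
  ifelse(r$activity == "handcraft" & !r$owns_trees, m[["handcraft_no_trees"]],
    ifelse(r$activity == "handcraft", m[["handcraft_owner"]],
      ifelse(r$age_category == "old", m[["old"]],
        ifelse(prime & r$schooling %in% c("primary", "secondary"),
               m[["prime_group_intermediate"]],
          ifelse(prime, m[["prime_group_extreme"]], m[["fallback"]])))))
}

#' Generate a complete synthetic survey dataset
#'
#' Composes respondent, cultivation-outcome and use-report generation into
#' one \code{\link{survey_dataset}} whose provenance records the seed and a
#' config checksum. The result always satisfies every schema invariant
#' (\code{\link{validate_dataset}} returns zero rows).
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return A \code{\link{survey_dataset}}.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(seed = 7))
#' nrow(ds$respondents)
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  r <- generate_respondents(cfg)
  r <- generate_cultivation_outcomes(r, cfg)
  u <- generate_use_reports(r, cfg)
  hash <- sum(as.integer(serialize(unclass(cfg)[order(names(cfg))],
                                   NULL, version = 2))) %% 999999937
  survey_dataset(r, u,
                 provenance = sprintf("synthetic; seed=%d; cfg_checksum=%d",
                                      cfg$seed, hash))
}
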