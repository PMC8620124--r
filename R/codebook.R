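#' Default codebook mapping free-text labels to canonical levels
#'
#' A codebook is a named list: one entry per field, each a named character
#' vector mapping observed spellings to canonical levels. Matching is
#' case-insensitive after trimming; canonical levels always map to
#' themselves. The default handles the accented group names (Sahouè, Wémé),
#' hyphen/space variants and capitalised category labels commonly found in
#' survey exports.
#'
#' @return A codebook list.
#' @export
#' @examples
#' cb <- default_codebook()
#' cb$category[["magico-spiritual"]]
default_codebook <- function() {
  list(
    group = c(
      "sahouè" = "Sahoue", "sahoue" = "Sahoue",
      "wémé" = "Weme", "weme" = "Weme", "wémè" = "Weme",
      "ga-adangbe" = "Ga-adangbe", "ga adangbe" = "Ga-adangbe"
    ),
    category = c(
      "magico-spiritual" = "magico_spiritual",
      "magico spiritual" = "magico_spiritual",
      "medicine" = "medicinal", "medicines" = "medicinal",
      "fuelwood" = "firewood"
    ),
    body_system = c(
      "endocrine, metabolic, and nutritional" = "endocrine_metabolic_nutritional",
      "general health and unspecified" = "general_health",
      "female genital system" = "female_genital",
      "male genital system" = "male_genital",
      "pregnancy and childbearing" = "pregnancy_childbearing"
    ),
    plant_part = c(
      "fruits" = "fruit", "leaves" = "leaf", "seeds" = "seed",
      "twigs" = "twig", "branches" = "twig", "roots" = "root",
      "flowers" = "flower"
    ),
    schooling = c(
      "no-schooling" = "none", ">bac" = "university", "bac+" = "university"
    ),
    activity = c("traditional healing" = "traditional_healing"),
    source_relation = c(
      "uncle" = "uncle_aunt", "aunt" = "uncle_aunt",
      "brother" = "sibling", "sister" = "sibling",
      "self" = "self_learning", "book" = "self_learning"
    )
  )
}

#' Read a codebook from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys are field names and
#'   whose values are maps from observed label to canonical level.
#' @return A codebook list.
#' @export
read_codebook <- function(path) {
  stopifnot(file.exists(path))
  cb <- yaml::read_yaml(path)
  lapply(cb, function(m) unlist(m))
}

## Normalize one character column against the canonical level set,
## consulting the codebook for non-canonical spellings.
normalize_labels <- function(x, field, levels, codebook) {
  x <- trimws(as.character(x))
  out <- x
  map <- codebook[[field]]
  low <- tolower(x)
  canon_low <- stats::setNames(levels, tolower(levels))
  hit <- low %in% names(canon_low)
  out[hit] <- canon_low[low[hit]]
  if (!is.null(map)) {
    names(map) <- tolower(names(map))
    m <- !hit & low %in% names(map)
    out[m] <- map[low[m]]
    hit <- hit | m
  }
  bad <- !hit & !is.na(x) & nzchar(x)
  if (any(bad)) {
    stop(sprintf("field '%s': unknown label(s) with no codebook mapping: %s",
                 field, paste(unique(x[bad]), collapse = ", ")),
         call. = FALSE)
  }
  out[!nzchar(x) | is.na(x)] <- NA_character_
  out
}
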