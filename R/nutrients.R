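#' Canonical nutrient names and units
#'
#' All nutrient bookkeeping in the package runs on canonical lower-case
#' snake_case names so that fixtures, user configuration files and
#' programmatic input interoperate. [canonical_nutrient()] maps common
#' spellings ("EPA+DHA", "DHA + EPA", "Vitamin B12", "omega-3", ...) onto the
#' canonical form; unknown names are passed through after normalisation so the
#' machinery extends to arbitrary nutrients.
#'
#' @param x character vector of nutrient names.
#' @return character vector of canonical names, same length as `x`.
#' @examples
#' canonical_nutrient(c("EPA+DHA", "Vitamin B12", "Omega-3", "selenium"))
#' @export
canonical_nutrient <- function(x) {
  stopifnot(is.character(x))
  key <- tolower(trimws(x))
  key <- gsub("µ|μ", "u", key)       # micro signs
  key <- gsub("[ +\\-]+", "_", key)
  key <- gsub("_+", "_", key)
  key <- gsub("^_|_$", "", key)
  hit <- match(key, names(.nutrient_aliases))
  out <- ifelse(is.na(hit), key, unname(.nutrient_aliases[hit]))
  as.character(out)
}

# alias -> canonical; keys are pre-normalised forms
.nutrient_aliases <- c(
  epa_dha        = "epa_dha",
  dha_epa        = "epa_dha",
  epadha         = "epa_dha",
  omega3         = "omega3",
  omega_3        = "omega3",
  omega3_total   = "omega3",
  n_3            = "omega3",
  n3             = "omega3",
  protein        = "protein",
  mufa           = "mufa",
  calcium        = "ca",
  ca             = "ca",
  iron           = "fe",
  fe             = "fe",
  riboflavin     = "riboflavin",
  vitamin_b2     = "riboflavin",
  folate         = "folate",
  folic_acid     = "folate",
  vitamin_b12    = "vitamin_b12",
  vit_b12        = "vitamin_b12",
  b12            = "vitamin_b12",
  selenium       = "se",
  se             = "se",
  zinc           = "zn",
  zn             = "zn",
  sodium         = "na",
  na             = "na",
  sfa            = "sfa",
  saturated_fat  = "sfa"
)

# recognised mass units and their factor to milligrams
.unit_to_mg <- c(g = 1000, mg = 1, ug = 0.001)

#' Normalise a mass unit label
#'
#' Accepts "g", "mg", "ug" plus the micro-sign and "mcg" spellings.
#' @param unit character vector of unit labels.
#' @return character vector drawn from `c("g", "mg", "ug")`.
#' @keywords internal
normalize_unit <- function(unit) {
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)
  u[u == "mcg"] <- "ug"
  bad <- !(u %in% names(.unit_to_mg))
  if (any(bad)) {
    stop("unrecognised mass unit(s): ", paste(unique(unit[bad]), collapse = ", "),
         call. = FALSE)
  }
  u
}

#' Convert a per-100 g content between mass units
#'
#' @param value numeric contents.
#' @param from,to unit labels understood by [normalize_unit()].
#' @return numeric vector of converted contents.
#' @keywords internal
convert_mass <- function(value, from, to) {
  value * .unit_to_mg[[normalize_unit(from)]] / .unit_to_mg[[normalize_unit(to)]]
}
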