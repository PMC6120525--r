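#' Percent of a daily reference intake delivered by a content
#'
#' The proportion, in percent, of a nutrient's daily reference intake covered
#' by its per-100 g content. Deliberately uncapped: a food may deliver more
#' than 100% of a reference in 100 g (beef supplies 133% of the vitamin B12
#' reference), and the index scores are only reproduced without a cap.
#'
#' @param content per-100 g quantity (same unit as `reference`); >= 0.
#' @param reference per-day reference quantity; > 0.
#' @return percent of reference per 100 g.
#' @examples
#' percent_reference(23.5, 50.25) # protein
#' @export
percent_reference <- function(content, reference) {
  content <- scalar_number(content, "content")
  reference <- scalar_number(reference, "reference")
  if (content < 0) stop("content must be non-negative", call. = FALSE)
  if (reference <= 0) stop("reference intake must be positive", call. = FALSE)
  100 * content / reference
}

# percent-of-reference terms for a set of nutrients, with unit reconciliation
percent_terms <- function(profile, nutrients, ref, spec_name) {
  missing_prof <- setdiff(nutrients, names(profile$contents))
  if (length(missing_prof) > 0L) {
    stop(sprintf("nutrient(s) %s required by spec '%s' missing from profile",
                 paste(missing_prof, collapse = ", "), spec_name), call. = FALSE)
  }
  missing_ref <- setdiff(nutrients, ref$nutrient)
  if (length(missing_ref) > 0L) {
    stop(sprintf("nutrient(s) %s required by spec '%s' missing from reference table",
                 paste(missing_ref, collapse = ", "), spec_name), call. = FALSE)
  }
  vapply(nutrients, function(nm) {
    content <- convert_mass(profile$contents[[nm]], profile$units[[nm]],
                            ref[nm, "unit"])
    percent_reference(content, ref[nm, "value"])
  }, numeric(1))
}

#' Nutrient-index score of a profile under one specification
#'
#' The score is the mean percent-of-reference over the qualifying nutrients,
#' minus the mean percent-of-reference over the disqualifying nutrients (zero
#' when that list is empty). Expressed as % RDI per 100 g: the share of a
#' day's recommended intake, averaged across the index nutrients and net of
#' penalty, that 100 g of the product delivers. Individual terms are not
#' capped at 100 and intermediate values are never rounded.
#'
#' @param profile a [nutrient_profile()].
#' @param spec an [index_spec()].
#' @param ref a [reference_intake_table()].
#' @return an `index_score` object with fields `value` and `spec_name`.
#' @examples
#' ref <- ukni_reference_intakes()
#' prof <- nutrient_profile(c(protein = 23.5), c(protein = "g"))
#' index_score(prof, index_spec("protein_only", "protein"), ref)
#' @export
index_score <- function(profile, spec, ref) {
  stopifnot(inherits(profile, "nutrient_profile"),
            inherits(spec, "index_spec"),
            inherits(ref, "reference_intake_table"))
  reward <- mean(percent_terms(profile, spec$qualifying, ref, spec$name))
  penalty <- if (length(spec$disqualifying) > 0L) {
    mean(percent_terms(profile, spec$disqualifying, ref, spec$name))
  } else 0
  structure(list(value = reward - penalty, spec_name = spec$name),
            class = "index_score")
}

#' @export
print.index_score <- function(x, ...) {
  cat(sprintf("<index_score> %s = %.4g %% RDI per 100 g\n", x$spec_name, x$value))
  invisible(x)
}

#' The four UKNI index specifications
#'
#' UKNIprot7 rewards seven nutrients typical of protein-rich foods (protein,
#' MUFA, EPA+DHA, calcium, iron, riboflavin, folate); UKNIprot10 adds vitamin
#' B12, selenium and zinc, micronutrients in which meat is particularly rich.
#' The "-2" variants additionally penalise the two limit nutrients, SFA and
#' sodium.
#'
#' @return named list of four [index_spec()] objects.
#' @export
build_ukni_specs <- function() {
  seven <- c("protein", "mufa", "epa_dha", "ca", "fe", "riboflavin", "folate")
  ten <- c(seven, "vitamin_b12", "se", "zn")
  limit <- c("sfa", "na")
  specs <- list(
    index_spec("UKNIprot7", seven),
    index_spec("UKNIprot7-2", seven, limit),
    index_spec("UKNIprot10", ten),
    index_spec("UKNIprot10-2", ten, limit)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Reference daily intakes used by the UKNI indices
#'
#' UK recommended daily intakes/allowances (female/male averages), with the
#' MUFA and EPA+DHA values adopted from the Finnish protein-food index family
#' where no UK-specific recommendation exists. Sodium and SFA carry their
#' maximum recommended amounts and are flagged `limited`.
#'
#' @return a [reference_intake_table()] of the 12 index nutrients.
#' @export
ukni_reference_intakes <- function() {
  reference_intake_table(
    nutrient = c("protein", "mufa", "epa_dha", "ca", "fe", "riboflavin",
                 "folate", "vitamin_b12", "se", "zn", "na", "sfa"),
    value = c(50.25, 37.5, 250, 700, 11.75, 1.2, 200, 1.5, 67.5, 8.25, 6, 25),
    unit = c("g", "g", "mg", "mg", "mg", "mg", "ug", "ug", "ug", "mg", "g", "g"),
    role = c(rep("encouraged", 10), "limited", "limited")
  )
}
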