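#' Define a functional unit
#'
#' Three kinds are supported: `"mass_meat"` (kg CO2-eq per kg edible meat),
#' `"nutrient_mass"` (kg CO2-eq per gram of a named nutrient) and
#' `"index_point"` (kg CO2-eq per 1 % RDI of a named index specification).
#'
#' @param kind one of `"mass_meat"`, `"nutrient_mass"`, `"index_point"`.
#' @param nutrient nutrient name, required for `nutrient_mass`.
#' @param spec index-spec name, required for `index_point`.
#' @return a `functional_unit` object.
#' @examples
#' functional_unit("nutrient_mass", nutrient = "omega3")
#' functional_unit("index_point", spec = "UKNIprot10-2")
#' @export
functional_unit <- function(kind, nutrient = NULL, spec = NULL) {
  kind <- match.arg(kind, c("mass_meat", "nutrient_mass", "index_point"))
  if (kind == "nutrient_mass") {
    if (is.null(nutrient)) stop("nutrient_mass unit needs a nutrient name", call. = FALSE)
    nutrient <- canonical_nutrient(nutrient)
  }
  if (kind == "index_point" && is.null(spec)) {
    stop("index_point unit needs an index-spec name", call. = FALSE)
  }
  structure(list(kind = kind, nutrient = nutrient, spec = spec),
            class = "functional_unit")
}

#' @export
print.functional_unit <- function(x, ...) {
  cat("<functional_unit>", fu_label(x), "\n")
  invisible(x)
}

#' Display label of a functional unit
#' @param fu a `functional_unit`.
#' @return single string, e.g. `"nutrient_mass:omega3"`.
#' @export
fu_label <- function(fu) {
  switch(fu$kind,
         mass_meat = "mass_meat",
         nutrient_mass = paste0("nutrient_mass:", fu$nutrient),
         index_point = paste0("index_point:", fu$spec))
}

#' Emission burden per gram of a nutrient
#'
#' Divides an edible-meat-basis emission intensity by the grams of nutrient
#' contained in one kilogram of meat. A content of `c` mg per 100 g is
#' `c / 100` g per kg, so the burden is `e / (content / 100)`.
#'
#' @param e_meat an [emission_intensity()] with basis `edible_meat`.
#' @param content_mg_per_100g nutrient content, mg per 100 g meat; > 0.
#' @return kg CO2-eq per gram of nutrient.
#' @examples
#' gwp_per_nutrient_mass(emission_intensity(4.4, "edible_meat"), 362)
#' @export
gwp_per_nutrient_mass <- function(e_meat, content_mg_per_100g) {
  stopifnot(inherits(e_meat, "emission_intensity"))
  if (e_meat$basis != "edible_meat") {
    stop("emission intensity must be on the edible_meat basis; rebase first",
         call. = FALSE)
  }
  content <- scalar_number(content_mg_per_100g, "nutrient content")
  if (content <= 0) {
    stop("nutrient content is zero; burden per gram is undefined for this system",
         call. = FALSE)
  }
  e_meat$value / (content / 100)
}

#' Emission burden per index point (1 % RDI)
#'
#' The index score is the % RDI delivered by 100 g of meat, so the burden of
#' one index point is the GWP of 100 g of meat divided by the score:
#' `(e / 10) / score`.
#'
#' @param e_meat an [emission_intensity()] with basis `edible_meat`.
#' @param score an [index_score()] with positive value.
#' @return kg CO2-eq per 1 % RDI.
#' @export
gwp_per_index_point <- function(e_meat, score) {
  stopifnot(inherits(e_meat, "emission_intensity"), inherits(score, "index_score"))
  if (e_meat$basis != "edible_meat") {
    stop("emission intensity must be on the edible_meat basis; rebase first",
         call. = FALSE)
  }
  if (!is.finite(score$value) || score$value <= 0) {
    stop("index score must be positive to serve as a functional unit", call. = FALSE)
  }
  (e_meat$value / 10) / score$value
}

#' Evaluate and rank systems under a functional unit
#'
#' Rebases every system to the edible-meat basis, expresses its burden under
#' the requested functional unit and ranks ascending (rank 1 = lowest
#' burden). Ties share the lower rank, with deterministic ordering by system
#' label. Systems for which the functional unit is undefined (zero nutrient
#' content, non-positive index score) are excluded with a warning rather
#' than assigned an infinite burden.
#'
#' @param systems list of `production_system` objects.
#' @param fu a [functional_unit()].
#' @param ref a [reference_intake_table()]; needed for `index_point`.
#' @param specs named list of [index_spec()] objects; needed for `index_point`.
#' @return data frame with columns `species`, `system`, `label`,
#'   `functional_unit`, `value`, `rank`, ordered by rank.
#' @examples
#' fx <- load_paper_fixtures()
#' evaluate_systems(fx$systems, functional_unit("mass_meat"))
#' @export
evaluate_systems <- function(systems, fu, ref = ukni_reference_intakes(),
                             specs = build_ukni_specs()) {
  stopifnot(is.list(systems), length(systems) >= 1L, inherits(fu, "functional_unit"))
  for (s in systems) stopifnot(inherits(s, "production_system"))
  labels <- vapply(systems, system_label, character(1))
  if (anyDuplicated(labels)) {
    stop("species+system labels must be unique within a study set", call. = FALSE)
  }
  if (fu$kind == "index_point") {
    if (!fu$spec %in% names(specs)) {
      stop("unknown index spec in functional unit: ", fu$spec, call. = FALSE)
    }
    spec <- specs[[fu$spec]]
  }
  values <- rep(NA_real_, length(systems))
  for (i in seq_along(systems)) {
    e_meat <- rebase_to_meat(systems[[i]])$emissions
    values[i] <- switch(fu$kind,
      mass_meat = e_meat$value,
      nutrient_mass = {
        prof <- systems[[i]]$nutrients
        if (!fu$nutrient %in% names(prof$contents)) {
          stop(sprintf("nutrient '%s' not present in system '%s'",
                       fu$nutrient, labels[i]), call. = FALSE)
        }
        content_mg <- convert_mass(prof$contents[[fu$nutrient]],
                                   prof$units[[fu$nutrient]], "mg")
        if (content_mg <= 0) NA_real_ else gwp_per_nutrient_mass(e_meat, content_mg)
      },
      index_point = {
        sc <- index_score(systems[[i]]$nutrients, spec, ref)
        if (sc$value <= 0) NA_real_ else gwp_per_index_point(e_meat, sc)
      })
  }
  dropped <- is.na(values)
  if (any(dropped)) {
    warning("excluded from ranking (functional unit undefined): ",
            paste(labels[dropped], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    species = vapply(systems, `[[`, character(1), "species")[!dropped],
    system = vapply(systems, `[[`, character(1), "system")[!dropped],
    label = labels[!dropped],
    functional_unit = fu_label(fu),
    value = values[!dropped],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$value, out$label), , drop = FALSE]
  out$rank <- rank(out$value, ties.method = "min")
  rownames(out) <- NULL
  out
}
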