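#' Mass reference bases of the conversion chain
#'
#' An emission intensity only has meaning relative to an explicit reference
#' mass. The chain runs liveweight -> carcass -> edible_meat: one kilogram of
#' liveweight dresses out to `kill_out_fraction` kilograms of carcass, of
#' which `meat_per_carcass_fraction` is edible deboned meat.
#'
#' @format character vector of the three basis labels, in chain order.
#' @export
MASS_BASES <- c("liveweight", "carcass", "edible_meat")

assert_basis <- function(basis) {
  if (!(is.character(basis) && length(basis) == 1L && basis %in% MASS_BASES)) {
    stop("mass basis must be one of: ", paste(MASS_BASES, collapse = ", "),
         call. = FALSE)
  }
  basis
}

scalar_number <- function(x, what) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x))) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  as.numeric(x)
}

#' Emission intensity tied to a mass basis
#'
#' A global warming potential (kg CO2-eq) per kilogram of an explicit
#' reference mass. A bare number is never accepted anywhere in the package:
#' the basis travels with the value so that rebasing is always well defined.
#'
#' @param value kg CO2-eq per kg of reference mass; non-negative.
#' @param basis one of `"liveweight"`, `"carcass"`, `"edible_meat"`.
#' @return an `emission_intensity` object.
#' @examples
#' emission_intensity(10.9, "liveweight")
#' @seealso [rebase_emissions()]
#' @export
emission_intensity <- function(value, basis) {
  value <- scalar_number(value, "emission intensity value")
  if (value < 0) stop("emission intensity must be non-negative", call. = FALSE)
  structure(list(value = value, basis = assert_basis(basis)),
            class = "emission_intensity")
}

#' @export
print.emission_intensity <- function(x, ...) {
  cat(sprintf("<emission_intensity> %.4g kg CO2-eq/kg %s\n", x$value, x$basis))
  invisible(x)
}

#' Carcass coefficients for one animal type
#'
#' @param kill_out_fraction kg carcass per kg liveweight, in (0, 1].
#' @param meat_per_carcass_fraction kg edible meat per kg carcass, in (0, 1].
#' @return a `carcass_coefficients` object.
#' @examples
#' carcass_coefficients(0.474, 0.88) # lamb
#' @export
carcass_coefficients <- function(kill_out_fraction, meat_per_carcass_fraction) {
  k <- scalar_number(kill_out_fraction, "kill_out_fraction")
  m <- scalar_number(meat_per_carcass_fraction, "meat_per_carcass_fraction")
  if (k <= 0 || k > 1) stop("kill_out_fraction must lie in (0, 1]", call. = FALSE)
  if (m <= 0 || m > 1) stop("meat_per_carcass_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(kill_out_fraction = k, meat_per_carcass_fraction = m),
            class = "carcass_coefficients")
}

#' Identity carcass coefficients
#'
#' Used when an emission intensity is already expressed per kg edible meat and
#' the chain must stay uniform across systems.
#' @return a `carcass_coefficients` object with both fractions equal to 1.
#' @export
identity_coefficients <- function() carcass_coefficients(1, 1)

#' Fatty-acid summary of a meat product
#'
#' Total omega-3 and the EPA+DHA subgroup per 100 g of edible meat, plus the
#' (descriptive) omega-6:omega-3 mass ratio. EPA and DHA are a subgroup of
#' omega-3, so `epa_dha <= omega3_total` always.
#'
#' @param omega3_total mg per 100 g meat.
#' @param epa_dha mg per 100 g meat; at most `omega3_total`.
#' @param omega6_omega3_ratio optional positive dimensionless ratio.
#' @return a `fatty_acid_summary` object.
#' @export
fatty_acid_summary <- function(omega3_total, epa_dha, omega6_omega3_ratio = NULL) {
  o3 <- scalar_number(omega3_total, "omega3_total")
  ed <- scalar_number(epa_dha, "epa_dha")
  if (o3 < 0 || ed < 0) stop("fatty-acid contents must be non-negative", call. = FALSE)
  if (ed > o3) stop("epa_dha cannot exceed omega3_total", call. = FALSE)
  if (!is.null(omega6_omega3_ratio)) {
    omega6_omega3_ratio <- scalar_number(omega6_omega3_ratio, "omega6_omega3_ratio")
    if (omega6_omega3_ratio <= 0) stop("omega6_omega3_ratio must be positive", call. = FALSE)
  }
  structure(list(omega3_total = o3, epa_dha = ed,
                 omega6_omega3_ratio = omega6_omega3_ratio),
            class = "fatty_acid_summary")
}

#' Nutrient profile of a meat product (per 100 g)
#'
#' A mapping from canonical nutrient name to content per 100 g edible meat,
#' with a per-nutrient unit. Zero is a legal content (some poultry products
#' contain no vitamin B12). Names are canonicalised on construction.
#'
#' @param contents named numeric vector of per-100 g contents.
#' @param units named character vector of mass units (`g`, `mg`, `ug`)
#'   parallel to `contents`.
#' @return a `nutrient_profile` object.
#' @examples
#' nutrient_profile(c(protein = 23.5, "EPA+DHA" = 3.4),
#'                  c(protein = "g", "EPA+DHA" = "mg"))
#' @export
nutrient_profile <- function(contents, units) {
  if (!is.numeric(contents) || is.null(names(contents))) {
    stop("contents must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(contents)) || any(contents < 0)) {
    stop("nutrient contents must be finite and non-negative", call. = FALSE)
  }
  nm <- canonical_nutrient(names(contents))
  if (anyDuplicated(nm)) {
    stop("duplicate nutrient names after canonicalisation: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(units))) names(units) <- names(contents)
  units <- vapply(units, normalize_unit, character(1))
  names(units) <- canonical_nutrient(names(units))
  if (!setequal(names(units), nm)) {
    stop("units must be supplied for exactly the nutrients in contents", call. = FALSE)
  }
  contents <- as.numeric(contents)
  names(contents) <- nm
  structure(list(contents = contents, units = units[nm]),
            class = "nutrient_profile")
}

#' Daily reference intakes (RDI/RDA) with nutrient roles
#'
#' Per-nutrient recommended daily intakes, with each nutrient flagged as
#' `encouraged` (contributes to the qualifying mean of an index) or `limited`
#' (a nutrient to be discouraged, eligible for the penalty term). Limit
#' nutrients carry their maximum recommended daily amount in the same column;
#' the role only routes them to the penalty term of an index.
#'
#' @param nutrient character vector of nutrient names.
#' @param value positive per-day reference quantities.
#' @param unit per-nutrient mass units (`g`, `mg`, `ug`).
#' @param role `"encouraged"` or `"limited"` per nutrient.
#' @return a `reference_intake_table`: a data frame with canonical rownames.
#' @export
reference_intake_table <- function(nutrient, value, unit, role) {
  stopifnot(length(nutrient) == length(value),
            length(nutrient) == length(unit),
            length(nutrient) == length(role))
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("reference intakes must be positive", call. = FALSE)
  }
  if (!all(role %in% c("encouraged", "limited"))) {
    stop("role must be 'encouraged' or 'limited'", call. = FALSE)
  }
  nm <- canonical_nutrient(nutrient)
  if (anyDuplicated(nm)) stop("duplicate nutrients in reference table", call. = FALSE)
  out <- data.frame(nutrient = nm, value = as.numeric(value),
                    unit = vapply(unit, normalize_unit, character(1)),
                    role = role, row.names = nm)
  class(out) <- c("reference_intake_table", "data.frame")
  out
}

#' Index specification (UKNI-style)
#'
#' Names the qualifying (rewarded) nutrients and the possibly empty set of
#' disqualifying (penalty) nutrients that define one nutrient-index variant.
#'
#' @param name identifier, e.g. `"UKNIprot7"`.
#' @param qualifying non-empty character vector of nutrient names.
#' @param disqualifying character vector of nutrient names, may be empty;
#'   must be disjoint from `qualifying`.
#' @return an `index_spec` object.
#' @seealso [build_ukni_specs()], [index_score()]
#' @export
index_spec <- function(name, qualifying, disqualifying = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  q <- canonical_nutrient(as.character(qualifying))
  d <- canonical_nutrient(as.character(disqualifying))
  if (length(q) == 0L) stop("qualifying nutrient list must be non-empty", call. = FALSE)
  if (anyDuplicated(q) || anyDuplicated(d)) {
    stop("nutrient lists must not contain duplicates", call. = FALSE)
  }
  if (length(intersect(q, d)) > 0L) {
    stop("qualifying and disqualifying lists must be disjoint: ",
         paste(intersect(q, d), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, qualifying = q, disqualifying = d),
            class = "index_spec")
}

#' A livestock production system under study
#'
#' Bundles the emission intensity (with its mass basis), the carcass
#' coefficients needed to rebase it to edible meat, the fatty-acid summary
#' and the full nutrient profile for one species x system treatment. The
#' fatty-acid summary is mirrored into the nutrient namespace (`omega3`,
#' `epa_dha`, mg per 100 g) so that any stored nutrient can serve as a
#' functional unit through one uniform mechanism.
#'
#' @param species one of `"beef"`, `"lamb"`, `"chicken"`, `"pork"`, `"other"`.
#' @param system free-text system label (e.g. `"forage"`, `"lowland"`).
#' @param emissions an [emission_intensity()].
#' @param coefficients a [carcass_coefficients()]; identity when the
#'   emissions basis is already edible meat.
#' @param fatty_acids a [fatty_acid_summary()].
#' @param nutrients a [nutrient_profile()].
#' @return a `production_system` object.
#' @export
production_system <- function(species, system, emissions, coefficients,
                              fatty_acids, nutrients) {
  stopifnot(is.character(species), length(species) == 1L,
            is.character(system), length(system) == 1L, nzchar(system))
  if (!species %in% c("beef", "lamb", "chicken", "pork", "other")) {
    stop("species must be beef, lamb, chicken, pork or other", call. = FALSE)
  }
  stopifnot(inherits(emissions, "emission_intensity"),
            inherits(coefficients, "carcass_coefficients"),
            inherits(fatty_acids, "fatty_acid_summary"),
            inherits(nutrients, "nutrient_profile"))
  # mirror fatty acids into the nutrient namespace (mg per 100 g)
  contents <- nutrients$contents
  units <- nutrients$units
  for (nm in c("omega3", "epa_dha")) {
    val <- if (nm == "omega3") fatty_acids$omega3_total else fatty_acids$epa_dha
    if (!nm %in% names(contents)) {
      contents[[nm]] <- val
      units[[nm]] <- "mg"
    }
  }
  nutrients <- nutrient_profile(contents, units)
  structure(list(species = species, system = system, emissions = emissions,
                 coefficients = coefficients, fatty_acids = fatty_acids,
                 nutrients = nutrients),
            class = "production_system")
}

#' @export
print.production_system <- function(x, ...) {
  cat(sprintf("<production_system> %s / %s: %.4g kg CO2-eq/kg %s; omega-3 %.4g, EPA+DHA %.4g mg/100 g; %d nutrients\n",
              x$species, x$system, x$emissions$value, x$emissions$basis,
              x$fatty_acids$omega3_total, x$fatty_acids$epa_dha,
              length(x$nutrients$contents)))
  invisible(x)
}

#' Display label of a production system
#' @param sys a `production_system`.
#' @return single string `"species system"`.
#' @export
system_label <- function(sys) paste(sys$species, sys$system)

#' Validate a production system and its components
#'
#' Re-runs every constructor invariant; useful for systems deserialised from
#' files or produced by the synthetic generator.
#'
#' @param sys a `production_system`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_system <- function(sys) {
  stopifnot(inherits(sys, "production_system"))
  emission_intensity(sys$emissions$value, sys$emissions$basis)
  carcass_coefficients(sys$coefficients$kill_out_fraction,
                       sys$coefficients$meat_per_carcass_fraction)
  fatty_acid_summary(sys$fatty_acids$omega3_total, sys$fatty_acids$epa_dha,
                     sys$fatty_acids$omega6_omega3_ratio)
  nutrient_profile(sys$nutrients$contents, sys$nutrients$units)
  invisible(TRUE)
}
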