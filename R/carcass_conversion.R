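#' Mass fraction between two reference bases
#'
#' Kilograms of `to_basis` mass obtained per kilogram of `from_basis` mass
#' under the given carcass coefficients. Along the chain one kg of liveweight
#' yields `kill_out_fraction` kg carcass, and one kg of carcass yields
#' `meat_per_carcass_fraction` kg edible meat; fractions compose by
#' multiplication, reversing direction takes the reciprocal, and identical
#' bases give exactly 1.
#'
#' @param from_basis,to_basis mass basis labels (see [MASS_BASES]).
#' @param coeff a [carcass_coefficients()].
#' @return dimensionless fraction (kg `to_basis` per kg `from_basis`).
#' @examples
#' mass_fraction("liveweight", "edible_meat", carcass_coefficients(0.474, 0.88))
#' @export
mass_fraction <- function(from_basis, to_basis, coeff) {
  assert_basis(from_basis)
  assert_basis(to_basis)
  stopifnot(inherits(coeff, "carcass_coefficients"))
  # mass remaining at each stage per kg liveweight
  stage <- c(liveweight = 1,
             carcass = coeff$kill_out_fraction,
             edible_meat = coeff$kill_out_fraction * coeff$meat_per_carcass_fraction)
  if (from_basis == to_basis) return(1)
  unname(stage[[to_basis]] / stage[[from_basis]])
}

#' Rebase an emission intensity onto another mass basis
#'
#' The total burden of the animal is conserved: moving the denominator from a
#' larger mass (liveweight) to a smaller one (edible meat) divides by the
#' mass fraction between the bases, so the per-kg intensity rises. Rebasing
#' to the current basis is the identity, and rebasing there and back recovers
#' the input to floating tolerance.
#'
#' @param e an [emission_intensity()].
#' @param target basis to express the intensity on.
#' @param coeff a [carcass_coefficients()].
#' @return an [emission_intensity()] on `target` basis.
#' @examples
#' e <- emission_intensity(10.9, "liveweight")
#' rebase_emissions(e, "edible_meat", carcass_coefficients(0.474, 0.88))
#' @export
rebase_emissions <- function(e, target, coeff) {
  stopifnot(inherits(e, "emission_intensity"))
  assert_basis(target)
  frac <- mass_fraction(e$basis, target, coeff)
  if (frac == 0) stop("mass fraction is zero; cannot rebase", call. = FALSE)
  emission_intensity(e$value / frac, target)
}

#' Rebase a production system's emissions to edible meat
#'
#' @param sys a `production_system`.
#' @return the system with `emissions` expressed per kg edible meat.
#' @export
rebase_to_meat <- function(sys) {
  stopifnot(inherits(sys, "production_system"))
  sys$emissions <- rebase_emissions(sys$emissions, "edible_meat", sys$coefficients)
  sys
}
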