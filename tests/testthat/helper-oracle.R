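# Independent brute-force oracle for index scores: a direct sum-of-terms
# evaluation that shares no code with index_score(). Contents and references
# must already be expressed in the same unit per nutrient.
oracle_score <- function(contents, refs, qualifying, disqualifying = character()) {
  total_q <- 0
  for (nm in qualifying) total_q <- total_q + 100 * contents[[nm]] / refs[[nm]]
  s <- total_q / length(qualifying)
  if (length(disqualifying) > 0) {
    total_d <- 0
    for (nm in disqualifying) total_d <- total_d + 100 * contents[[nm]] / refs[[nm]]
    s <- s - total_d / length(disqualifying)
  }
  s
}

# reference values keyed by canonical name, in the table's own units
ref_values <- function(ref) stats::setNames(ref$value, ref$nutrient)

# contents of a profile converted into the reference table's units
contents_in_ref_units <- function(profile, ref) {
  sapply(intersect(names(profile$contents), ref$nutrient), function(nm) {
    nutrifu:::convert_mass(profile$contents[[nm]], profile$units[[nm]],
                           ref[nm, "unit"])
  })
}

# a small random profile/reference pair over ad-hoc nutrient names
random_profile_case <- function(n_nutrients = 8) {
  nm <- paste0("nutr", seq_len(n_nutrients))
  units <- sample(c("g", "mg", "ug"), n_nutrients, replace = TRUE)
  contents <- stats::runif(n_nutrients, 0, 50)
  names(contents) <- nm
  names(units) <- nm
  refs <- stats::runif(n_nutrients, 1, 200)
  list(profile = nutrient_profile(contents, units),
       ref = reference_intake_table(nm, refs, units, rep("encouraged", n_nutrients)),
       names = nm)
}

# seven study systems with the published (rounded, mass-basis) GWP values as
# their emission intensities, for reproducing the published per-index-point
# rankings
published_basis_systems <- function() {
  fx <- load_paper_fixtures()
  pub <- load_published_gwp()
  lapply(fx$systems, function(s) {
    i <- which(pub$species == s$species & pub$system == s$system)
    production_system(s$species, s$system,
                      emission_intensity(pub$gwp_mass_basis[i], "edible_meat"),
                      identity_coefficients(), s$fatty_acids, s$nutrients)
  })
}
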