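# Default per-nutrient draw ranges: the span of each nutrient across the
# seven study compositions, widened by 50% on each side and clipped at zero,
# so that synthetic index scores land in a realistic band (roughly 5-35%
# RDI). Units as in the reference table (per 100 g).
.synthetic_nutrient_ranges <- local({
  span <- function(lo, hi) {
    w <- 0.5 * (hi - lo)
    c(max(0, lo - w), hi + w)
  }
  list(
    protein     = list(range = span(18.6, 26.3),   unit = "g"),
    mufa        = list(range = span(0.9, 5.4),     unit = "g"),
    ca          = list(range = span(5, 12),        unit = "mg"),
    fe          = list(range = span(0.4, 1.6),     unit = "mg"),
    riboflavin  = list(range = span(0.15, 0.26),   unit = "mg"),
    folate      = list(range = span(1, 16),        unit = "ug"),
    vitamin_b12 = list(range = span(0, 2),         unit = "ug"),
    se          = list(range = span(3, 15),        unit = "ug"),
    zn          = list(range = span(1.3, 4),       unit = "mg"),
    na          = list(range = span(0.053, 0.08),  unit = "g"),
    sfa         = list(range = span(0.9, 3.7),     unit = "g")
  )
})

#' Configuration for the synthetic study generator
#'
#' Bounds are uniform-draw ranges. EPA+DHA is drawn as a fraction of total
#' omega-3 so the subgroup constraint holds by construction; the per-nutrient
#' ranges default to the study compositions' spans widened by 50%.
#'
#' @param seed integer seed; together with the system index it fully
#'   determines each generated system.
#' @param n_systems number of systems in the study (>= 1).
#' @param gwp,kill_out,meat_per_carcass,omega3,epa_dha_fraction length-2
#'   numeric `(low, high)` ranges.
#' @param nutrient_ranges named list of `list(range = c(low, high), unit =)`
#'   entries; defaults to the built-in study-anchored ranges.
#' @return a `generator_config` object.
#' @export
generator_config <- function(seed = 1L, n_systems = 7L,
                             gwp = c(1, 40),
                             kill_out = c(0.4, 0.8),
                             meat_per_carcass = c(0.5, 0.95),
                             omega3 = c(10, 500),
                             epa_dha_fraction = c(0.05, 0.5),
                             nutrient_ranges = .synthetic_nutrient_ranges) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(n_systems), length(n_systems) == 1L, n_systems >= 1)
  check_range <- function(r, what) {
    if (!(is.numeric(r) && length(r) == 2L && r[1] < r[2])) {
      stop(what, " must be a (low, high) pair with low < high", call. = FALSE)
    }
    r
  }
  check_range(gwp, "gwp"); check_range(kill_out, "kill_out")
  check_range(meat_per_carcass, "meat_per_carcass")
  check_range(omega3, "omega3"); check_range(epa_dha_fraction, "epa_dha_fraction")
  for (nm in names(nutrient_ranges)) check_range(nutrient_ranges[[nm]]$range, nm)
  structure(list(seed = as.integer(seed), n_systems = as.integer(n_systems),
                 gwp = gwp, kill_out = kill_out,
                 meat_per_carcass = meat_per_carcass, omega3 = omega3,
                 epa_dha_fraction = epa_dha_fraction,
                 nutrient_ranges = nutrient_ranges),
            class = "generator_config")
}

# Run code under a private RNG stream keyed by (seed, index), restoring the
# caller's RNG state afterwards. Insertion or removal of systems therefore
# never perturbs the others.
with_system_stream <- function(seed, index, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) * 10007 + as.numeric(index)) %% (2^31 - 1))
  force(code)
}

#' Generate one synthetic production system
#'
#' Deterministic given `(config$seed, index)`: every field is drawn from its
#' configured range under a private random stream, the emissions basis is
#' drawn uniformly from the three mass bases, and EPA+DHA is a drawn
#' fraction of total omega-3 so every type invariant holds by construction.
#'
#' @param config a [generator_config()].
#' @param index zero-based system index, `< config$n_systems`.
#' @return a `production_system`.
#' @export
generate_system <- function(config, index) {
  stopifnot(inherits(config, "generator_config"),
            index >= 0, index < config$n_systems)
  with_system_stream(config$seed, index, {
    runif2 <- function(r) stats::runif(1, r[1], r[2])
    species <- sample(c("beef", "lamb", "chicken", "pork"), 1)
    basis <- sample(MASS_BASES, 1)
    omega3 <- runif2(config$omega3)
    epa_dha <- omega3 * runif2(config$epa_dha_fraction)
    contents <- vapply(config$nutrient_ranges,
                       function(x) runif2(x$range), numeric(1))
    units <- vapply(config$nutrient_ranges, `[[`, character(1), "unit")
    names(units) <- names(contents)
    production_system(
      species = species,
      system = sprintf("synthetic-%03d", index),
      emissions = emission_intensity(runif2(config$gwp), basis),
      coefficients = carcass_coefficients(runif2(config$kill_out),
                                          runif2(config$meat_per_carcass)),
      fatty_acids = fatty_acid_summary(omega3, epa_dha),
      nutrients = nutrient_profile(contents, units))
  })
}

#' Generate a full synthetic study
#'
#' @param config a [generator_config()].
#' @return list with `systems` (length `config$n_systems`, unique
#'   species+system labels by construction) and `reference` (the standard
#'   reference-intake table, which covers every generated nutrient).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  systems <- lapply(seq_len(config$n_systems) - 1L,
                    function(i) generate_system(config, i))
  ref <- ukni_reference_intakes()
  generated <- unique(unlist(lapply(systems, function(s) names(s$nutrients$contents))))
  missing <- setdiff(generated, ref$nutrient)
  if (length(missing) > 0L) {
    # nominal references for nutrients outside the standard table; total
    # omega-3 gets the UK long-chain omega-3 guideline of 450 mg/day
    vals <- ifelse(missing == "omega3", 450, 100)
    extra <- reference_intake_table(missing, vals,
                                    rep("mg", length(missing)),
                                    rep("encouraged", length(missing)))
    ref <- rbind(ref, extra)
    class(ref) <- c("reference_intake_table", "data.frame")
  }
  list(systems = systems, reference = ref)
}
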