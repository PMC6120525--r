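# File formats: systems and nutrient compositions as CSV with units embedded
# in the column headers ("<nutrient>_<unit>_per_100g"), reference intakes as
# CSV (nutrient, value, unit, role), index specifications as YAML. Numeric
# columns are written with 17 significant digits so that write -> read is the
# identity on doubles.

data_error <- function(file, msg) {
  stop(errorCondition(sprintf("%s: %s", file, msg),
                      class = c("nutrifu_data_error", "error")))
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) data_error(path, "file not found")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#"),
                 error = function(e) data_error(path, conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    data_error(path, paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  df
}

format_full <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else x
}

write_csv_full <- function(df, path) {
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_per100g_header <- function(nm) {
  m <- regmatches(nm, regexec("^(.*)_(g|mg|ug)_per_100g$", nm))[[1]]
  if (length(m) == 0L) return(NULL)
  list(nutrient = m[2], unit = m[3])
}

#' Read production systems from CSV files
#'
#' `systems_file` holds one row per system (species, system, GWP value and
#' basis, carcass coefficients, fatty-acid summary); `nutrients_file` holds
#' the per-100 g composition with units embedded in the headers, e.g.
#' `protein_g_per_100g`. The two are joined on species + system.
#'
#' @param systems_file,nutrients_file paths to the two CSVs.
#' @return list of `production_system` objects.
#' @seealso [write_systems()], [load_paper_fixtures()]
#' @export
read_systems <- function(systems_file, nutrients_file) {
  sy <- read_csv_checked(systems_file,
    c("species", "system", "gwp_value", "gwp_basis", "kill_out_fraction",
      "meat_per_carcass_fraction", "omega3_mg_per_100g", "epa_dha_mg_per_100g"))
  nu <- read_csv_checked(nutrients_file, c("species", "system"))
  nutr_cols <- Filter(Negate(is.null), lapply(names(nu), parse_per100g_header))
  col_names <- names(nu)[!vapply(lapply(names(nu), parse_per100g_header), is.null, logical(1))]
  if (length(nutr_cols) == 0L) {
    data_error(nutrients_file, "no '<nutrient>_<unit>_per_100g' columns found")
  }
  lapply(seq_len(nrow(sy)), function(i) {
    row <- sy[i, ]
    j <- which(nu$species == row$species & nu$system == row$system)
    if (length(j) != 1L) {
      data_error(nutrients_file,
                 sprintf("expected exactly one composition row for '%s %s', found %d",
                         row$species, row$system, length(j)))
    }
    contents <- vapply(col_names, function(cn) as.numeric(nu[j, cn]), numeric(1))
    names(contents) <- vapply(nutr_cols, `[[`, character(1), "nutrient")
    units <- vapply(nutr_cols, `[[`, character(1), "unit")
    names(units) <- names(contents)
    ratio <- if ("omega6_omega3_ratio" %in% names(row) && is.finite(row$omega6_omega3_ratio)) {
      row$omega6_omega3_ratio
    } else NULL
    tryCatch(
      production_system(
        species = row$species, system = row$system,
        emissions = emission_intensity(row$gwp_value, row$gwp_basis),
        coefficients = carcass_coefficients(row$kill_out_fraction,
                                            row$meat_per_carcass_fraction),
        fatty_acids = fatty_acid_summary(row$omega3_mg_per_100g,
                                         row$epa_dha_mg_per_100g, ratio),
        nutrients = nutrient_profile(contents, units)),
      error = function(e) data_error(systems_file,
        sprintf("row %d (%s %s): %s", i, row$species, row$system,
                conditionMessage(e))))
  })
}

#' Write production systems to the CSV schemas [read_systems()] reads
#'
#' @param systems list of `production_system` objects.
#' @param systems_file,nutrients_file destination paths.
#' @return invisibly, the two paths.
#' @export
write_systems <- function(systems, systems_file, nutrients_file) {
  sy <- do.call(rbind, lapply(systems, function(s) {
    data.frame(species = s$species, system = s$system,
               gwp_value = s$emissions$value, gwp_basis = s$emissions$basis,
               kill_out_fraction = s$coefficients$kill_out_fraction,
               meat_per_carcass_fraction = s$coefficients$meat_per_carcass_fraction,
               omega3_mg_per_100g = s$fatty_acids$omega3_total,
               epa_dha_mg_per_100g = s$fatty_acids$epa_dha,
               omega6_omega3_ratio = ifelse(is.null(s$fatty_acids$omega6_omega3_ratio),
                                            NA_real_, s$fatty_acids$omega6_omega3_ratio),
               stringsAsFactors = FALSE)
  }))
  write_csv_full(sy, systems_file)
  # union of nutrients across systems, in first-seen order
  all_nutrients <- unique(unlist(lapply(systems, function(s) names(s$nutrients$contents))))
  nu <- do.call(rbind, lapply(systems, function(s) {
    row <- data.frame(species = s$species, system = s$system,
                      stringsAsFactors = FALSE)
    for (nm in all_nutrients) {
      unit <- if (nm %in% names(s$nutrients$units)) s$nutrients$units[[nm]] else "mg"
      val <- if (nm %in% names(s$nutrients$contents)) s$nutrients$contents[[nm]] else 0
      row[[paste0(nm, "_", unit, "_per_100g")]] <- val
    }
    row
  }))
  write_csv_full(nu, nutrients_file)
  invisible(c(systems_file, nutrients_file))
}

#' Read a reference-intake table from CSV
#' @param path CSV with columns nutrient, value, unit, role.
#' @return a [reference_intake_table()].
#' @export
read_reference_intakes <- function(path) {
  df <- read_csv_checked(path, c("nutrient", "value", "unit", "role"))
  tryCatch(reference_intake_table(df$nutrient, df$value, df$unit, df$role),
           error = function(e) data_error(path, conditionMessage(e)))
}

#' Write a reference-intake table to CSV
#' @param ref a [reference_intake_table()].
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_reference_intakes <- function(ref, path) {
  write_csv_full(as.data.frame(ref)[c("nutrient", "value", "unit", "role")], path)
}

#' Read index specifications from YAML
#' @param path YAML file: a sequence of mappings with keys name, qualifying,
#'   disqualifying.
#' @return named list of [index_spec()] objects.
#' @export
read_index_specs <- function(path) {
  if (!file.exists(path)) data_error(path, "file not found")
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) data_error(path, conditionMessage(e)))
  specs <- lapply(raw, function(x) {
    if (is.null(x$name) || is.null(x$qualifying)) {
      data_error(path, "each spec needs 'name' and 'qualifying'")
    }
    tryCatch(index_spec(x$name, unlist(x$qualifying),
                        if (is.null(x$disqualifying)) character() else unlist(x$disqualifying)),
             error = function(e) data_error(path, sprintf("spec '%s': %s",
                                                          x$name, conditionMessage(e))))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) data_error(path, "spec names must be unique")
  specs
}

#' Write index specifications to YAML
#' @param specs list of [index_spec()] objects.
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_index_specs <- function(specs, path) {
  yaml::write_yaml(lapply(unname(specs), function(s) {
    list(name = s$name, qualifying = as.list(s$qualifying),
         disqualifying = as.list(s$disqualifying))
  }), path)
  invisible(path)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nutrifu")
  if (!nzchar(p)) data_error(file, "packaged fixture not found")
  p
}

#' Load the seven packaged study systems
#'
#' Returns the seven UK production systems of the case study — concentrate
#' and forage beef, lowland and upland lamb, intensive and free-range
#' chicken, and intensive pork — with their source-study GWP values (on
#' their original mass bases), carcass coefficients, fatty-acid summaries
#' and full nutrient compositions, together with the reference-intake table.
#' Chicken carries identity carcass coefficients because its GWP is already
#' per kg edible meat; for beef and pork, whose GWP basis is carcass weight,
#' the kill-out fraction is a placeholder (1.0) as the liveweight leg of the
#' chain is never exercised for them.
#'
#' @return list with elements `systems` (list of 7 `production_system`s),
#'   `reference` (a [reference_intake_table()]) and `specs` (the four UKNI
#'   [index_spec()]s read from the packaged YAML).
#' @export
load_paper_fixtures <- function() {
  systems <- read_systems(fixture_path("systems.csv"), fixture_path("nutrients.csv"))
  list(systems = systems,
       reference = read_reference_intakes(fixture_path("reference_intakes.csv")),
       specs = read_index_specs(fixture_path("ukni_specs.yaml")))
}

#' Published mass-basis GWP values of the seven study systems
#'
#' The mass-based emission intensities (kg CO2-eq per kg edible meat) as
#' reported, rounded to one decimal, by the source analysis. These are the
#' inputs that analysis fed into its per-index-point comparisons. Note the
#' concentrate-beef entry (9.8) is not consistent with its own inputs
#' (7.9 kg CO2-eq/kg carcass at 0.87 kg meat/kg carcass gives 9.08); the
#' value is reproduced here as published, not recomputed.
#'
#' @return data frame with columns `species`, `system`, `gwp_mass_basis`.
#' @export
load_published_gwp <- function() {
  read_csv_checked(fixture_path("published_gwp_mass_basis.csv"),
                   c("species", "system", "gwp_mass_basis"))
}
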