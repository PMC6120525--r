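test_that("percent of reference is a plain uncapped ratio", {
  expect_equal(percent_reference(23.5, 50.25), 100 * 23.5 / 50.25)
  expect_equal(percent_reference(0, 123), 0)
  expect_equal(percent_reference(2, 1.5), 100 * 2 / 1.5) # exceeds 100 by design
  expect_error(percent_reference(1, 0), "positive")
  expect_error(percent_reference(-1, 10), "non-negative")
})

test_that("the four UKNI specifications are built as defined", {
  specs <- build_ukni_specs()
  expect_length(specs, 4)
  expect_false(anyDuplicated(names(specs)) > 0)
  expect_length(specs[["UKNIprot7"]]$qualifying, 7)
  expect_length(specs[["UKNIprot7"]]$disqualifying, 0)
  expect_length(specs[["UKNIprot10"]]$qualifying, 10)
  expect_setequal(specs[["UKNIprot7-2"]]$disqualifying, c("sfa", "na"))
  expect_setequal(setdiff(specs[["UKNIprot10"]]$qualifying,
                          specs[["UKNIprot7"]]$qualifying),
                  c("vitamin_b12", "se", "zn"))
})

test_that("index scores reproduce the published table within 0.1", {
  fx <- load_paper_fixtures()
  by_label <- setNames(fx$systems, vapply(fx$systems, system_label, character(1)))
  published <- list(
    "UKNIprot7"    = c("beef concentrate" = 13.6, "beef forage" = 15.2,
                       "lamb lowland" = 12.4, "lamb upland" = 12.7,
                       "chicken intensive" = 13.4, "chicken free_range" = 13.9,
                       "pork intensive" = 9.4),
    "UKNIprot7-2"  = c("beef concentrate" = 10.7, "beef forage" = 11.6,
                       "lamb lowland" = 9.2, "lamb upland" = 9.7,
                       "chicken intensive" = 7.9, "chicken free_range" = 5.9,
                       "pork intensive" = 7.1),
    "UKNIprot10"   = c("beef concentrate" = 28.9, "beef forage" = 30.0,
                       "lamb lowland" = 18.2, "lamb upland" = 18.4,
                       "chicken intensive" = 13.4, "chicken free_range" = 13.8,
                       "pork intensive" = 16.4),
    "UKNIprot10-2" = c("beef concentrate" = 26.0, "beef forage" = 26.4,
                       "lamb lowland" = 15.0, "lamb upland" = 15.4,
                       "chicken intensive" = 7.9, "chicken free_range" = 5.7,
                       "pork intensive" = 14.2))
  for (spec_name in names(published)) {
    for (lab in names(published[[spec_name]])) {
      got <- index_score(by_label[[lab]]$nutrients, fx$specs[[spec_name]],
                         fx$reference)$value
      expect_lt(abs(got - published[[spec_name]][[lab]]), 0.1,
                label = sprintf("|%s %s (%0.3f) - published|", spec_name, lab, got))
    }
  }
})

test_that("index score matches the brute-force oracle on random cases", {
  set.seed(2024)
  for (i in 1:1000) {
    case <- random_profile_case(n_nutrients = sample(3:10, 1))
    nq <- sample(seq_along(case$names), 1)
    q <- sample(case$names, nq)
    d <- sample(setdiff(case$names, q), sample(0:min(2, length(case$names) - nq), 1))
    got <- index_score(case$profile, index_spec("rand", q, d), case$ref)$value
    want <- oracle_score(contents_in_ref_units(case$profile, case$ref),
                         ref_values(case$ref), q, d)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("index score has the expected structural properties", {
  ref <- ukni_reference_intakes()
  prof <- nutrient_profile(
    c(protein = 20, fe = 1.2, sfa = 0, na = 0.06),
    c(protein = "g", fe = "mg", sfa = "g", na = "g"))

  # single-nutrient spec equals that nutrient's percent of reference
  expect_equal(index_score(prof, index_spec("p", "protein"), ref)$value,
               percent_reference(20, 50.25))

  # a zero-content disqualifying nutrient leaves the score unchanged
  s_plain <- index_score(prof, index_spec("q", c("protein", "fe")), ref)$value
  s_pen0 <- index_score(prof, index_spec("q2", c("protein", "fe"), "sfa"), ref)$value
  expect_equal(s_pen0, s_plain)

  # mean of percents never exceeds the max single percent
  terms <- c(percent_reference(20, 50.25), percent_reference(1.2, 11.75))
  expect_lte(s_plain, max(terms))

  # scale invariance: scaling a content and its reference together is a no-op
  prof2 <- nutrient_profile(c(protein = 40, fe = 1.2),
                            c(protein = "g", fe = "mg"))
  ref2 <- reference_intake_table(c("protein", "fe"), c(100.5, 11.75),
                                 c("g", "mg"), rep("encouraged", 2))
  expect_equal(index_score(prof2, index_spec("q", c("protein", "fe")), ref2)$value,
               s_plain)

  # monotonicity: up in qualifying, down in disqualifying
  richer <- nutrient_profile(c(protein = 21, fe = 1.2, sfa = 1, na = 0.06),
                             c(protein = "g", fe = "mg", sfa = "g", na = "g"))
  spec_pen <- index_spec("pen", c("protein", "fe"), "na")
  expect_gt(index_score(richer, index_spec("q", c("protein", "fe")), ref)$value, s_plain)
  saltier <- nutrient_profile(c(protein = 20, fe = 1.2, na = 0.5),
                              c(protein = "g", fe = "mg", na = "g"))
  expect_lt(index_score(saltier, spec_pen, ref)$value,
            index_score(prof, spec_pen, ref)$value)

  # all-zero profile scores zero under any spec
  zeros <- nutrient_profile(c(protein = 0, fe = 0, sfa = 0, na = 0),
                            c(protein = "g", fe = "mg", sfa = "g", na = "g"))
  expect_equal(index_score(zeros, index_spec("z", c("protein", "fe"),
                                             c("sfa", "na")), ref)$value, 0)
})

test_that("a nutrient missing from profile or reference is reported by name", {
  ref <- ukni_reference_intakes()
  prof <- nutrient_profile(c(protein = 20), c(protein = "g"))
  err <- expect_error(index_score(prof, index_spec("s", c("protein", "zn")), ref))
  expect_match(conditionMessage(err), "zn")
  expect_match(conditionMessage(err), "'s'")
  prof2 <- nutrient_profile(c(exotic = 5), c(exotic = "mg"))
  expect_match(conditionMessage(expect_error(
    index_score(prof2, index_spec("s2", "exotic"), ref))), "exotic")
})

test_that("unit bookkeeping reconciles profile and reference units", {
  # same physical content expressed in different units scores identically
  ref <- reference_intake_table("fe", 11.75, "mg", "encouraged")
  p_mg <- nutrient_profile(c(fe = 1.6), c(fe = "mg"))
  p_ug <- nutrient_profile(c(fe = 1600), c(fe = "ug"))
  spec <- index_spec("fe_only", "fe")
  expect_equal(index_score(p_mg, spec, ref)$value,
               index_score(p_ug, spec, ref)$value, tolerance = 1e-12)
  expect_error(nutrient_profile(c(fe = 1), c(fe = "furlongs")), "unit")
})
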