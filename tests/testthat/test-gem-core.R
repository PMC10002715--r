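test_that("formula parsing tokenizes elements case-sensitively", {
  expect_equal(carbon_count("C6H12O6"), 6L)
  expect_equal(carbon_count("H2O"), 0L)
  # "Cu" must stay one token, not split into C + u
  expect_equal(carbon_count("CuSO4"), 0L)
  expect_equal(carbon_count("C"), 1L)
  expect_equal(parse_formula("C6H12O6"),
               c(C = 6L, H = 12L, O = 6L))
  expect_error(parse_formula("c6h12"), "parse")
  expect_error(parse_formula("C0"), "count")
  expect_error(parse_formula(""), "nonempty")
})

test_that("carbon count is additive over fragments and order-invariant", {
  frags <- c("C6H12O6", "CuSO4", "C2H4O2", "Fe", "NaCl", "C10")
  for (i in seq_along(frags)) {
    for (j in seq_along(frags)) {
      expect_equal(carbon_count(paste0(frags[i], frags[j])),
                   carbon_count(frags[i]) + carbon_count(frags[j]))
    }
  }
  expect_equal(carbon_count("C6H12O6"), carbon_count("H12O6C6"))
})

test_that("models round-trip through JSON and SBML", {
  m <- make_taxon_model(taxon_archetype("butyrogen", taxon_id = "Roseburia",
                                        carbon_balanced = TRUE))
  m$metabolites[["glucose_e"]]$annotations <- list(host_absorbable = TRUE)
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(m, path, fmt)
    m2 <- load_taxon_model(path, fmt)
    expect_equal(m2$taxon_id, m$taxon_id)
    expect_equal(m2$rank, m$rank)
    expect_setequal(names(m2$metabolites), names(m$metabolites))
    expect_setequal(names(m2$reactions), names(m$reactions))
    for (rid in names(m$reactions)) {
      r1 <- m$reactions[[rid]]; r2 <- m2$reactions[[rid]]
      expect_equal(sort(names(r2$stoichiometry)),
                   sort(names(r1$stoichiometry)))
      expect_equal(r2$stoichiometry[names(r1$stoichiometry)],
                   r1$stoichiometry, tolerance = 1e-12)
      expect_equal(r2$lower_bound, r1$lower_bound)
      expect_equal(r2$upper_bound, r1$upper_bound)
      expect_equal(r2$is_exchange, r1$is_exchange)
      expect_equal(r2$is_biomass, r1$is_biomass)
    }
    expect_equal(m2$metabolites[["glucose_e"]]$formula,
                 m$metabolites[["glucose_e"]]$formula)
    expect_true(isTRUE(m2$metabolites[["glucose_e"]]$annotations$host_absorbable))
    unlink(path)
  }
})

test_that("SBML exchanges written with the opposite convention are normalized", {
  m <- make_taxon_model(taxon_archetype("butyrogen", taxon_id = "X"))
  path <- tempfile(fileext = ".xml")
  write_model(m, path, "sbml")
  # flip EX_glucose_e to the metabolite-as-product convention by hand
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core")
  rx <- xml2::xml_find_first(
    doc, ".//s:reaction[@id='EX_glucose_e']", ns)
  lr <- xml2::xml_find_first(rx, ".//s:listOfReactants", ns)
  xml2::xml_set_name(lr, "listOfProducts")
  lb <- xml2::xml_find_first(
    doc, ".//s:parameter[@id='EX_glucose_e_lb']", ns)
  ub <- xml2::xml_find_first(
    doc, ".//s:parameter[@id='EX_glucose_e_ub']", ns)
  xml2::xml_set_attr(lb, "value", "-1000")
  xml2::xml_set_attr(ub, "value", "10")
  xml2::write_xml(doc, path)
  m2 <- load_taxon_model(path, "sbml")
  r <- m2$reactions[["EX_glucose_e"]]
  expect_equal(unname(r$stoichiometry), -1)
  expect_equal(r$lower_bound, -10)
  expect_equal(r$upper_bound, 1000)
  unlink(path)
})

test_that("structural violations are caught", {
  # biomass flag on zero reactions -> error on construction/load
  expect_error(
    taxon_model("bad", "genus",
                list(metabolite("a_e")),
                list(reaction("EX_a", c(a_e = -1), -1, 1, is_exchange = TRUE))),
    "biomass")
  bad_json <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    taxon_id = "bad", rank = "genus",
    metabolites = list(list(id = "a_e", compartment = "e")),
    reactions = list(list(id = "EX_a", stoichiometry = list(a_e = -1),
                          lower_bound = -1, upper_bound = 1,
                          is_exchange = TRUE, is_biomass = FALSE))),
    bad_json, auto_unbox = TRUE)
  expect_error(load_taxon_model(bad_json), "biomass")
  unlink(bad_json)
  # inverted bounds rejected at reaction construction
  expect_error(reaction("r", c(a = -1), 2, 1), "lower_bound")
  # malformed file -> parse error naming the file
  broken <- tempfile(fileext = ".json")
  writeLines("{not json", broken)
  expect_error(load_taxon_model(broken), "parse")
  unlink(broken)
})

test_that("validate_model flags blocked biomass and accepts working toys", {
  for (nm in archetype_names()) {
    v <- validate_model(make_taxon_model(taxon_archetype(nm)))
    expect_equal(nrow(v), 0)
  }
  # biomass precursor with no producing reaction
  blocked <- taxon_model("blocked", "genus",
    list(metabolite("a_e"), metabolite("x_c", compartment = "c")),
    list(reaction("EX_a", c(a_e = -1), -10, 1000, is_exchange = TRUE),
         reaction("BIOMASS", c(x_c = -1), 0, 1000, is_biomass = TRUE)))
  v <- validate_model(blocked)
  expect_true("biomass_blocked" %in% v$code)
})

test_that("the toy butyrogen has the expected reaction structure", {
  m <- make_taxon_model(taxon_archetype("butyrogen"))
  is_ex <- vapply(m$reactions, `[[`, logical(1), "is_exchange")
  expect_equal(sum(is_ex), 2L)   # glucose + butyrate exchanges
  expect_equal(sum(!is_ex), 2L)  # catabolism + biomass
})
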