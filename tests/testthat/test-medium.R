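toy_diet <- function() {
  diet_definition(
    "toy",
    entries = c(glucose_e = 10, inulin_e = 5, mucin_e = 2, fe3_e = 0.1),
    host_absorbable = "glucose_e",
    residual_fiber = "inulin_e",
    host_supplied = "mucin_e",
    formulas = c(glucose_e = "C6H12O6", inulin_e = "C36H62O31",
                 mucin_e = "C8H15NO6"))
}

test_that("host absorption dilutes flagged entries only", {
  med <- apply_host_absorption(toy_diet(), retain = 0.2)
  expect_equal(med$entries[["glucose_e"]], 2.0)
  expect_equal(med$entries[["inulin_e"]], 5.0)
  expect_equal(med$entries[["fe3_e"]], 0.1)
  ident <- apply_host_absorption(toy_diet(), retain = 1.0)
  expect_equal(ident$entries,
               stats::setNames(toy_diet()$table$flux,
                               toy_diet()$table$metabolite))
})

test_that("host metabolites are added with the max-merge rule", {
  med <- as_medium(diet_definition("d", c(a_e = 1)))
  m1 <- add_host_metabolites(med, c(mucin_e = 1))
  expect_equal(m1$entries[["mucin_e"]], 1)
  expect_true(med_flag <- m1$info$host_supplied[m1$info$metabolite == "mucin_e"])
  m2 <- add_host_metabolites(
    as_medium(diet_definition("d", c(mucin_e = 2))), c(mucin_e = 1))
  expect_equal(m2$entries[["mucin_e"]], 2)
  expect_identical(add_host_metabolites(med, numeric(0))$entries, med$entries)
})

test_that("completion adds the minimal support needed to reach the floor", {
  # a taxon whose biomass requires iron(III), on an iron-free medium
  med <- glucose_medium(10)
  res <- complete_medium(med, iron_requiring_model(), growth_floor = 0.3)
  expect_equal(names(res$additions), "fe3_e")
  # growth floor 0.3 needs 0.01 * 0.3 iron flux
  expect_equal(unname(res$additions), 0.003, tolerance = 1e-4)
  # model already growing: no additions, medium unchanged
  ok <- make_taxon_model(taxon_archetype("butyrogen"))
  res2 <- complete_medium(med, ok, growth_floor = 0.3)
  expect_equal(length(res2$additions), 0L)
  expect_equal(res2$medium$entries, med$entries)
  # needed metabolite excluded from candidates -> infeasible error
  expect_error(
    complete_medium(med, iron_requiring_model(), growth_floor = 0.3,
                    candidates = "glucose_e"),
    "infeasible")
})

test_that("completion is idempotent", {
  med <- glucose_medium(10)
  first <- complete_medium(med, iron_requiring_model(), 0.3)
  second <- complete_medium(first$medium, iron_requiring_model(), 0.3)
  expect_equal(length(second$additions), 0L)
  expect_equal(second$medium$entries, first$medium$entries)
})

test_that("carbon stripping spares residual fiber and host metabolites", {
  med <- as_medium(toy_diet())
  stripped <- strip_carbon(med)
  expect_false("glucose_e" %in% names(stripped$entries))
  expect_equal(stripped$entries[["inulin_e"]], 5)   # residual fiber kept
  expect_equal(stripped$entries[["mucin_e"]], 2)    # host supplied kept
  expect_equal(stripped$entries[["fe3_e"]], 0.1)    # carbon-free kept
  # formula-free metabolites are carbon-free unless overridden
  d2 <- diet_definition("d", c(mystery = 1, flagged = 1),
                        carbon_source_override = "flagged")
  s2 <- strip_carbon(as_medium(d2))
  expect_equal(names(s2$entries), "mystery")
  # no carbon entries -> identity
  d3 <- as_medium(diet_definition("d", c(fe3_e = 0.1)))
  expect_equal(strip_carbon(d3)$entries, d3$entries)
})

test_that("dilution scales globally but rescales residual fiber to the study", {
  med <- as_medium(toy_diet())
  d <- dilute(med, 0.1, fiber_dilution = 5)
  expect_equal(d$entries[["glucose_e"]], 1.0)       # 10 * 0.1
  expect_equal(d$entries[["inulin_e"]], 1.0)        # diet 5 / dilution 5
  expect_equal(d$entries[["mucin_e"]], 0.2)
  # without a study dilution residual fiber follows the global factor
  d2 <- dilute(med, 0.1)
  expect_equal(d2$entries[["inulin_e"]], 0.5)
  expect_equal(dilute(med, 1.0)$entries, med$entries)
  expect_error(dilute(med, 0.1, fiber_dilution = -1), "positive")
})

test_that("fiber supplementation uses the carbon-derived default bounds", {
  med <- as_medium(diet_definition("d", c(glucose_e = 1)))
  expect_equal(supplement_fiber(med, "pectin")$entries[["pectin_e"]], 1.0)
  expect_equal(supplement_fiber(med, "inulin")$entries[["inulin_e"]], 10.0)
  expect_equal(supplement_fiber(med, "fos")$entries[["fos_e"]], 100)
  expect_equal(supplement_fiber(med, "inulin", 3)$entries[["inulin_e"]], 3)
  expect_error(supplement_fiber(med, "cellulose"), "unknown fiber")
})

test_that("ex-vivo recipe leaves carbon only in residual fiber and host entries", {
  st <- synthetic_study(11)
  coh <- make_cohort(st)
  med <- build_medium(coh$diet, "ex_vivo", models = coh$library,
                      fiber_dilution = 5, host_set = c(mucin_e = 1))
  info <- med$info[match(names(med$entries), med$info$metabolite), ]
  carbon <- vapply(seq_along(med$entries), function(i) {
    f <- info$formula[i]
    !is.na(f) && nzchar(f) && carbon_count(f) > 0
  }, logical(1))
  expect_true(all(info$residual_fiber[carbon] | info$host_supplied[carbon]))
  # residual fiber equals diet value / study dilution
  expect_equal(med$entries[["inulin_e"]], 5 / 5)
})

test_that("in-vivo recipe keeps absorbable carbon at the retained fraction", {
  st <- synthetic_study(11)
  coh <- make_cohort(st)
  med <- build_medium(coh$diet, "in_vivo", models = coh$library)
  expect_equal(med$entries[["glucose_e"]], 10 * 0.2)
})

test_that("provenance replay reproduces built media bit-exactly", {
  st <- synthetic_study(13)
  coh <- make_cohort(st)
  for (recipe in c("in_vivo", "ex_vivo")) {
    med <- build_medium(coh$diet, recipe, models = coh$library,
                        fiber_dilution = if (recipe == "ex_vivo") 5 else NULL,
                        host_set = c(mucin_e = 1.5),
                        supplement = "inulin")
    replayed <- replay_provenance(coh$diet, med)
    expect_identical(unname(replayed), unname(med$entries))
    expect_identical(names(replayed), names(med$entries))
  }
})

test_that("transformations are flux-monotone in the documented direction", {
  med <- as_medium(toy_diet())
  dec <- list(
    function(m) apply_host_absorption(toy_diet(), 0.2),
    function(m) strip_carbon(m),
    function(m) dilute(m, 0.1))
  for (f in dec) {
    out <- f(med)
    common <- intersect(names(out$entries), names(med$entries))
    expect_true(all(out$entries[common] <= med$entries[common] + 1e-12))
  }
  inc <- list(
    function(m) add_host_metabolites(m, c(bile_e = 0.5)),
    function(m) supplement_fiber(m, "pectin"),
    function(m) complete_medium(m, iron_requiring_model(), 0.3)$medium)
  for (f in inc) {
    out <- f(med)
    expect_true(all(out$entries[names(med$entries)] >=
                      med$entries - 1e-12))
  }
})

test_that("diet definitions round-trip through TSV", {
  d <- toy_diet()
  path <- tempfile(fileext = ".tsv")
  write_diet(d, path)
  d2 <- read_diet(path, name = d$name)
  expect_equal(d2$table$flux, d$table$flux)
  expect_equal(d2$table$residual_fiber, d$table$residual_fiber)
  expect_equal(d2$table$formula, d$table$formula)
  unlink(path)
})
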