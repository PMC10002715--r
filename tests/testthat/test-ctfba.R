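test_that("step-1 community growth matches the vertex-enumeration oracle", {
  cm <- two_taxon_community(10)
  s <- solve_max_growth(cm)
  expect_equal(s$status, "optimal")
  expect_equal(s$mu_max, oracle_toy_max_growth(10), tolerance = 1e-4)
  expect_equal(s$mu_max, 3.0, tolerance = 1e-4)
  # single butyrogen alone
  lib1 <- model_library(list(
    make_taxon_model(taxon_archetype("butyrogen", taxon_id = "A"))))
  cm1 <- build_community(abundance_profile("s", c(A = 1)), lib1,
                         glucose_medium(10))
  expect_equal(solve_max_growth(cm1)$mu_max, 2.0, tolerance = 1e-4)
  # empty medium, no internal sources
  cm0 <- build_community(abundance_profile("s", c(A = 1)), lib1,
                         as_medium(diet_definition("empty", c(fe3_e = 0.1))))
  expect_equal(solve_max_growth(cm0)$mu_max, 0, tolerance = 1e-6)
})

test_that("the tradeoff QP matches the grid-search oracle on the toy", {
  cm <- two_taxon_community(10)
  for (tf in c(0.5, 0.7, 0.9)) {
    sol <- solve_ctfba(cm, tf)
    expect_equal(sol$status, "optimal")
    oracle <- oracle_toy_ctfba(tf)
    expect_equal(unname(sol$taxon_growth[c("A", "B")]), oracle,
                 tolerance = 1e-4)
  }
  # frozen hand-KKT values: mu_A pinned at its uptake cap, mu_B at the
  # active cooperativity constraint
  sol7 <- solve_ctfba(cm, 0.7)
  expect_equal(unname(sol7$taxon_growth["A"]), 2.0, tolerance = 1e-4)
  expect_equal(unname(sol7$taxon_growth["B"]), 2.2, tolerance = 1e-4)
  sol5 <- solve_ctfba(cm, 0.5)
  expect_equal(unname(sol5$taxon_growth[c("A", "B")]), c(1.5, 1.5),
               tolerance = 1e-4)
  # tf = 1 forces the step-1 optimum
  expect_equal(solve_ctfba(cm, 1.0)$community_growth, 3.0, tolerance = 1e-4)
})

test_that("flux solutions satisfy steady state and the tradeoff bound", {
  cm <- two_taxon_community(10)
  sol <- solve_ctfba(cm, 0.7)
  expect_lt(max(abs(cm$S %*% sol$fluxes)), 1e-6)
  expect_gte(sol$community_growth, 0.7 * sol$mu_max - 1e-6)
  expect_equal(sol$community_growth,
               sum(cm$members$abundance *
                     sol$taxon_growth[cm$members$taxon_id]),
               tolerance = 1e-6)
})

test_that("production rates floor net imports at zero", {
  cm <- two_taxon_community(10)
  sol <- solve_ctfba(cm, 0.7)
  pr <- production_rates(sol)
  expect_equal(pr$rate[pr$metabolite == "butyrate_e"], 10.0,
               tolerance = 1e-4)
  expect_equal(pr$rate[pr$metabolite == "glucose_e"], 0)  # net import
  expect_false("propionate_e" %in% pr$metabolite)          # never exchanged
  expect_error(production_rates(structure(list(status = "infeasible"),
                                          class = "flux_solution")),
               "optimal")
})

test_that("flux ranges expose degeneracy and only degeneracy", {
  cm <- two_taxon_community(10)
  sol <- solve_ctfba(cm, 0.7)
  fr <- flux_range_at_optimum(cm, sol, "butyrate_e")
  expect_lt(fr["max"] - fr["min"], 1e-4)  # single pathway: unique flux
  dg <- degenerate_community()
  dsol <- solve_ctfba(dg, 0.7)
  fr_prop <- flux_range_at_optimum(dg, dsol, "propionate_e")
  expect_lt(fr_prop["max"] - fr_prop["min"], 1e-4)
  for (met in c("acetate_e", "butyrate_e")) {
    fr_deg <- flux_range_at_optimum(dg, dsol, met)
    expect_gt(fr_deg["max"] - fr_deg["min"], 1)
  }
})

test_that("objective and width are monotone in the tradeoff", {
  cm <- two_taxon_community(10)
  grid <- c(0.3, 0.5, 0.7, 0.9, 1.0)
  scan <- tradeoff_scan(cm, grid)
  # min sum of squared growth rates is non-decreasing in tf
  expect_true(all(diff(scan$sum_sq_growth) >= -1e-6))
  expect_true(all(scan$community_growth >= grid * 3.0 - 1e-5))
  # on the toy every taxon grows at every tf
  expect_true(all(scan$fraction_growing == 1))
})

test_that("infeasible and closed models are reported, not crashed", {
  # forced flux consuming a metabolite with no source -> infeasible
  bad <- taxon_model("bad", "genus",
    list(metabolite("a_e"), metabolite("x_c", compartment = "c")),
    list(reaction("EX_a", c(a_e = -1), -10, 1000, is_exchange = TRUE),
         reaction("SINK", c(a_e = -1, x_c = 1), 2, 1000),
         reaction("BIOMASS", c(x_c = -1), 5, 1000, is_biomass = TRUE)))
  lib <- model_library(list(bad))
  cm <- build_community(abundance_profile("s", c(bad = 1)), lib,
                        as_medium(diet_definition("none", c(fe3_e = 0.1))))
  s <- solve_max_growth(cm)
  expect_true(s$status %in% c("infeasible", "numeric_failure"))
  sol <- solve_ctfba(cm, 0.7)
  expect_true(sol$status != "optimal")
})

test_that("raising a medium bound never decreases the growth optimum", {
  cm <- two_taxon_community(5)
  base <- solve_max_growth(cm)$mu_max
  cm_up <- two_taxon_community(8)
  expect_gte(solve_max_growth(cm_up)$mu_max, base - 1e-6)
})

test_that("carbon is conserved in carbon-balanced communities", {
  lib <- model_library(list(
    make_taxon_model(taxon_archetype("butyrogen", taxon_id = "A",
                                     carbon_balanced = TRUE)),
    make_taxon_model(taxon_archetype("acetogen", taxon_id = "B",
                                     carbon_balanced = TRUE))))
  cm <- build_community(abundance_profile("s", c(A = 0.5, B = 0.5)), lib,
                        glucose_medium(10))
  sol <- solve_ctfba(cm, 0.7)
  cc <- c(glucose_e = 6, acetate_e = 2, butyrate_e = 4)
  exch_carbon <- sum(cc[names(sol$exchange_fluxes)] * sol$exchange_fluxes)
  biomass_carbon <- sum(cm$members$abundance *
                          sol$taxon_growth[cm$members$taxon_id]) * 4
  # net imported carbon all ends up in biomass (C4 nominal content)
  expect_equal(exch_carbon + biomass_carbon, 0, tolerance = 1e-6)
})
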