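# Fixtures built in code, plus independent oracles (grid search, vertex
# enumeration, exhaustive rank enumeration, hand formulas) against which
# the solver-based implementation is checked.

## ---- fixtures -------------------------------------------------------------

# Two-taxon glucose toy: butyrogen A (0.2 biomass + 2 butyrate per
# glucose) and non-producer B (0.4 biomass per glucose), per-taxon uptake
# <= 10, shared glucose <= 10, equal abundance.
two_taxon_library <- function() {
  model_library(list(
    make_taxon_model(taxon_archetype("butyrogen", taxon_id = "A")),
    make_taxon_model(taxon_archetype("non_producer", taxon_id = "B"))))
}

glucose_medium <- function(flux = 10) {
  as_medium(diet_definition("glc", c(glucose_e = flux)))
}

two_taxon_community <- function(glucose = 10) {
  build_community(abundance_profile("toy", c(A = 0.5, B = 0.5)),
                  two_taxon_library(), glucose_medium(glucose))
}

# Degeneracy fixture: propionogen (single propionate pathway) plus a
# taxon with two isoenergetic glucose pathways secreting either acetate
# or butyrate, so the acetate/butyrate split is free at the optimum.
degenerate_community <- function() {
  lib <- model_library(list(
    make_taxon_model(taxon_archetype("propionogen", taxon_id = "P")),
    make_taxon_model(taxon_archetype("degenerate_producer", taxon_id = "D"))))
  build_community(abundance_profile("degen", c(P = 0.5, D = 0.5)),
                  lib, glucose_medium())
}

# A taxon whose biomass requires iron(III): used by the completion tests.
iron_requiring_model <- function(taxon_id = "IR") {
  taxon_model(taxon_id, "genus",
    metabolites = list(
      metabolite("glucose_e", compartment = "e", formula = "C6H12O6"),
      metabolite("fe3_e", compartment = "e"),
      metabolite("biomass_c", compartment = "c")),
    reactions = list(
      reaction("EX_glucose_e", c(glucose_e = -1), -10, 1000,
               is_exchange = TRUE),
      reaction("EX_fe3_e", c(fe3_e = -1), -1000, 1000, is_exchange = TRUE),
      reaction("CATAB", c(glucose_e = -1, biomass_c = 0.2), 0, 1000),
      reaction("BIOMASS", c(biomass_c = -1, fe3_e = -0.01), 0, 1000,
               is_biomass = TRUE)))
}

## ---- oracles --------------------------------------------------------------

# Exact step-1 oracle for the two-taxon toy by vertex enumeration of the
# reduced 2-variable LP over per-taxon glucose uptakes (g_A, g_B):
# maximize 0.5*0.2*g_A + 0.5*0.4*g_B s.t. 0 <= g <= 10, 0.5*(g_A+g_B) <= G.
oracle_toy_max_growth <- function(glucose = 10) {
  lines <- list(c(1, 0, 0), c(1, 0, 10), c(0, 1, 0), c(0, 1, 10),
                c(0.5, 0.5, glucose))  # a*gA + b*gB = rhs
  verts <- list()
  for (i in seq_along(lines)) for (j in seq_along(lines)) {
    if (i >= j) next
    A <- rbind(lines[[i]][1:2], lines[[j]][1:2])
    if (abs(det(A)) < 1e-12) next
    v <- solve(A, c(lines[[i]][3], lines[[j]][3]))
    feas <- v[1] >= -1e-9 && v[1] <= 10 + 1e-9 &&
      v[2] >= -1e-9 && v[2] <= 10 + 1e-9 &&
      0.5 * sum(v) <= glucose + 1e-9
    if (feas) verts[[length(verts) + 1L]] <- v
  }
  max(vapply(verts, function(v) 0.5 * 0.2 * v[1] + 0.5 * 0.4 * v[2],
             numeric(1)))
}

# Grid-search oracle for the toy's step-2 QP in the reduced (mu_A, mu_B)
# space: minimize mu_A^2 + mu_B^2 subject to mu_A <= 2, mu_B <= 4,
# glucose 2.5*mu_A + 1.25*mu_B <= glucose bound, and the cooperativity
# constraint 0.5*(mu_A + mu_B) >= tf * mu_star. Two-stage refinement.
oracle_toy_ctfba <- function(tf, glucose = 10, iters = 10) {
  mu_star <- oracle_toy_max_growth(glucose)
  lo <- c(0, 0); hi <- c(2, 4)
  best <- NULL
  for (it in seq_len(iters)) {
    ga <- seq(lo[1], hi[1], length.out = 121)
    gb <- seq(lo[2], hi[2], length.out = 121)
    grid <- expand.grid(mu_a = ga, mu_b = gb)
    feas <- grid$mu_a <= 2 + 1e-12 & grid$mu_b <= 4 + 1e-12 &
      2.5 * grid$mu_a + 1.25 * grid$mu_b <= glucose + 1e-9 &
      0.5 * (grid$mu_a + grid$mu_b) >= tf * mu_star - 1e-9
    g <- grid[feas, ]
    k <- which.min(g$mu_a^2 + g$mu_b^2)
    best <- c(g$mu_a[k], g$mu_b[k])
    span <- (hi - lo) / 121 * 4
    lo <- pmax(c(0, 0), best - span)
    hi <- pmin(c(2, 4), best + span)
  }
  best
}

# Exhaustive Mann-Whitney oracle: U for the first group and the exact
# two-sided p by enumerating every assignment of the pooled ranks.
oracle_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# Hand-formula Pearson r and its t-based two-sided p.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Expected Pearson correlation between a positive vector P and P*exp(eps)
# with eps ~ N(0, sigma^2), from the empirical moments of P (the analytic
# attenuation caused by multiplicative lognormal noise).
oracle_lognormal_attenuation <- function(p, sigma) {
  m <- exp(sigma^2 / 2)
  mu_p <- mean(p)
  var_p <- mean((p - mu_p)^2)   # population moments
  ep2 <- mean(p^2)
  m * var_p / (sqrt(var_p) * sqrt(ep2 * exp(2 * sigma^2) - mu_p^2 * m^2))
}

# Random small community for property sweeps: 2-5 archetypes, Dirichlet
# abundances, random glucose/inulin/acetate medium.
random_community <- function() {
  pool <- archetype_names()
  k <- sample(2:5, 1)
  taxa <- sample(pool, k)
  lib <- model_library(lapply(seq_along(taxa), function(i)
    make_taxon_model(taxon_archetype(taxa[i], taxon_id = sprintf("T%d", i)))))
  ab <- stats::rgamma(k, 1) + 1e-3
  prof <- abundance_profile("rnd", stats::setNames(ab, sprintf("T%d", seq_len(k))))
  med <- as_medium(diet_definition("rnd", c(
    glucose_e = stats::runif(1, 2, 15),
    inulin_e = stats::runif(1, 0, 5),
    acetate_e = stats::runif(1, 0, 5))))
  build_community(prof, lib, med)
}
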