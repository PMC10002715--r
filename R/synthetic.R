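# Toy genome-scale models, simulated cohorts, and noisy measurements with
# known ground truth. Each archetype is one or two catabolic pathways
# (substrate -> biomass precursor + SCFAs) plus a biomass reaction and
# exchanges, small enough that optima can be verified by hand or by grid
# enumeration, yet structured enough to exercise cross-feeding through
# shared metabolites.

#' Built-in taxon archetypes
#'
#' @return Character vector of archetype names accepted by
#'   [taxon_archetype()].
#' @export
archetype_names <- function() {
  c("fiber_degrader", "butyrogen", "propionogen", "acetogen",
    "acetate_to_butyrate_crossfeeder", "non_producer",
    "degenerate_producer")
}

#' Describe a taxon archetype
#'
#' An archetype is a named set of catabolic pathways, each converting one
#' substrate into biomass precursor (at `biomass_yield` gDW per mmol) and
#' SCFAs (at the stated mmol-per-mmol yields), with an uptake bound on
#' the substrate exchange. The defaults:
#' \describe{
#'   \item{butyrogen}{glucose <= 10, 0.2 biomass + 2 butyrate}
#'   \item{non_producer}{glucose <= 10, 0.4 biomass}
#'   \item{acetogen}{glucose <= 10, 0.3 biomass + 2 acetate}
#'   \item{propionogen}{glucose <= 10, 0.25 biomass + 2 propionate}
#'   \item{fiber_degrader}{glucose <= 10, 0.2 biomass + 2 butyrate; plus
#'     inulin <= 2, 1.0 biomass + 10 butyrate}
#'   \item{acetate_to_butyrate_crossfeeder}{acetate <= 20, 0.1 biomass +
#'     0.5 butyrate}
#'   \item{degenerate_producer}{two isoenergetic glucose pathways
#'     (0.2 biomass each) secreting either 2 acetate or 2 butyrate,
#'     leaving the acetate/butyrate split undetermined at the growth
#'     optimum}
#' }
#'
#' @param name One of [archetype_names()].
#' @param taxon_id Taxon label (defaults to the archetype name).
#' @param rank Taxonomic rank of the model (default `"genus"`).
#' @param carbon_balanced When `TRUE`, elemental formulas are attached
#'   and pathway yields are adjusted so that substrate carbon equals
#'   biomass plus product carbon exactly, making carbon-conservation
#'   checks exact.
#' @return An object of class `taxon_archetype`.
#' @export
taxon_archetype <- function(name, taxon_id = name, rank = "genus",
                            carbon_balanced = FALSE) {
  name <- match.arg(name, archetype_names())
  pw <- function(substrate, bound, yield, ...) {
    list(substrate = substrate, uptake_bound = bound, biomass_yield = yield,
         products = c(...))
  }
  pathways <- switch(name,
    butyrogen = list(pw("glucose_e", 10, 0.2, butyrate_e = 2)),
    non_producer = list(pw("glucose_e", 10, 0.4)),
    acetogen = list(pw("glucose_e", 10, 0.3, acetate_e = 2)),
    propionogen = list(pw("glucose_e", 10, 0.25, propionate_e = 2)),
    fiber_degrader = list(pw("glucose_e", 10, 0.2, butyrate_e = 2),
                          pw("inulin_e", 2, 1.0, butyrate_e = 10)),
    acetate_to_butyrate_crossfeeder =
      list(pw("acetate_e", 20, 0.1, butyrate_e = 0.5)),
    degenerate_producer = list(pw("glucose_e", 10, 0.2, acetate_e = 2),
                               pw("glucose_e", 10, 0.2, butyrate_e = 2)))
  formulas <- NULL
  if (carbon_balanced) {
    # biomass precursor assigned a nominal 4-carbon content; product
    # yields are reduced so substrate carbon can cover them and the
    # biomass yield is re-derived so each pathway closes exactly
    formulas <- c(glucose_e = "C6H12O6", inulin_e = "C36H62O31",
                  acetate_e = "C2H4O2", propionate_e = "C3H6O2",
                  butyrate_e = "C4H8O2", biomass_c = "C4H8O2N")
    cc <- vapply(formulas, carbon_count, integer(1))
    balanced_products <- switch(name,
      butyrogen = list(c(butyrate_e = 1)),
      non_producer = list(numeric(0)),
      acetogen = list(c(acetate_e = 2)),
      propionogen = list(c(propionate_e = 1)),
      fiber_degrader = list(c(butyrate_e = 1), c(butyrate_e = 6)),
      acetate_to_butyrate_crossfeeder = list(c(butyrate_e = 0.25)),
      degenerate_producer = list(c(acetate_e = 2), c(butyrate_e = 1)))
    pathways <- Map(function(p, prod) {
      p$products <- prod
      c_prod <- if (length(prod)) sum(prod * cc[names(prod)]) else 0
      p$biomass_yield <- (cc[[p$substrate]] - c_prod) / cc[["biomass_c"]]
      if (p$biomass_yield <= 0) {
        stop(sprintf(
          "archetype '%s': pathway from %s cannot be carbon balanced",
          name, p$substrate), call. = FALSE)
      }
      p
    }, pathways, balanced_products)
  }
  structure(list(name = name, taxon_id = taxon_id, rank = rank,
                 pathways = pathways, formulas = formulas),
            class = "taxon_archetype")
}

#' Build a toy taxon model from an archetype
#'
#' The model has one exchange reaction per external metabolite (uptake
#' bound on substrates, secretion-only on products), one catabolic
#' reaction per pathway, and one biomass reaction draining the biomass
#' precursor. When the archetype carries formulas, each pathway's carbon
#' balance is checked on construction and a construction error is raised
#' if it does not close.
#'
#' @param archetype A [taxon_archetype()].
#' @return A [taxon_model()] that passes [validate_model()].
#' @export
make_taxon_model <- function(archetype) {
  stopifnot(inherits(archetype, "taxon_archetype"))
  pws <- archetype$pathways
  substrates <- vapply(pws, `[[`, character(1), "substrate")
  products <- unique(unlist(lapply(pws, function(p) names(p$products))))
  externals <- unique(c(substrates, products))
  forms <- archetype$formulas
  if (!is.null(forms)) {
    cc <- vapply(forms, carbon_count, integer(1))
    for (p in pws) {
      c_in <- cc[[p$substrate]]
      c_out <- p$biomass_yield * cc[["biomass_c"]] +
        if (length(p$products)) sum(p$products * cc[names(p$products)]) else 0
      if (abs(c_in - c_out) > 1e-6) {
        stop(sprintf(
          "archetype '%s': pathway from %s is carbon imbalanced (%.4g in, %.4g out)",
          archetype$name, p$substrate, c_in, c_out), call. = FALSE)
      }
    }
  }
  mets <- lapply(externals, function(id) {
    metabolite(id, compartment = "e",
               formula = if (!is.null(forms) && id %in% names(forms))
                 forms[[id]] else NULL)
  })
  mets <- c(mets, list(metabolite(
    "biomass_c", compartment = "c",
    formula = if (!is.null(forms)) forms[["biomass_c"]] else NULL)))
  rxns <- list()
  for (id in externals) {
    uptake <- max(c(0, vapply(pws, function(p)
      if (p$substrate == id) p$uptake_bound else 0, numeric(1))))
    rxns[[length(rxns) + 1L]] <- reaction(
      paste0("EX_", id), stats::setNames(-1, id),
      lower_bound = -uptake, upper_bound = 1000, is_exchange = TRUE)
  }
  for (k in seq_along(pws)) {
    p <- pws[[k]]
    st <- c(stats::setNames(-1, p$substrate),
            stats::setNames(p$biomass_yield, "biomass_c"), p$products)
    rxns[[length(rxns) + 1L]] <- reaction(
      sprintf("CATAB%d_%s", k, sub("_e$", "", p$substrate)), st,
      lower_bound = 0, upper_bound = 1000)
  }
  rxns[[length(rxns) + 1L]] <- reaction(
    "BIOMASS", c(biomass_c = -1), lower_bound = 0, upper_bound = 1000,
    is_biomass = TRUE)
  taxon_model(archetype$taxon_id, archetype$rank, mets, rxns)
}

#' Define a synthetic study
#'
#' Captures every knob of the generator so a single seed reproduces the
#' full study: community compositions, measurement noise, and clinical
#' marker coupling.
#'
#' @param seed Integer seed.
#' @param n_samples Number of samples (default 20).
#' @param archetypes Archetype names forming the community pool; the
#'   default includes the acetogen plus acetate-to-butyrate cross-feeder
#'   pair so shared-metabolite coupling is always exercised.
#' @param alpha Dirichlet concentration; scalar (symmetric) or one value
#'   per archetype (default 1, uniform over the simplex).
#' @param noise_sigma Lognormal sigma of multiplicative measurement noise
#'   (default 0.3).
#' @param dilution_factor Ex-vivo slurry dilution of the study
#'   (default 5, i.e. 1:5).
#' @param treatment_arms Treatment labels (default control and inulin).
#' @return An object of class `synthetic_study`.
#' @export
synthetic_study <- function(seed, n_samples = 20,
                            archetypes = c("butyrogen", "non_producer",
                                           "acetogen", "propionogen",
                                           "fiber_degrader",
                                           "acetate_to_butyrate_crossfeeder"),
                            alpha = 1, noise_sigma = 0.3,
                            dilution_factor = 5,
                            treatment_arms = c("control", "inulin")) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (length(alpha) == 1L) alpha <- rep(alpha, length(archetypes))
  stopifnot(length(alpha) == length(archetypes), all(alpha > 0))
  structure(list(seed = as.integer(seed), n_samples = n_samples,
                 archetypes = archetypes, alpha = alpha,
                 noise_sigma = noise_sigma,
                 dilution_factor = dilution_factor,
                 treatment_arms = treatment_arms),
            class = "synthetic_study")
}

# One Dirichlet draw per row.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cohort
#'
#' Draws Dirichlet community compositions for every sample, builds the
#' taxon model library from the study's archetypes, and assembles the
#' default diet (glucose as an absorbable carbon source, inulin as
#' residual fiber, a host-supplied mucin, and carbon-free iron(III)).
#' Identical seeds give identical output.
#'
#' @param study A [synthetic_study()].
#' @return A list with `abundances` (data frame: sample_id, taxon,
#'   relative_abundance), `profiles` (list of [abundance_profile()]s),
#'   `library` (a [model_library()]), and `diet` (a
#'   [diet_definition()]).
#' @export
make_cohort <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(study$seed)
  taxa <- study$archetypes
  library <- model_library(lapply(taxa, function(nm)
    make_taxon_model(taxon_archetype(nm))))
  if (study$n_samples > 0) {
    A <- rdirichlet(study$n_samples, study$alpha)
    sample_ids <- sprintf("S%03d", seq_len(study$n_samples))
    abundances <- data.frame(
      sample_id = rep(sample_ids, each = length(taxa)),
      taxon = rep(taxa, study$n_samples),
      relative_abundance = as.vector(t(A)),
      stringsAsFactors = FALSE)
    profiles <- lapply(seq_len(study$n_samples), function(i)
      abundance_profile(sample_ids[i], stats::setNames(A[i, ], taxa)))
    names(profiles) <- sample_ids
  } else {
    abundances <- data.frame(sample_id = character(), taxon = character(),
                             relative_abundance = numeric(),
                             stringsAsFactors = FALSE)
    profiles <- list()
  }
  diet <- diet_definition(
    "synthetic_european",
    entries = c(glucose_e = 10, inulin_e = 5, mucin_e = 1, fe3_e = 0.1),
    host_absorbable = "glucose_e",
    residual_fiber = "inulin_e",
    host_supplied = "mucin_e",
    formulas = c(glucose_e = "C6H12O6", inulin_e = "C36H62O31",
                 mucin_e = "C8H15NO6"))
  list(abundances = abundances, profiles = profiles, library = library,
       diet = diet)
}

#' Simulate measured SCFA fluxes from the forward model
#'
#' Runs the full prediction pipeline (filter, match, assemble,
#' cooperative tradeoff solve, production rates) for every sample, then
#' generates "measured" fluxes as predicted flux times multiplicative
#' lognormal noise exp(N(0, sigma^2)). Ground-truth predictions are kept
#' alongside the noisy values so recovery can be tested.
#'
#' @param cohort Output of [make_cohort()].
#' @param medium A `medium` applied to every sample.
#' @param tradeoff Tradeoff parameter (default 0.7).
#' @param noise_sigma Lognormal sigma (0 = noise-free).
#' @param seed Seed for the measurement noise.
#' @param scfas Metabolites to report (default butyrate, propionate,
#'   acetate).
#' @param study_id,treatment,dilution_factor Metadata stamped on every
#'   row.
#' @return A study table: data frame with columns sample_id, study_id,
#'   treatment, dilution_factor, metabolite, predicted_flux,
#'   measured_flux, status.
#' @export
simulate_measurements <- function(cohort, medium, tradeoff = 0.7,
                                  noise_sigma = 0.3, seed = 1,
                                  scfas = c("butyrate_e", "propionate_e",
                                            "acetate_e"),
                                  study_id = "S1", treatment = "control",
                                  dilution_factor = NA_real_) {
  set.seed(seed)
  rows <- lapply(names(cohort$profiles), function(sid) {
    base <- data.frame(sample_id = sid, study_id = study_id,
                       treatment = treatment,
                       dilution_factor = dilution_factor,
                       metabolite = scfas, predicted_flux = NA_real_,
                       measured_flux = NA_real_, status = "optimal",
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      cm <- build_community(cohort$profiles[[sid]], cohort$library, medium)
      sol <- solve_ctfba(cm, tradeoff)
      if (sol$status != "optimal") stop(sol$status, call. = FALSE)
      pr <- production_rates(sol)
      vapply(scfas, function(m) {
        i <- match(m, pr$metabolite)
        if (is.na(i)) 0 else pr$rate[i]
      }, numeric(1))
    }, error = function(e) conditionMessage(e))
    if (is.numeric(res)) {
      base$predicted_flux <- unname(res)
      eps <- stats::rnorm(length(scfas), 0, noise_sigma)
      base$measured_flux <- base$predicted_flux * exp(eps)
    } else {
      base$status <- res
    }
    base
  })
  do.call(rbind, rows)
}

#' Simulate clinical markers coupled to a flux
#'
#' Each marker j is generated as
#' beta_j * flux_z + 0.2 * age_z + 0.1 * sex + 0.15 * (vendor == "V2") +
#' N(0, 1) noise, with age ~ N(45, 12^2), sex ~ Bernoulli(0.5) and vendor
#' drawn uniformly from two levels. Zero betas give null markers for FDR
#' calibration.
#'
#' @param flux Numeric vector of per-sample fluxes.
#' @param effect_betas Numeric vector of standardized effects, one per
#'   marker (zeros allowed).
#' @param seed Seed.
#' @return A list with `markers` (data frame, one column per marker named
#'   `m001`, ...) and `covariates` (data frame: age, sex, vendor).
#' @export
simulate_clinical <- function(flux, effect_betas, seed = 1) {
  set.seed(seed)
  n <- length(flux)
  k <- length(effect_betas)
  covariates <- data.frame(
    age = stats::rnorm(n, 45, 12),
    sex = stats::rbinom(n, 1, 0.5),
    vendor = sample(c("V1", "V2"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  flux_z <- (flux - mean(flux)) / stats::sd(flux)
  age_z <- (covariates$age - mean(covariates$age)) / stats::sd(covariates$age)
  markers <- vapply(seq_len(k), function(j) {
    effect_betas[j] * flux_z + 0.2 * age_z + 0.1 * covariates$sex +
      0.15 * (covariates$vendor == "V2") + stats::rnorm(n)
  }, numeric(n))
  markers <- as.data.frame(markers)
  names(markers) <- sprintf("m%03d", seq_len(k))
  list(markers = markers, covariates = covariates)
}
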