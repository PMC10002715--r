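#' Pipeline configuration
#'
#' Bundles every tunable parameter of the prediction workflows with the
#' package defaults: tradeoff 0.7, abundance cutoff 0.001, completion
#' growth floor 0.3 1/h, host-absorption retention 0.2, fecal dilution
#' 0.1, probiotic fraction 0.05.
#'
#' @param tradeoff Cooperative tradeoff parameter.
#' @param cutoff Relative-abundance cutoff.
#' @param growth_floor Medium-completion growth floor (1/h).
#' @param retain Host-absorption retained fraction.
#' @param dilution_factor Ex-vivo global dilution.
#' @param probiotic_fraction Default probiotic relative abundance.
#' @param baseline_cut,increase_cut Responder-classification thresholds.
#' @param seed Seed stamped on outputs.
#' @param target SCFA whose production drives classification/screening.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tradeoff = 0.7, cutoff = 0.001,
                            growth_floor = 0.3, retain = 0.2,
                            dilution_factor = 0.1,
                            probiotic_fraction = 0.05,
                            baseline_cut = 15, increase_cut = 0.20,
                            seed = 1L, target = "butyrate_e") {
  stopifnot(tradeoff > 0, tradeoff <= 1, cutoff >= 0, cutoff < 1,
            growth_floor > 0, retain > 0, retain <= 1,
            probiotic_fraction >= 0, probiotic_fraction < 1)
  structure(list(tradeoff = tradeoff, cutoff = cutoff,
                 growth_floor = growth_floor, retain = retain,
                 dilution_factor = dilution_factor,
                 probiotic_fraction = probiotic_fraction,
                 baseline_cut = baseline_cut, increase_cut = increase_cut,
                 seed = as.integer(seed), target = target),
            class = "pipeline_config")
}

# Deterministic provenance fingerprint of a config (not cryptographic).
config_fingerprint <- function(config) {
  s <- paste(names(unlist(config)), format(unlist(config), digits = 17),
             collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

stamp <- function(table, config) {
  attr(table, "config_fingerprint") <- config_fingerprint(config)
  attr(table, "seed") <- config$seed
  table
}

#' Predict SCFA production for a cohort
#'
#' For every sample: filter rare taxa, match models, assemble the
#' community, solve cooperative tradeoff FBA on the given medium, and
#' extract production rates. Failures are isolated per sample: the
#' sample's rows are flagged in the `status` column and the run
#' continues.
#'
#' @param config A [pipeline_config()].
#' @param profiles Named list of [abundance_profile()]s.
#' @param library A [model_library()].
#' @param medium A `medium`.
#' @param scfas Metabolites to report.
#' @return Data frame with columns sample_id, metabolite,
#'   production_rate, community_growth, status; the config fingerprint
#'   and seed are attached as attributes.
#' @export
run_prediction <- function(config, profiles, library, medium,
                           scfas = c("butyrate_e", "propionate_e",
                                     "acetate_e")) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- lapply(profiles, function(prof) {
    base <- data.frame(sample_id = prof$sample_id, metabolite = scfas,
                       production_rate = NA_real_,
                       community_growth = NA_real_, status = "optimal",
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      cm <- build_community(prof, library, medium, config$cutoff)
      sol <- solve_ctfba(cm, config$tradeoff)
      if (sol$status != "optimal") stop(sol$status, call. = FALSE)
      pr <- production_rates(sol)
      list(rates = vapply(scfas, function(m) {
        i <- match(m, pr$metabolite)
        if (is.na(i)) 0 else pr$rate[i]
      }, numeric(1)), growth = sol$community_growth)
    }, error = function(e) conditionMessage(e))
    if (is.list(res)) {
      base$production_rate <- unname(res$rates)
      base$community_growth <- res$growth
    } else {
      base$status <- res
    }
    base
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  stamp(out, config)
}

#' Compare predicted and measured fluxes
#'
#' Z-scores measured and predicted fluxes within each study (and
#' metabolite), then reports the Pearson correlation per metabolite
#' across the pooled z-scored values.
#'
#' @param config A [pipeline_config()].
#' @param study_table A study table (as from [simulate_measurements()]):
#'   columns sample_id, study_id, metabolite, measured_flux,
#'   predicted_flux.
#' @return Data frame with one row per metabolite: metabolite, r, p, n.
#' @export
run_validation <- function(config, study_table) {
  ok <- study_table$status == "optimal" &
    !is.na(study_table$measured_flux) & !is.na(study_table$predicted_flux)
  tab <- study_table[ok, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no joined measured/predicted rows", call. = FALSE)
  tab <- zscore_within(tab, group_key = c("study_id", "metabolite"))
  rows <- lapply(split(tab, tab$metabolite), function(d) {
    pa <- pearson_assoc(d$predicted_flux, d$measured_flux)
    data.frame(metabolite = d$metabolite[1L], r = pa$r, p = pa$p, n = pa$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  stamp(out, config)
}

#' Classify diet response and screen interventions
#'
#' Solves every sample on both diets, labels each sample responder /
#' non-responder / regressor from its butyrate production, and runs the
#' intervention screen for the non-responders and regressors.
#'
#' @param config A [pipeline_config()].
#' @param profiles Named list of [abundance_profile()]s.
#' @param library A [model_library()].
#' @param media Named list of media; must contain `european` and
#'   `high_fiber`.
#' @param specs List of [intervention_spec()]s for the screen (default:
#'   pectin, inulin and a Faecalibacterium-style probiotic on each diet
#'   are left to the caller).
#' @return A list with `classification` (sample_id, butyrate_eu,
#'   butyrate_hf, label) and `screen` (one block of spec rows per
#'   flagged sample, with column sample_id).
#' @export
run_screen <- function(config, profiles, library, media, specs = list()) {
  stopifnot(all(c("european", "high_fiber") %in% names(media)))
  cls <- lapply(profiles, function(prof) {
    rate_on <- function(medium) {
      cm <- build_community(prof, library, medium, config$cutoff)
      sol <- solve_ctfba(cm, config$tradeoff)
      if (sol$status != "optimal") return(NA_real_)
      pr <- production_rates(sol)
      i <- match(config$target, pr$metabolite)
      if (is.na(i)) 0 else pr$rate[i]
    }
    eu <- tryCatch(rate_on(media$european), error = function(e) NA_real_)
    hf <- tryCatch(rate_on(media$high_fiber), error = function(e) NA_real_)
    label <- if (is.na(eu) || is.na(hf)) NA_character_ else {
      classify_response(eu, hf, config$baseline_cut, config$increase_cut)
    }
    data.frame(sample_id = prof$sample_id, butyrate_eu = eu,
               butyrate_hf = hf, label = label, stringsAsFactors = FALSE)
  })
  classification <- do.call(rbind, c(cls, make.row.names = FALSE))
  screen <- NULL
  flagged <- classification$sample_id[
    classification$label %in% c("non_responder", "regressor")]
  if (length(flagged) && length(specs)) {
    blocks <- lapply(flagged, function(sid) {
      sc <- screen_interventions(profiles[[sid]], library, specs, media,
                                 tradeoff = config$tradeoff,
                                 cutoff = config$cutoff,
                                 target = config$target)
      cbind(sample_id = sid, sc, stringsAsFactors = FALSE)
    })
    screen <- do.call(rbind, c(blocks, make.row.names = FALSE))
  }
  list(classification = stamp(classification, config),
       screen = if (!is.null(screen)) stamp(screen, config) else NULL)
}
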