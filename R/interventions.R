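#' Apply an in-silico probiotic to an abundance profile
#'
#' Existing abundances are scaled to (1 - fraction) of their values and
#' the probiotic taxon is added at `fraction` relative abundance (its
#' scaled abundance is incremented when already present), so the profile
#' still sums to 1.
#'
#' @param profile An [abundance_profile()].
#' @param taxon Taxon id of the probiotic (must have a model when used
#'   with a library downstream).
#' @param fraction Relative abundance to introduce, in \[0, 1);
#'   default 0.05.
#' @param library Optional [model_library()]; when given, the probiotic
#'   taxon must have a model in it.
#' @return An [abundance_profile()].
#' @export
apply_probiotic <- function(profile, taxon, fraction = 0.05, library = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (!is.null(library) && !taxon %in% names(library)) {
    stop(sprintf("probiotic taxon '%s' has no model in the library", taxon),
         call. = FALSE)
  }
  entries <- profile$entries / sum(profile$entries)
  if (fraction == 0) {
    return(abundance_profile(profile$sample_id, entries, profile$rank))
  }
  entries <- entries * (1 - fraction)
  if (taxon %in% names(entries)) {
    entries[[taxon]] <- entries[[taxon]] + fraction
  } else {
    entries[[taxon]] <- fraction
  }
  abundance_profile(profile$sample_id, entries, profile$rank)
}

#' Classify the butyrate response to a high-fiber diet
#'
#' Compares butyrate production under an average European diet
#' (`butyrate_eu`) and a high-fiber diet (`butyrate_hf`). Regressors
#' produce less on the high-fiber diet; non-responders produce below
#' `baseline_cut` on the European diet and gain less than `increase_cut`
#' relative on the high-fiber diet; everyone else is a responder.
#' Conventions for degenerate input: with `butyrate_eu` = 0 and
#' `butyrate_hf` > 0 the relative increase is treated as infinite
#' (responder); with both 0 the sample is a non-responder.
#'
#' @param butyrate_eu,butyrate_hf Nonnegative production rates
#'   (mmol/gDW/h).
#' @param baseline_cut European-diet production threshold (default 15
#'   mmol/gDW/h).
#' @param increase_cut Relative-increase threshold (default 0.20).
#' @return One of `"responder"`, `"non_responder"`, `"regressor"`.
#' @export
classify_response <- function(butyrate_eu, butyrate_hf, baseline_cut = 15,
                              increase_cut = 0.20) {
  stopifnot(length(butyrate_eu) == 1L, length(butyrate_hf) == 1L,
            butyrate_eu >= 0, butyrate_hf >= 0)
  if (butyrate_hf < butyrate_eu) return("regressor")
  rel_increase <- if (butyrate_eu == 0) {
    if (butyrate_hf > 0) Inf else 0
  } else {
    (butyrate_hf - butyrate_eu) / butyrate_eu
  }
  if (butyrate_eu < baseline_cut && rel_increase < increase_cut) {
    return("non_responder")
  }
  "responder"
}

#' Create an intervention specification
#'
#' @param diet Name of a diet/medium (resolved against the `media` list
#'   passed to [screen_interventions()]).
#' @param fiber Optional single fiber supplement (`"pectin"`, `"inulin"`,
#'   `"fos"`).
#' @param probiotic Optional probiotic taxon id.
#' @param probiotic_fraction Relative abundance of the probiotic
#'   (default 0.05).
#' @param label Human-readable spec label.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(diet, fiber = NULL, probiotic = NULL,
                              probiotic_fraction = 0.05,
                              label = NULL) {
  if (!is.null(fiber) && length(fiber) > 1L) {
    stop("at most one fiber per intervention spec", call. = FALSE)
  }
  stopifnot(probiotic_fraction >= 0, probiotic_fraction < 1)
  if (is.null(label)) {
    label <- paste(c(diet, fiber,
                     if (!is.null(probiotic)) paste0("+", probiotic)),
                   collapse = "/")
  }
  structure(list(diet = diet, fiber = fiber, probiotic = probiotic,
                 probiotic_fraction = probiotic_fraction, label = label),
            class = "intervention_spec")
}

#' Screen interventions for one individual
#'
#' Runs one full medium build + community assembly + cooperative tradeoff
#' solve per specification and reports the butyrate production rate of
#' each, flagging the argmax (ties broken by spec order). Infeasible
#' solves are flagged in the `status` column rather than aborting the
#' screen.
#'
#' @param profile An [abundance_profile()].
#' @param library A [model_library()].
#' @param specs List of [intervention_spec()]s.
#' @param media Named list of `medium` objects; spec `diet` fields must
#'   resolve into it.
#' @param tradeoff Tradeoff parameter (default 0.7).
#' @param cutoff Abundance cutoff (default 0.001).
#' @param target Metabolite whose production is screened
#'   (default `"butyrate_e"`).
#' @return A data frame with one row per spec: `spec`, `diet`, `fiber`,
#'   `probiotic`, `production`, `status`, `best`.
#' @export
screen_interventions <- function(profile, library, specs, media,
                                 tradeoff = 0.7, cutoff = 0.001,
                                 target = "butyrate_e") {
  stopifnot(length(specs) > 0)
  rows <- lapply(specs, function(sp) {
    row <- data.frame(
      spec = sp$label, diet = sp$diet,
      fiber = sp$fiber %||% NA_character_,
      probiotic = sp$probiotic %||% NA_character_,
      production = NA_real_, status = "optimal",
      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (!sp$diet %in% names(media)) {
        stop(sprintf("spec '%s': no medium named '%s'", sp$label, sp$diet),
             call. = FALSE)
      }
      medium <- media[[sp$diet]]
      if (!is.null(sp$fiber)) medium <- supplement_fiber(medium, sp$fiber)
      prof <- profile
      if (!is.null(sp$probiotic)) {
        prof <- apply_probiotic(prof, sp$probiotic, sp$probiotic_fraction,
                                library)
      }
      cm <- build_community(prof, library, medium, cutoff)
      sol <- solve_ctfba(cm, tradeoff)
      if (sol$status != "optimal") stop(sol$status, call. = FALSE)
      pr <- production_rates(sol)
      i <- match(target, pr$metabolite)
      if (is.na(i)) 0 else pr$rate[i]
    }, error = function(e) conditionMessage(e))
    if (is.numeric(res)) row$production <- res
    else row$status <- res
    row
  })
  out <- do.call(rbind, rows)
  out$best <- FALSE
  ok <- which(!is.na(out$production))
  if (length(ok)) out$best[ok[which.max(out$production[ok])]] <- TRUE
  out
}
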