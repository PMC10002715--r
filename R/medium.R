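#' Create a diet definition
#'
#' A diet is the raw, pre-transformation description of nutrient
#' availability: one maximum import flux per metabolite plus the boolean
#' flags that drive the medium pipeline. `host_absorbable` marks
#' components taken up in the small intestine (diluted by the absorption
#' step); `host_supplied` marks metabolites the host secretes into the gut
#' (mucins, bile acids; protected from carbon stripping); `residual_fiber`
#' marks indigestible fiber (resistant starch, dextrin, cellulose;
#' protected from stripping and rescaled by the ex-vivo slurry dilution
#' instead of the global dilution).
#'
#' @param name Diet name.
#' @param entries Named numeric vector, metabolite id -> flux
#'   (mmol/gDW/h), all nonnegative.
#' @param host_absorbable,host_supplied,residual_fiber,carbon_source_override
#'   Character vectors of metabolite ids carrying each flag (default:
#'   none).
#' @param formulas Named character vector of elemental formulas (optional,
#'   used by carbon stripping).
#' @return An object of class `diet_definition`.
#' @export
diet_definition <- function(name, entries, host_absorbable = character(),
                            host_supplied = character(),
                            residual_fiber = character(),
                            carbon_source_override = character(),
                            formulas = character()) {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (any(entries < 0)) stop("diet fluxes must be nonnegative", call. = FALSE)
  ids <- names(entries)
  tab <- data.frame(
    metabolite = ids,
    flux = as.numeric(entries),
    host_absorbable = ids %in% host_absorbable,
    host_supplied = ids %in% host_supplied,
    residual_fiber = ids %in% residual_fiber,
    carbon_source_override = ids %in% carbon_source_override,
    formula = ifelse(ids %in% names(formulas), formulas[ids], NA_character_),
    stringsAsFactors = FALSE
  )
  structure(list(name = name, table = tab), class = "diet_definition")
}

#' Read a diet definition from TSV/CSV
#'
#' Expected columns: `metabolite`, `flux`, and optionally the logical
#' columns `host_absorbable`, `host_supplied`, `residual_fiber`,
#' `carbon_source_override` and a character `formula` column. Header
#' required; '.' decimal separator.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @param name Diet name; defaults to the file stem.
#' @return A [diet_definition()].
#' @export
read_diet <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("metabolite", "flux") %in% names(tab))) {
    stop(sprintf("diet file '%s' must have columns metabolite, flux", path),
         call. = FALSE)
  }
  flag <- function(col) {
    if (col %in% names(tab)) tab$metabolite[as.logical(tab[[col]])]
    else character()
  }
  forms <- if ("formula" %in% names(tab)) {
    ok <- !is.na(tab$formula) & nzchar(tab$formula)
    stats::setNames(tab$formula[ok], tab$metabolite[ok])
  } else character()
  diet_definition(name, stats::setNames(tab$flux, tab$metabolite),
                  host_absorbable = flag("host_absorbable"),
                  host_supplied = flag("host_supplied"),
                  residual_fiber = flag("residual_fiber"),
                  carbon_source_override = flag("carbon_source_override"),
                  formulas = forms)
}

#' Write a diet definition to TSV
#'
#' @param diet A [diet_definition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diet <- function(diet, path) {
  utils::write.table(diet$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# A Medium is a diet after zero or more pipeline transformations: current
# import bounds, the carried-over flag/formula table, the original diet
# fluxes (needed by the residual-fiber rescale), and an ordered provenance
# log per metabolite from which the medium can be replayed bit-exactly.
new_medium <- function(entries, info, provenance) {
  stopifnot(is.numeric(entries))
  if (any(entries < 0)) stop("medium fluxes must be nonnegative", call. = FALSE)
  structure(list(entries = entries, info = info, provenance = provenance),
            class = "medium")
}

#' Initialize a medium from a diet definition
#'
#' The identity transformation: import bounds equal the diet fluxes and
#' the provenance log is opened.
#'
#' @param diet A [diet_definition()].
#' @return An object of class `medium`.
#' @export
as_medium <- function(diet) {
  stopifnot(inherits(diet, "diet_definition"))
  entries <- stats::setNames(diet$table$flux, diet$table$metabolite)
  prov <- stats::setNames(vector("list", length(entries)), names(entries))
  new_medium(entries, diet$table, prov)
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %d metabolites, total import capacity %.4g mmol/gDW/h\n",
              length(x$entries), sum(x$entries)))
  invisible(x)
}

med_flag <- function(medium, id, flag) {
  i <- match(id, medium$info$metabolite)
  !is.na(i) && isTRUE(medium$info[[flag]][i])
}

log_op <- function(medium, id, op, value = NULL) {
  medium$provenance[[id]] <- c(medium$provenance[[id]],
                               list(list(op = op, value = value)))
  medium
}

#' Dilute host-absorbable diet components
#'
#' Components the host can import are assumed to be partially absorbed in
#' the small intestine before reaching the colon; their import flux is
#' multiplied by `retain` (default 0.2, i.e. diluted to 20% of the diet
#' value). Unflagged components pass through unchanged.
#'
#' @param diet A [diet_definition()] or a [as_medium()] medium.
#' @param retain Fraction retained, in (0, 1].
#' @return A `medium`.
#' @export
apply_host_absorption <- function(diet, retain = 0.2) {
  stopifnot(retain > 0, retain <= 1)
  medium <- if (inherits(diet, "diet_definition")) as_medium(diet) else diet
  for (id in names(medium$entries)) {
    if (med_flag(medium, id, "host_absorbable")) {
      medium$entries[[id]] <- medium$entries[[id]] * retain
      medium <- log_op(medium, id, "scale", retain)
    }
  }
  medium
}

#' Add host-supplied metabolites to a medium
#'
#' Mucins, bile acids and similar host secretions are available to the
#' community regardless of diet. Entries already present keep the larger
#' of the two fluxes; the merge is recorded in the provenance log. Added
#' metabolites are flagged `host_supplied` so carbon stripping retains
#' them.
#'
#' @param medium A `medium`.
#' @param host_set Named numeric vector, metabolite -> flux (>= 0).
#' @return A `medium`.
#' @export
add_host_metabolites <- function(medium, host_set) {
  if (length(host_set) == 0L) return(medium)
  stopifnot(is.numeric(host_set), !is.null(names(host_set)),
            all(host_set >= 0))
  for (id in names(host_set)) {
    if (id %in% names(medium$entries)) {
      medium$entries[[id]] <- max(medium$entries[[id]], host_set[[id]])
      medium <- log_op(medium, id, "max", host_set[[id]])
      medium$info$host_supplied[medium$info$metabolite == id] <- TRUE
    } else {
      medium$entries[[id]] <- host_set[[id]]
      medium$provenance[[id]] <- list(list(op = "add", value = host_set[[id]]))
      medium$info <- rbind(medium$info, data.frame(
        metabolite = id, flux = NA_real_, host_absorbable = FALSE,
        host_supplied = TRUE, residual_fiber = FALSE,
        carbon_source_override = FALSE, formula = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  medium
}

#' Complete a medium so every model reaches a growth floor
#'
#' For each model, solves the linear program
#' minimize sum(e_m) subject to growth >= growth_floor with candidate
#' import bounds medium(m) + e_m, e_m >= 0, and applies the union (the
#' per-metabolite maximum over models) of the nonzero additions to the
#' medium. Because raising import bounds only relaxes the feasible set,
#' every input model grows at or above the floor on the returned medium.
#' The minimal-total-flux objective is a linear program whose support is
#' reported as the added metabolite set; its minimum-norm solution makes
#' ties deterministic.
#'
#' @param medium A `medium`.
#' @param models A list of [taxon_model()]s, a single model, or a
#'   `community_model`.
#' @param growth_floor Required growth rate (1/h), default 0.3.
#' @param candidates Metabolite ids eligible for addition; defaults to all
#'   exchangeable metabolites across the models.
#' @param tol Additions at or below `tol` are treated as zero
#'   (default 1e-6).
#' @return A list with elements `medium` (the completed medium) and
#'   `additions` (named numeric vector of added fluxes).
#' @export
complete_medium <- function(medium, models, growth_floor = 0.3,
                            candidates = NULL, tol = 1e-6) {
  stopifnot(growth_floor > 0)
  if (inherits(models, "taxon_model") || inherits(models, "community_model")) {
    models <- list(models)
  }
  if (is.null(candidates)) {
    candidates <- unique(unlist(lapply(models, function(m) {
      if (inherits(m, "community_model")) m$shared_metabolites
      else exchange_metabolites(m)
    })))
  }
  additions <- stats::setNames(numeric(length(candidates)), candidates)
  for (m in models) {
    e <- completion_lp(medium, m, growth_floor, candidates)
    additions <- pmax(additions, e)
  }
  additions <- additions[additions > tol]
  out <- medium
  for (id in names(additions)) {
    if (id %in% names(out$entries)) {
      out$entries[[id]] <- out$entries[[id]] + additions[[id]]
      out <- log_op(out, id, "increment", additions[[id]])
    } else {
      out$entries[[id]] <- additions[[id]]
      out$provenance[[id]] <- list(list(op = "add", value = additions[[id]]))
      out$info <- rbind(out$info, data.frame(
        metabolite = id, flux = NA_real_, host_absorbable = FALSE,
        host_supplied = FALSE, residual_fiber = FALSE,
        carbon_source_override = FALSE, formula = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  list(medium = out, additions = additions)
}

# Minimal-addition LP for one model: variables are the model fluxes plus
# one slack e_m per candidate exchange metabolite.
completion_lp <- function(medium, model, growth_floor, candidates) {
  if (inherits(model, "community_model")) {
    sys <- list(S = model$S, lb = model$lb, ub = model$ub,
                rxn_info = model$rxn_info)
    ex_idx <- which(model$rxn_info$type == "community_exchange")
    label <- model$sample_id
    growth_obj <- community_growth_objective(model)
  } else {
    sys <- model_system(model)
    ex_idx <- which(sys$rxn_info$is_exchange)
    label <- model$taxon_id
    growth_obj <- as.numeric(sys$rxn_info$is_biomass)
  }
  ex_met <- sys$rxn_info$metabolite[ex_idx]
  med <- function(id) if (id %in% names(medium$entries)) medium$entries[[id]] else 0
  n <- nrow(sys$rxn_info)
  lb <- sys$lb
  ub <- sys$ub
  # exchanges: uptake limited by medium (candidates get slack, below)
  for (k in seq_along(ex_idx)) {
    lb[ex_idx[k]] <- max(lb[ex_idx[k]], -med(ex_met[k]))
  }
  cand_k <- which(ex_met %in% candidates)
  ne <- length(cand_k)
  S_aug <- cbind(sys$S, matrix(0, nrow(sys$S), ne))
  lb_aug <- c(lb, rep(0, ne))
  ub_aug <- c(ub, rep(1000, ne))
  obj <- c(rep(0, n), rep(1, ne))
  # v_ex + e >= -medium  (slack relaxes the uptake bound)
  extra_A <- matrix(0, ne + 1L, n + ne)
  extra_rhs <- numeric(ne + 1L)
  for (j in seq_len(ne)) {
    i <- ex_idx[cand_k[j]]
    lb_aug[i] <- -1000  # bound handled by the slack row instead
    extra_A[j, i] <- 1
    extra_A[j, n + j] <- 1
    extra_rhs[j] <- -med(ex_met[cand_k[j]])
  }
  extra_A[ne + 1L, seq_len(n)] <- growth_obj
  extra_rhs[ne + 1L] <- growth_floor
  sol <- solve_lp(obj, S_aug, lb_aug, ub_aug, extra_A, extra_rhs,
                  maximize = FALSE)
  if (sol$status != "optimal") {
    stop(sprintf(
      "medium completion infeasible for model '%s': cannot reach growth %.3g even with all candidates opened",
      label, growth_floor), call. = FALSE)
  }
  e <- pmax(sol$x[n + seq_len(ne)], 0)
  out <- stats::setNames(numeric(length(candidates)), candidates)
  out[ex_met[cand_k]] <- e
  out
}

#' Strip carbon sources from a medium
#'
#' Removes every entry that is a carbon source — carbon_count(formula) > 0
#' or the `carbon_source_override` flag — except entries flagged
#' `residual_fiber` or `host_supplied`, which persist in stool.
#' Metabolites without a formula are treated as carbon-free unless
#' overridden.
#'
#' @param medium A `medium`.
#' @return A `medium`.
#' @export
strip_carbon <- function(medium) {
  for (id in names(medium$entries)) {
    i <- match(id, medium$info$metabolite)
    frm <- medium$info$formula[i]
    if (is_carbon_source(frm, medium$info$carbon_source_override[i]) &&
        !medium$info$residual_fiber[i] && !medium$info$host_supplied[i]) {
      medium$entries <- medium$entries[names(medium$entries) != id]
      medium <- log_op(medium, id, "remove")
    }
  }
  medium
}

#' Dilute a medium to the fecal microenvironment
#'
#' Non-residual entries are multiplied by `factor` (default 0.1, i.e.
#' diluted to 10% of their flux). Residual-fiber entries instead follow
#' the ex-vivo slurry dilution: when `fiber_dilution` is given (e.g. 5 for
#' a 1:5 slurry), each residual-fiber entry is set to its original diet
#' value divided by `fiber_dilution`, replacing — not composing with —
#' the global factor; without `fiber_dilution` they are diluted like
#' everything else.
#'
#' @param medium A `medium`.
#' @param factor Global dilution factor in (0, 1].
#' @param fiber_dilution Positive slurry dilution factor, or `NULL`.
#' @return A `medium`.
#' @export
dilute <- function(medium, factor = 0.1, fiber_dilution = NULL) {
  stopifnot(factor > 0, factor <= 1)
  if (!is.null(fiber_dilution) && fiber_dilution <= 0) {
    stop("fiber_dilution must be positive", call. = FALSE)
  }
  for (id in names(medium$entries)) {
    if (med_flag(medium, id, "residual_fiber") && !is.null(fiber_dilution)) {
      diet_value <- medium$info$flux[match(id, medium$info$metabolite)]
      medium$entries[[id]] <- diet_value / fiber_dilution
      medium <- log_op(medium, id, "set", diet_value / fiber_dilution)
    } else {
      medium$entries[[id]] <- medium$entries[[id]] * factor
      medium <- log_op(medium, id, "scale", factor)
    }
  }
  medium
}

FIBER_DEFAULTS <- c(pectin = 1.0, inulin = 10.0, fos = 100)

#' Supplement a medium with a single dietary fiber
#'
#' Sets the fiber's import flux to `amount`. Default amounts reflect the
#' carbon content of each fiber: 1.0 mmol/gDW/h for pectin, 10.0 for
#' inulin, 100 for fructo-oligosaccharide (FOS).
#'
#' @param medium A `medium`.
#' @param fiber One of `"pectin"`, `"inulin"`, `"fos"`.
#' @param amount Import flux; defaults per fiber.
#' @param metabolite_id Exchange-metabolite id the fiber resolves to in
#'   the model library's namespace (default `"<fiber>_e"`).
#' @return A `medium`.
#' @export
supplement_fiber <- function(medium, fiber, amount = NULL,
                             metabolite_id = paste0(fiber, "_e")) {
  if (!fiber %in% names(FIBER_DEFAULTS)) {
    stop(sprintf("unknown fiber '%s' (known: %s)", fiber,
                 paste(names(FIBER_DEFAULTS), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(amount)) amount <- FIBER_DEFAULTS[[fiber]]
  id <- metabolite_id
  if (id %in% names(medium$entries)) {
    medium$entries[[id]] <- amount
    medium <- log_op(medium, id, "set", amount)
  } else {
    medium$entries[[id]] <- amount
    medium$provenance[[id]] <- list(list(op = "add", value = amount))
    medium$info <- rbind(medium$info, data.frame(
      metabolite = id, flux = NA_real_, host_absorbable = FALSE,
      host_supplied = FALSE, residual_fiber = TRUE,
      carbon_source_override = FALSE, formula = NA_character_,
      stringsAsFactors = FALSE))
  }
  medium
}

#' Build a growth medium from a diet using a fixed recipe
#'
#' The in-vivo recipe is host absorption, then host-metabolite addition,
#' then completion against the model library. The ex-vivo recipe
#' additionally strips carbon sources and dilutes to the fecal
#' microenvironment (global factor 0.1; residual fiber rescaled by the
#' study's slurry dilution). The completion guarantee (every model grows
#' at or above `growth_floor`) is asserted on the pre-strip medium;
#' stripping may reduce growth afterwards.
#'
#' @param diet A [diet_definition()].
#' @param recipe `"in_vivo"` or `"ex_vivo"`.
#' @param models Model library (list of [taxon_model()]) for completion;
#'   `NULL` skips completion.
#' @param retain Host-absorption retained fraction (default 0.2).
#' @param host_set Named numeric vector of host-supplied metabolites to
#'   add (default none).
#' @param growth_floor Completion growth floor (default 0.3 1/h).
#' @param dilution_factor Ex-vivo global dilution (default 0.1).
#' @param fiber_dilution Ex-vivo slurry dilution factor (required for the
#'   ex-vivo recipe).
#' @param supplement Optional fiber name passed to [supplement_fiber()]
#'   after the recipe.
#' @return A `medium`.
#' @export
build_medium <- function(diet, recipe = c("in_vivo", "ex_vivo"),
                         models = NULL, retain = 0.2, host_set = NULL,
                         growth_floor = 0.3, dilution_factor = 0.1,
                         fiber_dilution = NULL, supplement = NULL) {
  recipe <- match.arg(recipe)
  if (recipe == "ex_vivo" && is.null(fiber_dilution)) {
    stop("ex_vivo recipe requires fiber_dilution", call. = FALSE)
  }
  medium <- apply_host_absorption(diet, retain)
  if (!is.null(host_set)) medium <- add_host_metabolites(medium, host_set)
  if (!is.null(models)) {
    medium <- complete_medium(medium, models, growth_floor)$medium
  }
  if (recipe == "ex_vivo") {
    medium <- strip_carbon(medium)
    medium <- dilute(medium, dilution_factor, fiber_dilution)
  }
  if (!is.null(supplement)) medium <- supplement_fiber(medium, supplement)
  medium
}

#' Replay a medium's provenance log against its raw diet
#'
#' Applies the recorded transformation log, in order, to the diet fluxes.
#' Because the log stores the exact numeric arguments of each operation,
#' the replay reproduces the built medium bit-exactly; a mismatch
#' indicates provenance corruption.
#'
#' @param diet The original [diet_definition()].
#' @param medium The built `medium`.
#' @return A named numeric vector of replayed fluxes (same order as
#'   `medium$entries`).
#' @export
replay_provenance <- function(diet, medium) {
  base <- stats::setNames(diet$table$flux, diet$table$metabolite)
  out <- numeric(0)
  ids <- union(names(base), names(medium$provenance))
  for (id in ids) {
    x <- if (id %in% names(base)) base[[id]] else NA_real_
    removed <- FALSE
    for (step in medium$provenance[[id]]) {
      switch(step$op,
        add = { x <- step$value; removed <- FALSE },
        scale = { x <- x * step$value },
        set = { x <- step$value },
        max = { x <- max(x, step$value) },
        increment = { x <- x + step$value },
        remove = { removed <- TRUE },
        stop(sprintf("unknown provenance op '%s'", step$op), call. = FALSE))
    }
    if (!removed && !is.na(x)) out[id] <- x
  }
  out[names(medium$entries)]
}
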