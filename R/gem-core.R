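#' Create a metabolite
#'
#' A metabolite is identified by an opaque string id, lives in one
#' compartment, and optionally carries an elemental formula and a set of
#' annotation flags. The flags used downstream by the medium pipeline are
#' `host_absorbable`, `host_supplied`, `residual_fiber` and
#' `carbon_source_override`.
#'
#' @param id Nonempty string, unique within a model.
#' @param name Free-text name; defaults to `id`.
#' @param compartment Compartment identifier (e.g. `"e"` for external,
#'   `"c"` for cytosol).
#' @param formula Optional elemental formula string such as `"C6H12O6"`.
#'   Validated on construction.
#' @param annotations Named list of boolean/string flags.
#' @return An object of class `metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "e", formula = NULL,
                       annotations = list()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("metabolite id must be a nonempty string", call. = FALSE)
  }
  if (!is.null(formula)) parse_formula(formula)  # validates
  structure(
    list(id = id, name = name, compartment = compartment,
         formula = formula, annotations = annotations),
    class = "metabolite"
  )
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative = consumed, positive =
#' produced. An exchange reaction touches exactly one metabolite with
#' coefficient -1, so that positive flux means secretion to the boundary
#' and negative flux means uptake.
#'
#' @param id Nonempty string.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds in mmol/gDW/h.
#' @param is_exchange Logical; boundary reaction flag.
#' @param is_biomass Logical; growth (objective) reaction flag.
#' @return An object of class `reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     is_exchange = FALSE, is_biomass = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("reaction id must be a nonempty string", call. = FALSE)
  }
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("stoichiometry must be a nonempty named numeric vector", call. = FALSE)
  }
  if (lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': lower_bound > upper_bound", id), call. = FALSE)
  }
  if (is_exchange &&
      !(length(stoichiometry) == 1L && stoichiometry[[1L]] == -1)) {
    stop(sprintf(
      "exchange reaction '%s' must touch exactly one metabolite with coefficient -1",
      id), call. = FALSE)
  }
  structure(
    list(id = id, stoichiometry = stoichiometry,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         is_exchange = isTRUE(is_exchange), is_biomass = isTRUE(is_biomass)),
    class = "reaction"
  )
}

#' Create a single-taxon genome-scale metabolic model
#'
#' @param taxon_id Taxon label at genus or species rank.
#' @param rank `"genus"` or `"species"`.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects; exactly one must have
#'   `is_biomass = TRUE`.
#' @return An object of class `taxon_model`.
#' @export
taxon_model <- function(taxon_id, rank = c("genus", "species"),
                        metabolites, reactions) {
  rank <- match.arg(rank)
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids", call. = FALSE)
  bio <- rxn_ids[vapply(reactions, `[[`, logical(1), "is_biomass")]
  if (length(bio) != 1L) {
    stop(sprintf("model '%s' must have exactly one biomass reaction (found %d)",
                 taxon_id, length(bio)), call. = FALSE)
  }
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  m <- structure(
    list(taxon_id = taxon_id, rank = rank, metabolites = metabolites,
         reactions = reactions, biomass_reaction_id = bio),
    class = "taxon_model"
  )
  dangling <- setdiff(
    unique(unlist(lapply(reactions, function(r) names(r$stoichiometry)))),
    met_ids)
  if (length(dangling)) {
    stop(sprintf("model '%s': reactions reference unknown metabolites: %s",
                 taxon_id, paste(dangling, collapse = ", ")), call. = FALSE)
  }
  m
}

#' @export
print.taxon_model <- function(x, ...) {
  n_ex <- sum(vapply(x$reactions, `[[`, logical(1), "is_exchange"))
  cat(sprintf("<taxon_model> %s (%s): %d metabolites, %d reactions (%d exchange)\n",
              x$taxon_id, x$rank, length(x$metabolites),
              length(x$reactions), n_ex))
  invisible(x)
}

#' Parse an elemental formula
#'
#' Tokenizes case-sensitively: an element is one uppercase letter optionally
#' followed by one lowercase letter ("C", "Cu", "Fe"), optionally followed by
#' a positive integer count.
#'
#' @param formula Formula string, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stop("formula must be a nonempty string", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  }
  elems <- sub("[0-9]+$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  if (any(counts <= 0L)) {
    stop(sprintf("formula '%s' has a nonpositive element count", formula),
         call. = FALSE)
  }
  out <- vapply(split(counts, elems), sum, integer(1))
  out[order(names(out))]
}

#' Count carbon atoms in a formula
#'
#' @param formula Elemental formula string.
#' @return Nonnegative integer count of element C (0 when absent).
#' @export
#' @examples
#' carbon_count("C6H12O6")  # 6
#' carbon_count("CuSO4")    # 0 -- "Cu" is one element token
carbon_count <- function(formula) {
  counts <- parse_formula(formula)
  if ("C" %in% names(counts)) unname(counts[["C"]]) else 0L
}

# Does a metabolite count as a carbon source for the medium pipeline?
# Formula-free metabolites are carbon-free unless carbon_source_override.
is_carbon_source <- function(formula, override = FALSE) {
  if (isTRUE(override)) return(TRUE)
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(FALSE)
  carbon_count(formula) > 0L
}

#' Structurally and functionally validate a taxon model
#'
#' Checks the type invariants (unique ids, one biomass reaction, consistent
#' bounds, exchange-reaction structure, no dangling metabolite references)
#' and then solves a feasibility LP with all exchange bounds opened to
#' check that the model can carry nonzero biomass flux at all.
#'
#' @param model A [taxon_model()].
#' @return A data frame of violations with columns `code` and `message`;
#'   zero rows when the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(code, message) {
    v[[length(v) + 1L]] <<- data.frame(code = code, message = message,
                                       stringsAsFactors = FALSE)
  }
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound) {
      add("inverted_bounds",
          sprintf("reaction '%s' has lower_bound > upper_bound", r$id))
    }
    if (r$is_exchange &&
        !(length(r$stoichiometry) == 1L && r$stoichiometry[[1L]] == -1)) {
      add("bad_exchange",
          sprintf("exchange reaction '%s' is not single-metabolite/-1", r$id))
    }
    missing <- setdiff(names(r$stoichiometry), names(model$metabolites))
    if (length(missing)) {
      add("dangling_metabolite",
          sprintf("reaction '%s' references unknown metabolites: %s",
                  r$id, paste(missing, collapse = ", ")))
    }
  }
  if (length(v) == 0L) {
    # feasibility: maximize biomass with all exchanges fully open
    sys <- model_system(model)
    open <- sys$rxn_info$is_exchange
    sys$lb[open] <- -1000
    sys$ub[open] <- 1000
    obj <- as.numeric(sys$rxn_info$is_biomass)
    sol <- solve_lp(obj, sys$S, sys$lb, sys$ub, maximize = TRUE)
    if (sol$status != "optimal" || sol$objective < 1e-6) {
      add("biomass_blocked",
          sprintf("model '%s' cannot carry biomass flux under open exchanges",
                  model$taxon_id))
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(code = character(), message = character(),
                  stringsAsFactors = FALSE)
}

# Build the stoichiometric system (S matrix, bounds, reaction metadata)
# of a single taxon model. Rows = metabolites, columns = reactions.
model_system <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  rxn_info <- data.frame(
    id = rxn_ids,
    lower_bound = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(model$reactions, `[[`, numeric(1), "upper_bound"),
    is_exchange = vapply(model$reactions, `[[`, logical(1), "is_exchange"),
    is_biomass = vapply(model$reactions, `[[`, logical(1), "is_biomass"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rxn_info$metabolite <- vapply(model$reactions, function(r) {
    if (r$is_exchange) names(r$stoichiometry) else NA_character_
  }, character(1))
  list(S = S, lb = rxn_info$lower_bound, ub = rxn_info$upper_bound,
       rxn_info = rxn_info)
}

# Exchangeable metabolite ids of a model (the single metabolite of each
# exchange reaction).
exchange_metabolites <- function(model) {
  unlist(lapply(model$reactions, function(r) {
    if (r$is_exchange) names(r$stoichiometry) else NULL
  }), use.names = FALSE)
}

#' Write a taxon model to disk
#'
#' The canonical internal format is a small documented JSON dialect; SBML
#' Level 3 with the FBC flux-bound attributes is supported for
#' interoperability with other constraint-based modeling tools.
#'
#' @param model A [taxon_model()].
#' @param path Output file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension
#'   when omitted.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- guess_model_format(path, format)
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

#' Load a taxon model from disk
#'
#' Exchange reactions are normalized on load to the package-wide sign
#' convention (metabolite coefficient -1; positive flux = secretion). SBML
#' files written with the opposite convention (metabolite as product) have
#' their exchange stoichiometry flipped and their bounds negated and
#' swapped.
#'
#' @param path Input file path.
#' @param format `"json"` or `"sbml"`; guessed from the extension when
#'   omitted.
#' @return A [taxon_model()].
#' @export
load_taxon_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  format <- guess_model_format(path, format)
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

guess_model_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("json", "sbml")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json")) "json"
  else if (ext %in% c("xml", "sbml")) "sbml"
  else stop(sprintf("cannot guess model format from '%s'; pass format=", path),
            call. = FALSE)
}

## ---- JSON dialect ---------------------------------------------------------
## {
##   "taxon_id": "...", "rank": "genus"|"species",
##   "metabolites": [{"id", "name", "compartment", "formula"?, "annotations"?}],
##   "reactions":   [{"id", "stoichiometry": {met: coef}, "lower_bound",
##                    "upper_bound", "is_exchange", "is_biomass"}]
## }

write_model_json <- function(model, path) {
  mets <- lapply(model$metabolites, function(m) {
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.null(m$formula)) out$formula <- m$formula
    if (length(m$annotations)) out$annotations <- m$annotations
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         is_exchange = r$is_exchange, is_biomass = r$is_biomass)
  })
  obj <- list(taxon_id = model$taxon_id, rank = model$rank,
              metabolites = unname(mets), reactions = unname(rxns))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_model_json <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("JSON parse failure in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  for (field in c("taxon_id", "rank", "metabolites", "reactions")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("model JSON '%s' lacks required field '%s'", path, field),
           call. = FALSE)
    }
  }
  mets <- lapply(obj$metabolites, function(m) {
    metabolite(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "e",
               formula = m$formula,
               annotations = m$annotations %||% list())
  })
  rxns <- lapply(obj$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(id = r$id, stoichiometry = st,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% 1000,
             is_exchange = isTRUE(r$is_exchange),
             is_biomass = isTRUE(r$is_biomass))
  })
  taxon_model(obj$taxon_id, obj$rank, mets, rxns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- SBML Level 3 + FBC ---------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, `xmlns:fbc` = FBC_NS,
    level = "3", version = "1", `fbc:required` = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sbml_id(model$taxon_id),
                             name = model$taxon_id,
                             `fbc:strict` = "true")
  xml2::xml_set_attr(mdl, "metaid", model$rank)  # rank stashed in metaid
  comps <- unique(vapply(model$metabolites, `[[`, character(1), "compartment"))
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    sp <- xml2::xml_add_child(
      los, "species", id = sanitize_sbml_id(m$id), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    if (!is.null(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
    if (length(m$annotations)) {
      ann <- xml2::xml_add_child(sp, "notes")
      xml2::xml_add_child(ann, "flags",
                          jsonlite::toJSON(m$annotations, auto_unbox = TRUE))
    }
  }
  # flux bounds live in global parameters, FBC style
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rid <- sanitize_sbml_id(r$id)
    for (side in c("lb", "ub")) {
      val <- if (side == "lb") r$lower_bound else r$upper_bound
      xml2::xml_add_child(lop, "parameter",
                          id = paste0(rid, "_", side),
                          value = format(val, digits = 17),
                          constant = "true")
    }
    rx <- xml2::xml_add_child(
      lor, "reaction", id = rid, reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      `fbc:lowerFluxBound` = paste0(rid, "_lb"),
      `fbc:upperFluxBound` = paste0(rid, "_ub"))
    if (r$is_biomass) xml2::xml_set_attr(rx, "metaid", "biomass")
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in seq_along(reac)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sanitize_sbml_id(names(reac)[i]),
                            stoichiometry = format(-reac[[i]], digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in seq_along(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sanitize_sbml_id(names(prod)[i]),
                            stoichiometry = format(prod[[i]], digits = 17),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
}

# SBML SIds cannot contain arbitrary characters; map to a safe subset.
# Ids used by the synthetic fixtures are already safe; this is a guard.
sanitize_sbml_id <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "SBML parse failure in '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop(sprintf("'%s': no <model> element", path), call. = FALSE)
  }
  rank <- xml2::xml_attr(mdl, "metaid")
  if (is.na(rank) || !rank %in% c("genus", "species")) rank <- "genus"
  params <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  mets <- lapply(xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns),
                 function(sp) {
    ann <- list()
    note <- xml2::xml_find_first(sp, ".//s:notes/s:flags", ns)
    if (!inherits(note, "xml_missing")) {
      ann <- as.list(jsonlite::fromJSON(xml2::xml_text(note)))
    }
    frm <- xml2::xml_attr(sp, "chemicalFormula")
    metabolite(id = xml2::xml_attr(sp, "id"),
               name = xml2::xml_attr(sp, "name") %|NA|% xml2::xml_attr(sp, "id"),
               compartment = xml2::xml_attr(sp, "compartment"),
               formula = if (is.na(frm)) NULL else frm,
               annotations = ann)
  })
  rxns <- lapply(xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns),
                 function(rx) {
    rid <- xml2::xml_attr(rx, "id")
    take <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath, ns)
      if (length(refs) == 0L) return(numeric(0))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
        xml2::xml_attr(refs, "species"))
    }
    st <- c(take(".//s:listOfReactants/s:speciesReference", -1),
            take(".//s:listOfProducts/s:speciesReference", +1))
    lb_id <- xml2::xml_attr(rx, "lowerFluxBound")
    ub_id <- xml2::xml_attr(rx, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(pvals)) pvals[[lb_id]] else -1000
    ub <- if (!is.na(ub_id) && ub_id %in% names(pvals)) pvals[[ub_id]] else 1000
    is_ex <- length(st) == 1L && grepl("^EX_", rid)
    if (is_ex && st[[1L]] == 1) {
      # opposite exchange convention (metabolite as product): normalize
      st[[1L]] <- -1
      tmp <- lb; lb <- -ub; ub <- -tmp
    }
    reaction(id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub,
             is_exchange = is_ex,
             is_biomass = identical(xml2::xml_attr(rx, "metaid"), "biomass"))
  })
  taxon_model(xml2::xml_attr(mdl, "name") %|NA|% xml2::xml_attr(mdl, "id"),
              rank, mets, rxns)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a
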