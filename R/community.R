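#' Create a relative-abundance profile
#'
#' @param sample_id Sample identifier.
#' @param entries Named numeric vector, taxon id -> relative abundance
#'   (all > 0). Kept as given; [filter_and_normalize()] (or
#'   `normalize = TRUE`) rescales to sum to 1.
#' @param rank `"genus"` or `"species"`; must match the model library.
#' @param normalize Rescale entries to sum to 1 (default `FALSE` so the
#'   abundance cutoff applies to the raw values).
#' @return An object of class `abundance_profile`.
#' @export
abundance_profile <- function(sample_id, entries, rank = c("genus", "species"),
                              normalize = FALSE) {
  rank <- match.arg(rank)
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (any(entries <= 0)) {
    stop("relative abundances must be strictly positive", call. = FALSE)
  }
  if (normalize) entries <- entries / sum(entries)
  structure(list(sample_id = sample_id, entries = entries, rank = rank),
            class = "abundance_profile")
}

#' Read abundance profiles from a TSV/CSV table
#'
#' Expected columns: `sample_id`, `taxon`, `relative_abundance` (header
#' required, UTF-8, '.' decimal).
#'
#' @param path File path; delimiter inferred from the extension.
#' @param rank Taxonomic rank of the table.
#' @return A named list of [abundance_profile()]s, one per sample.
#' @export
read_abundances <- function(path, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sample_id", "taxon", "relative_abundance")
  if (!all(need %in% names(tab))) {
    stop(sprintf("abundance table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(split(tab, tab$sample_id), function(d) {
    abundance_profile(d$sample_id[1L],
                      stats::setNames(d$relative_abundance, d$taxon), rank)
  })
  out[unique(tab$sample_id)]
}

#' Filter rare taxa and renormalize
#'
#' Taxa below the relative-abundance cutoff (default 0.001, i.e. 0.1%)
#' are removed and the remaining abundances renormalized to sum to 1.
#'
#' @param profile An [abundance_profile()].
#' @param cutoff Abundance cutoff in \[0, 1).
#' @return A filtered [abundance_profile()]; the number of removed taxa is
#'   attached as attribute `"n_removed"`.
#' @export
filter_and_normalize <- function(profile, cutoff = 0.001) {
  stopifnot(cutoff >= 0, cutoff < 1)
  keep <- profile$entries >= cutoff
  if (!any(keep)) {
    stop(sprintf("sample '%s': all taxa below the %.4g abundance cutoff",
                 profile$sample_id, cutoff), call. = FALSE)
  }
  out <- abundance_profile(profile$sample_id, profile$entries[keep],
                           profile$rank, normalize = TRUE)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Create a model library
#'
#' @param models List of [taxon_model()]s with unique taxon ids.
#' @return A named list of class `model_library`.
#' @export
model_library <- function(models) {
  ids <- vapply(models, `[[`, character(1), "taxon_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("model library has duplicate taxon ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  structure(stats::setNames(models, ids), class = "model_library")
}

#' Match profile taxa to library models
#'
#' Exact-identifier matching only. Unmatched taxa are reported with their
#' abundance mass and subsequently dropped (the community is rebuilt from
#' matched taxa only, with abundances renormalized).
#'
#' @param profile An [abundance_profile()].
#' @param library A [model_library()].
#' @param floor Warn when the matched abundance fraction falls below this
#'   value (default 0.5).
#' @return A list with `matches` (named list taxon -> model),
#'   `matched_fraction` (pre-renormalization abundance mass matched) and
#'   `unmatched` (named numeric vector of dropped abundances).
#' @export
match_models <- function(profile, library, floor = 0.5) {
  if (length(library) == 0L) {
    stop("model library is empty", call. = FALSE)
  }
  ranks <- unique(vapply(library, `[[`, character(1), "rank"))
  if (!identical(ranks, profile$rank)) {
    stop(sprintf("profile rank '%s' does not match library rank(s) %s",
                 profile$rank, paste(ranks, collapse = ",")), call. = FALSE)
  }
  hit <- names(profile$entries) %in% names(library)
  matched_fraction <- sum(profile$entries[hit])
  if (matched_fraction == 0) {
    stop(sprintf("sample '%s': no taxa matched the model library",
                 profile$sample_id), call. = FALSE)
  }
  if (matched_fraction < floor) {
    warning(sprintf(
      "sample '%s': only %.1f%% of abundance matched the model library",
      profile$sample_id, 100 * matched_fraction), call. = FALSE)
  }
  unmatched <- profile$entries[!hit]
  matches <- library[names(profile$entries)[hit]]
  list(matches = matches, matched_fraction = matched_fraction,
       unmatched = unmatched)
}

#' Assemble an abundance-weighted community model
#'
#' Each taxon's network is namespaced into its own compartments; its
#' exchange reaction for metabolite m becomes a transfer between the
#' taxon and a shared external pool whose contribution to the shared mass
#' balance carries the taxon's relative abundance a_i. Taxon fluxes thus
#' stay in mmol per gram dry weight of that taxon per hour, while shared
#' pools and community exchanges are per gram dry weight of total
#' community biomass. One community exchange is created per shared
#' metabolite, with lower bound -medium(m) (0 when the metabolite is
#' absent from the medium) and upper bound `exchange_ub`. Community
#' growth is the abundance-weighted sum of taxon growth rates.
#'
#' @param profile An [abundance_profile()] (normalized over matched taxa).
#' @param matches Named list taxon -> [taxon_model()], as returned by
#'   [match_models()].
#' @param medium A `medium`, or `NULL` for a closed environment.
#' @param matched_fraction Abundance mass retained by matching (recorded
#'   on the model).
#' @param exchange_ub Community exchange upper bound (default 1000).
#' @return An object of class `community_model` holding the block
#'   stoichiometric matrix, bounds and reaction metadata.
#' @export
assemble <- function(profile, matches, medium = NULL, matched_fraction = 1,
                     exchange_ub = 1000) {
  taxa <- names(profile$entries)
  missing <- setdiff(taxa, names(matches))
  if (length(missing)) {
    # drop unmatched taxa and renormalize over the matched ones
    profile <- abundance_profile(profile$sample_id,
                                 profile$entries[names(matches)],
                                 profile$rank, normalize = TRUE)
    taxa <- names(profile$entries)
  }
  if (abs(sum(profile$entries) - 1) > 1e-9) {
    stop(sprintf("sample '%s': profile must be normalized before assembly",
                 profile$sample_id), call. = FALSE)
  }
  a <- profile$entries
  cols <- list()   # one entry per reaction: list(id, stoich, lb, ub, meta)
  shared <- character(0)
  for (tx in taxa) {
    m <- matches[[tx]]
    for (r in m$reactions) {
      rid <- paste0(r$id, "__", tx)
      if (r$is_exchange) {
        met <- names(r$stoichiometry)
        shared <- union(shared, met)
        st <- stats::setNames(c(-1, a[[tx]]),
                              c(paste0(met, "__", tx), met))
        cols[[length(cols) + 1L]] <- list(
          id = rid, st = st, lb = r$lower_bound, ub = r$upper_bound,
          taxon = tx, type = "taxon_exchange", metabolite = met,
          is_biomass = FALSE)
      } else {
        st <- r$stoichiometry
        names(st) <- paste0(names(st), "__", tx)
        cols[[length(cols) + 1L]] <- list(
          id = rid, st = st, lb = r$lower_bound, ub = r$upper_bound,
          taxon = tx, type = "internal", metabolite = NA_character_,
          is_biomass = r$is_biomass)
      }
    }
  }
  med <- function(id) {
    if (!is.null(medium) && id %in% names(medium$entries)) {
      medium$entries[[id]]
    } else 0
  }
  for (met in shared) {
    cols[[length(cols) + 1L]] <- list(
      id = paste0("EX_", met, "__community"),
      st = stats::setNames(-1, met), lb = -med(met), ub = exchange_ub,
      taxon = NA_character_, type = "community_exchange", metabolite = met,
      is_biomass = FALSE)
  }
  rxn_ids <- vapply(cols, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) {
    stop(sprintf("assembly produced duplicate reaction ids: %s",
                 paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  met_ids <- unique(unlist(lapply(cols, function(cl) names(cl$st))))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(cols)) S[names(cols[[j]]$st), j] <- cols[[j]]$st
  rxn_info <- data.frame(
    id = rxn_ids,
    taxon = vapply(cols, `[[`, character(1), "taxon"),
    type = vapply(cols, `[[`, character(1), "type"),
    metabolite = vapply(cols, `[[`, character(1), "metabolite"),
    is_biomass = vapply(cols, `[[`, logical(1), "is_biomass"),
    stringsAsFactors = FALSE
  )
  structure(
    list(sample_id = profile$sample_id,
         members = data.frame(taxon_id = taxa, abundance = unname(a),
                              stringsAsFactors = FALSE),
         models = matches,
         S = S,
         lb = vapply(cols, `[[`, numeric(1), "lb"),
         ub = vapply(cols, `[[`, numeric(1), "ub"),
         rxn_info = rxn_info,
         shared_metabolites = shared,
         medium = medium,
         matched_fraction = matched_fraction),
    class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf(
    "<community_model> %s: %d taxa, %d reactions, %d shared metabolites\n",
    x$sample_id, nrow(x$members), ncol(x$S), length(x$shared_metabolites)))
  invisible(x)
}

# Objective vector of community growth: a_i on each taxon biomass column.
community_growth_objective <- function(cm) {
  obj <- numeric(ncol(cm$S))
  bio <- which(cm$rxn_info$is_biomass)
  obj[bio] <- cm$members$abundance[match(cm$rxn_info$taxon[bio],
                                         cm$members$taxon_id)]
  obj
}

#' Build a community model from profile, library and medium in one call
#'
#' Convenience wrapper: [filter_and_normalize()], [match_models()],
#' renormalization over matched taxa, then [assemble()].
#'
#' @param profile An [abundance_profile()].
#' @param library A [model_library()].
#' @param medium A `medium` or `NULL`.
#' @param cutoff Abundance cutoff (default 0.001).
#' @return A `community_model`.
#' @export
build_community <- function(profile, library, medium = NULL, cutoff = 0.001) {
  profile <- filter_and_normalize(profile, cutoff)
  mm <- match_models(profile, library)
  keep <- abundance_profile(profile$sample_id,
                            profile$entries[names(mm$matches)], profile$rank,
                            normalize = TRUE)
  assemble(keep, mm$matches, medium, matched_fraction = mm$matched_fraction)
}
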