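#' Maximize community growth (step 1 of cooperative tradeoff FBA)
#'
#' Solves the linear program maximizing the abundance-weighted community
#' growth rate mu_c = sum(a_i * mu_i) subject to steady state (S v = 0)
#' and flux bounds, with the medium applied as community-exchange lower
#' bounds during assembly.
#'
#' @param cm A `community_model`.
#' @return A list with `mu_max` (1/h), `solution` (flux vector), and
#'   `status` (`"optimal"`, `"infeasible"` or `"numeric_failure"`).
#' @export
solve_max_growth <- function(cm) {
  obj <- community_growth_objective(cm)
  sol <- solve_lp(obj, cm$S, cm$lb, cm$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(list(mu_max = NA_real_, solution = NULL, status = sol$status,
                message = sol$message))
  }
  list(mu_max = max(0, sol$objective), solution = sol$x, status = "optimal",
       message = "")
}

#' Cooperative tradeoff flux balance analysis
#'
#' Two-step scheme: step 1 finds the maximal community growth rate mu_c*
#' (a linear program); step 2 infers taxon-specific growth rates and
#' fluxes by minimizing the sum of squared taxon growth rates subject to
#' the same constraints plus the cooperativity constraint
#' sum(a_i * mu_i) >= tradeoff * mu_c* (a quadratic program). The tradeoff
#' parameter balances individual against community-wide growth; 0.7 is
#' the package default.
#'
#' @param cm A `community_model`.
#' @param tradeoff Fraction of maximal community growth to enforce, in
#'   (0, 1].
#' @return An object of class `flux_solution` with community and
#'   per-taxon growth rates, community exchange fluxes (positive =
#'   secretion), per-taxon exchange fluxes, the full flux vector, and a
#'   solver status.
#' @export
solve_ctfba <- function(cm, tradeoff = 0.7) {
  stopifnot(tradeoff > 0, tradeoff <= 1)
  step1 <- solve_max_growth(cm)
  if (step1$status != "optimal") {
    return(structure(list(status = step1$status, message = step1$message,
                          tradeoff = tradeoff), class = "flux_solution"))
  }
  obj <- community_growth_objective(cm)
  quad_w <- as.numeric(cm$rxn_info$is_biomass)
  sol <- solve_lp(numeric(ncol(cm$S)), cm$S, cm$lb, cm$ub,
                  extra_A = matrix(obj, 1L),
                  extra_rhs = tradeoff * step1$mu_max,
                  quad_w = quad_w)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, message = sol$message,
                          tradeoff = tradeoff, mu_max = step1$mu_max),
                     class = "flux_solution"))
  }
  v <- stats::setNames(sol$x, cm$rxn_info$id)
  bio <- cm$rxn_info$is_biomass
  taxon_growth <- stats::setNames(v[bio], cm$rxn_info$taxon[bio])
  cx <- cm$rxn_info$type == "community_exchange"
  exchange_fluxes <- stats::setNames(v[cx], cm$rxn_info$metabolite[cx])
  tex <- cm$rxn_info$type == "taxon_exchange"
  taxon_exchange_fluxes <- data.frame(
    taxon = cm$rxn_info$taxon[tex],
    metabolite = cm$rxn_info$metabolite[tex],
    flux = unname(v[tex]),
    stringsAsFactors = FALSE)
  structure(
    list(status = "optimal",
         community_growth = sum(obj * sol$x),
         taxon_growth = taxon_growth,
         exchange_fluxes = exchange_fluxes,
         taxon_exchange_fluxes = taxon_exchange_fluxes,
         fluxes = v,
         tradeoff = tradeoff,
         mu_max = step1$mu_max,
         residual = sol$residual,
         message = ""),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat(sprintf("<flux_solution> status: %s (%s)\n", x$status, x$message))
    return(invisible(x))
  }
  cat(sprintf("<flux_solution> community growth %.4g 1/h (tradeoff %.2g, max %.4g)\n",
              x$community_growth, x$tradeoff, x$mu_max))
  invisible(x)
}

#' Extract community production rates from a flux solution
#'
#' The production rate of a metabolite is the nonnegative part of its net
#' community exchange flux — what the community exports to its
#' environment (for gut models, what reaches the colonic epithelium).
#' Net-imported metabolites get rate 0; metabolites never exchanged are
#' absent.
#'
#' @param solution An optimal `flux_solution`.
#' @return An object of class `production_profile`: a data frame with
#'   columns `metabolite` and `rate` (mmol/gDW/h), with the solution
#'   attached as attribute `"basis"`.
#' @export
production_rates <- function(solution) {
  if (!identical(solution$status, "optimal")) {
    stop("production_rates requires an optimal flux solution", call. = FALSE)
  }
  out <- data.frame(metabolite = names(solution$exchange_fluxes),
                    rate = pmax(0, unname(solution$exchange_fluxes)),
                    stringsAsFactors = FALSE)
  attr(out, "basis") <- solution
  class(out) <- c("production_profile", "data.frame")
  out
}

#' Flux range of a community exchange at the growth optimum
#'
#' Minimizes and maximizes the community exchange flux of one metabolite
#' subject to the model constraints with every taxon growth rate fixed at
#' its returned value. A zero width means the exchange flux is uniquely
#' determined by the growth solution; a positive width quantifies
#' degeneracy (alternative flux distributions attaining the same growth),
#' as seen for weakly growth-coupled metabolites such as acetate.
#'
#' @param cm The `community_model` the solution came from.
#' @param solution An optimal `flux_solution`.
#' @param metabolite A shared metabolite id.
#' @param mu_tol Tolerance on the fixed growth rates (default 1e-6),
#'   absorbing solver feasibility noise.
#' @return Named numeric vector `c(min = , max = )`.
#' @export
flux_range_at_optimum <- function(cm, solution, metabolite, mu_tol = 1e-6) {
  if (!identical(solution$status, "optimal")) {
    stop("flux_range_at_optimum requires an optimal flux solution",
         call. = FALSE)
  }
  j <- which(cm$rxn_info$type == "community_exchange" &
             cm$rxn_info$metabolite == metabolite)
  if (length(j) != 1L) {
    stop(sprintf("'%s' has no community exchange", metabolite), call. = FALSE)
  }
  lb <- cm$lb
  ub <- cm$ub
  bio <- which(cm$rxn_info$is_biomass)
  mu <- solution$taxon_growth[cm$rxn_info$taxon[bio]]
  lb[bio] <- mu - mu_tol
  ub[bio] <- mu + mu_tol
  obj <- numeric(ncol(cm$S))
  obj[j] <- 1
  lo <- solve_lp(obj, cm$S, lb, ub, maximize = FALSE)
  hi <- solve_lp(obj, cm$S, lb, ub, maximize = TRUE)
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop(sprintf("flux range LP failed for '%s'", metabolite), call. = FALSE)
  }
  c(min = lo$objective, max = hi$objective)
}

#' Scan the tradeoff parameter
#'
#' For each tradeoff value, solves the two-step problem and reports the
#' fraction of taxa with positive growth, the community growth rate, and
#' the minimized sum of squared taxon growth rates. The conventional
#' parameter choice is the highest tradeoff that still lets most (>90%)
#' of taxa grow.
#'
#' @param cm A `community_model`.
#' @param grid Tradeoff values to scan.
#' @param growth_tol Growth rates above this count as growing
#'   (default 1e-6).
#' @return A data frame with columns `tradeoff`, `fraction_growing`,
#'   `community_growth`, `sum_sq_growth`.
#' @export
tradeoff_scan <- function(cm, grid = seq(0.1, 1, by = 0.1),
                          growth_tol = 1e-6) {
  rows <- lapply(grid, function(tf) {
    sol <- solve_ctfba(cm, tf)
    if (sol$status != "optimal") {
      return(data.frame(tradeoff = tf, fraction_growing = NA_real_,
                        community_growth = NA_real_, sum_sq_growth = NA_real_))
    }
    data.frame(tradeoff = tf,
               fraction_growing = mean(sol$taxon_growth > growth_tol),
               community_growth = sol$community_growth,
               sum_sq_growth = sum(sol$taxon_growth^2))
  })
  do.call(rbind, rows)
}
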