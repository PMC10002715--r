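#' Estimate a production flux from endpoint concentrations
#'
#' The production flux over an incubation is the concentration change
#' divided by the incubation time, optionally normalized to total biomass
#' via optical density (OD600) for in-vitro cultures. Negative values
#' indicate net consumption and are returned as-is.
#'
#' @param c_start,c_end Concentrations at the start and end of the
#'   incubation (same units).
#' @param hours Incubation time in hours (> 0).
#' @param od Optional OD600 (> 0) to normalize by.
#' @return Flux in concentration units per hour (per OD when given).
#' @export
endpoint_flux <- function(c_start, c_end, hours, od = NULL) {
  if (any(hours <= 0)) stop("hours must be positive", call. = FALSE)
  flux <- (c_end - c_start) / hours
  if (!is.null(od)) {
    if (any(od <= 0)) stop("od must be positive", call. = FALSE)
    flux <- flux / od
  }
  flux
}

#' Z-score flux columns within study groups
#'
#' Measured and predicted fluxes live on different scales (mmol/L/h vs
#' mmol/gDW/h) and differ between study protocols; Z-scoring within each
#' study makes them comparable under the assumption that the two are
#' proportional. Uses the sample (n-1) standard deviation, so each group
#' has mean 0 and sd 1 afterwards.
#'
#' @param table A data frame (a study table).
#' @param group_key Column name(s) defining the groups (default
#'   `"study_id"`).
#' @param cols Numeric columns to score (default `measured_flux` and
#'   `predicted_flux`, keeping those present).
#' @return The table with the scored columns replaced.
#' @export
zscore_within <- function(table, group_key = "study_id",
                          cols = c("measured_flux", "predicted_flux")) {
  cols <- intersect(cols, names(table))
  stopifnot(length(cols) > 0, all(group_key %in% names(table)))
  key <- interaction(table[group_key], drop = TRUE, sep = "/")
  for (g in levels(key)) {
    idx <- which(key == g)
    for (cl in cols) {
      x <- table[[cl]][idx]
      if (length(idx) < 2L || stats::sd(x) == 0 || anyNA(x)) {
        stop(sprintf(
          "group '%s': column '%s' is constant or has fewer than 2 values",
          g, cl), call. = FALSE)
      }
      table[[cl]][idx] <- (x - mean(x)) / stats::sd(x)
    }
  }
  table
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation with the p-value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return A list with `r`, `p`, and `n`.
#' @export
pearson_assoc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("pearson_assoc requires finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum): exact p-value for
#' combined sample size <= 20 without ties, otherwise the normal
#' approximation with continuity correction (and midranks for ties).
#'
#' @param values_a,values_b Nonempty numeric vectors.
#' @return A list with `U` (statistic for the first group), `p`
#'   (two-sided), and `exact` (whether the exact distribution was used).
#' @export
group_test <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  use_exact <- !has_ties && (length(values_a) + length(values_b)) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Covariate-adjusted association scan with BY-FDR control
#'
#' Regresses each clinical marker on a predicted flux with ordinary least
#' squares, adjusting for age, sex and microbiome sequencing vendor
#' (marker ~ flux + age + sex + vendor). Continuous variables (marker,
#' flux, age) are z-standardized so the reported beta is a standardized
#' coefficient; sex enters as a binary indicator and vendor as a
#' categorical indicator set. P-values come from the two-sided t-test on
#' the flux coefficient and are adjusted across markers with the
#' Benjamini-Yekutieli method, which controls the false discovery rate
#' under arbitrary dependence.
#'
#' Rows with missing values are dropped per marker (complete-case
#' analysis); markers with fewer than `min_n` complete cases are skipped
#' and reported in the `skipped` attribute. Perfect collinearity (an
#' aliased coefficient or a residual-free fit) raises an error naming the
#' marker.
#'
#' @param flux Numeric vector of predicted fluxes (one per sample).
#' @param markers Data frame of clinical markers (samples x markers).
#' @param covariates Data frame with columns `age` (numeric), `sex`
#'   (0/1 or factor), `vendor` (factor/character).
#' @param alpha FDR significance level (default 0.05).
#' @param min_n Minimum complete cases per marker (default 10).
#' @return A data frame with one row per tested marker: `marker_id`,
#'   `beta`, `se`, `p_raw`, `p_fdr`, `n`, `significant`; skipped markers
#'   are recorded in attribute `"skipped"`.
#' @export
clinical_scan <- function(flux, markers, covariates, alpha = 0.05,
                          min_n = 10) {
  stopifnot(nrow(markers) == length(flux), nrow(covariates) == length(flux),
            all(c("age", "sex", "vendor") %in% names(covariates)))
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  skipped <- character(0)
  rows <- list()
  for (mk in names(markers)) {
    y <- markers[[mk]]
    d <- data.frame(y = y, flux = flux, age = covariates$age,
                    sex = covariates$sex,
                    vendor = as.factor(covariates$vendor))
    d <- d[stats::complete.cases(d), , drop = FALSE]
    if (nrow(d) < min_n) {
      skipped <- c(skipped, mk)
      next
    }
    d$y <- zs(d$y)
    d$flux <- zs(d$flux)
    d$age <- zs(d$age)
    form <- if (nlevels(droplevels(d$vendor)) > 1L) {
      y ~ flux + age + sex + vendor
    } else {
      y ~ flux + age + sex
    }
    fit <- stats::lm(form, data = d)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop(sprintf("marker '%s': perfect collinearity in the design", mk),
           call. = FALSE)
    }
    sm <- summary(fit)
    if (sm$sigma < 1e-10) {
      stop(sprintf("marker '%s': residual-free fit (collinearity with a covariate)",
                   mk), call. = FALSE)
    }
    ct <- sm$coefficients["flux", ]
    rows[[mk]] <- data.frame(marker_id = mk, beta = unname(ct["Estimate"]),
                             se = unname(ct["Std. Error"]),
                             p_raw = unname(ct["Pr(>|t|)"]), n = nrow(d),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(marker_id = character(), beta = numeric(),
                      se = numeric(), p_raw = numeric(), p_fdr = numeric(),
                      n = integer(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BY")
  out$significant <- out$p_fdr < alpha
  attr(out, "skipped") <- skipped
  out
}
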