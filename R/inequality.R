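#' Population-weighted Lorenz curve of sub-national coverage
#'
#' Areas are ranked ascending by per-capita coverage (ties broken by area id
#' for determinism); the cumulative share of national "use"
#' (population x coverage) is plotted against the cumulative population
#' share.  With per-capita ranking the curve is convex and lies on or below
#' the diagonal.  Ranking by raw share of national use is available for
#' sensitivity analysis.
#'
#' @param coverage numeric in \[0, 1\], per area.
#' @param population positive numeric, per area.
#' @param ids optional area ids (used for deterministic tie-breaks).
#' @param rank_by `"per_capita"` (default) or `"share"` (raw use share).
#' @return tibble of class `wss_lorenz` with columns `q` (cumulative
#'   population share) and `L` (cumulative use share), starting at (0, 0)
#'   and ending at (1, 1).
#' @export
lorenz_curve <- function(coverage, population, ids = NULL,
                         rank_by = c("per_capita", "share")) {
  rank_by <- match.arg(rank_by)
  stopifnot(length(coverage) == length(population))
  if (any(population <= 0)) stop("populations must be positive")
  if (any(coverage < 0 | coverage > 1)) stop("coverage must lie in [0, 1]")
  if (is.null(ids)) ids <- as.character(seq_along(coverage))
  use <- population * coverage
  total_use <- sum(use)
  if (total_use == 0) stop("zero national use: Lorenz curve undefined")
  key <- switch(rank_by, per_capita = coverage, share = use / total_use)
  ord <- order(key, ids)
  q <- cumsum(population[ord]) / sum(population)
  L <- cumsum(use[ord]) / total_use
  out <- tibble::tibble(q = c(0, q), L = c(0, L))
  # endpoints exact despite floating accumulation
  out$q[nrow(out)] <- 1; out$L[nrow(out)] <- 1
  class(out) <- c("wss_lorenz", class(out))
  out
}

#' GINI coefficient from a Lorenz curve
#'
#' Twice the area between the diagonal of equality and the Lorenz curve,
#' via the trapezoid rule:
#' \eqn{G = 1 - \sum_i (q_i - q_{i-1})(L_i + L_{i-1})}.
#'
#' @param curve a `wss_lorenz` tibble.
#' @return scalar in \[0, 1\] (0 = perfect equality).
#' @export
gini <- function(curve) {
  q <- curve$q; L <- curve$L
  1 - sum(diff(q) * (L[-1] + L[-length(L)]))
}

#' GINI coefficient directly from coverage and population
#'
#' @inheritParams lorenz_curve
#' @return scalar GINI.
#' @export
gini_coverage <- function(coverage, population, ids = NULL,
                          rank_by = "per_capita") {
  gini(lorenz_curve(coverage, population, ids, rank_by))
}

#' Convert open-defecation prevalence to any-sanitation coverage
#'
#' Inequality in the open-defecation indicator is measured on households
#' *with* access to any type of sanitation, i.e. the complement.
#'
#' @param p_open_defecation numeric in \[0, 1\].
#' @return `1 - p_open_defecation`.
#' @export
od_to_any_sanitation <- function(p_open_defecation) {
  stopifnot(all(p_open_defecation >= 0 & p_open_defecation <= 1))
  1 - p_open_defecation
}

#' Cross-country regression of GINI on national coverage
#'
#' Ordinary least squares of the geographical GINI coefficient against
#' national coverage.  Because coverage is bounded, GINI declines with
#' coverage; the fitted line defines the inequality *expected* at a given
#' coverage level.  Fitted values are clipped to \[0, 1\] for reporting
#' only; residuals are computed unclipped.
#'
#' @param gini_by_country named numeric: point-estimate GINI per country.
#' @param coverage_by_country named numeric: national coverage per country
#'   (same names).
#' @return list of class `wss_gini_reg`: `slope`, `intercept`,
#'   `residual_se`, `expected` (named, clipped), `expected_raw` (unclipped),
#'   `residuals`.
#' @export
fit_gini_coverage_regression <- function(gini_by_country,
                                         coverage_by_country) {
  co <- names(gini_by_country)
  stopifnot(!is.null(co), setequal(co, names(coverage_by_country)))
  if (length(co) < 3) stop("need at least 3 countries")
  x <- coverage_by_country[co]; y <- gini_by_country[co]
  if (stats::var(x) == 0) stop("zero variance in national coverage")
  fit <- stats::lm(y ~ x)
  expected_raw <- stats::setNames(unname(stats::fitted(fit)), co)
  rs <- stats::resid(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    residual_se = sqrt(sum(rs^2) / (length(co) - 2)),
    expected = pmin(pmax(expected_raw, 0), 1),
    expected_raw = expected_raw,
    residuals = stats::setNames(unname(stats::resid(fit)), co)
  ), class = "wss_gini_reg")
}

#' Relative geographic inequality (RGI) scores
#'
#' RGI is the observed geographical GINI minus the GINI expected from the
#' cross-country regression at the country's national coverage; positive
#' values mean more sub-national inequality than expected at that coverage
#' level.  The regression is fitted once on posterior medians; uncertainty
#' is propagated through the per-draw GINIs: per draw,
#' RGI = GINI(draw) - expected(median coverage).  Significance: the 95% BCI
#' of RGI excluding 0 gives `"higher"`/`"lower"`, else `"none"`.
#'
#' @param gini_draws matrix (draws x countries, named columns) of per-draw
#'   GINIs, or a named numeric of point estimates (degenerate draws).
#' @param regression a `wss_gini_reg` fitted on the posterior-median GINIs.
#' @param indicator label carried into the output.
#' @return tibble: country, indicator, `gini` (median), `gini_lower/upper`,
#'   `expected_gini`, `rgi`, `rgi_lower/upper`, `significant`
#'   (`lower`/`higher`/`none`) and `arrow` (-1, 0, +1).
#' @export
rgi_scores <- function(gini_draws, regression,
                       indicator = "improved_water") {
  if (is.null(dim(gini_draws)))
    gini_draws <- matrix(gini_draws, nrow = 1,
                         dimnames = list(NULL, names(gini_draws)))
  co <- colnames(gini_draws)
  missing_c <- setdiff(co, names(regression$expected_raw))
  if (length(missing_c))
    stop("country absent from regression: ",
         paste(missing_c, collapse = ", "))
  rows <- lapply(co, function(cc) {
    g <- gini_draws[, cc]
    exp_g <- regression$expected_raw[[cc]]
    rgi <- g - exp_g
    gq <- stats::quantile(g, c(0.5, 0.025, 0.975), names = FALSE)
    rq <- stats::quantile(rgi, c(0.5, 0.025, 0.975), names = FALSE)
    # numerical guard: an interval within rounding error of 0 is not
    # evidence in either direction
    tol <- 1e-12
    sig <- if (rq[2] > tol) "higher" else if (rq[3] < -tol) "lower"
           else "none"
    tibble::tibble(country = cc, indicator = indicator,
                   gini = gq[1], gini_lower = gq[2], gini_upper = gq[3],
                   expected_gini = max(0, min(1, exp_g)),
                   rgi = rq[1], rgi_lower = rq[2], rgi_upper = rq[3],
                   significant = sig,
                   arrow = if (sig == "higher") 1L
                           else if (sig == "lower") -1L else 0L)
  })
  do.call(rbind, rows)
}

#' Per-draw geographical GINIs for all countries
#'
#' Convenience wrapper: computes, for each posterior draw, the
#' population-weighted GINI of district overall coverage within each
#' country.
#'
#' @param agg output of [aggregate_population()].
#' @param complement if `TRUE`, GINIs are computed on `1 - coverage`
#'   (used for the open-defecation indicator, see [od_to_any_sanitation()]).
#' @return matrix draws x countries.
#' @export
gini_draws_by_country <- function(agg, complement = FALSE) {
  countries <- colnames(agg$national)
  S <- nrow(agg$overall)
  out <- matrix(NA_real_, S, length(countries),
                dimnames = list(NULL, countries))
  for (co in countries) {
    sel <- names(agg$country_of)[agg$country_of == co]
    sel <- sel[!is.na(agg$P_total[sel]) & agg$P_total[sel] > 0]
    pop <- agg$P_total[sel]
    for (s in seq_len(S)) {
      cv <- agg$overall[s, sel]
      if (complement) cv <- od_to_any_sanitation(cv)
      out[s, co] <- gini_coverage(cv, pop, ids = sel)
    }
  }
  out
}
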