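#' True generating parameters for a synthetic scenario
#'
#' The generator inverts the analysis model: on the logit scale, coverage at
#' a survey site is a country intercept and linear time slope for its stratum
#' (urban/rural), plus an ICAR district effect and an unstructured province
#' effect.  Intercepts are centred at `t0` (default 2012), so `mu_alpha` is
#' the average logit-coverage in the prediction year.
#'
#' Defaults describe an indicator around 50% rural / 73% urban coverage in
#' 2012, rising by 0.05 (rural) and 0.03 (urban) per year on the logit scale,
#' with moderate between-country spread and sub-national heterogeneity.
#'
#' @param hierarchy an `admin_hierarchy`.
#' @param mu_alpha,mu_beta length-2 numeric `(rural, urban)`: grand mean
#'   intercept (logit coverage at `t0`) and slope (logit/year).
#' @param sigma_alpha,sigma_beta length-2: between-country SDs.
#' @param sigma_u ICAR SD (single value or named per country).
#' @param sigma_v province-effect SD.
#' @param t0 reference year.
#' @param u optional named vector overriding the drawn district effects.
#' @param v optional named vector overriding the drawn province effects.
#' @param seed integer seed.
#' @return list of class `wss_truth`.
#' @export
true_parameters <- function(hierarchy,
                            mu_alpha = c(rural = 0, urban = 1),
                            mu_beta = c(rural = 0.05, urban = 0.03),
                            sigma_alpha = c(rural = 0.5, urban = 0.5),
                            sigma_beta = c(rural = 0.02, urban = 0.02),
                            sigma_u = 0.5,
                            sigma_v = 0.3,
                            t0 = 2012,
                            u = NULL, v = NULL,
                            seed = 1L) {
  stopifnot(all(c(sigma_alpha, sigma_beta, sigma_u, sigma_v) >= 0))
  nm2 <- function(x) {
    if (length(x) == 1) x <- c(x, x)
    if (is.null(names(x))) names(x) <- c("rural", "urban")
    x
  }
  mu_alpha <- nm2(mu_alpha); mu_beta <- nm2(mu_beta)
  sigma_alpha <- nm2(sigma_alpha); sigma_beta <- nm2(sigma_beta)
  co <- hierarchy$countries
  if (is.null(names(sigma_u)))
    sigma_u <- stats::setNames(rep(sigma_u[1], length(co)), co)
  strata <- c("rural", "urban")
  withr::with_seed(seed, {
    alpha <- outer(stats::setNames(numeric(length(co)), co),
                   stats::setNames(numeric(2), strata), "+")
    beta <- alpha
    for (r in strata) {
      alpha[, r] <- stats::rnorm(length(co), mu_alpha[[r]], sigma_alpha[[r]])
      beta[, r] <- stats::rnorm(length(co), mu_beta[[r]], sigma_beta[[r]])
    }
    v_draw <- stats::setNames(
      stats::rnorm(length(hierarchy$admin1), 0, sigma_v), hierarchy$admin1)
    u_seed <- sample.int(.Machine$integer.max, 1)
  })
  u_draw <- sample_icar_effects(hierarchy, sigma_u, seed = u_seed)
  if (!is.null(u)) u_draw[names(u)] <- u
  if (!is.null(v)) v_draw[names(v)] <- v
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 alpha = alpha, beta = beta, u = u_draw, v = v_draw,
                 t0 = t0), class = "wss_truth")
}

#' Default per-indicator truths
#'
#' Water coverage is set higher and rising, improved sanitation lower and
#' rising slowly, and open defecation (a "bad" indicator) moderate and
#' declining.  Used by the demo pipeline; any subset may be overridden.
#'
#' @inheritParams true_parameters
#' @return named list of `wss_truth`, one per indicator.
#' @export
default_truths <- function(hierarchy, seed = 1L, t0 = 2012) {
  list(
    improved_water = true_parameters(
      hierarchy, mu_alpha = c(rural = 0.3, urban = 1.3),
      mu_beta = c(rural = 0.05, urban = 0.03), t0 = t0, seed = seed),
    improved_sanitation = true_parameters(
      hierarchy, mu_alpha = c(rural = -0.8, urban = 0.4),
      mu_beta = c(rural = 0.03, urban = 0.03), t0 = t0, seed = seed + 1L),
    open_defecation = true_parameters(
      hierarchy, mu_alpha = c(rural = -0.4, urban = -1.6),
      mu_beta = c(rural = -0.04, urban = -0.03), t0 = t0, seed = seed + 2L)
  )
}

#' Simulate a cluster-sample survey dataset
#'
#' Emits one row per survey site (cluster) with binomial household counts per
#' indicator, following DHS/MICS structure: sites nested in districts,
#' urban/rural strata, repeated survey years.  Districts selected as
#' unsampled receive no sites; a configured fraction of sites loses its
#' district label (province-only location).  Strata with zero population in a
#' district generate no sites there.
#'
#' @param hierarchy an `admin_hierarchy`.
#' @param populations tibble from [make_population_table()].
#' @param truths named list of `wss_truth` (one per indicator column), or a
#'   single `wss_truth` (then only `k_improved_water` is simulated from it
#'   and the other indicator columns are `NA`).
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @return tibble with columns `country, admin1, admin2, urban, year,
#'   n_households, k_improved_water, k_improved_sanitation,
#'   k_open_defecation, weight`; `admin2` is `NA` for province-only sites,
#'   `weight` is 1 (allocation happens later, see [allocate_admin1_only()]).
#' @export
simulate_survey <- function(hierarchy, populations, truths, config) {
  stopifnot(inherits(config, "wss_sim_config"))
  if (inherits(truths, "wss_truth"))
    truths <- list(improved_water = truths)
  indicators <- c("improved_water", "improved_sanitation", "open_defecation")
  pop <- as.data.frame(populations)
  rownames(pop) <- pop$admin2
  withr::with_seed(config$seed, {
    unsampled <- character(0)
    for (co in hierarchy$countries) {
      ids <- hierarchy$admin2[hierarchy$country_of_admin2 == co]
      n_un <- round(config$fraction_unsampled_admin2 * length(ids))
      if (n_un > 0) unsampled <- c(unsampled, sample(ids, n_un))
    }
    sampled <- setdiff(hierarchy$admin2, unsampled)
    grid <- expand.grid(admin2 = sampled, year = config$survey_years,
                        urban = c(0L, 1L),
                        site = seq_len(config$sites_per_admin2_per_year),
                        stringsAsFactors = FALSE)
    # drop strata with zero population
    pkeep <- ifelse(grid$urban == 1, pop[grid$admin2, "P_urban"],
                    pop[grid$admin2, "P_rural"]) > 0
    grid <- grid[pkeep, , drop = FALSE]
    n_sites <- nrow(grid)
    nh <- config$households_per_site
    out <- tibble::tibble(
      country = unname(hierarchy$country_of_admin2[grid$admin2]),
      admin1 = unname(hierarchy$admin2_of[grid$admin2]),
      admin2 = grid$admin2,
      urban = grid$urban,
      year = grid$year,
      n_households = rep(nh, n_sites),
      k_improved_water = NA_integer_,
      k_improved_sanitation = NA_integer_,
      k_open_defecation = NA_integer_,
      weight = rep(1, n_sites))
    stratum <- ifelse(grid$urban == 1, "urban", "rural")
    for (ind in indicators) {
      tr <- truths[[ind]]
      if (is.null(tr)) next
      eta <- tr$alpha[cbind(out$country, stratum)] +
        tr$beta[cbind(out$country, stratum)] * (out$year - tr$t0) +
        tr$u[out$admin2] + tr$v[out$admin1]
      out[[paste0("k_", ind)]] <-
        stats::rbinom(n_sites, nh, stats::plogis(eta))
    }
    if (config$fraction_admin1_only > 0 && n_sites > 0) {
      n_a1 <- round(config$fraction_admin1_only * n_sites)
      if (n_a1 > 0) {
        idx <- sample(n_sites, n_a1)
        out$admin2[idx] <- NA_character_
      }
    }
    out
  })
}

#' Write / read the canonical site-level survey CSV
#'
#' @param sites tibble as produced by [simulate_survey()].
#' @param path file path.
#' @export
write_survey_csv <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  for (col in c("country", "admin1", "admin2"))
    if (col %in% names(x)) x[[col]] <- as.character(x[[col]])
  for (col in grep("^(k_|n_)|^urban$|^year$", names(x), value = TRUE))
    x[[col]] <- as.integer(x[[col]])
  if ("weight" %in% names(x)) x$weight <- as.numeric(x$weight)
  tibble::as_tibble(x)
}

#' Serialize generating truth for test harnesses
#'
#' @param truth a `wss_truth`.
#' @param path file path (`.yaml` or `.json` by extension).
#' @export
write_truth <- function(truth, path) {
  x <- lapply(unclass(truth), function(z) {
    if (is.matrix(z)) list(rows = rownames(z), cols = colnames(z),
                           values = as.numeric(z))
    else if (!is.null(names(z))) as.list(z)
    else z
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
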