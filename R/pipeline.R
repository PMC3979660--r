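#' Build an admin hierarchy from population and adjacency tables
#'
#' Constructor for real (non-simulated) inputs: the population table defines
#' the universe of districts and their nesting; the edge list defines
#' within-country adjacency.
#'
#' @param populations data frame with columns `country`, `admin1`, `admin2`,
#'   `P_urban`, `P_rural`.
#' @param adjacency two-column character matrix of admin2 pairs.
#' @return an `admin_hierarchy`.
#' @export
hierarchy_from_tables <- function(populations, adjacency) {
  need <- c("country", "admin1", "admin2", "P_urban", "P_rural")
  stopifnot(all(need %in% names(populations)))
  pop <- as.data.frame(populations)
  admin2 <- pop$admin2
  if (anyDuplicated(admin2)) stop("duplicated admin2 in population table")
  admin2_of <- stats::setNames(pop$admin1, admin2)
  a1 <- unique(pop[c("admin1", "country")])
  if (anyDuplicated(a1$admin1))
    stop("admin1 mapped to multiple countries")
  admin1_of <- stats::setNames(a1$country, a1$admin1)
  country_of_admin2 <- stats::setNames(unname(admin1_of[pop$admin1]),
                                       admin2)
  if (NROW(adjacency)) {
    bad <- !(adjacency[, 1] %in% admin2 & adjacency[, 2] %in% admin2)
    if (any(bad)) stop("adjacency references unknown admin2")
    cross <- country_of_admin2[adjacency[, 1]] !=
      country_of_admin2[adjacency[, 2]]
    if (any(cross)) stop("adjacency crosses a country boundary")
  }
  deg <- table(factor(c(adjacency), levels = admin2))
  structure(list(countries = unique(a1$country), admin1 = a1$admin1,
                 admin2 = admin2, admin1_of = admin1_of,
                 admin2_of = admin2_of,
                 country_of_admin2 = country_of_admin2,
                 adjacency = adjacency, islands = admin2[deg == 0]),
            class = "admin_hierarchy")
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, fit = 23L, impute = 37L, predict = 41L,
               inequality = 53L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full coverage-and-inequality pipeline
#'
#' Orchestrates simulate (or load) -> allocate -> fit -> predict ->
#' aggregate -> inequality, writing CSV outputs, a diagnostics table and a
#' JSON manifest.  All randomness derives deterministically from `seed`.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{scenario}{a [sim_config()] for synthetic runs, OR}
#'     \item{sites_csv, adjacency_file, populations_csv}{paths for real
#'       inputs (populations CSV must carry `country`, `admin1`, `admin2`
#'       columns);}
#'     \item{indicators}{character vector (default `"improved_water"`);}
#'     \item{n_chains, n_iter, n_warmup, thin}{sampler settings;}
#'     \item{year}{prediction year (default 2012); `t0` reference year;}
#'     \item{out_dir}{output directory;}
#'     \item{seed}{integer seed.}
#'   }
#'   A YAML file path may be given instead of a list.
#' @return invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  indicators <- config$indicators %||% "improved_water"
  year <- config$year %||% 2012
  t0 <- config$t0 %||% 2012
  n_chains <- config$n_chains %||% 2
  n_iter <- config$n_iter %||% 2000
  n_warmup <- config$n_warmup %||% 1000
  thin <- config$thin %||% 1L

  has_scenario <- !is.null(config$scenario)
  has_real <- !is.null(config$sites_csv)
  if (has_scenario == has_real)
    stop("config must supply exactly one of scenario / real inputs")

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (has_scenario) {
    sc <- config$scenario
    if (!inherits(sc, "wss_sim_config")) sc <- do.call(sim_config, sc)
    sc$seed <- stage_seed(seed, "simulate")
    sim <- run_stage("simulate", {
      hierarchy <- build_admin_hierarchy(sc)
      populations <- make_population_table(hierarchy, seed = sc$seed)
      truths <- default_truths(hierarchy, seed = sc$seed, t0 = t0)
      sites <- simulate_survey(hierarchy, populations, truths, sc)
      list(hierarchy = hierarchy, populations = populations, sites = sites)
    })
    hierarchy <- sim$hierarchy
    populations <- sim$populations
    sites <- sim$sites
    write_survey_csv(sites, file.path(out_dir, "sites.csv"))
    utils::write.csv(as.data.frame(populations),
                     file.path(out_dir, "populations.csv"),
                     row.names = FALSE)
    write_adjacency(hierarchy, file.path(out_dir, "adjacency.txt"))
  } else {
    loaded <- run_stage("load", {
      if (is.null(config$adjacency_file) ||
          !file.exists(config$adjacency_file))
        stop("adjacency file missing: ",
             config$adjacency_file %||% "(not set)")
      populations <- tibble::as_tibble(
        utils::read.csv(config$populations_csv,
                        stringsAsFactors = FALSE))
      adjacency <- read_adjacency(config$adjacency_file)
      hierarchy <- hierarchy_from_tables(populations, adjacency)
      sites <- read_survey_csv(config$sites_csv)
      list(hierarchy = hierarchy, populations = populations, sites = sites)
    })
    hierarchy <- loaded$hierarchy
    populations <- loaded$populations
    sites <- loaded$sites
  }

  sites <- run_stage("allocate", allocate_admin1_only(sites, hierarchy))

  estimates <- list(); ineq <- list(); lorenz_out <- list()
  diag_rows <- list()
  for (ind in indicators) {
    fit <- run_stage("fit", {
      md <- build_model_data(sites, hierarchy, indicator = ind, t0 = t0)
      run_mcmc(md, n_chains = n_chains, n_iter = n_iter,
               n_warmup = n_warmup, thin = thin,
               seed = stage_seed(seed, "fit"))
    })
    dg <- diagnostics(fit)
    dg$summary$indicator <- ind
    diag_rows[[ind]] <- dg$summary
    pred <- run_stage("predict", {
      completed <- impute_unsampled_effects(
        fit, hierarchy, seed = stage_seed(seed, "impute"))
      predict_coverage(completed, hierarchy, year = year,
                       seed = stage_seed(seed, "predict"))
    })
    agg <- run_stage("aggregate", aggregate_population(pred, populations))
    estimates[[ind]] <- summarize_coverage(pred, agg, indicator = ind)
    if (ncol(agg$national) >= 3) {
      res <- run_stage("inequality", {
        gd <- gini_draws_by_country(agg,
                                    complement = ind == "open_defecation")
        g_med <- apply(gd, 2, stats::median)
        nat_med <- apply(agg$national, 2, stats::median)
        if (ind == "open_defecation")
          nat_med <- od_to_any_sanitation(nat_med)
        reg <- fit_gini_coverage_regression(g_med, nat_med)
        list(rgi = rgi_scores(gd, reg, indicator = ind), reg = reg,
             nat = nat_med)
      })
      ineq[[ind]] <- res$rgi
      lorenz_out[[ind]] <- do.call(rbind, lapply(
        colnames(agg$national), function(co) {
          sel <- names(agg$country_of)[agg$country_of == co]
          cv <- apply(agg$overall[, sel, drop = FALSE], 2, stats::median)
          if (ind == "open_defecation") cv <- od_to_any_sanitation(cv)
          lc <- lorenz_curve(cv, agg$P_total[sel], ids = sel)
          tibble::tibble(country = co, indicator = ind, q = lc$q, L = lc$L)
        }))
    }
  }

  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  est_all <- do.call(rbind, estimates)
  utils::write.csv(fmt(est_all),
                   file.path(out_dir, "coverage_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(do.call(rbind, diag_rows)),
                   file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
  if (length(ineq)) {
    utils::write.csv(fmt(do.call(rbind, ineq)),
                     file.path(out_dir, "inequality.csv"),
                     row.names = FALSE)
    utils::write.csv(fmt(do.call(rbind, lorenz_out)),
                     file.path(out_dir, "lorenz.csv"), row.names = FALSE)
  }
  if (!is.null(config$boundaries_geojson))
    write_geojson(est_all, config$boundaries_geojson,
                  file.path(out_dir, "coverage.geojson"))

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("wsscover")),
    indicators = indicators, year = year,
    sampler = list(n_chains = n_chains, n_iter = n_iter,
                   n_warmup = n_warmup, thin = thin),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach coverage estimates to GeoJSON boundaries
#'
#' Writes a FeatureCollection whose features carry, per indicator,
#' `<ind>_median`, `<ind>_lower`, `<ind>_upper`, `<ind>_flag` properties for
#' the overall-population estimates.  Features are matched on an `admin2`
#' property (or feature `id`); unmatched features pass through with a
#' warning.
#'
#' @param estimates coverage estimates tibble ([summarize_coverage()]).
#' @param boundaries path to a GeoJSON FeatureCollection, or an equivalent
#'   parsed list.
#' @param path output file path.
#' @export
write_geojson <- function(estimates, boundaries, path) {
  gj <- if (is.character(boundaries))
    jsonlite::read_json(boundaries) else boundaries
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  est <- as.data.frame(estimates[estimates$stratum == "overall", ])
  unmatched <- character(0)
  gj$features <- lapply(gj$features, function(f) {
    id <- f$properties$admin2 %||% f$id
    rows <- est[est$admin2 %in% id, , drop = FALSE]
    if (!nrow(rows)) {
      unmatched <<- c(unmatched, as.character(id %||% "(no id)"))
      return(f)
    }
    for (i in seq_len(nrow(rows))) {
      ind <- rows$indicator[i]
      f$properties[[paste0(ind, "_median")]] <- rows$median[i]
      f$properties[[paste0(ind, "_lower")]] <- rows$lower[i]
      f$properties[[paste0(ind, "_upper")]] <- rows$upper[i]
      f$properties[[paste0(ind, "_flag")]] <- rows$flag[i]
    }
    f
  })
  if (length(unmatched))
    warning("features without estimates: ",
            paste(unmatched, collapse = ", "))
  if (!nrow(est)) warning("empty estimates; boundaries passed through")
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
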