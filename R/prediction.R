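#' Complete district effects for unsampled districts
#'
#' For every country that has directly-located district data, the ICAR
#' effects of districts without data are drawn, per posterior draw, from the
#' joint Gaussian conditional of the intrinsic CAR given the sampled
#' districts' effects (block solve of the precision system on the country's
#' full adjacency graph — see [icar_conditional()]).  Countries with data
#' located only to province level fall back to province-level prediction
#' (`basis = "admin1-level"`, no district effect).  Missing districts in
#' components with no sampled district (including islands) get effect 0 with
#' a warning (`basis = "imputed"`).
#'
#' @param draws a `wss_draws`.
#' @param hierarchy the full `admin_hierarchy`.
#' @param seed integer seed for the conditional draws.
#' @return object of class `wss_completed`: pooled draw matrices for all
#'   parameter blocks, `$u_all` (pooled draws x all predictable districts)
#'   and `$basis` (named character per district:
#'   sampled / imputed / admin1-level).
#' @export
impute_unsampled_effects <- function(draws, hierarchy, seed = 1L) {
  stopifnot(inherits(draws, "wss_draws"))
  data <- draws$data
  blocks <- c("mu_alpha", "mu_beta", "alpha", "beta", "sigma_alpha",
              "sigma_beta", "sigma_u", "sigma_v", "v")
  pooled <- lapply(stats::setNames(blocks, blocks),
                   function(b) pooled_draws(draws, b))
  u_obs <- pooled_draws(draws, "u")
  S <- nrow(u_obs)

  target_admin2 <- hierarchy$admin2[
    hierarchy$country_of_admin2[hierarchy$admin2] %in% data$country_levels]
  u_all <- matrix(0, S, length(target_admin2),
                  dimnames = list(NULL, target_admin2))
  basis <- stats::setNames(rep("imputed", length(target_admin2)),
                           target_admin2)
  obs_ids <- data$admin2_levels
  basis[intersect(target_admin2, obs_ids)] <- "sampled"
  u_all[, intersect(target_admin2, obs_ids)] <-
    u_obs[, intersect(target_admin2, obs_ids)]

  withr::with_seed(seed, {
    for (cix in seq_along(data$country_levels)) {
      co <- data$country_levels[cix]
      ids <- hierarchy$admin2[hierarchy$country_of_admin2 == co]
      if (!data$country_has_admin2_data[cix]) {
        basis[ids] <- "admin1-level"
        u_all[, ids] <- 0
        next
      }
      obs_c <- intersect(ids, obs_ids)
      miss <- setdiff(ids, obs_c)
      if (!length(miss)) next
      edges_c <- hierarchy$adjacency[
        hierarchy$adjacency[, 1] %in% ids, , drop = FALSE]
      cond <- icar_conditional(ids, edges_c,
                               stats::setNames(numeric(length(obs_c)),
                                               obs_c))
      if (length(cond$unanchored))
        warning("country ", co, ": ", length(cond$unanchored),
                " unsampled district(s) in components without data; ",
                "effect set to 0")
      anchored <- setdiff(miss, cond$unanchored)
      if (length(anchored)) {
        L <- graph_laplacian(ids, edges_c)
        Qmm <- L[anchored, anchored, drop = FALSE]
        Qmo <- L[anchored, obs_c, drop = FALSE]
        A <- -solve(Qmm, Qmo)              # conditional mean operator
        R <- chol(Qmm)                     # cov = sigma^2 Qmm^{-1}
        sig <- pooled$sigma_u[, co]
        for (s in seq_len(S)) {
          mu_s <- as.numeric(A %*% u_obs[s, obs_c])
          z <- stats::rnorm(length(anchored))
          u_all[s, anchored] <- mu_s + sig[s] * backsolve(R, z)
        }
      }
    }
  })
  structure(c(pooled, list(u_all = u_all, basis = basis, data = data,
                           S = S)),
            class = "wss_completed")
}

#' Posterior draws of coverage per district and stratum
#'
#' For each draw, coverage is the inverse-logit of the country
#' intercept + slope x (year - t0) + district effect + province effect.
#' Districts with `basis = "admin1-level"` omit the district effect.
#' Province effects for provinces absent from the data are drawn from their
#' prior Normal(0, sigma_v) per draw.
#'
#' @param completed a `wss_completed` from [impute_unsampled_effects()].
#' @param hierarchy the full `admin_hierarchy`.
#' @param year prediction year (default 2012).
#' @param seed seed for prior draws of unobserved province effects.
#' @return object of class `wss_prediction`: `$p` array
#'   (draws x districts x strata `rural`,`urban`), `$admin2`, `$basis`,
#'   `$year`.
#' @export
predict_coverage <- function(completed, hierarchy, year = 2012, seed = 1L) {
  stopifnot(inherits(completed, "wss_completed"))
  data <- completed$data
  a2 <- colnames(completed$u_all)
  S <- completed$S
  dt <- year - data$t0
  a1_of <- hierarchy$admin2_of[a2]
  co_of <- hierarchy$country_of_admin2[a2]
  # province effects: observed from draws, unobserved from prior
  all_a1 <- unique(a1_of)
  v_mat <- matrix(0, S, length(all_a1), dimnames = list(NULL, all_a1))
  obs_a1 <- intersect(all_a1, data$admin1_levels)
  v_mat[, obs_a1] <- completed$v[, obs_a1]
  new_a1 <- setdiff(all_a1, obs_a1)
  if (length(new_a1)) {
    withr::with_seed(seed, {
      for (k in new_a1)
        v_mat[, k] <- stats::rnorm(S, 0, completed$sigma_v[, 1])
    })
  }
  strata <- c("rural", "urban")
  p <- array(NA_real_, dim = c(S, length(a2), 2),
             dimnames = list(NULL, a2, strata))
  u_used <- completed$u_all
  u_used[, completed$basis[a2] == "admin1-level"] <- 0
  for (r in strata) {
    al <- completed$alpha[, paste0(co_of, ":", r), drop = FALSE]
    be <- completed$beta[, paste0(co_of, ":", r), drop = FALSE]
    p[, , r] <- stats::plogis(al + be * dt + u_used[, a2] + v_mat[, a1_of])
  }
  structure(list(p = p, admin2 = a2, basis = completed$basis[a2],
                 country_of = co_of, year = year, S = S),
            class = "wss_prediction")
}

#' Population-weighted aggregation of coverage draws
#'
#' Per draw: district overall coverage is the urban/rural population-weighted
#' mean; national coverage is the district-population-weighted mean of
#' district overall coverage.  Districts with zero total population are
#' excluded from the national sum and get `NA` overall coverage, with a
#' warning.
#'
#' @param pred a `wss_prediction`.
#' @param populations tibble with `admin2`, `P_urban`, `P_rural` covering
#'   all predicted districts.
#' @return list with `overall` (draws x districts), `national`
#'   (draws x countries), `P_total` (named), `country_of` (named).
#' @export
aggregate_population <- function(pred, populations) {
  stopifnot(inherits(pred, "wss_prediction"))
  pop <- as.data.frame(populations)
  rownames(pop) <- pop$admin2
  miss <- setdiff(pred$admin2, pop$admin2)
  if (length(miss))
    stop("populations missing for admin2: ", paste(miss, collapse = ", "))
  Pu <- pop[pred$admin2, "P_urban"]; Pr <- pop[pred$admin2, "P_rural"]
  if (any(Pu < 0 | Pr < 0)) stop("negative populations")
  Pt <- Pu + Pr
  zero <- Pt == 0
  if (any(zero))
    warning(sum(zero), " district(s) with zero population excluded ",
            "from aggregation")
  pu <- matrix(pred$p[, , "urban"], nrow = pred$S)
  pr <- matrix(pred$p[, , "rural"], nrow = pred$S)
  overall <- sweep(pu, 2, Pu, "*") + sweep(pr, 2, Pr, "*")
  overall <- sweep(overall, 2, ifelse(zero, NA, Pt), "/")
  colnames(overall) <- pred$admin2
  countries <- unique(pred$country_of)
  national <- matrix(NA_real_, pred$S, length(countries),
                     dimnames = list(NULL, countries))
  for (co in countries) {
    sel <- pred$country_of == co & !zero
    wts <- Pt[sel] / sum(Pt[sel])
    national[, co] <- overall[, sel, drop = FALSE] %*% wts
  }
  list(overall = overall, national = national,
       P_total = stats::setNames(Pt, pred$admin2),
       country_of = pred$country_of)
}

#' Flag districts significantly different from the national mean
#'
#' Per district, the posterior draws of the difference between district
#' overall coverage and its country's national coverage are summarized;
#' `"low"` if the 97.5% quantile of the difference is below 0, `"high"` if
#' the 2.5% quantile is above 0, else `"none"`.
#'
#' @param agg output of [aggregate_population()].
#' @return named character vector of flags per district (`NA` population
#'   districts get `"none"`).
#' @export
flag_significant_areas <- function(agg) {
  a2 <- colnames(agg$overall)
  flags <- stats::setNames(rep("none", length(a2)), a2)
  for (j in a2) {
    d <- agg$overall[, j] - agg$national[, agg$country_of[[j]]]
    if (anyNA(d)) next
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    if (q[2] < 0) flags[j] <- "low" else if (q[1] > 0) flags[j] <- "high"
  }
  flags
}

#' Summarize coverage draws into an estimates table
#'
#' @param pred a `wss_prediction`.
#' @param agg output of [aggregate_population()].
#' @param indicator indicator label carried into the table.
#' @return tibble (one row per district x stratum incl. `overall`):
#'   posterior `median`, `lower`/`upper` (95% BCI), `flag` (overall rows
#'   only; `"none"` otherwise) and `basis`.
#' @export
summarize_coverage <- function(pred, agg, indicator = "improved_water") {
  flags <- flag_significant_areas(agg)
  qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE,
                                    na.rm = FALSE)
  rows <- list()
  for (j in pred$admin2) {
    for (r in c("rural", "urban")) {
      q <- qs(pred$p[, j, r])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        admin2 = j, stratum = r, indicator = indicator,
        median = q[1], lower = q[2], upper = q[3],
        flag = "none", basis = unname(pred$basis[j]))
    }
    q <- qs(agg$overall[, j])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      admin2 = j, stratum = "overall", indicator = indicator,
      median = q[1], lower = q[2], upper = q[3],
      flag = unname(flags[j]), basis = unname(pred$basis[j]))
  }
  do.call(rbind, rows)
}
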