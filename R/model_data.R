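#' Encode survey records and hierarchy for model fitting
#'
#' Produces the dense-index representation the sampler consumes: record
#' vectors (`k`, `n`, `weight`, stratum, country/admin1/admin2 indices,
#' centred time), the adjacency of the *observed* districts (the subgraph
#' induced on districts that carry data, within-country only), neighbour
#' degrees, connected components and the ICAR rank per country.
#'
#' Records with a missing count or `n = 0` for the target indicator are
#' dropped with a message.  Records must already be located to a district
#' (run [allocate_admin1_only()] first).
#'
#' @param records site-level tibble (canonical survey columns).
#' @param hierarchy an `admin_hierarchy`.
#' @param indicator one of `"improved_water"`, `"improved_sanitation"`,
#'   `"open_defecation"`.
#' @param t0 reference year for centring time (default 2012).
#' @return list of class `wss_model_data`.
#' @export
build_model_data <- function(records, hierarchy,
                             indicator = "improved_water", t0 = 2012) {
  kcol <- paste0("k_", indicator)
  ncol <- if (paste0("n_", indicator) %in% names(records))
    paste0("n_", indicator) else "n_households"
  stopifnot(kcol %in% names(records), ncol %in% names(records))
  if (anyNA(records$admin2))
    stop("records with missing admin2 present; run allocate_admin1_only()")
  bad <- setdiff(unique(records$admin2), hierarchy$admin2)
  if (length(bad))
    stop("unknown admin2 in records: ", paste(bad, collapse = ", "))
  k <- records[[kcol]]; n <- records[[ncol]]
  keep <- !is.na(k) & !is.na(n) & n > 0
  if (any(!keep))
    message("dropping ", sum(!keep), " record(s) with no responses for ",
            indicator)
  rec <- records[keep, , drop = FALSE]
  k <- k[keep]; n <- n[keep]
  if (!nrow(rec)) stop("no usable records for ", indicator)
  if (any(k > n)) stop("k > n for ", sum(k > n), " record(s)")

  admin2_levels <- sort(unique(rec$admin2))
  admin1_levels <- sort(unique(rec$admin1))
  country_levels <- sort(unique(rec$country))
  a2 <- match(rec$admin2, admin2_levels)
  a1 <- match(rec$admin1, admin1_levels)
  cc <- match(rec$country, country_levels)
  r <- ifelse(rec$urban == 1, 2L, 1L)  # 1 = rural, 2 = urban

  adj <- hierarchy$adjacency
  keep_e <- adj[, 1] %in% admin2_levels & adj[, 2] %in% admin2_levels
  adj <- adj[keep_e, , drop = FALSE]
  edges <- cbind(match(adj[, 1], admin2_levels),
                 match(adj[, 2], admin2_levels))
  deg <- tabulate(c(edges), nbins = length(admin2_levels))
  island <- deg == 0
  comp <- icar_components(admin2_levels, adj)
  a2_country <- match(unname(hierarchy$country_of_admin2[admin2_levels]),
                      country_levels)
  # ICAR rank per country: sum over non-singleton components of (size - 1)
  icar_rank <- integer(length(country_levels))
  for (cix in seq_along(country_levels)) {
    in_c <- which(a2_country == cix & !island)
    if (length(in_c)) {
      sz <- table(comp[in_c])
      icar_rank[cix] <- sum(pmax(sz - 1L, 0L))
    }
  }
  direct <- if ("allocated" %in% names(rec)) !rec$allocated
            else rec$weight == 1
  country_has_admin2_data <- vapply(
    seq_along(country_levels), function(i) any(direct[cc == i]), logical(1))

  structure(list(
    k = as.integer(k), n = as.integer(n), w = as.numeric(rec$weight),
    r = as.integer(r), c_idx = as.integer(cc), a1_idx = as.integer(a1),
    a2_idx = as.integer(a2), tt = as.numeric(rec$year - t0),
    C = length(country_levels), K = length(admin1_levels),
    J = length(admin2_levels),
    edges = matrix(as.integer(edges), ncol = 2),
    deg = as.integer(deg), island = island, comp = as.integer(comp),
    icar_rank = icar_rank, a2_country = as.integer(a2_country),
    admin2_levels = admin2_levels, admin1_levels = admin1_levels,
    country_levels = country_levels,
    country_has_admin2_data = country_has_admin2_data,
    indicator = indicator, t0 = t0
  ), class = "wss_model_data")
}

#' Hyperprior scales for the hierarchical model
#'
#' Weakly-informative defaults on the logit scale: Normal(0, 5) on the grand
#' intercepts/slopes, half-Normal(1) on all standard deviations.
#'
#' @param mu_sd prior SD of the grand means.
#' @param sigma_alpha_scale,sigma_beta_scale,sigma_u_scale,sigma_v_scale
#'   half-normal scales of the respective SDs.
#' @return list of class `wss_hyperpriors`.
#' @export
hyperpriors <- function(mu_sd = 5, sigma_alpha_scale = 1,
                        sigma_beta_scale = 1, sigma_u_scale = 1,
                        sigma_v_scale = 1) {
  scales <- c(mu_sd, sigma_alpha_scale, sigma_beta_scale, sigma_u_scale,
              sigma_v_scale)
  if (any(scales <= 0)) stop("hyperprior scales must be positive")
  structure(list(mu_sd = mu_sd, sigma_alpha_scale = sigma_alpha_scale,
                 sigma_beta_scale = sigma_beta_scale,
                 sigma_u_scale = sigma_u_scale,
                 sigma_v_scale = sigma_v_scale),
            class = "wss_hyperpriors")
}

log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(x)))

dhalfnorm_log <- function(x, scale)
  0.5 * log(2 / pi) - log(scale) - x^2 / (2 * scale^2)

#' Unnormalized log posterior of the spatial coverage model
#'
#' Reference (pure R) evaluation of the posterior kernel targeted by
#' [run_mcmc()]: the weighted binomial log-likelihood with linear predictor
#' \eqn{\alpha_{c,r} + \beta_{c,r}(t - t_0) + u_j + v_k}, the intrinsic CAR
#' prior on `u` (pairwise-difference form, per-country scale, islands
#' excluded), Gaussian priors on `v`, `alpha`, `beta`, and the hyperpriors.
#' Record weights enter as powers on the binomial contributions.
#'
#' @param data a `wss_model_data`.
#' @param params list with elements `mu_alpha`, `mu_beta` (length 2),
#'   `alpha`, `beta` (C x 2 matrices, columns rural/urban), `sigma_alpha`,
#'   `sigma_beta` (length 2), `sigma_u` (length C), `sigma_v` (scalar),
#'   `u` (length J), `v` (length K).
#' @param hyper a [hyperpriors()] list.
#' @return scalar log density (up to a constant); `-Inf` for any
#'   non-positive SD (a rejected state, not an error).
#' @export
log_unnormalized_posterior <- function(data, params,
                                       hyper = hyperpriors()) {
  p <- params
  if (any(c(p$sigma_alpha, p$sigma_beta, p$sigma_u, p$sigma_v) <= 0))
    return(-Inf)
  eta <- p$alpha[cbind(data$c_idx, data$r)] +
    p$beta[cbind(data$c_idx, data$r)] * data$tt +
    p$u[data$a2_idx] + p$v[data$a1_idx]
  ll <- sum(data$w * (lchoose(data$n, data$k) + data$k * eta -
                        data$n * log1pexp(eta)))
  # ICAR prior, per country, islands excluded
  icar <- 0
  if (nrow(data$edges)) {
    d2 <- (p$u[data$edges[, 1]] - p$u[data$edges[, 2]])^2
    ec <- data$a2_country[data$edges[, 1]]
    for (cix in seq_len(data$C)) {
      if (data$icar_rank[cix] > 0)
        icar <- icar - data$icar_rank[cix] * log(p$sigma_u[cix]) -
          sum(d2[ec == cix]) / (2 * p$sigma_u[cix]^2)
    }
  }
  lv <- sum(stats::dnorm(p$v, 0, p$sigma_v, log = TRUE))
  lab <- 0
  for (r in 1:2) {
    lab <- lab +
      sum(stats::dnorm(p$alpha[, r], p$mu_alpha[r], p$sigma_alpha[r],
                       log = TRUE)) +
      sum(stats::dnorm(p$beta[, r], p$mu_beta[r], p$sigma_beta[r],
                       log = TRUE))
  }
  hp <- sum(stats::dnorm(c(p$mu_alpha, p$mu_beta), 0, hyper$mu_sd,
                         log = TRUE)) +
    sum(dhalfnorm_log(p$sigma_alpha, hyper$sigma_alpha_scale)) +
    sum(dhalfnorm_log(p$sigma_beta, hyper$sigma_beta_scale)) +
    sum(dhalfnorm_log(p$sigma_u, hyper$sigma_u_scale)) +
    dhalfnorm_log(p$sigma_v, hyper$sigma_v_scale)
  ll + icar + lv + lab + hp
}
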