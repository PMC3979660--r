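default_inits <- function(data, jitter = 0.1) {
  # empirical logit by stratum as starting intercept
  mu_a <- numeric(2)
  for (r in 1:2) {
    sel <- data$r == r
    mu_a[r] <- if (any(sel))
      stats::qlogis((sum(data$k[sel]) + 0.5) / (sum(data$n[sel]) + 1))
    else 0
  }
  C <- data$C
  list(mu_alpha = mu_a + stats::rnorm(2, 0, jitter),
       mu_beta = stats::rnorm(2, 0, jitter / 10),
       alpha = rep(mu_a, C) + stats::rnorm(2 * C, 0, jitter),
       beta = stats::rnorm(2 * C, 0, jitter / 10),
       sigma_alpha = stats::runif(2, 0.3, 0.7),
       sigma_beta = stats::runif(2, 0.05, 0.2),
       sigma_u = stats::runif(C, 0.3, 0.7),
       sigma_v = stats::runif(1, 0.2, 0.5),
       u = numeric(data$J), v = numeric(data$K))
}

#' Fit the spatial coverage model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs targeting the posterior of
#' [log_unnormalized_posterior()]: scalar random-walk updates for country
#' intercepts/slopes, district (ICAR) and province effects, log-scale
#' random-walk updates for all SDs (proposal scales adapted during warmup to
#' ~0.38 acceptance), and conjugate Gibbs draws for the grand means.  The
#' per-component sum-to-zero constraint on the ICAR effects is re-imposed
#' after every sweep.  Chains run sequentially with seeds derived from
#' `seed`, so results are fully reproducible.
#'
#' @param data a `wss_model_data` from [build_model_data()].
#' @param hyper a [hyperpriors()] list.
#' @param n_chains number of chains (>= 2 recommended for diagnostics).
#' @param n_iter total iterations per chain (including warmup).
#' @param n_warmup adaptation/burn-in iterations discarded from output.
#' @param thin keep every `thin`-th post-warmup draw.
#' @param seed integer seed.
#' @return object of class `wss_draws`: `$chains` is a list (one per chain)
#'   of named draw matrices with labelled columns; `$accept` per-chain
#'   acceptance rates; `$data`, `$hyper` and sampler settings are retained.
#' @export
run_mcmc <- function(data, hyper = hyperpriors(), n_chains = 2,
                     n_iter = 4000, n_warmup = 2000, thin = 1, seed = 1L) {
  stopifnot(inherits(data, "wss_model_data"))
  if (!(n_iter > n_warmup && n_warmup >= 0))
    stop("need n_iter > n_warmup >= 0")
  strata <- c("rural", "urban")
  cr_names <- as.vector(t(outer(data$country_levels, strata, paste,
                                sep = ":")))
  chains <- vector("list", n_chains)
  accept <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    res <- withr::with_seed(seed + ch - 1L, {
      init <- default_inits(data)
      run_mcmc_cpp(unclass(data), unclass(hyper), init,
                   as.integer(n_iter), as.integer(n_warmup),
                   as.integer(thin))
    })
    colnames(res$mu_alpha) <- colnames(res$mu_beta) <- strata
    colnames(res$sigma_alpha) <- colnames(res$sigma_beta) <- strata
    colnames(res$alpha) <- colnames(res$beta) <- cr_names
    colnames(res$sigma_u) <- data$country_levels
    colnames(res$sigma_v) <- "sigma_v"
    colnames(res$u) <- data$admin2_levels
    colnames(res$v) <- data$admin1_levels
    accept[[ch]] <- res$accept
    res$accept <- NULL
    chains[[ch]] <- res
  }
  structure(list(chains = chains, accept = accept, data = data,
                 hyper = hyper, n_chains = n_chains, n_iter = n_iter,
                 n_warmup = n_warmup, thin = thin, seed = seed),
            class = "wss_draws")
}

#' Pool post-warmup draws of one parameter block across chains
#'
#' @param draws a `wss_draws`.
#' @param name block name (`"mu_alpha"`, `"alpha"`, `"sigma_u"`, `"u"`, ...).
#' @return matrix with one row per pooled draw, labelled columns.
#' @export
pooled_draws <- function(draws, name) {
  do.call(rbind, lapply(draws$chains, `[[`, name))
}

#' @export
print.wss_draws <- function(x, ...) {
  cat("wss_draws:", x$n_chains, "chains x",
      nrow(x$chains[[1]]$mu_alpha), "kept draws;",
      x$data$C, "countries,", x$data$J, "admin2,", x$data$K, "admin1;",
      "indicator:", x$data$indicator, "\n")
  invisible(x)
}
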