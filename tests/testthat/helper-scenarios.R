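# Shared fixtures built in code.

# a single-country path graph of n districts (1 x n lattice)
path_hierarchy <- function(n, seed = 1L) {
  build_admin_hierarchy(sim_config(n_countries = 1, admin1_per_country = 1,
                                   admin2_lattice = c(1L, n), seed = seed))
}

# the parameter-recovery study design: 3 countries x 2 provinces x a 3x3
# district lattice, 2 strata, surveys in 1998/2005/2011, 2 clusters of 25
# households per district, stratum and year; truth has a rural logit slope
# of 0.05/yr and ICAR SD 0.5
scenario5_config <- function(seed) sim_config(seed = seed)

scenario5_replicate <- function(seed, u_override = NULL,
                                zero_random_effects = FALSE) {
  sc <- scenario5_config(seed)
  h <- build_admin_hierarchy(sc)
  # the null (no sub-national heterogeneity) design also fixes the urban
  # share, so districts truly share their country's overall coverage
  pop <- make_population_table(
    h, urban_fraction = if (zero_random_effects) 1 / 3,
    seed = seed)
  tr <- if (zero_random_effects)
    true_parameters(h, sigma_u = 0, sigma_v = 0, seed = seed)
  else true_parameters(h, u = u_override, seed = seed)
  sites <- simulate_survey(h, pop, tr, sc)
  md <- build_model_data(sites, h)
  fit <- run_mcmc(md, n_chains = 2, n_iter = 4000, n_warmup = 2000,
                  seed = seed + 1000L)
  list(hierarchy = h, populations = pop, truth = tr, sites = sites,
       data = md, fit = fit)
}

# memoised copy of one replicate for tests that only need any valid fit
.fit_cache <- new.env(parent = emptyenv())
cached_replicate <- function(seed = 101L) {
  key <- as.character(seed)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- scenario5_replicate(seed)
  .fit_cache[[key]]
}

# dense Laplacian built independently of the package's graph code
dense_laplacian <- function(ids, edges) {
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (NROW(edges)) for (i in seq_len(NROW(edges))) {
    W[edges[i, 1], edges[i, 2]] <- 1
    W[edges[i, 2], edges[i, 1]] <- 1
  }
  diag(rowSums(W)) - W
}

# brute-force population-weighted pairwise GINI oracle:
# G = sum_ij w_i w_j |x_i - x_j| / (2 * mean(x)) with w population shares
gini_pairwise_oracle <- function(coverage, population) {
  w <- population / sum(population)
  xbar <- sum(w * coverage)
  sum(outer(w, w) * abs(outer(coverage, coverage, "-"))) / (2 * xbar)
}

# random parameter set dimensioned for a model-data object
random_params <- function(data, seed) {
  withr::with_seed(seed, {
    C <- data$C
    list(mu_alpha = rnorm(2), mu_beta = rnorm(2, 0, 0.1),
         alpha = matrix(rnorm(C * 2), C, 2),
         beta = matrix(rnorm(C * 2, 0, 0.1), C, 2),
         sigma_alpha = runif(2, 0.2, 1), sigma_beta = runif(2, 0.05, 0.5),
         sigma_u = runif(C, 0.2, 1), sigma_v = runif(1, 0.2, 1),
         u = rnorm(data$J, 0, 0.5), v = rnorm(data$K, 0, 0.5))
  })
}
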