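small_records <- function() {
  tibble::tibble(
    country = "C01", admin1 = "C01_A01",
    admin2 = c("C01_A01_D01", "C01_A01_D02", "C01_A01_D03",
               "C01_A01_D01", "C01_A01_D02"),
    urban = c(0L, 1L, 0L, 0L, 1L),
    year = c(2005L, 2005L, 2012L, 2010L, 2010L),
    n_households = 10L,
    k_improved_water = c(3L, 5L, 7L, 2L, 9L),
    weight = 1)
}

test_that("model data uses dense indices, centred time and keeps duplicates", {
  h <- path_hierarchy(3)
  md <- build_model_data(small_records(), h)
  expect_s3_class(md, "wss_model_data")
  expect_equal(sort(unique(md$a2_idx)), 1:3)
  expect_equal(md$tt[3], 0)          # year 2012 with t0 = 2012
  expect_equal(length(md$k), 5)
  dup <- small_records()[c(1, 1), ]
  md2 <- build_model_data(dup, h)
  expect_equal(length(md2$k), 2)     # duplicated sites both retained

  bad <- small_records(); bad$admin2[1] <- "C09_A01_D01"
  expect_error(build_model_data(bad, h), "unknown admin2")

  z <- small_records(); z$k_improved_water[2] <- NA
  expect_message(md3 <- build_model_data(z, h), "dropping 1")
  expect_equal(length(md3$k), 4)
})

test_that("log posterior matches a direct binomial pmf evaluation", {
  h <- path_hierarchy(1)
  rec <- tibble::tibble(country = "C01", admin1 = "C01_A01",
                        admin2 = "C01_A01_D01", urban = 0L, year = 2012L,
                        n_households = 10L, k_improved_water = 3L,
                        weight = 1)
  md1 <- build_model_data(rec, h)
  rec0 <- rec; rec0$weight <- 0
  md0 <- build_model_data(rec0, h)
  par <- list(mu_alpha = c(0, 0), mu_beta = c(0, 0),
              alpha = matrix(0, 1, 2), beta = matrix(0, 1, 2),
              sigma_alpha = c(1, 1), sigma_beta = c(1, 1),
              sigma_u = 1, sigma_v = 1, u = 0, v = 0)
  # the record's contribution at predictor 0 is log C(10,3) + 10 log(1/2)
  contrib <- log_unnormalized_posterior(md1, par) -
    log_unnormalized_posterior(md0, par)
  expect_equal(contrib, lchoose(10, 3) + 10 * log(0.5), tolerance = 1e-12)
  expect_equal(contrib, dbinom(3, 10, 0.5, log = TRUE), tolerance = 1e-12)
})

test_that("saturated record density increases monotonically in the predictor", {
  h <- path_hierarchy(1)
  rec <- tibble::tibble(country = "C01", admin1 = "C01_A01",
                        admin2 = "C01_A01_D01", urban = 0L, year = 2012L,
                        n_households = 10L, k_improved_water = 10L,
                        weight = 1)
  rec0 <- rec; rec0$weight <- 0
  md <- build_model_data(rec, h)
  md0 <- build_model_data(rec0, h)
  par <- random_params(md, 1)
  # isolate the record's likelihood contribution via the weight power
  ll <- sapply(c(0, 1, 3, 10), function(a) {
    p <- par; p$alpha <- matrix(a, 1, 2); p$beta[] <- 0; p$u <- 0; p$v <- 0
    log_unnormalized_posterior(md, p) - log_unnormalized_posterior(md0, p)
  })
  expect_true(all(diff(ll) > 0))
  expect_lt(max(ll), 0)  # approaches the point mass from below
})

test_that("non-positive SDs yield -Inf, not an error", {
  md <- build_model_data(small_records(), path_hierarchy(3))
  par <- random_params(md, 2)
  par$sigma_v <- 0
  expect_identical(log_unnormalized_posterior(md, par), -Inf)
  par$sigma_v <- -1
  expect_identical(log_unnormalized_posterior(md, par), -Inf)
})

test_that("compiled posterior kernel equals the R reference on random parameters", {
  rep1 <- cached_replicate()
  md <- rep1$data
  hy <- hyperpriors()
  for (s in 1:10) {
    par <- random_params(md, s)
    expect_equal(logpost_cpp(unclass(md), par, unclass(hy)),
                 log_unnormalized_posterior(md, par, hy),
                 tolerance = 1e-10)
  }
  # with non-default hyperpriors too
  hy2 <- hyperpriors(mu_sd = 2, sigma_u_scale = 0.5)
  par <- random_params(md, 99)
  expect_equal(logpost_cpp(unclass(md), par, unclass(hy2)),
               log_unnormalized_posterior(md, par, hy2),
               tolerance = 1e-10)
})

test_that("splitting a record into two half-weight copies leaves the posterior unchanged", {
  h <- path_hierarchy(3)
  rec <- small_records()
  split <- rbind(rec, rec[1, ])
  split$weight[c(1, 6)] <- 0.5
  md_a <- build_model_data(rec, h)
  md_b <- build_model_data(split, h)
  for (s in 1:5) {
    par <- random_params(md_a, s)
    expect_equal(log_unnormalized_posterior(md_a, par),
                 log_unnormalized_posterior(md_b, par), tolerance = 1e-10)
  }
})

test_that("MCMC is reproducible and respects the sum-to-zero constraint", {
  rep1 <- cached_replicate()
  f2 <- run_mcmc(rep1$data, n_chains = 2, n_iter = 4000, n_warmup = 2000,
                 seed = 1101L)
  expect_identical(rep1$fit$chains, f2$chains)
  u <- pooled_draws(rep1$fit, "u")
  comp <- rep1$data$comp
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2) next
    expect_lt(max(abs(rowSums(u[, members, drop = FALSE]))), 1e-10)
  }
  expect_true(all(pooled_draws(rep1$fit, "sigma_u") > 0))
  expect_true(all(pooled_draws(rep1$fit, "sigma_v") > 0))
})

test_that("a single-area model shrinks the raw proportion towards the prior mean", {
  h <- path_hierarchy(1)
  rec <- tibble::tibble(country = "C01", admin1 = "C01_A01",
                        admin2 = "C01_A01_D01", urban = 0L, year = 2012L,
                        n_households = 25L, k_improved_water = 20L,
                        weight = 1)
  md <- build_model_data(rec, h)
  # informative prior scales make the pull towards the prior mean visible
  fit <- run_mcmc(md, hyper = hyperpriors(mu_sd = 1, sigma_alpha_scale = 0.5,
                                          sigma_v_scale = 0.5),
                  n_chains = 2, n_iter = 6000, n_warmup = 2000, seed = 3)
  # coverage draws for that district at t0 (u is an island -> 0)
  al <- pooled_draws(fit, "alpha")[, "C01:rural"]
  v <- pooled_draws(fit, "v")[, 1]
  p <- plogis(al + v)
  raw <- 20 / 25
  expect_lt(mean(p), raw)
  expect_gt(mean(p), 0.5)  # inverse-logit of the prior mean 0
})

test_that("convergence diagnostics behave on known chains", {
  rep1 <- cached_replicate()
  # identical chains: between-chain variance vanishes
  fake <- rep1$fit
  fake$chains[[2]] <- fake$chains[[1]]
  dg <- diagnostics(fake, blocks = c("mu_alpha", "sigma_v"))
  expect_true(all(abs(dg$summary$rhat - 1) < 0.02))

  # independent white-noise chains: ESS close to the number of draws
  n <- 1000
  wn <- withr::with_seed(5, matrix(rnorm(2 * n), n, 2))
  expect_lt(abs(ess_mean(wn) - 2 * n) / (2 * n), 0.25)
  expect_lt(abs(split_rhat(wn) - 1), 0.02)

  # constant chain: undefined, flagged
  expect_true(is.na(ess_mean(matrix(1, n, 2))))
  expect_true(is.na(split_rhat(matrix(1, n, 2))))

  one <- rep1$fit
  one$chains <- one$chains[1]
  one$accept <- one$accept[1]
  one$n_chains <- 1
  expect_warning(d1 <- diagnostics(one, blocks = "mu_alpha"),
                 "single chain")
  expect_true(all(is.na(d1$summary$rhat)))
})

test_that("the demo scenario converges (split R-hat < 1.05 on all monitored scalars)", {
  rep1 <- cached_replicate()
  dg <- diagnostics(rep1$fit)
  expect_false(dg$any_flagged)
  expect_lt(max(dg$summary$rhat, na.rm = TRUE), 1.05)
})
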