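# minimal completed-draws object with hand-set parameter values
fake_completed <- function(h, md, S, alpha = 0, beta = 0, u = 0, v = 0,
                           sigma_v = 0.3) {
  strata <- c("rural", "urban")
  cr <- as.vector(t(outer(md$country_levels, strata, paste, sep = ":")))
  mk <- function(val, cols) matrix(val, S, length(cols),
                                   dimnames = list(NULL, cols))
  structure(list(
    mu_alpha = mk(alpha, strata), mu_beta = mk(beta, strata),
    alpha = mk(alpha, cr), beta = mk(beta, cr),
    sigma_alpha = mk(0.5, strata), sigma_beta = mk(0.1, strata),
    sigma_u = mk(0.5, md$country_levels), sigma_v = mk(sigma_v, "sigma_v"),
    v = mk(v, md$admin1_levels),
    u_all = mk(u, md$admin2_levels),
    basis = setNames(rep("sampled", md$J), md$admin2_levels),
    data = md, S = S), class = "wss_completed")
}

test_that("single-node ICAR conditional is Normal(neighbour mean, sigma^2/m)", {
  h <- path_hierarchy(3)
  # middle node missing, ends observed at 0.2 and 0.4
  cond <- icar_conditional(h$admin2, h$adjacency,
                           c(C01_A01_D01 = 0.2, C01_A01_D03 = 0.4),
                           sigma = 1)
  expect_equal(unname(cond$mean["C01_A01_D02"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(cond$cov[1, 1]), 0.5, tolerance = 1e-12)
  # all neighbours at zero -> conditional mean zero
  cond0 <- icar_conditional(h$admin2, h$adjacency,
                            c(C01_A01_D01 = 0, C01_A01_D03 = 0))
  expect_equal(unname(cond0$mean), 0)
})

test_that("joint conditional on a 5-node path matches dense-oracle conditioning", {
  h <- path_hierarchy(5)
  u_obs <- c(C01_A01_D01 = 0.5, C01_A01_D03 = -0.2, C01_A01_D05 = 0.1)
  sigma <- 0.7
  cond <- icar_conditional(h$admin2, h$adjacency, u_obs, sigma = sigma)
  # oracle: generic Gaussian conditioning on the dense precision matrix
  Q <- dense_laplacian(h$admin2, h$adjacency) / sigma^2
  miss <- c("C01_A01_D02", "C01_A01_D04")
  obs <- names(u_obs)
  mu_o <- -solve(Q[miss, miss]) %*% Q[miss, obs] %*% u_obs
  V_o <- solve(Q[miss, miss])
  expect_equal(cond$mean[miss], setNames(as.numeric(mu_o), miss),
               tolerance = 1e-10)
  expect_equal(unname(cond$cov[miss, miss]), unname(V_o),
               tolerance = 1e-10)
})

test_that("imputation completes unsampled districts with extra uncertainty", {
  sc <- sim_config(n_countries = 3, fraction_unsampled_admin2 = 0.15,
                   seed = 31)
  h <- build_admin_hierarchy(sc)
  pop <- make_population_table(h, seed = 31)
  tr <- true_parameters(h, seed = 31)
  sites <- simulate_survey(h, pop, tr, sc)
  md <- build_model_data(sites, h)
  fit <- run_mcmc(md, n_chains = 2, n_iter = 2000, n_warmup = 1000,
                  seed = 32)
  comp <- impute_unsampled_effects(fit, h, seed = 33)
  expect_setequal(colnames(comp$u_all), h$admin2)
  expect_setequal(unique(unname(comp$basis)), c("sampled", "imputed"))
  miss <- names(comp$basis)[comp$basis == "imputed"]
  expect_gt(length(miss), 0)
  # determinism
  comp2 <- impute_unsampled_effects(fit, h, seed = 33)
  expect_identical(comp$u_all, comp2$u_all)
  # imputed-effect draws are more dispersed than sampled ones on average
  sd_miss <- mean(apply(comp$u_all[, miss, drop = FALSE], 2, sd))
  sd_obs <- mean(apply(comp$u_all[, comp$basis == "sampled"], 2, sd))
  expect_gt(sd_miss, sd_obs)
})

test_that("countries with only province-located data fall back to admin1-level prediction", {
  sc <- sim_config(n_countries = 2, seed = 44)
  h <- build_admin_hierarchy(sc)
  pop <- make_population_table(h, seed = 44)
  tr <- true_parameters(h, seed = 44)
  sites <- simulate_survey(h, pop, tr, sc)
  # strip district locations for country 2 entirely
  c2 <- sites$country == "C02"
  sites$admin2[c2] <- NA
  sites <- allocate_admin1_only(sites, h)
  md <- build_model_data(sites, h)
  expect_equal(md$country_has_admin2_data, c(TRUE, FALSE))
  fit <- run_mcmc(md, n_chains = 2, n_iter = 1500, n_warmup = 750,
                  seed = 45)
  comp <- impute_unsampled_effects(fit, h, seed = 46)
  c2_admin2 <- h$admin2[h$country_of_admin2 == "C02"]
  expect_true(all(comp$basis[c2_admin2] == "admin1-level"))
  expect_true(all(comp$u_all[, c2_admin2] == 0))
  pred <- predict_coverage(comp, h, year = 2012, seed = 47)
  # within a province, all districts share the same admin1-level draw
  a1 <- h$admin2[h$admin2_of == "C02_A01"]
  expect_equal(pred$p[, a1[1], "rural"], pred$p[, a1[2], "rural"])
})

test_that("coverage prediction is the inverse-logit of the linear predictor", {
  sc <- sim_config(n_countries = 1, admin1_per_country = 1,
                   admin2_lattice = c(2, 2), seed = 3)
  h <- build_admin_hierarchy(sc)
  sites <- simulate_survey(h, make_population_table(h, seed = 3),
                           true_parameters(h, seed = 3), sc)
  md <- build_model_data(sites, h)
  S <- 50
  # all parameters zero -> p = 0.5 everywhere
  pred0 <- predict_coverage(fake_completed(h, md, S), h, year = 2012)
  expect_true(all(pred0$p == 0.5))
  # alpha = 2, rest zero -> p = 0.8808 (4 d.p.)
  pred2 <- predict_coverage(fake_completed(h, md, S, alpha = 2), h,
                            year = 2012)
  expect_equal(unique(as.numeric(pred2$p)), 0.8808, tolerance = 1e-4)
  # slope enters through (year - t0)
  pred_b <- predict_coverage(fake_completed(h, md, S, beta = 0.1), h,
                             year = 2007)
  expect_equal(unique(as.numeric(pred_b$p)), plogis(-0.5),
               tolerance = 1e-12)
})

test_that("population aggregation conserves the weighted mean", {
  sc <- sim_config(n_countries = 1, admin1_per_country = 1,
                   admin2_lattice = c(1, 2), seed = 3)
  h <- build_admin_hierarchy(sc)
  sites <- simulate_survey(h, make_population_table(h, seed = 3),
                           true_parameters(h, seed = 3), sc)
  md <- build_model_data(sites, h)
  comp <- fake_completed(h, md, 1)
  pred <- predict_coverage(comp, h)
  # hand-set draws: district 1 urban 0.9 / rural 0.5; district 2 all 1
  pred$p[, 1, "urban"] <- 0.9; pred$p[, 1, "rural"] <- 0.5
  pred$p[, 2, ] <- 1
  pops <- tibble::tibble(admin2 = h$admin2, P_urban = c(1000, 0),
                         P_rural = c(3000, 1000))
  agg <- aggregate_population(pred, pops)
  expect_equal(unname(agg$overall[1, 1]), 0.6)   # (1000*.9 + 3000*.5)/4000
  expect_equal(unname(agg$national[1, 1]), (4000 * 0.6 + 1000 * 1) / 5000)
  # all districts equal coverage c -> national = c exactly
  pred$p[, , ] <- 0.37
  agg2 <- aggregate_population(pred, pops)
  expect_equal(unname(agg2$national[1, 1]), 0.37, tolerance = 1e-15)
  # two-district hand case: P = 1 at p = 0, P = 3 at p = 1 -> national 0.75
  pred$p[, 1, ] <- 0; pred$p[, 2, ] <- 1
  pops2 <- tibble::tibble(admin2 = h$admin2, P_urban = c(1, 3),
                          P_rural = c(0, 0))
  agg3 <- aggregate_population(pred, pops2)
  expect_equal(unname(agg3$national[1, 1]), 0.75)
  # zero-population district: excluded with a warning, overall NA
  pops3 <- tibble::tibble(admin2 = h$admin2, P_urban = c(0, 10),
                          P_rural = c(0, 0))
  expect_warning(agg4 <- aggregate_population(pred, pops3), "zero")
  expect_true(is.na(agg4$overall[1, 1]))
  expect_equal(unname(agg4$national[1, 1]), 1)
})

test_that("significance flags come from the 95% interval of the difference", {
  overall <- cbind(a = rep(0.5, 200), b = rep(0.5, 200))
  national <- matrix(0.5, 200, 1, dimnames = list(NULL, "C01"))
  agg <- list(overall = overall, national = national,
              P_total = c(a = 1, b = 1),
              country_of = c(a = "C01", b = "C01"))
  expect_equal(unname(flag_significant_areas(agg)), c("none", "none"))
  agg$overall[, "a"] <- 0.4  # all difference draws negative
  expect_equal(unname(flag_significant_areas(agg)["a"]), "low")
  agg$overall[, "b"] <- 0.9
  expect_equal(unname(flag_significant_areas(agg)["b"]), "high")
})

test_that("coverage summaries have monotone quantiles and carry flags", {
  r <- cached_replicate()
  comp <- impute_unsampled_effects(r$fit, r$hierarchy, seed = 5)
  pred <- predict_coverage(comp, r$hierarchy, seed = 6)
  agg <- aggregate_population(pred, r$populations)
  est <- summarize_coverage(pred, agg)
  expect_true(all(est$lower <= est$median & est$median <= est$upper))
  expect_true(all(est$lower >= 0 & est$upper <= 1))
  expect_true(all(est$flag %in% c("low", "high", "none")))
  expect_true(all(est$flag[est$stratum != "overall"] == "none"))
  expect_equal(nrow(est), 54 * 3)
})
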