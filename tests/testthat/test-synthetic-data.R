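test_that("lattice hierarchies have the expected rook/queen adjacency", {
  h22 <- build_admin_hierarchy(sim_config(n_countries = 1,
                                          admin1_per_country = 1,
                                          admin2_lattice = c(2, 2)))
  nb <- neighbour_list(h22)
  expect_length(h22$admin2, 4)
  expect_true(all(lengths(nb) == 2))  # every corner of a 2x2 rook lattice

  h33 <- build_admin_hierarchy(sim_config(n_countries = 1,
                                          admin1_per_country = 1,
                                          admin2_lattice = c(3, 3)))
  nb <- neighbour_list(h33)
  # centre node of the 3x3 grid is id 5 (row-major)
  expect_length(nb[["C01_A01_D05"]], 4)
  expect_setequal(nb[["C01_A01_D05"]],
                  paste0("C01_A01_D0", c(2, 4, 6, 8)))
  # rook 3x3 has 12 edges
  expect_equal(nrow(h33$adjacency), 12)

  hq <- build_admin_hierarchy(sim_config(n_countries = 1,
                                         admin1_per_country = 1,
                                         admin2_lattice = c(2, 2),
                                         contiguity = "queen"))
  expect_true(all(lengths(neighbour_list(hq)) == 3))
})

test_that("isolated districts are recorded as islands; no cross-country edges", {
  h <- build_admin_hierarchy(sim_config(n_countries = 2,
                                        admin1_per_country = 1,
                                        admin2_lattice = c(1, 1)))
  expect_equal(nrow(h$adjacency), 0)
  expect_setequal(h$islands, h$admin2)

  h2 <- build_admin_hierarchy(sim_config(n_countries = 3))
  co <- h2$country_of_admin2
  expect_true(all(co[h2$adjacency[, 1]] == co[h2$adjacency[, 2]]))
  # symmetric-irreflexive: no self loops, each unordered pair once
  expect_false(any(h2$adjacency[, 1] == h2$adjacency[, 2]))
  key <- apply(h2$adjacency, 1, function(e) paste(sort(e), collapse = "|"))
  expect_false(any(duplicated(key)))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_countries = 0), "positive")
  expect_error(sim_config(households_per_site = -5), "positive")
  expect_error(sim_config(fraction_admin1_only = 1.5), "fractions")
})

test_that("ICAR draws honour the degenerate, constraint and covariance properties", {
  h <- path_hierarchy(5)
  expect_equal(unname(sample_icar_effects(h, 0, seed = 3)), rep(0, 5))

  for (s in 1:5) {
    u <- sample_icar_effects(h, 1, seed = s)
    expect_lt(abs(sum(u)), 1e-10)  # per-component sum-to-zero
  }

  # oracle: covariance of the proper representative is sigma^2 * pinv(L)
  L <- dense_laplacian(h$admin2, h$adjacency)
  es <- eigen(L, symmetric = TRUE)
  pos <- es$values > 1e-8
  pinv <- es$vectors[, pos] %*% diag(1 / es$values[pos]) %*%
    t(es$vectors[, pos])
  nrep <- 4000
  draws <- t(sapply(seq_len(nrep), function(i)
    sample_icar_effects(h, 1, seed = 10000 + i)))
  # variance of u_i - u_j grows with path distance, matching the oracle
  vd <- function(i, j) var(draws[, i] - draws[, j])
  od <- function(i, j) pinv[i, i] + pinv[j, j] - 2 * pinv[i, j]
  pairs <- cbind(1, 2:5)
  emp <- mapply(vd, pairs[, 1], pairs[, 2])
  ora <- mapply(od, pairs[, 1], pairs[, 2])
  expect_true(all(diff(emp) > 0))   # increases with |i - j|
  expect_true(all(abs(emp - ora) < 4 * ora / sqrt(nrep / 2) + 0.05))
  # island receives exactly zero
  h_isl <- build_admin_hierarchy(sim_config(n_countries = 1,
                                            admin1_per_country = 2,
                                            admin2_lattice = c(1, 1)))
  expect_equal(unname(sample_icar_effects(h_isl, 1, seed = 1)), c(0, 0))
})

test_that("empirical ICAR covariance matches the Laplacian pseudo-inverse on a small lattice", {
  h <- build_admin_hierarchy(sim_config(n_countries = 1,
                                        admin1_per_country = 1,
                                        admin2_lattice = c(2, 3)))
  L <- dense_laplacian(h$admin2, h$adjacency)
  es <- eigen(L, symmetric = TRUE)
  pos <- es$values > 1e-8
  pinv <- es$vectors[, pos] %*% diag(1 / es$values[pos]) %*%
    t(es$vectors[, pos])
  nrep <- 4000
  draws <- t(sapply(seq_len(nrep), function(i)
    sample_icar_effects(h, 0.7, seed = 500 + i)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - 0.49 * pinv)), 0.06)
})

test_that("survey simulation is deterministic and has the right binomial structure", {
  sc <- sim_config(n_countries = 1, admin1_per_country = 1,
                   admin2_lattice = c(3, 3), sites_per_admin2_per_year = 4,
                   survey_years = c(2005, 2011), seed = 9)
  h <- build_admin_hierarchy(sc)
  pop <- make_population_table(h, seed = 9)
  tr <- true_parameters(h, mu_alpha = c(rural = 0, urban = 0),
                        mu_beta = c(rural = 0, urban = 0),
                        sigma_alpha = c(0, 0), sigma_beta = c(0, 0),
                        sigma_u = 0, sigma_v = 0, seed = 9)
  s1 <- simulate_survey(h, pop, tr, sc)
  s2 <- simulate_survey(h, pop, tr, sc)
  expect_identical(s1, s2)
  # total households: sites x households_per_site exactly
  expect_equal(sum(s1$n_households), nrow(s1) * 25)
  # all effects zero: pooled proportion near 1/2
  phat <- sum(s1$k_improved_water) / sum(s1$n_households)
  se <- sqrt(0.25 / sum(s1$n_households))
  expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("mean site proportion matches inverse-logit of the intercept", {
  # 2,000+ sites with linear predictor exactly 1 everywhere
  sc <- sim_config(n_countries = 1, admin1_per_country = 1,
                   admin2_lattice = c(5, 5), sites_per_admin2_per_year = 20,
                   survey_years = c(2011, 2012), seed = 21)
  h <- build_admin_hierarchy(sc)
  pop <- make_population_table(h, seed = 21)
  tr <- true_parameters(h, mu_alpha = c(rural = 1, urban = 1),
                        mu_beta = c(rural = 0, urban = 0),
                        sigma_alpha = c(0, 0), sigma_beta = c(0, 0),
                        sigma_u = 0, sigma_v = 0, t0 = 2012, seed = 21)
  s <- simulate_survey(h, pop, tr, sc)
  expect_gte(nrow(s), 2000)
  expect_lt(abs(mean(s$k_improved_water / s$n_households) - plogis(1)),
            0.01)
})

test_that("unsampled-district and province-only fractions are honoured", {
  sc <- sim_config(fraction_unsampled_admin2 = 0.25,
                   fraction_admin1_only = 0.2, seed = 4)
  h <- build_admin_hierarchy(sc)
  pop <- make_population_table(h, seed = 4)
  tr <- true_parameters(h, seed = 4)
  s <- simulate_survey(h, pop, tr, sc)
  per_country <- round(0.25 * 18) * 3  # 18 districts per country
  expect_equal(length(setdiff(h$admin2, unique(na.omit(s$admin2)))) >=
                 per_country, TRUE)
  expect_equal(sum(is.na(s$admin2)), round(0.2 * nrow(s)))
  expect_true(all(s$weight == 1))
})

test_that("survey CSV round-trips through the canonical format", {
  sc <- sim_config(n_countries = 1, admin1_per_country = 1,
                   admin2_lattice = c(2, 2), fraction_admin1_only = 0.2,
                   seed = 5)
  h <- build_admin_hierarchy(sc)
  s <- simulate_survey(h, make_population_table(h, seed = 5),
                       true_parameters(h, seed = 5), sc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(s, f)
  s2 <- read_survey_csv(f)
  expect_equal(as.data.frame(s2), as.data.frame(s))
})
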