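#!/usr/bin/env Rscript

# Stage 1 — build the synthetic study region and survey data.
#
# Six countries, each with two provinces holding a 3x3 rook lattice of
# districts (108 districts in all), surveyed in 1998/2005/2011 with two
# 25-household clusters per district, stratum and year.  10% of districts
# are never sampled and 10% of sites are located to province only, the two
# data imperfections the downstream stages must handle.

library(wsscover)

seed <- 2026L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

sc <- sim_config(n_countries = 6, admin1_per_country = 2,
                 admin2_lattice = c(3, 3), sites_per_admin2_per_year = 2,
                 survey_years = c(1998, 2005, 2011),
                 fraction_unsampled_admin2 = 0.10,
                 fraction_admin1_only = 0.10, seed = seed)
hierarchy <- build_admin_hierarchy(sc)
populations <- make_population_table(hierarchy, seed = seed)
truths <- default_truths(hierarchy, seed = seed)
sites <- simulate_survey(hierarchy, populations, truths, sc)

write_survey_csv(sites, "results/data/sites.csv")
write.csv(as.data.frame(populations), "results/data/populations.csv",
          row.names = FALSE)
write_adjacency(hierarchy, "results/data/adjacency.txt")
write_truth(truths$improved_water, "results/data/truth_improved_water.yaml")
saveRDS(list(sc = sc, hierarchy = hierarchy, populations = populations,
             truths = truths, sites = sites, seed = seed),
        "scratch/01_state.rds")

cat("Districts:", length(hierarchy$admin2),
    "| survey sites:", nrow(sites),
    "| households:", sum(sites$n_households), "\n")
cat("Unsampled districts:",
    length(setdiff(hierarchy$admin2, unique(na.omit(sites$admin2)))),
    "| province-only sites:", sum(is.na(sites$admin2)), "\n")
cat("Raw site-level improved-water proportion:",
    round(sum(sites$k_improved_water) / sum(sites$n_households), 3), "\n")
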