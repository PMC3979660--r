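#' Simulation scenario configuration
#'
#' Bundles the knobs of the synthetic survey generator: the shape of the
#' administrative hierarchy, the cluster-sampling design and the two
#' "messiness" fractions (districts never visited by a survey, and survey
#' sites located only to province level, as happens when district names are
#' missing from a survey).
#'
#' Each admin1 ("province") holds a rectangular rook-contiguity lattice of
#' admin2 ("districts"), so the within-country adjacency graph has one
#' connected component per province.
#'
#' @param n_countries number of countries.
#' @param admin1_per_country provinces per country.
#' @param admin2_lattice integer vector of length 2: the lattice of districts
#'   inside each province (rows, cols).
#' @param contiguity `"rook"` (edge-sharing, the default) or `"queen"`
#'   (edge- or corner-sharing) lattice neighbourhood.
#' @param sites_per_admin2_per_year survey clusters generated per district,
#'   stratum and survey year.
#' @param households_per_site households interviewed per cluster (DHS-style
#'   cluster take; default 25).
#' @param survey_years calendar years in which surveys take place.
#' @param fraction_unsampled_admin2 fraction of districts (per country) that
#'   receive no survey sites at all.
#' @param fraction_admin1_only fraction of emitted sites whose district is
#'   unknown (located to province only).
#' @param seed integer seed making the whole scenario reproducible.
#' @return a list of class `wss_sim_config`.
#' @export
sim_config <- function(n_countries = 3,
                       admin1_per_country = 2,
                       admin2_lattice = c(3, 3),
                       contiguity = c("rook", "queen"),
                       sites_per_admin2_per_year = 2,
                       households_per_site = 25,
                       survey_years = c(1998, 2005, 2011),
                       fraction_unsampled_admin2 = 0,
                       fraction_admin1_only = 0,
                       seed = 1L) {
  contiguity <- match.arg(contiguity)
  counts <- c(n_countries = n_countries,
              admin1_per_country = admin1_per_country,
              sites_per_admin2_per_year = sites_per_admin2_per_year,
              households_per_site = households_per_site)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("configuration error: counts must be positive integers: ",
         paste(names(counts)[counts <= 0 | counts != round(counts)],
               collapse = ", "))
  if (length(admin2_lattice) != 2 || any(admin2_lattice < 1))
    stop("configuration error: admin2_lattice must be two positive integers")
  fr <- c(fraction_unsampled_admin2, fraction_admin1_only)
  if (any(fr < 0 | fr > 1))
    stop("configuration error: fractions must lie in [0, 1]")
  if (length(survey_years) < 1)
    stop("configuration error: at least one survey year required")
  structure(list(
    n_countries = as.integer(n_countries),
    admin1_per_country = as.integer(admin1_per_country),
    admin2_lattice = as.integer(admin2_lattice),
    contiguity = contiguity,
    sites_per_admin2_per_year = as.integer(sites_per_admin2_per_year),
    households_per_site = as.integer(households_per_site),
    survey_years = as.integer(survey_years),
    fraction_unsampled_admin2 = fraction_unsampled_admin2,
    fraction_admin1_only = fraction_admin1_only,
    seed = as.integer(seed)
  ), class = "wss_sim_config")
}

lattice_edges <- function(nr, nc, contiguity = "rook") {
  # node id = (row-1)*nc + col, 1-based
  id <- function(r, c) (r - 1L) * nc + c
  e <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc) e[[length(e) + 1L]] <- c(id(r, c), id(r, c + 1L))
    if (r < nr) e[[length(e) + 1L]] <- c(id(r, c), id(r + 1L, c))
    if (contiguity == "queen" && r < nr) {
      if (c < nc) e[[length(e) + 1L]] <- c(id(r, c), id(r + 1L, c + 1L))
      if (c > 1L) e[[length(e) + 1L]] <- c(id(r, c), id(r + 1L, c - 1L))
    }
  }
  if (length(e) == 0) matrix(integer(), ncol = 2) else do.call(rbind, e)
}

#' Build a nested administrative hierarchy with district adjacency
#'
#' Countries contain provinces (admin1), provinces contain a lattice of
#' districts (admin2).  Adjacency is within-country only; districts with no
#' neighbours are recorded as islands.
#'
#' @param config a [sim_config()].
#' @return list of class `admin_hierarchy` with elements `countries`,
#'   `admin1` (ids), `admin2` (ids), `admin1_of` (named: admin1 -> country),
#'   `admin2_of` (named: admin2 -> admin1), `country_of_admin2`, `adjacency`
#'   (two-column character matrix of unordered admin2 pairs) and `islands`.
#' @export
build_admin_hierarchy <- function(config) {
  stopifnot(inherits(config, "wss_sim_config"))
  countries <- sprintf("C%02d", seq_len(config$n_countries))
  admin1 <- character(0); admin1_of <- character(0)
  admin2 <- character(0); admin2_of <- character(0)
  edges <- list()
  nr <- config$admin2_lattice[1]; nc <- config$admin2_lattice[2]
  for (co in countries) {
    for (a in seq_len(config$admin1_per_country)) {
      a1 <- sprintf("%s_A%02d", co, a)
      admin1 <- c(admin1, a1)
      admin1_of[a1] <- co
      ids <- sprintf("%s_D%02d", a1, seq_len(nr * nc))
      admin2 <- c(admin2, ids)
      admin2_of[ids] <- a1
      le <- lattice_edges(nr, nc, config$contiguity)
      if (nrow(le) > 0)
        edges[[length(edges) + 1L]] <- cbind(ids[le[, 1]], ids[le[, 2]])
    }
  }
  adjacency <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(), ncol = 2)
  deg <- table(factor(c(adjacency), levels = admin2))
  islands <- admin2[deg == 0]
  country_of_admin2 <- admin1_of[admin2_of[admin2]]
  names(country_of_admin2) <- admin2
  structure(list(countries = countries, admin1 = admin1, admin2 = admin2,
                 admin1_of = admin1_of, admin2_of = admin2_of,
                 country_of_admin2 = country_of_admin2,
                 adjacency = adjacency, islands = islands),
            class = "admin_hierarchy")
}

#' Neighbour list of an admin hierarchy
#'
#' @param hierarchy an `admin_hierarchy`.
#' @return named list: admin2 id -> character vector of neighbouring admin2.
#' @export
neighbour_list <- function(hierarchy) {
  nb <- stats::setNames(vector("list", length(hierarchy$admin2)),
                        hierarchy$admin2)
  for (j in hierarchy$admin2) nb[[j]] <- character(0)
  adj <- hierarchy$adjacency
  if (nrow(adj)) for (i in seq_len(nrow(adj))) {
    nb[[adj[i, 1]]] <- c(nb[[adj[i, 1]]], adj[i, 2])
    nb[[adj[i, 2]]] <- c(nb[[adj[i, 2]]], adj[i, 1])
  }
  nb
}

#' Synthetic urban/rural district population table
#'
#' Draws district populations around a typical size of ~200,000 people
#' (log-normal, CV about 0.5) and splits each into urban and rural parts with
#' a Beta-distributed urban fraction (mean ~1/3, reflecting predominantly
#' rural sub-Saharan settings).
#'
#' @param hierarchy an `admin_hierarchy`.
#' @param mean_population expected district population.
#' @param urban_fraction optional fixed urban share applied to every
#'   district (overrides the Beta draw; useful for controlled designs).
#' @param seed integer seed.
#' @return tibble with columns `admin2`, `P_urban`, `P_rural`.
#' @export
make_population_table <- function(hierarchy, mean_population = 2e5,
                                  urban_fraction = NULL, seed = 1L) {
  withr::with_seed(seed, {
    n <- length(hierarchy$admin2)
    sdl <- sqrt(log(1 + 0.5^2))
    tot <- stats::rlnorm(n, log(mean_population) - sdl^2 / 2, sdl)
    urb <- if (is.null(urban_fraction)) stats::rbeta(n, 2, 4)
           else rep(urban_fraction, n)
    tibble::tibble(admin2 = hierarchy$admin2,
                   P_urban = round(tot * urb),
                   P_rural = round(tot * (1 - urb)))
  })
}

#' Write / read an admin2 adjacency edge list
#'
#' Plain two-column whitespace-separated text, one unordered pair per line.
#'
#' @param hierarchy an `admin_hierarchy` (for writing).
#' @param path file path.
#' @export
write_adjacency <- function(hierarchy, path) {
  utils::write.table(hierarchy$adjacency, path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @return `read_adjacency()`: a two-column character matrix.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  x <- utils::read.table(path, colClasses = "character")
  as.matrix(x)
}
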