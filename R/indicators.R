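# Indicator classification follows the WHO/UNICEF JMP category lists, with
# two deliberate departures used throughout this package: shared facilities
# are NOT demoted to unimproved in the main improved-sanitation indicator
# (a separate private_improved flag carries that distinction), and pit
# latrines whose slab status is unknown (older DHS coding) are counted as
# unimproved to avoid misclassification.

.wss_env <- new.env(parent = emptyenv())

normalize_category <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Load the water/sanitation category vocabulary
#'
#' The vocabulary is data, not code: a CSV with columns
#' `domain` (`water`/`sanitation`), `category` (normalized string) and
#' `class` (`improved`/`unimproved`/`open_defecation`).  Survey-specific
#' synonyms can be supplied through `extra`.
#'
#' @param extra optional data frame with the same columns, appended to the
#'   packaged vocabulary (taking precedence on duplicates).
#' @return data frame vocabulary.
#' @export
category_vocabulary <- function(extra = NULL) {
  if (is.null(.wss_env$vocab)) {
    path <- system.file("extdata", "wss_categories.csv", package = "wsscover")
    .wss_env$vocab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  v <- .wss_env$vocab
  if (!is.null(extra)) {
    stopifnot(all(c("domain", "category", "class") %in% names(extra)))
    extra$category <- normalize_category(extra$category)
    v <- rbind(extra, v)
    v <- v[!duplicated(v[c("domain", "category")]), ]
  }
  v
}

lookup_class <- function(domain, category, vocab) {
  key <- normalize_category(category)
  hit <- vocab$class[vocab$domain == domain & vocab$category == key]
  if (length(hit)) hit[1] else NA_character_
}

#' Classify a drinking-water source category
#'
#' A source is improved if it appears in the JMP improved-water list
#' (piped into dwelling / to yard, public tap or standpipe, tubewell or
#' borewell, protected dug well, protected spring, rainwater).  It is
#' additionally *accessible* improved when within `km_threshold` km or
#' `minutes_threshold` minutes of the household; when neither distance nor
#' time is supplied the accessible flag is `NA`.
#'
#' Unknown categories are treated as unimproved (and reported via a
#' `"wss_unknown_category"` condition class message).
#'
#' @param category water-source category string.
#' @param minutes one-way time to source, minutes (optional).
#' @param km distance to source, km (optional).
#' @param minutes_threshold,km_threshold accessibility thresholds
#'   (defaults 15 min / 1 km).
#' @param vocab vocabulary from [category_vocabulary()].
#' @return list with logical `improved` and `accessible_improved`.
#' @export
classify_water_source <- function(category, minutes = NULL, km = NULL,
                                  minutes_threshold = 15, km_threshold = 1,
                                  vocab = category_vocabulary()) {
  stopifnot(nzchar(category))
  cls <- lookup_class("water", category, vocab)
  if (is.na(cls)) {
    message("unknown water category '", category, "' -> unimproved")
    cls <- "unimproved"
  }
  improved <- cls == "improved"
  accessible <- if (is.null(minutes) && is.null(km)) NA else {
    improved && ((!is.null(km) && km <= km_threshold) ||
                 (!is.null(minutes) && minutes <= minutes_threshold))
  }
  list(improved = improved, accessible_improved = accessible)
}

#' Classify a sanitation facility category
#'
#' Improved facilities are those in the JMP improved-sanitation list (flush
#' toilet, piped sewer system, septic tank, VIP latrine, pit latrine with
#' slab, composting toilet).  Pit latrines of unknown slab status
#' (`slab_known = FALSE`, pre-2003 DHS coding) are classed unimproved.
#' Sharing never demotes the main indicator; `private_improved` is
#' `improved AND !shared` (`NA` when sharing is unknown).  Open defecation is
#' "no facilities / bush / field".
#'
#' @param category facility category string.
#' @param shared logical: facility shared with other households (optional).
#' @param slab_known logical: whether the survey distinguishes pit-latrine
#'   slab status (default `TRUE`).
#' @param vocab vocabulary from [category_vocabulary()].
#' @return list with logicals `improved`, `open_defecation` and
#'   `private_improved` (possibly `NA`).
#' @export
classify_sanitation <- function(category, shared = NULL, slab_known = TRUE,
                                vocab = category_vocabulary()) {
  stopifnot(nzchar(category))
  key <- normalize_category(category)
  cls <- lookup_class("sanitation", category, vocab)
  if (is.na(cls)) {
    message("unknown sanitation category '", category, "' -> unimproved")
    cls <- "unimproved"
  }
  improved <- cls == "improved"
  if (!slab_known && grepl("pit latrine", key)) improved <- FALSE
  od <- cls == "open_defecation"
  private <- if (is.null(shared) || is.na(shared)) NA
             else improved && !shared
  list(improved = improved, open_defecation = od,
       private_improved = private)
}

#' Aggregate household rows to site-level binomial records
#'
#' Per site and indicator, `n` counts households with a non-missing response
#' and `k` those classified positive.  Sites with no non-missing response for
#' an indicator carry `NA` for its `n`/`k`; entirely empty sites produce a
#' warning and are dropped.
#'
#' @param households data frame with columns `site`, `country`, `admin1`,
#'   `admin2`, `urban`, `year` and one logical column per indicator (any of
#'   `improved_water`, `improved_sanitation`, `open_defecation`,
#'   `accessible_improved_water`, `private_improved_sanitation`), `NA`
#'   allowed.
#' @return tibble with one row per site: location fields, per-indicator
#'   `n_<indicator>` and `k_<indicator>`, plus `n_households` (max n over
#'   indicators) and `weight = 1`.
#' @export
aggregate_to_sites <- function(households) {
  need <- c("site", "country", "admin1", "admin2", "urban", "year")
  stopifnot(all(need %in% names(households)))
  inds <- intersect(c("improved_water", "improved_sanitation",
                      "open_defecation", "accessible_improved_water",
                      "private_improved_sanitation"), names(households))
  if (!length(inds)) stop("no indicator columns found")
  # location fields must be constant within a site
  for (s in unique(households$site)) {
    rows <- households[households$site == s, need[-1]]
    if (nrow(unique(rows)) > 1)
      stop("inconsistent location fields for site '", s, "'")
  }
  sites <- households[!duplicated(households$site),
                      c("site", need[-1])]
  out <- tibble::as_tibble(sites)
  for (ind in inds) {
    n <- tapply(!is.na(households[[ind]]), households$site, sum)
    k <- tapply(households[[ind]], households$site,
                function(x) sum(x, na.rm = TRUE))
    n <- as.integer(n[out$site]); k <- as.integer(k[out$site])
    k[n == 0] <- NA_integer_
    n[n == 0] <- NA_integer_
    out[[paste0("n_", ind)]] <- n
    out[[paste0("k_", ind)]] <- k
  }
  ncols <- paste0("n_", inds)
  allna <- apply(is.na(as.data.frame(out[ncols])), 1, all)
  if (any(allna)) {
    warning("dropping ", sum(allna), " site(s) with no responses: ",
            paste(out$site[allna], collapse = ", "))
    out <- out[!allna, , drop = FALSE]
  }
  out$n_households <- suppressWarnings(
    apply(as.data.frame(out[ncols]), 1, max, na.rm = TRUE))
  out$weight <- 1
  out
}

#' Allocate province-only sites across their districts
#'
#' A site located only to admin1 is replaced by one copy per admin2 in that
#' admin1, each down-weighted by 1/m so the total information mass is
#' conserved (weights enter the likelihood as a power on the binomial
#' contribution).  Located sites pass through unchanged.
#'
#' @param records site-level tibble with `admin1`, `admin2` (may be `NA`)
#'   and `weight` columns.
#' @param hierarchy an `admin_hierarchy`.
#' @return tibble with no `NA` admin2 and total weight equal to the input
#'   row count.
#' @export
allocate_admin1_only <- function(records, hierarchy) {
  if (!"allocated" %in% names(records)) records$allocated <- FALSE
  miss <- is.na(records$admin2)
  if (!any(miss)) return(records)
  kept <- records[!miss, , drop = FALSE]
  pieces <- list(kept)
  a2_by_a1 <- split(hierarchy$admin2, hierarchy$admin2_of[hierarchy$admin2])
  for (i in which(miss)) {
    a1 <- records$admin1[i]
    targets <- a2_by_a1[[a1]]
    if (is.null(targets) || !length(targets))
      stop("admin1 '", a1, "' contains no admin2; cannot allocate")
    m <- length(targets)
    rep_rows <- records[rep(i, m), , drop = FALSE]
    rep_rows$admin2 <- targets
    rep_rows$weight <- records$weight[i] / m
    rep_rows$allocated <- TRUE
    pieces[[length(pieces) + 1L]] <- rep_rows
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
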