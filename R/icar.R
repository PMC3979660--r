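#' Graph Laplacian of an adjacency edge list
#'
#' @param ids node ids (defines row/column order).
#' @param edges two-column matrix of unordered id pairs.
#' @return dense Laplacian matrix D - W with dimnames `ids`.
#' @keywords internal
graph_laplacian <- function(ids, edges) {
  n <- length(ids)
  L <- matrix(0, n, n, dimnames = list(ids, ids))
  if (NROW(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    L[a, b] <- L[a, b] - 1
    L[b, a] <- L[b, a] - 1
    L[a, a] <- L[a, a] + 1
    L[b, b] <- L[b, b] + 1
  }
  L
}

icar_components <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[ids]
  stats::setNames(as.integer(comp), ids)
}

#' Sample intrinsic CAR (ICAR) spatial effects
#'
#' Draws district effects from the proper representative of the intrinsic CAR
#' distribution: a zero-mean Gaussian with covariance
#' \eqn{\sigma_u^2 L^{+}} (Laplacian pseudo-inverse), realised through the
#' spectral decomposition of each connected component's Laplacian, which
#' enforces the per-component sum-to-zero constraint by construction.
#' Islands (districts with no neighbours) receive exactly 0.
#'
#' @param hierarchy an `admin_hierarchy`.
#' @param sigma_u named numeric: ICAR standard deviation per country (a
#'   single unnamed value is recycled).
#' @param seed integer seed.
#' @return named numeric vector over `hierarchy$admin2`.
#' @export
sample_icar_effects <- function(hierarchy, sigma_u, seed = 1L) {
  if (is.null(names(sigma_u)))
    sigma_u <- stats::setNames(rep(sigma_u[1], length(hierarchy$countries)),
                               hierarchy$countries)
  if (any(sigma_u < 0)) stop("sigma_u must be non-negative")
  u <- stats::setNames(numeric(length(hierarchy$admin2)), hierarchy$admin2)
  withr::with_seed(seed, {
    for (co in hierarchy$countries) {
      ids <- hierarchy$admin2[hierarchy$country_of_admin2 == co]
      if (!length(ids)) next
      s <- sigma_u[[co]]
      if (s == 0) next
      keep <- if (nrow(hierarchy$adjacency))
        hierarchy$adjacency[hierarchy$adjacency[, 1] %in% ids, , drop = FALSE]
      else hierarchy$adjacency
      comp <- icar_components(ids, keep)
      for (cc in unique(comp)) {
        members <- ids[comp == cc]
        if (length(members) < 2) next  # island: stays 0
        ec <- keep[keep[, 1] %in% members, , drop = FALSE]
        L <- graph_laplacian(members, ec)
        es <- eigen(L, symmetric = TRUE)
        pos <- es$values > max(es$values) * 1e-10
        z <- stats::rnorm(sum(pos))
        draw <- es$vectors[, pos, drop = FALSE] %*%
          (z / sqrt(es$values[pos]))
        draw <- s * as.numeric(draw)
        u[members] <- draw - mean(draw)  # exact re-centre (numerical)
      }
    }
  })
  u
}

#' Conditional distribution of missing ICAR effects given observed ones
#'
#' For a Gaussian Markov random field with (intrinsic) precision
#' \eqn{Q = (D - W)/\sigma^2}, the effects at missing nodes given observed
#' nodes are Gaussian with mean \eqn{-Q_{mm}^{-1} Q_{mo} u_o} and covariance
#' \eqn{Q_{mm}^{-1}}.  For a single missing node this reduces to the familiar
#' full conditional: Normal(mean of the neighbours' effects,
#' \eqn{\sigma^2 / m_j}).  The conditional is proper whenever every missing
#' node's connected component contains at least one observed node.
#'
#' @param ids all node ids in the (sub)graph.
#' @param edges two-column matrix of unordered id pairs among `ids`.
#' @param u_obs named numeric of observed effects (names are a subset of
#'   `ids`; the rest are treated as missing).
#' @param sigma ICAR standard deviation (scales the covariance only).
#' @return list with `missing` (ids), `mean` (named numeric) and `cov`
#'   (matrix); missing nodes in fully unobserved components get mean 0 and
#'   are listed in `$unanchored`.
#' @export
icar_conditional <- function(ids, edges, u_obs, sigma = 1) {
  miss <- setdiff(ids, names(u_obs))
  if (!length(miss))
    return(list(missing = character(0), mean = numeric(0),
                cov = matrix(0, 0, 0), unanchored = character(0)))
  comp <- icar_components(ids, edges)
  unanchored <- miss[!(comp[miss] %in% comp[names(u_obs)])]
  miss_ok <- setdiff(miss, unanchored)
  mean_out <- stats::setNames(numeric(length(miss)), miss)
  cov_out <- matrix(0, length(miss), length(miss),
                    dimnames = list(miss, miss))
  if (length(miss_ok)) {
    L <- graph_laplacian(ids, edges)
    Qmm <- L[miss_ok, miss_ok, drop = FALSE]
    Qmo <- L[miss_ok, names(u_obs), drop = FALSE]
    Vm <- solve(Qmm)
    mean_out[miss_ok] <- -as.numeric(Vm %*% (Qmo %*% u_obs[names(u_obs)]))
    cov_out[miss_ok, miss_ok] <- sigma^2 * Vm
  }
  list(missing = miss, mean = mean_out, cov = cov_out,
       unanchored = unanchored)
}
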