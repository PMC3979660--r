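#' Split R-hat of one scalar parameter
#'
#' Potential scale reduction factor computed on chains split in half,
#' following the standard BDA formulation.
#'
#' @param x iterations x chains matrix of draws.
#' @return scalar R-hat; `NA` if the draws are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- floor(nrow(x) / 2)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of one scalar parameter
#'
#' Multi-chain ESS using chain-averaged autocovariances and Geyer's initial
#' monotone positive sequence to truncate the autocorrelation sum.
#'
#' @param x iterations x chains matrix of draws.
#' @return scalar ESS; `NA` if the draws are constant.
#' @export
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- if (m > 1) n * stats::var(colMeans(x)) else 0
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 2, 1000)
  acov <- sapply(seq_len(m), function(ch) {
    a <- stats::acf(x[, ch], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer: sum consecutive pairs while positive and non-increasing
  npairs <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (p in seq_len(npairs)) {
    pr <- rho[2 * p - 1] + rho[2 * p]
    if (pr < 0) break
    pr <- min(pr, prev)
    tau <- tau + 2 * pr
    prev <- pr
  }
  m * n / tau
}

#' Convergence diagnostics for fitted draws
#'
#' Split R-hat and effective sample size for every stored scalar parameter,
#' plus per-chain acceptance rates.  Parameters with R-hat above 1.05 (or
#' undefined diagnostics, e.g. constant chains) are flagged.
#'
#' @param draws a `wss_draws`.
#' @param blocks which parameter blocks to monitor.
#' @return list with `summary` (tibble: param, rhat, ess, flagged),
#'   `accept` (matrix), and `any_flagged`.  With a single chain R-hat is
#'   omitted with a warning.
#' @export
diagnostics <- function(draws,
                        blocks = c("mu_alpha", "mu_beta", "alpha", "beta",
                                   "sigma_alpha", "sigma_beta", "sigma_u",
                                   "sigma_v", "u", "v")) {
  stopifnot(inherits(draws, "wss_draws"))
  single <- draws$n_chains < 2
  if (single)
    warning("single chain: R-hat omitted; run >= 2 chains for diagnostics")
  rows <- list()
  for (b in blocks) {
    cols <- colnames(draws$chains[[1]][[b]])
    for (j in seq_along(cols)) {
      mat <- sapply(draws$chains, function(ch) ch[[b]][, j])
      rhat <- if (single) NA_real_ else split_rhat(mat)
      ess <- ess_mean(mat)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        param = paste0(b, "[", cols[j], "]"),
        rhat = rhat, ess = ess,
        flagged = (!single && (is.na(rhat) || rhat > 1.05)) ||
          is.na(ess))
    }
  }
  summary <- do.call(rbind, rows)
  accept <- do.call(rbind, lapply(draws$accept, function(a)
    stats::setNames(as.numeric(a), names(a))))
  list(summary = summary, accept = accept,
       any_flagged = any(summary$flagged))
}
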