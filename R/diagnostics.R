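#' Effective sample size of a scalar MCMC trace
#'
#' Autocorrelation-time estimator with Geyer's initial-positive-sequence
#' truncation: autocorrelations are summed in consecutive pairs until a pair
#' sum turns non-positive, and `ESS = n / (1 + 2 * sum(rho))`.
#'
#' @param x numeric vector (one scalar statistic across draws).
#' @return effective sample size (numeric scalar, capped at `length(x)`).
#' @export
trace_ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(as.numeric(n))
  lag_max <- min(n - 2L, 2000L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  s <- 0
  m <- 0
  while (2 * m + 2 <= length(rho)) {
    pair <- rho[2 * m + 1] + rho[2 * m + 2]
    if (pair <= 0) break
    s <- s + pair
    m <- m + 1
  }
  tau <- 1 + 2 * s
  min(n / tau, n)
}

#' Between-chain discrepancy of a scalar statistic
#'
#' The absolute difference of the two chain means divided by the pooled
#' standard deviation (the convention of the `tracecomp` convergence tool
#' used with phylogenetic MCMC); 0 for identical chains, values below 0.2
#' indicate good agreement.
#'
#' @param x,y numeric vectors (the same statistic from two chains).
#' @return non-negative numeric scalar.
#' @export
chain_discrepancy <- function(x, y) {
  sp <- sqrt((stats::var(x) * (length(x) - 1) +
                stats::var(y) * (length(y) - 1)) /
               (length(x) + length(y) - 2))
  if (!is.finite(sp) || sp == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 0 else Inf)
  }
  abs(mean(x) - mean(y)) / sp
}

#' Convergence diagnostics across two independent chains
#'
#' For every scalar statistic of the traces (post burn-in), reports the
#' effective sample size of each chain and the between-chain discrepancy.
#'
#' @param fit1,fit2 two `codon_fit` objects (or plain tibbles with an `iter`
#'   column) from independent chains of the same analysis.
#' @param burnin number of initial sweeps to discard; defaults to the fits'
#'   configured burn-in.
#' @return a tibble with columns `statistic`, `ess1`, `ess2`, `min_ess`,
#'   `discrepancy`.
#' @export
diagnostics <- function(fit1, fit2, burnin = NULL) {
  tr1 <- if (inherits(fit1, "codon_fit")) fit1$trace else tibble::as_tibble(fit1)
  tr2 <- if (inherits(fit2, "codon_fit")) fit2$trace else tibble::as_tibble(fit2)
  if (!identical(names(tr1), names(tr2))) {
    stop("traces have different statistic schemas", call. = FALSE)
  }
  if (is.null(burnin)) {
    burnin <- if (inherits(fit1, "codon_fit")) fit1$config$burnin else 0
  }
  tr1 <- tr1[tr1$iter > burnin, , drop = FALSE]
  tr2 <- tr2[tr2$iter > burnin, , drop = FALSE]
  stats_cols <- setdiff(names(tr1), "iter")
  purrr::map_dfr(stats_cols, function(s) {
    e1 <- trace_ess(tr1[[s]]); e2 <- trace_ess(tr2[[s]])
    tibble::tibble(statistic = s, ess1 = e1, ess2 = e2,
                   min_ess = min(e1, e2),
                   discrepancy = chain_discrepancy(tr1[[s]], tr2[[s]]))
  })
}
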