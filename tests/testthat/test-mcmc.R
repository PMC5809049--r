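test_that("prior draws are reproducible and match the stated marginals", {
  ct <- test_ct2()
  s1 <- sample_prior(ct, 5, "DS", seed = 99)
  s2 <- sample_prior(ct, 5, "DS", seed = 99)
  expect_identical(s1, s2)
  # every fitness profile lies on the simplex
  expect_equal(apply(s1$F, c(1, 2), sum), matrix(1, 5, 2),
               tolerance = 1e-12)
  # Monte-Carlo check of the hyperprior mean of lambda (Exponential, mean 0.1)
  set.seed(123)
  draws <- vapply(1:5000, function(i) sample_prior(ct, 1, "DS")$lambda, 0)
  expect_lt(abs(mean(draws) - 0.1), 4 * 0.1 / sqrt(5000))
  # OM draws respect the gamma shape/scale parameterization
  so <- sample_prior(ct, 2000, "OM", seed = 7)
  expect_equal(mean(so$omega[, 1]), so$alpha[1] * so$beta[1],
               tolerance = 0.15 * so$alpha[1] * so$beta[1] + 0.05)
})

test_that("seeded chains are bit-reproducible", {
  ct <- test_ct2()
  m <- test_mutation()
  sim <- simulate_alignment(ct, m, test_fitness(4, 2, seed = 31), seed = 32)
  f1 <- run_chain(sim$aln, ct, model = "DS", n_iter = 40, burnin = 10,
                  seed = 5)
  f2 <- run_chain(sim$aln, ct, model = "DS", n_iter = 40, burnin = 10,
                  seed = 5)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$F_draws, f2$F_draws)
})

test_that("stochastic mapping conserves time and respects tip data", {
  ct <- test_ct2()
  m <- test_mutation()
  F <- test_fitness(6, 2, seed = 41)
  sim <- simulate_alignment(ct, m, F, seed = 42)
  set.seed(43)
  map <- stochastic_map(sim$aln, ct, m, F)
  # total mapped time per condition = branch length in condition x sites
  for (k in 0:1) {
    expect_equal(map$condwait[k + 1],
                 sum(map$elen[map$econd == k]) * ncol(sim$aln),
                 tolerance = 1e-9)
  }
  # mapped tip states equal the observed codons
  tips0 <- codonDS:::.tips_for_cpp(sim$aln, ct)
  expect_identical(map$nodestate[1:4, ], unname(tips0))
  # per-branch dwells on each site sum to the branch length
  agg <- tapply(map$segments$dwell,
                list(map$segments$site, map$segments$edge), sum)
  for (e in seq_along(map$elen)) {
    expect_equal(unname(agg[, e]), rep(map$elen[e], 6), tolerance = 1e-9)
  }
})

test_that("pruning likelihood agrees with a direct matrix-exponential oracle", {
  m <- test_mutation()
  tr <- read_newick("((A:0.2,B:0.3):0.1,C:0.4);")
  ct <- conditioned_tree(tr, rep(0L, nrow(tr$edge)), K = 1L)
  F <- test_fitness(4, 1, seed = 51)
  sim <- simulate_alignment(ct, m, F, seed = 52)
  ll <- site_loglik(sim$aln, ct, m, F)

  po <- ape::reorder.phylo(ct$tree, "postorder")
  brute <- vapply(1:4, function(i) {
    R <- ds_rate_matrix(m, F, i, 1)
    st <- ds_stationary(m, F, i, 1)
    P <- function(t) {
      e <- eigen(diag(sqrt(st)) %*% R %*% diag(1 / sqrt(st)),
                 symmetric = TRUE)
      diag(1 / sqrt(st)) %*% e$vectors %*% diag(exp(e$values * t)) %*%
        t(e$vectors) %*% diag(sqrt(st))
    }
    tipstate <- sim$aln[ct$tree$tip.label, i]
    L <- matrix(1, 61, 5)
    for (t in 1:3) { L[, t] <- 0; L[tipstate[t], t] <- 1 }
    for (e in seq_len(nrow(po$edge))) {
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      L[, par] <- L[, par] * as.vector(P(po$edge.length[e]) %*% L[, ch])
    }
    log(sum(st * L[, 4]))
  }, 0)
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("endpoint-conditioned paths match a forward-simulation oracle", {
  # on a single branch with fixed endpoints, the sampled number of
  # substitutions must follow the same distribution as rejection-sampled
  # forward (Gillespie) paths
  m <- test_mutation()
  F <- test_fitness(1, 1, seed = 2)
  R <- ds_rate_matrix(m, F, 1, 1)
  gc <- genetic_code()
  a <- match("GCT", gc$codons); b <- match("TCT", gc$codons)
  t_len <- 0.6

  set.seed(99)
  fwd <- codonDS:::cpp_forward_paths(R, a, t_len, 200000)
  sel <- fwd[, 2] == b
  expect_gt(sum(sel), 5000)
  p_fwd <- tabulate(pmin(fwd[sel, 1], 5) + 1L, 6)
  p_fwd <- p_fwd / sum(p_fwd)

  # mapping sampler: 2-taxon tree, one informative branch of length t, the
  # other (near-zero) branch pins the second endpoint
  tr <- read_newick(sprintf("(A:%f,B:0.000001);", t_len))
  ct <- conditioned_tree(tr, c(0L, 0L), K = 1L)
  aln <- as_codon_alignment(matrix(c(b, a), 2, 1,
                                   dimnames = list(c("A", "B"), NULL)))
  set.seed(7)
  counts <- integer(6)
  long_edge <- NULL
  for (r in 1:3000) {
    map <- stochastic_map(aln, ct, m, F)
    if (is.null(long_edge)) long_edge <- which(map$elen > 1e-4)
    n <- sum(map$events$edge == long_edge)
    counts[min(n, 5) + 1] <- counts[min(n, 5) + 1] + 1
  }
  keep <- p_fwd > 0.002
  chi <- sum((counts[keep] - sum(counts) * p_fwd[keep])^2 /
               (sum(counts) * p_fwd[keep]))
  expect_lt(chi, qchisq(0.999, df = sum(keep) - 1))
})

test_that("a data-free sweep targets the prior (lambda recovery)", {
  ct <- test_ct2()
  aln <- masked_alignment(c("A", "B", "C", "D"), 2)
  fit <- run_chain(aln, ct, model = "DS", n_iter = 6000, burnin = 300,
                   seed = 11)
  lam <- fit$trace$lambda[fit$trace$iter > 300]
  # the hyperprior mean is 0.1; the bound allows for the chain's
  # autocorrelation (effective size a few hundred) while catching any
  # gross bias of the kind a broken Hastings ratio produces
  expect_lt(abs(mean(lam) - 0.1), 0.03)
  # support is respected throughout
  expect_true(all(lam > 0))
  expect_true(all(fit$trace$tree_length > 0))
  expect_true(all(fit$F_draws >= 0 & fit$F_draws <= 1, na.rm = TRUE))
})

test_that("ESS estimator matches analytic expectations", {
  set.seed(61)
  x <- rnorm(4000)
  expect_equal(trace_ess(x), 4000, tolerance = 0.15 * 4000)
  # AR(1) with rho = 0.5: ESS ~= n (1 - rho) / (1 + rho) = n / 3
  rho <- 0.5
  ar <- as.numeric(arima.sim(list(ar = rho), 8000))
  expect_equal(trace_ess(ar), 8000 * (1 - rho) / (1 + rho),
               tolerance = 0.25 * 8000 / 3)
})

test_that("chain discrepancy is zero for identical traces and errors on schema mismatch", {
  ct <- test_ct2()
  aln <- masked_alignment(c("A", "B", "C", "D"), 1)
  fit <- run_chain(aln, ct, model = "DS", n_iter = 60, burnin = 10, seed = 3)
  d <- diagnostics(fit, fit)
  expect_true(all(d$discrepancy == 0))
  expect_equal(chain_discrepancy(1:10, 1:10), 0)
  bad <- fit
  bad$trace <- dplyr::rename(bad$trace, foo = "lambda")
  expect_error(diagnostics(fit, bad), "schema")
})
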