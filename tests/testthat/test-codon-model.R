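test_that("genetic code tables have the expected structure", {
  gc <- genetic_code()
  expect_length(gc$codons, 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% gc$codons))
  expect_true(all(gc$aa_index %in% 1:20))
  # single-step pairs are symmetric and never bridge 2+ nucleotide changes
  p <- gc$pairs
  key <- paste(p$from, p$to)
  rev_key <- paste(p$to, p$from)
  expect_true(all(rev_key %in% key))
  nd <- rowSums(gc$codon_nuc[p$from, ] != gc$codon_nuc[p$to, ])
  expect_true(all(nd == 1))
})

test_that("mutation rate matrix is a normalized reversible GTR generator", {
  # equal exchangeabilities + uniform frequencies: all off-diagonals equal
  jc <- mutation_model(rep(1, 6), rep(0.25, 4))
  off <- jc$Q[row(jc$Q) != col(jc$Q)]
  expect_equal(max(off) - min(off), 0)
  expect_equal(rowSums(jc$Q), rep(0, 4), ignore_attr = TRUE)

  # off-diagonal pattern proportional to exchangeabilities at uniform pi
  m <- mutation_model(c(1, 2, 1, 1, 2, 1), rep(0.25, 4))
  expect_equal(m$Q["A", "G"] / m$Q["A", "C"], 2)
  expect_equal(m$Q["C", "T"] / m$Q["G", "T"], 2)

  # detailed balance pi_i q_ij = pi_j q_ji for arbitrary parameters
  set.seed(42)
  for (r in 1:5) {
    ex <- rexp(6); pi <- rgamma(4, 1); pi <- pi / sum(pi)
    q <- mutation_model(ex, pi)$Q
    flux <- diag(pi) %*% q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    expect_equal(-sum(pi * diag(q)), 1, tolerance = 1e-12)
  }

  expect_error(mutation_model(c(-1, 1, 1, 1, 1, 1), rep(0.25, 4)),
               "positive")
  expect_error(mutation_model(rep(1, 6), c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("scaled selection coefficient is the log fitness ratio", {
  F <- test_fitness(1, 1, seed = 3)
  expect_equal(selection_coefficient(F, 1, 1, 4, 4), 0)
  # constructed field with a known 2:1 ratio
  f <- rep(1, 20); f[2] <- 2; f[1] <- 1
  F2 <- fitness_field(array(f, c(1, 1, 20)))
  expect_equal(selection_coefficient(F2, 1, 1, "A", "C"), log(2))
  # antisymmetry
  expect_equal(selection_coefficient(F, 1, 1, 5, 11),
               -selection_coefficient(F, 1, 1, 11, 5))
})

test_that("fixation factor matches the diffusion formula and is smooth", {
  expect_equal(fixation_factor(0), 1)
  expect_equal(fixation_factor(log(2)), 2 * log(2))
  expect_equal(fixation_factor(log(2)) / fixation_factor(-log(2)), 2,
               tolerance = 1e-12)
  # identity P(S)/P(-S) = e^S on a grid
  s <- seq(-5, 5, by = 0.25)
  expect_equal(fixation_factor(s) / fixation_factor(-s), exp(s),
               tolerance = 1e-10)
  # monotone increasing on a wide grid
  g <- fixation_factor(seq(-20, 20, by = 0.05))
  expect_true(all(diff(g) > 0))
  # C1-continuity across the series-expansion switch at |S| = 1e-4:
  # central finite-difference slopes agree across the boundary
  h <- 1e-6
  slope_below <- (fixation_factor(1e-4 - h) - fixation_factor(1e-4 - 3 * h)) / (2 * h)
  slope_above <- (fixation_factor(1e-4 + 3 * h) - fixation_factor(1e-4 + h)) / (2 * h)
  expect_equal(slope_below, slope_above, tolerance = 1e-4)
  expect_equal(fixation_factor(1e-4 * (1 - 1e-9)),
               fixation_factor(1e-4 * (1 + 1e-9)), tolerance = 1e-9)
})

test_that("DS rate matrix reduces to the neutral matrix for flat profiles", {
  m <- test_mutation()
  Fflat <- fitness_field(array(1, c(1, 1, 20)))
  w1 <- omega_field(matrix(1, 1, 1))
  expect_equal(ds_rate_matrix(m, Fflat, 1, 1), om_rate_matrix(m, w1, 1, 1))
})

test_that("DS rate matrices satisfy detailed balance against the closed form", {
  set.seed(7)
  m <- test_mutation()
  F <- test_fitness(5, 2, seed = 8)
  for (i in 1:5) {
    for (k in 1:2) {
      R <- ds_rate_matrix(m, F, i, k)
      expect_lt(max(abs(rowSums(R))), 1e-10)
      st <- ds_stationary(m, F, i, k)
      flux <- diag(st) %*% R
      expect_lt(max(abs(flux - t(flux))), 1e-12)
      # numerical null-space solution agrees with the closed form
      expect_equal(unname(stationary_distribution(R)), unname(st),
                   tolerance = 1e-8)
    }
  }
})

test_that("multi-nucleotide codon changes have rate exactly zero", {
  m <- test_mutation()
  F <- test_fitness(1, 1, seed = 9)
  R <- ds_rate_matrix(m, F, 1, 1)
  gc <- genetic_code()
  nd <- as.matrix(dist(gc$codon_nuc, method = "manhattan"))
  multi <- (gc$codon_nuc[rep(1:61, 61), ] !=
              gc$codon_nuc[rep(1:61, each = 61), ])
  ndiff <- matrix(rowSums(matrix(multi, ncol = 3)), 61, 61)
  expect_true(all(R[ndiff >= 2] == 0))
})

test_that("omega scales exactly the non-synonymous rates", {
  m <- test_mutation()
  R1 <- om_rate_matrix(m, omega_field(matrix(1, 1, 1)), 1, 1)
  Rh <- om_rate_matrix(m, omega_field(matrix(0.5, 1, 1)), 1, 1)
  gc <- genetic_code()
  p <- gc$pairs
  ns <- cbind(p$from[!p$syn], p$to[!p$syn])
  sy <- cbind(p$from[p$syn], p$to[p$syn])
  expect_equal(Rh[ns], R1[ns] * 0.5)
  expect_equal(Rh[sy], R1[sy])
})

test_that("stationary_distribution rejects reducible generators", {
  R <- matrix(0, 61, 61)  # absorbing everywhere: null space dim 61
  expect_error(stationary_distribution(R), "reducible")
})
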