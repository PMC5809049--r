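test_that("zero-length branches copy the root state to every tip", {
  tr <- read_newick("((A:0,B:0):0,C:0);")
  ct <- conditioned_tree(tr, rep(0L, nrow(tr$edge)), K = 1L)
  sim <- simulate_alignment(ct, test_mutation(), test_fitness(20, 1, seed = 2),
                            seed = 5)
  for (i in 1:20) expect_true(all(sim$aln[, i] == sim$rootstate[i]))
})

test_that("long neutral simulation matches the stationary distribution", {
  m <- test_mutation()
  tr <- read_newick("(A:0.5,B:0.5);")
  ct <- conditioned_tree(tr, c(0L, 0L), K = 1L)
  w <- omega_field(matrix(1, 4000, 1))
  sim <- simulate_alignment(ct, m, w, seed = 31)
  st <- neutral_codon_stationary(m)
  emp <- tabulate(sim$aln, 61) / length(sim$aln)
  chi <- sum((emp - st)^2 / st) * length(sim$aln)
  # 60 degrees of freedom; generous quantile to keep the check sharp but
  # stable under the fixed seed
  expect_lt(chi, qchisq(0.999, df = 60))
})

test_that("realized dN/dS recovers the generating regime", {
  m <- test_mutation()
  tr <- read_newick("(A:0.4,B:0.6);")
  ct <- conditioned_tree(tr, c(0L, 0L), K = 1L)

  sim_neutral <- simulate_alignment(ct, m, omega_field(matrix(1, 4000, 1)),
                                    seed = 11)
  expect_equal(realized_dnds(sim_neutral), 1, tolerance = 0.06)

  sim_02 <- simulate_alignment(ct, m, omega_field(matrix(0.2, 4000, 1)),
                               seed = 12)
  expect_equal(realized_dnds(sim_02), 0.2, tolerance = 0.06)

  # single-condition mutation-selection process at stationarity
  sim_ds <- simulate_alignment(ct, m, test_fitness(4000, 1, seed = 13),
                               seed = 14)
  expect_lt(realized_dnds(sim_ds), 1)
})

test_that("condition-specific fitness shifts enrich the favoured amino acid", {
  m <- test_mutation()
  tr <- read_newick("(A:3,B:3);")
  ct <- conditioned_tree(tr, c(0L, 1L), K = 2L)  # one branch per condition
  # condition 0 favours alanine, condition 1 favours serine, strongly
  f0 <- codonDS:::.inject_profile("A", "S")
  f1 <- codonDS:::.inject_profile("S", "A")
  F <- array(NA_real_, c(200, 2, 20))
  for (i in 1:200) { F[i, 1, ] <- f0; F[i, 2, ] <- f1 }
  sim <- simulate_alignment(ct, m, fitness_field(F), seed = 17)
  gc <- genetic_code()
  aa_A <- gc$aa[sim$aln["A", ]]  # tip under condition 0
  aa_B <- gc$aa[sim$aln["B", ]]  # tip under condition 1
  expect_gt(mean(aa_A == "A"), mean(aa_B == "A"))
  expect_gt(mean(aa_B == "S"), mean(aa_A == "S"))
  expect_gt(mean(aa_B == "S"), 0.5)
})

test_that("substitution counts scale linearly with branch length", {
  m <- test_mutation()
  lens <- c(0.2, 0.5, 1, 2)
  counts <- sapply(lens, function(L) {
    tr <- read_newick(sprintf("(A:%f,B:0.001);", L))
    ct <- conditioned_tree(tr, c(0L, 0L), K = 1L)
    sim <- simulate_alignment(ct, m, omega_field(matrix(1, 800, 1)),
                              seed = 100 + round(L * 10))
    sum(sim$nsyn + sim$nnonsyn) / 800
  })
  fit <- lm(counts ~ lens)
  # neutral process normalized to 1 substitution/nt site => 3 per codon site
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 0.1)
  expect_lt(abs(coef(fit)[1]), 0.1)
})

test_that("benchmark fixtures are deterministic and self-contained", {
  d1 <- tempfile(); d2 <- tempfile()
  fx1 <- make_benchmark_fixture("ds3-small", d1, seed = 4)
  fx2 <- make_benchmark_fixture("ds3-small", d2, seed = 4)
  for (nm in names(fx1$paths)) {
    expect_identical(readLines(fx1$paths[[nm]]), readLines(fx2$paths[[nm]]))
  }
  # files re-read into consistent objects
  aln <- read_alignment(fx1$paths$alignment)
  tr <- read_newick(fx1$paths$tree)
  ph <- read_phenotypes(fx1$paths$phenotypes)
  expect_equal(dim(aln), c(20L, 100L))
  expect_equal(sort(rownames(aln)), sort(tr$tip.label))
  expect_equal(sum(ph == "C4"), 10)
  truth <- jsonlite::read_json(fx1$paths$truth)
  expect_equal(truth$preset, "ds3-small")

  # omega presets build on a shallower tree and record their truth
  fo <- make_benchmark_fixture("om1-small", tempfile(), seed = 2)
  expect_equal(fo$ct$K, 1L)
  expect_equal(sort(unlist(fo$truth$positive_sites)),
               which(unlist(fo$truth$omega) > 1))
  expect_lt(sum(fo$ct$tree$edge.length), 15)
  fn <- make_benchmark_fixture("neutral", tempfile(), seed = 2)
  expect_true(all(unlist(fn$truth$omega) == 1))
  expect_error(make_benchmark_fixture("nope", tempfile()), "arg")
})

test_that("time-reversed stationary histories are statistically indistinguishable", {
  # detailed-balance symmetry: for a stationary DS process the count of
  # a1 -> a2 substitutions matches a2 -> a1 within sampling error
  m <- test_mutation()
  tr <- read_newick("(A:2,B:2);")
  ct <- conditioned_tree(tr, c(0L, 0L), K = 1L)
  F <- test_fitness(1500, 1, seed = 23)
  sim <- simulate_alignment(ct, m, F, seed = 24, return_events = TRUE)
  gc <- genetic_code()
  ev <- sim$events
  key <- paste(pmin(ev$from, ev$to), pmax(ev$from, ev$to))
  dir <- ev$from < ev$to
  tab <- table(key, dir)
  both <- rownames(tab)[rowSums(tab > 0) > 0 & rowSums(tab) >= 8]
  # binomial z-scores of forward vs backward counts pooled into a chi^2
  chi <- 0; dfree <- 0
  for (k in both) {
    n <- sum(tab[k, ]); x <- tab[k, "TRUE"]
    chi <- chi + (x - n / 2)^2 / (n / 4)
    dfree <- dfree + 1
  }
  expect_gt(dfree, 5)
  expect_lt(chi, qchisq(0.999, df = dfree))
})
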