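# shared in-code fixtures for the test suite; everything is generated at
# test time, nothing is read from disk

# a small GTR mutation model with transition bias
test_mutation <- function() {
  mutation_model(c(1, 2, 1, 1, 2, 1), c(0.30, 0.19, 0.21, 0.30))
}

# a reproducible random fitness field
test_fitness <- function(nsites = 1, K = 1, seed = 1, shape = 1) {
  set.seed(seed)
  fitness_field(array(stats::rgamma(nsites * K * 20, shape, 1) + 1e-9,
                      c(nsites, K, 20)))
}

# a fully masked alignment (no data): the posterior is the prior
masked_alignment <- function(taxa, nsites) {
  aln <- matrix(NA_integer_, length(taxa), nsites,
                dimnames = list(taxa, NULL))
  structure(aln, n_nuc = 3L * nsites,
            class = c("codon_alignment", "matrix", "array"))
}

# wrap an integer codon matrix as a codon_alignment
as_codon_alignment <- function(m) {
  structure(m, n_nuc = 3L * ncol(m),
            class = c("codon_alignment", "matrix", "array"))
}

# a 4-taxon two-condition tree used across MCMC tests
test_ct2 <- function() {
  tr <- read_newick("((A:0.2,B:0.3):0.1,(C:0.2,D:0.4):0.2);")
  conditioned_tree(tr, rep(0:1, length.out = nrow(tr$edge)), K = 2L)
}

# build a minimal DS codon_fit object with explicit fitness draws, for
# testing the posterior decision layer in isolation
fake_ds_fit <- function(F_draws, burnin = 0) {
  nd <- dim(F_draws)[1]
  structure(list(
    model = "DS", K = dim(F_draws)[3], nsites = dim(F_draws)[2],
    trace = tibble::tibble(iter = seq_len(nd), loglik = 0),
    ef_iters = seq_len(nd) + burnin,
    F_draws = F_draws,
    config = list(n_iter = nd + burnin, burnin = burnin, seed = 1)
  ), class = "codon_fit")
}

fake_om_fit <- function(omega_draws, burnin = 0) {
  nd <- dim(omega_draws)[1]
  structure(list(
    model = "OM", K = dim(omega_draws)[3], nsites = dim(omega_draws)[2],
    trace = tibble::tibble(iter = seq_len(nd), loglik = 0),
    ef_iters = seq_len(nd) + burnin,
    omega_draws = omega_draws,
    config = list(n_iter = nd + burnin, burnin = burnin, seed = 1)
  ), class = "codon_fit")
}
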