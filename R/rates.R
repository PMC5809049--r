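#' Site- and condition-specific amino-acid fitness profiles
#'
#' The random-effects field of the differential-selection (DS) models: one
#' 20-vector of amino-acid fitness values per site and per branch condition.
#' Profiles are stored simplex-normalized (each sums to 1). The substitution
#' process is invariant to rescaling a profile by a positive constant, so the
#' normalization only fixes the gauge; under the model's prior each profile is
#' an independent uniform Dirichlet draw.
#'
#' @param F numeric array `sites x conditions x 20` (or a `sites x 20` matrix
#'   for a single condition) of strictly positive fitness values.
#' @return A `fitness_field` object (the normalized array with class).
#' @export
fitness_field <- function(F) {
  if (is.matrix(F)) F <- array(F, dim = c(nrow(F), 1L, ncol(F)))
  if (!is.array(F) || length(dim(F)) != 3L || dim(F)[3] != 20L) {
    stop("`F` must be a sites x conditions x 20 array", call. = FALSE)
  }
  if (any(!is.finite(F)) || any(F <= 0)) {
    stop("all fitness values must be strictly positive and finite",
         call. = FALSE)
  }
  F <- sweep_normalize_profiles(F)
  structure(F, class = "fitness_field")
}

# normalize each [i, k, ] slice of a 3-d array to sum to 1
sweep_normalize_profiles <- function(F) {
  tot <- apply(F, c(1, 2), sum)
  for (k in seq_len(dim(F)[2])) F[, k, ] <- F[, k, ] / tot[, k]
  F
}

#' Site- and condition-specific dN/dS field
#'
#' The random-effects field of the omega-based (OM) models: a positive dN/dS
#' value per site and condition, with per-condition gamma hyperparameters.
#' The gamma distribution is parameterized by shape `alpha` and *scale*
#' `beta` (mean `alpha * beta`), not shape/rate.
#'
#' @param omega numeric `sites x conditions` matrix of positive dN/dS values.
#' @param alpha,beta numeric vectors (one per condition) of positive gamma
#'   shape and scale hyperparameters; default 1.
#' @return An `omega_field` object.
#' @export
omega_field <- function(omega, alpha = NULL, beta = NULL) {
  if (is.vector(omega)) omega <- matrix(omega, ncol = 1L)
  if (!is.matrix(omega) || any(!is.finite(omega)) || any(omega <= 0)) {
    stop("`omega` must be a matrix of strictly positive values", call. = FALSE)
  }
  K <- ncol(omega)
  if (is.null(alpha)) alpha <- rep(1, K)
  if (is.null(beta)) beta <- rep(1, K)
  if (length(alpha) != K || length(beta) != K ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be positive, one per condition",
         call. = FALSE)
  }
  structure(list(omega = omega, alpha = alpha, beta = beta),
            class = "omega_field")
}

#' Scaled selection coefficient between two amino acids
#'
#' The population-scaled selection coefficient of a mutation replacing
#' amino acid `a1` (wild type) by `a2` (mutant) at site `i` under condition
#' `k`: `S = ln(F[i, k, a2] / F[i, k, a1])`. Antisymmetric in its amino-acid
#' arguments.
#'
#' @param F a [fitness_field()].
#' @param i site index.
#' @param k condition index.
#' @param a1,a2 amino acids, as indices into [aa_alphabet()] or one-letter
#'   codes.
#' @return numeric scalar.
#' @export
#' @examples
#' F <- fitness_field(array(1, c(1, 1, 20)))
#' selection_coefficient(F, 1, 1, "A", "S")  # 0 under a flat profile
selection_coefficient <- function(F, i, k, a1, a2) {
  stopifnot(inherits(F, "fitness_field"))
  a1 <- .aa_to_index(a1); a2 <- .aa_to_index(a2)
  f1 <- F[i, k, a1]; f2 <- F[i, k, a2]
  if (f1 <= 0 || f2 <= 0) stop("fitness values must be positive", call. = FALSE)
  log(f2 / f1)
}

.aa_to_index <- function(a) {
  if (is.character(a)) {
    idx <- match(toupper(a), aa_alphabet())
    if (any(is.na(idx))) stop("unknown amino acid: ", a, call. = FALSE)
    idx
  } else {
    as.integer(a)
  }
}

#' Relative fixation probability of a selection coefficient
#'
#' The diffusion-approximation fixation factor `S / (1 - exp(-S))`, the
#' probability of fixation of a mutant with scaled selection coefficient `S`
#' relative to a neutral mutant. Continuous at `S = 0` with value 1 (a Taylor
#' expansion `1 + S/2 + S^2/12` is used for `|S| < 1e-4`), strictly
#' increasing, and satisfying `P(S)/P(-S) = exp(S)`.
#'
#' @param S numeric vector of scaled selection coefficients.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' fixation_factor(0)        # 1
#' fixation_factor(log(2))   # 2 log 2
fixation_factor <- function(S) {
  S <- as.numeric(S)
  out <- numeric(length(S))
  small <- abs(S) < 1e-4
  out[small] <- 1 + S[small] / 2 + S[small]^2 / 12
  pos <- !small & S > 0
  out[pos] <- S[pos] / (1 - exp(-S[pos]))
  neg <- !small & S < 0
  # for S < 0 write as -S e^S / (1 - e^S): stable down to the underflow limit
  out[neg] <- -S[neg] * exp(S[neg]) / (1 - exp(S[neg]))
  out
}

#' Mutation-selection (differential-selection) codon rate matrix
#'
#' The 61x61 generator of the DS substitution process at one site under one
#' condition. Codon pairs differing at a single nucleotide exchange at the
#' mutation rate `Q[n1, n2]`, multiplied for non-synonymous pairs by the
#' fixation factor of the scaled selection coefficient between the two amino
#' acids; multi-nucleotide changes have rate zero.
#'
#' @param m a [mutation_model()].
#' @param F a [fitness_field()].
#' @param i site index.
#' @param k condition index.
#' @return 61x61 numeric generator (rows sum to zero), codon names attached.
#' @export
ds_rate_matrix <- function(m, F, i = 1L, k = 1L) {
  stopifnot(inherits(m, "mutation_model"), inherits(F, "fitness_field"))
  gc <- genetic_code()
  p <- gc$pairs
  logF <- log(F[i, k, ])
  R <- matrix(0, 61, 61, dimnames = list(gc$codons, gc$codons))
  rate <- m$Q[cbind(p$n1, p$n2)]
  ns <- !p$syn
  rate[ns] <- rate[ns] *
    fixation_factor(logF[p$aa_to[ns]] - logF[p$aa_from[ns]])
  R[cbind(p$from, p$to)] <- rate
  diag(R) <- -rowSums(R)
  R
}

#' Omega-based codon rate matrix
#'
#' The 61x61 generator of the Muse-Gaut style process at one site under one
#' condition: synonymous single-nucleotide changes at the mutation rate,
#' non-synonymous single-nucleotide changes at the mutation rate times the
#' site/condition dN/dS `omega`, zero otherwise.
#'
#' @param m a [mutation_model()].
#' @param w an [omega_field()].
#' @inheritParams ds_rate_matrix
#' @return 61x61 numeric generator.
#' @export
om_rate_matrix <- function(m, w, i = 1L, k = 1L) {
  stopifnot(inherits(m, "mutation_model"), inherits(w, "omega_field"))
  gc <- genetic_code()
  p <- gc$pairs
  omega <- w$omega[i, k]
  R <- matrix(0, 61, 61, dimnames = list(gc$codons, gc$codons))
  rate <- m$Q[cbind(p$n1, p$n2)]
  rate[!p$syn] <- rate[!p$syn] * omega
  R[cbind(p$from, p$to)] <- rate
  diag(R) <- -rowSums(R)
  R
}

#' Stationary distribution of a codon rate matrix
#'
#' Solves `pi R = 0` numerically (null space of the transpose); the result is
#' normalized to sum to 1. Errors if the chain is reducible (null space of
#' dimension > 1).
#'
#' @param R a square generator matrix (rows summing to 0).
#' @param tol numerical tolerance for identifying the null space.
#' @return numeric vector summing to 1.
#' @export
stationary_distribution <- function(R, tol = 1e-8) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  d <- svd(t(R))
  null_dim <- sum(d$d < tol * max(d$d))
  if (null_dim != 1L) {
    stop("rate matrix is reducible (null space dimension ", null_dim, ")",
         call. = FALSE)
  }
  v <- d$v[, ncol(R)]
  v <- v / sum(v)
  if (any(v < -tol)) stop("negative stationary entries; invalid generator",
                          call. = FALSE)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(R))
}

#' Closed-form stationary distribution of a DS codon process
#'
#' At mutation-selection balance the stationary probability of codon `c` is
#' proportional to the product of the mutational equilibrium frequencies of
#' its three nucleotides times the fitness of its encoded amino acid.
#'
#' @inheritParams ds_rate_matrix
#' @return numeric(61) summing to 1.
#' @export
ds_stationary <- function(m, F, i = 1L, k = 1L) {
  gc <- genetic_code()
  w <- exp(log(m$pi)[gc$codon_nuc[, 1]] +
             log(m$pi)[gc$codon_nuc[, 2]] +
             log(m$pi)[gc$codon_nuc[, 3]]) * F[i, k, gc$aa_index]
  stats::setNames(w / sum(w), gc$codons)
}

#' Closed-form stationary distribution of the neutral / OM codon process
#'
#' Stationary probabilities proportional to the product of the mutational
#' nucleotide frequencies over the codon's three positions (independent of
#' omega).
#'
#' @param m a [mutation_model()].
#' @return numeric(61) summing to 1.
#' @export
neutral_codon_stationary <- function(m) {
  gc <- genetic_code()
  w <- m$pi[gc$codon_nuc[, 1]] * m$pi[gc$codon_nuc[, 2]] *
    m$pi[gc$codon_nuc[, 3]]
  stats::setNames(w / sum(w), gc$codons)
}
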