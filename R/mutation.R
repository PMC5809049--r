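#' General time-reversible nucleotide mutation model
#'
#' The mutation process shared by all sites and branches: a GTR rate matrix
#' parameterized by six relative exchangeabilities (pair order AC, AG, AT, CG,
#' CT, GT) and an equilibrium frequency vector over A, C, G, T. By default the
#' matrix is scaled so that the neutral process produces one expected
#' substitution per nucleotide site per unit branch length, which fixes the
#' otherwise arbitrary scale of the exchangeabilities and makes branch lengths
#' interpretable in expected neutral substitutions.
#'
#' @param exchangeabilities numeric(6), strictly positive relative rates.
#' @param pi numeric(4), nucleotide equilibrium frequencies; must sum to 1.
#' @param normalize logical; scale to unit neutral substitution rate.
#' @return An object of class `mutation_model`: a list with elements
#'   `exchangeabilities`, `pi`, and `Q` (the 4x4 generator).
#' @export
#' @examples
#' m <- mutation_model(rep(1, 6), rep(0.25, 4))  # Jukes-Cantor shape
#' m$Q
mutation_model <- function(exchangeabilities = rep(1, 6),
                           pi = rep(0.25, 4),
                           normalize = TRUE) {
  exchangeabilities <- as.numeric(exchangeabilities)
  pi <- as.numeric(pi)
  if (length(exchangeabilities) != 6L || any(!is.finite(exchangeabilities)) ||
      any(exchangeabilities <= 0)) {
    stop("`exchangeabilities` must be 6 strictly positive finite numbers",
         call. = FALSE)
  }
  if (length(pi) != 4L || any(!is.finite(pi)) || any(pi <= 0)) {
    stop("`pi` must be 4 strictly positive finite frequencies", call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-8) {
    stop("`pi` must sum to 1 (got ", format(sum(pi)), ")", call. = FALSE)
  }
  pi <- pi / sum(pi)
  m <- structure(
    list(exchangeabilities = exchangeabilities, pi = pi),
    class = "mutation_model"
  )
  m$Q <- mutation_rate_matrix(m, normalize = normalize)
  m
}

#' Nucleotide rate matrix of a mutation model
#'
#' Off-diagonal entries are `exchangeability(n1, n2) * pi[n2]`; diagonals
#' close each row to zero, so the matrix satisfies detailed balance against
#' `pi` by construction.
#'
#' @param m a [mutation_model()].
#' @param normalize logical; scale so that `-sum(pi * diag(Q)) == 1`.
#' @return 4x4 numeric generator with rownames/colnames A, C, G, T.
#' @export
mutation_rate_matrix <- function(m, normalize = TRUE) {
  stopifnot(inherits(m, "mutation_model"))
  idx <- .exch_index()
  Q <- matrix(0, 4, 4, dimnames = list(nuc_alphabet(), nuc_alphabet()))
  for (i in 1:4) for (j in 1:4) {
    if (i != j) Q[i, j] <- m$exchangeabilities[idx[i, j]] * m$pi[j]
  }
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    rate <- -sum(m$pi * diag(Q))
    Q <- Q / rate
  }
  Q
}
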