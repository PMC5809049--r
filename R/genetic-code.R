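#' The standard genetic code restricted to sense codons
#'
#' Precomputed lookup tables for the 61 sense codons of the standard genetic
#' code: codon strings, encoded amino acids, nucleotide composition, and the
#' list of ordered single-nucleotide neighbour pairs. All codon-level rate
#' matrices in the package are indexed by this fixed codon ordering (the
#' TCAG lexicographic order of [Biostrings::GENETIC_CODE], stop codons
#' removed).
#'
#' @return A list with components:
#'   \describe{
#'     \item{codons}{character(61), codon triplets.}
#'     \item{aa}{character(61), one-letter amino acid per codon.}
#'     \item{aa_index}{integer(61), amino acid index into [aa_alphabet()].}
#'     \item{codon_nuc}{61 x 3 integer matrix, nucleotide index (ACGT = 1..4)
#'       at each codon position.}
#'     \item{pairs}{tibble of ordered single-nucleotide sense codon pairs with
#'       columns `from`, `to` (codon indices), `pos` (1..3), `n1`, `n2`
#'       (nucleotide indices), `syn` (logical), `aa_from`, `aa_to`.}
#'   }
#' @export
#' @examples
#' gc <- genetic_code()
#' length(gc$codons)  # 61
genetic_code <- function() {
  if (!is.null(.codonDS_cache$code)) {
    return(.codonDS_cache$code)
  }
  tab <- Biostrings::GENETIC_CODE
  codons <- names(tab)[tab != "*"]
  aa <- unname(tab[codons])
  nuc <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  codon_nuc <- t(vapply(strsplit(codons, ""), function(x) nuc[x], integer(3)))
  dimnames(codon_nuc) <- NULL
  aa_index <- match(aa, aa_alphabet())

  # ordered pairs of sense codons differing at exactly one nucleotide
  from <- integer(0); to <- integer(0); pos <- integer(0)
  n1 <- integer(0); n2 <- integer(0)
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i == j) next
      diff <- which(codon_nuc[i, ] != codon_nuc[j, ])
      if (length(diff) == 1L) {
        from <- c(from, i); to <- c(to, j); pos <- c(pos, diff)
        n1 <- c(n1, codon_nuc[i, diff]); n2 <- c(n2, codon_nuc[j, diff])
      }
    }
  }
  pairs <- tibble::tibble(
    from = from, to = to, pos = pos, n1 = n1, n2 = n2,
    syn = aa[from] == aa[to],
    aa_from = aa_index[from], aa_to = aa_index[to]
  )
  code <- list(codons = codons, aa = aa, aa_index = aa_index,
               codon_nuc = codon_nuc, pairs = pairs)
  .codonDS_cache$code <- code
  code
}

.codonDS_cache <- new.env(parent = emptyenv())

#' Amino acid alphabet used for fitness profiles
#'
#' @return character(20), one-letter amino acid codes in alphabetical order
#'   (`ACDEFGHIKLMNPQRSTVWY`); all 20-vectors of fitness values in the package
#'   follow this ordering.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Nucleotide alphabet and pair ordering
#'
#' Nucleotides are indexed A, C, G, T. The six exchangeability parameters of
#' the mutation model follow the unordered pair ordering
#' AC, AG, AT, CG, CT, GT.
#'
#' @return character(4)
#' @export
nuc_alphabet <- function() c("A", "C", "G", "T")

# 4x4 matrix mapping a nucleotide pair to its exchangeability slot (1..6)
.exch_index <- function() {
  m <- matrix(0L, 4, 4)
  k <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    k <- k + 1L
    m[i, j] <- k; m[j, i] <- k
  }
  m
}
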