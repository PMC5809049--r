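#' Read a codon alignment from FASTA or sequential PHYLIP
#'
#' Reads an in-frame nucleotide alignment whose length is divisible by 3 and
#' encodes it as an integer codon matrix (taxa x codon sites), using the
#' 61-state sense-codon ordering of [genetic_code()]. Any codon containing a
#' gap or ambiguous nucleotide is masked (`NA`). An in-frame stop codon is a
#' hard error naming the offending taxon and site.
#'
#' @param path alignment file path.
#' @param format `"fasta"`, `"phylip"` (sequential), or `"auto"` (by first
#'   character: `>` means FASTA).
#' @return a `codon_alignment`: integer matrix taxa x sites with `NA` for
#'   masked codons; attributes `n_nuc` (alignment length in nucleotides).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  dna <- ape::read.dna(path, format = if (format == "fasta") "fasta" else "sequential",
                       as.character = TRUE, as.matrix = TRUE)
  codon_alignment(dna)
}

#' Encode a character nucleotide matrix as a codon alignment
#'
#' @param x character matrix (taxa x nucleotide columns) or a named character
#'   vector of equal-length sequences.
#' @return a `codon_alignment` (see [read_alignment()]).
#' @export
codon_alignment <- function(x) {
  if (is.vector(x)) {
    if (length(unique(nchar(x))) != 1L) {
      stop("sequences must all have the same length", call. = FALSE)
    }
    x <- t(vapply(x, function(s) strsplit(s, "")[[1]], character(nchar(x[[1]]))))
  }
  stopifnot(is.matrix(x))
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sequence names: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  n_nuc <- ncol(x)
  if (n_nuc %% 3L != 0L) {
    stop("alignment length (", n_nuc, ") is not divisible by 3", call. = FALSE)
  }
  x <- toupper(x)
  x[x == "U"] <- "T"
  gc <- genetic_code()
  n_sites <- n_nuc %/% 3L
  out <- matrix(NA_integer_, nrow(x), n_sites,
                dimnames = list(rownames(x), NULL))
  stops <- c("TAA", "TAG", "TGA")
  for (s in seq_len(n_sites)) {
    cols <- (3L * (s - 1L) + 1L):(3L * s)
    cod <- paste0(x[, cols[1]], x[, cols[2]], x[, cols[3]])
    clean <- grepl("^[ACGT]{3}$", cod)
    hit_stop <- clean & cod %in% stops
    if (any(hit_stop)) {
      stop("in-frame stop codon at codon site ", s, " in taxon ",
           rownames(x)[which(hit_stop)[1]], call. = FALSE)
    }
    out[clean, s] <- match(cod[clean], gc$codons)
  }
  structure(out, n_nuc = n_nuc, class = c("codon_alignment", "matrix", "array"))
}

#' Write a codon alignment to FASTA
#'
#' Masked codons are written as `---`.
#'
#' @param aln a `codon_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  gc <- genetic_code()
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    cod <- ifelse(is.na(aln[i, ]), "---", gc$codons[aln[i, ]])
    writeLines(c(paste0(">", rownames(aln)[i]), paste(cod, collapse = "")), con)
  }
  invisible(path)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", nrow(x), "taxa x", ncol(x), "codon sites (",
      attr(x, "n_nuc"), "nt );", sum(is.na(x)), "masked codons\n")
  invisible(x)
}

# cross-check taxon sets between alignment, tree and phenotypes before a run
check_taxa <- function(aln, ct, phenotypes = NULL) {
  tips <- ct$tree$tip.label
  a <- rownames(aln)
  extra <- setdiff(a, tips); missing <- setdiff(tips, a)
  if (length(extra) || length(missing)) {
    stop("taxon mismatch between alignment and tree; ",
         "missing from alignment: ", paste(missing, collapse = ", "),
         "; absent from tree: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!is.null(phenotypes)) {
    un <- setdiff(tips, names(phenotypes))
    if (length(un)) {
      stop("tips without phenotype label: ", paste(un, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
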