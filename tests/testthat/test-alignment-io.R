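test_that("FASTA codon alignments are read and integer-coded", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ATGAAA", ">s2", "ATGGAA"), f)
  aln <- read_alignment(f)
  expect_equal(dim(aln), c(2L, 2L))
  gc <- genetic_code()
  expect_equal(gc$codons[aln["s1", ]], c("ATG", "AAA"))
  expect_equal(gc$codons[aln["s2", ]], c("ATG", "GAA"))
})

test_that("gaps and ambiguities mask whole codons; stops are fatal", {
  aln <- codon_alignment(c(s1 = "ATGA-ATTT", s2 = "ATGNAATTC"))
  expect_true(is.na(aln[1, 2]))
  expect_true(is.na(aln[2, 2]))
  expect_false(anyNA(aln[, c(1, 3)]))

  expect_error(codon_alignment(c(s1 = "ATGTAAAAA")), "stop codon.*s1")
  expect_error(codon_alignment(c(s1 = "ATGAA")), "divisible by 3")
  expect_error(codon_alignment(c(s1 = "ATGAAA", s1 = "ATGAAA")), "duplicate")
})

test_that("sequential PHYLIP is read through the same interface", {
  f <- tempfile(fileext = ".phy")
  writeLines(c(" 2 6", "s1  ATGAAA", "s2  ATGGAA"), f)
  aln <- read_alignment(f, format = "phylip")
  expect_equal(dim(aln), c(2L, 2L))
  gc <- genetic_code()
  expect_equal(gc$codons[aln["s2", ]], c("ATG", "GAA"))
})

test_that("FASTA writing round-trips, masking as gaps", {
  aln <- codon_alignment(c(s1 = "ATGA-ATTT", s2 = "ATGCAATTC"))
  f <- tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, f)
  back <- read_alignment(f)
  expect_equal(unclass(back), unclass(aln), ignore_attr = TRUE)
})

test_that("taxon mismatches are caught before any sampling", {
  ct <- test_ct2()
  aln <- masked_alignment(c("A", "B", "C", "X"), 2)
  expect_error(run_chain(aln, ct, model = "DS", n_iter = 10, burnin = 1),
               "mismatch")
})
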