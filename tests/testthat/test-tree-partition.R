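test_that("read_newick parses, validates, and round-trips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(nrow(tr$edge), 4)

  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- read_newick(f)
  expect_equal(ape::Ntip(tr2), 3)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))

  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")
  expect_error(read_newick("((A:1,B),C:2);"), "branch lengths")
})

test_that("unrooted input is rooted deterministically", {
  tr1 <- read_newick("(A:1,B:1,(C:1,D:1):1);")
  tr2 <- read_newick("(A:1,B:1,(C:1,D:1):1);")
  expect_true(ape::is.rooted(tr1))
  expect_true(ape::all.equal.phylo(tr1, tr2, use.edge.length = TRUE))
  # total length is preserved by midpoint insertion
  expect_equal(sum(tr1$edge.length), 4 + 1)
})

test_that("DS3 allocation assigns maximal pure clades plus basal branches", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  ph <- c(A = "C3", B = "C3", C = "C4", D = "C4")
  ct <- allocate_conditions(tr, ph, "ds3")
  cen <- branch_condition_census(ct)
  expect_equal(cen$n_branches[cen$label == "C3"], 3)  # cherry + basal
  expect_equal(cen$n_branches[cen$label == "C4"], 3)
  expect_equal(sum(cen$n_branches), nrow(tr$edge))

  # a single derived tip among ancestral tips is its own maximal clade
  tr2 <- read_newick("((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
  ph2 <- c(A = "C3", B = "C3", C = "C3", D = "C4", E = "C3")
  ct2 <- allocate_conditions(tr2, ph2, "ds3")
  cen2 <- branch_condition_census(ct2)
  expect_equal(cen2$n_branches[cen2$label == "C4"], 1)

  expect_error(allocate_conditions(tr, ph[1:3], "ds3"), "without phenotype")
})

test_that("DS2 allocation gives everything outside C4 clades to C3", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # all-ancestral tree: every branch condition 0
  ph_all3 <- c(A = "C3", B = "C3", C = "C3", D = "C3")
  ct <- allocate_conditions(tr, ph_all3, "ds2")
  expect_true(all(ct$condition == 0L))

  ph <- c(A = "C3", B = "C3", C = "C4", D = "C4")
  ct2 <- allocate_conditions(tr, ph, "ds2")
  cen <- branch_condition_census(ct2)
  expect_equal(cen$n_branches[cen$label == "C4"], 3)
  expect_equal(cen$n_branches[cen$label == "C3"], 3)
})

test_that("DS2 and DS3 agree on the C4 branch set (property)", {
  set.seed(21)
  for (r in 1:8) {
    tr <- ape::rtree(12)
    tr$tip.label <- paste0("t", 1:12)
    ph <- stats::setNames(sample(c("C3", "C4"), 12, replace = TRUE),
                          tr$tip.label)
    if (!any(ph == "C4") || !any(ph == "C3")) next
    ct3 <- allocate_conditions(tr, ph, "ds3")
    ct2 <- allocate_conditions(tr, ph, "ds2")
    expect_equal(which(ct3$condition == 2L), which(ct2$condition == 1L))
    # conditions partition the branch set
    expect_equal(sum(branch_condition_census(ct3)$n_branches),
                 nrow(ct3$tree$edge))
  }
})

test_that("phenotype tables read from TSV", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A\tC3", "B\tC4"), f)
  ph <- read_phenotypes(f)
  expect_equal(ph, c(A = "C3", B = "C4"))
})
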