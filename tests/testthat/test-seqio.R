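test_that("alignments round-trip through all three formats", {
  a <- rand_aln(5, 40, seed = 1, p_missing = 0.05)
  for (fmt in c("fasta", "phylip_relaxed", "nexus")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_alignment(a, f, fmt)
    b <- read_alignment(f, fmt)
    expect_identical(unclass(b), unclass(a), label = fmt)
  }
})

test_that("reading normalizes case and RNA bases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "acgu", ">B", "ACGT"), f)
  a <- read_alignment(f, "fasta")
  expect_identical(unname(unclass(a)[1, ]), c("A", "C", "G", "T"))
})

test_that("malformed alignments are rejected with informative messages", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACGT", ">B", "ACG"), f)
  expect_error(read_alignment(f, "fasta"), "B")
  writeLines(c(">A", "ACGT", ">A", "ACGA"), f)
  expect_error(read_alignment(f, "fasta"), "duplicate")
  writeLines(c(">A", "ACXT", ">B", "ACGA"), f)
  expect_error(read_alignment(f, "fasta"), "unknown character 'X'")
  g <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 4", "A ACGT", "B ACG"), g)
  expect_error(read_alignment(g, "phylip_relaxed"), "declares 4")
})

test_that("PHYLIP header carries the alignment dimensions", {
  a <- rand_aln(4, 17, seed = 2)
  f <- withr::local_tempfile()
  write_alignment(a, f, "phylip_relaxed")
  expect_identical(strsplit(trimws(readLines(f)[1]), "\\s+")[[1]], c("4", "17"))
})

test_that("newick supports are scaled to [0,1] and lengths survive round trips", {
  tr <- read_tree("((A,B)95:0.1,C:0.2,D:0.3);")
  expect_equal(tr$node.label[2], 0.95)
  tr2 <- read_tree("((A,B)0.95:0.1,C:0.2,D:0.3);")
  expect_equal(tr2$node.label[2], 0.95)
  expect_error(read_tree("((A,B),(A,C));"), "duplicate")
  expect_error(read_tree("((A,B,C);"), "Newick")
  # lossless length serialization
  t3 <- rand_tree(8, seed = 3)
  t3$edge.length <- t3$edge.length * pi / 7
  f <- withr::local_tempfile()
  write_tree(t3, f)
  t4 <- read_tree(f)
  g3 <- radsplit:::graph_from_phylo(t3)
  g4 <- radsplit:::graph_from_phylo(t4)
  expect_equal(sort(unname(g4$len)), sort(unname(g3$len)), tolerance = 1e-10)
  # support omitted when flag off
  t5 <- read_tree("((A,B)0.9:0.1,C:0.2,D:0.3);")
  expect_false(grepl("0.9", write_tree(t5, include_support = FALSE), fixed = TRUE))
})

test_that("absent branch lengths stay unknown, not zero", {
  tr <- read_tree("((A,B),C,D);")
  expect_null(tr$edge.length)
  expect_false(grepl(":0", write_tree(tr), fixed = TRUE))
})

test_that("concatenation appends columns and builds a covering partition", {
  a1 <- rand_aln(4, 3, seed = 4); a2 <- rand_aln(4, 4, seed = 5)
  cc <- concatenate(list(locus("L1", a1), locus("L2", a2)))
  expect_equal(aln_ncol(cc$alignment), 7L)
  expect_equal(cc$partition$start, c(1L, 4L))
  expect_equal(cc$partition$end, c(3L, 7L))
  expect_identical(unclass(cc$alignment)[, 1:3], unclass(a1))
  # associativity in content
  a3 <- rand_aln(4, 5, seed = 6)
  one <- concatenate(list(locus("L1", a1), locus("L2", a2), locus("L3", a3)))
  two <- concatenate(list(locus("L12", concatenate(list(locus("L1", a1),
                                                        locus("L2", a2)))$alignment),
                          locus("L3", a3)))
  expect_identical(unclass(one$alignment), unclass(two$alignment))
  # taxon-set mismatch names the taxa
  b <- rand_aln(4, 3, seed = 7)
  rownames(b)[1] <- "other"
  expect_error(concatenate(list(locus("L1", a1), locus("LB", aln(unclass(b))))),
               "other")
})

test_that("partition files round-trip in the DNA dialect", {
  part <- data.frame(name = c("g1", "g2"), start = c(1L, 11L), end = c(10L, 25L))
  f <- withr::local_tempfile()
  write_partition(part, f)
  expect_match(readLines(f)[1], "^DNA, g1 = 1-10$")
  expect_identical(read_partition(f), part)
  writeLines(c("DNA, g1 = 1-10", "DNA, g2 = 12-20"), f)
  expect_error(read_partition(f), "contiguous")
})
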