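test_that("parsimony-informative and variable site counts follow the definitions", {
  same <- aln(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  expect_equal(count_parsimony_informative(same), 0L)
  expect_equal(count_variable(same), 0L)
  one_col <- function(chars) aln(matrix(chars, ncol = 1,
                                        dimnames = list(letters[seq_along(chars)], NULL)))
  expect_equal(count_parsimony_informative(one_col(c("A", "A", "C", "C"))), 1L)
  expect_equal(count_parsimony_informative(one_col(c("A", "A", "A", "C"))), 0L)
  expect_equal(count_parsimony_informative(one_col(c("A", "A", "-", "C"))), 0L)
  expect_equal(count_variable(one_col(c("A", "A", "A", "C"))), 1L)
  # ambiguity codes are never states
  expect_equal(count_parsimony_informative(one_col(c("R", "R", "C", "C"))), 0L)
})

test_that("0 <= PI <= variable <= length on random alignments", {
  for (s in 1:40) {
    a <- rand_aln(sample(3:8, 1), sample(10:60, 1), seed = s, p_missing = 0.1)
    pi_n <- count_parsimony_informative(a)
    v <- count_variable(a)
    expect_true(pi_n >= 0 && pi_n <= v && v <= aln_ncol(a))
  }
})

test_that("duplicating a row never decreases the PI count", {
  for (s in 1:10) {
    a <- rand_aln(4, 30, seed = 100 + s)
    m <- unclass(a)
    m2 <- rbind(m, dup = m[1, ])
    expect_gte(count_parsimony_informative(aln(m2)),
               count_parsimony_informative(a))
  }
})

test_that("p-distances match hand computation and pairwise deletion", {
  expect_equal(pairwise_distance_matrix(
    aln(c(A = "AAAAAAAAAA", B = "AAACCCAAAA")))["A", "B"], 0.3)
  d0 <- pairwise_distance_matrix(aln(c(A = "ACGT", B = "ACGT")))
  expect_true(all(d0 == 0))
  # sites with a gap or ambiguity in either member are excluded
  a <- aln(c(A = "ACGTAC", B = "A-GTNC"))
  expect_equal(pairwise_distance_matrix(a)["A", "B"], 0)
  b <- aln(c(A = "ACGTAC", B = "A-TTNC"))
  expect_equal(pairwise_distance_matrix(b)["A", "B"], 0.25)  # 1 of 4 compared
  expect_error(pairwise_distance_matrix(aln(c(A = "A-", B = "-A"))),
               "no comparable sites")
})

test_that("distance matrices are symmetric with zero diagonal, matching ape", {
  for (s in 1:5) {
    a <- simulate_alignment(rand_tree(6, seed = 200 + s, mean_bl = 0.08),
                            substitution_model("HKY85", kappa = 3), 400,
                            seed = 200 + s)
    m <- unclass(a)
    m[cbind(sample(1:6, 20, TRUE), sample(1:400, 20, TRUE))] <- "-"
    a <- aln(m)
    for (metric in c("p_distance", "k2p")) {
      d <- pairwise_distance_matrix(a, metric)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      db <- ape::dist.dna(ape::as.DNAbin(strsplit(apply(unclass(a), 1, paste,
                                                        collapse = ""), "")),
                          model = if (metric == "p_distance") "raw" else "K80",
                          pairwise.deletion = TRUE)
      expect_equal(as.numeric(as.dist(d)), as.numeric(db), tolerance = 1e-10)
    }
  }
})

test_that("K2P exceeds p-distance for divergent pairs", {
  tr <- read_tree("(A:0.15,B:0.15);")
  a <- simulate_alignment(tr, substitution_model("K80", kappa = 4), 2000, seed = 9)
  p <- pairwise_distance_matrix(a, "p_distance")["A", "B"]
  k <- pairwise_distance_matrix(a, "k2p")["A", "B"]
  expect_gt(p, 0.05)
  expect_gt(k, p)
})

test_that("locus characterization aggregates the statistics", {
  a <- aln(c(A = "ACGTACGT", B = "ACGTACGT"))
  row <- characterize_locus(locus("L", a))
  expect_equal(row$aligned_length, 8L)
  expect_equal(row$pi_sites, 0L)
  expect_equal(row$variable_sites, 0L)
  expect_equal(row$mean_pairwise_distance, 0)
  for (s in 1:20) {
    r <- characterize_locus(rand_aln(5, 30, seed = 300 + s, p_missing = 0.05))
    expect_true(r$pi_sites <= r$variable_sites)
    expect_true(r$variable_sites <= r$aligned_length)
    expect_true(r$mean_pairwise_distance >= 0 && r$mean_pairwise_distance <= 1)
  }
})

test_that("coding-integrity screen flags premature stops and frameshifts", {
  r1 <- coding_integrity_check("ATGAAATAA", "vertebrate_mt", 1)
  expect_true(r1$clean)
  expect_true(r1$terminal_stop)
  expect_length(r1$internal_stops, 0)
  r2 <- coding_integrity_check("ATGTAAAAA", "vertebrate_mt", 1)
  expect_false(r2$clean)
  expect_equal(r2$internal_stops, 2L)
  # AGA is a stop in the vertebrate mt code but not the standard code
  expect_false(coding_integrity_check("ATGAGAAAA", "vertebrate_mt", 1)$clean)
  expect_true(coding_integrity_check("ATGAGAAAA", "standard", 1)$clean)
  r3 <- coding_integrity_check("ATGAA-AAA", "standard", 1)
  expect_false(r3$clean)
  expect_true(r3$frameshift)
  expect_error(coding_integrity_check("ATGAAA", "standard", 4), "frame")
})
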