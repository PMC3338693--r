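test_that("species tree validation enforces the invariants", {
  expect_error(build_species_tree(species_tree_spec("((A:1,A:1):1,B:2);")),
               "duplicate")
  expect_error(build_species_tree(species_tree_spec("((A:1,B:1,C:1):1,D:2);")),
               "binary")
  expect_error(build_species_tree(species_tree_spec("((A:1,B:2):1,C:2);")),
               "ultrametric")
  # two-taxon cherry: smallest valid tree
  cherry <- build_species_tree(species_tree_spec("(A:1,B:1);"))
  expect_equal(length(cherry$tip.label), 2L)
  expect_equal(cherry$Nnode, 1L)
  # zero-length internode accepted
  z <- build_species_tree(species_tree_spec("((A:1,B:1):0,C:1);"))
  expect_true(inherits(z, "phylo"))
  gt <- sample_gene_tree(z, seed = 1)
  expect_equal(sort(gt$tip.label), c("A", "B", "C"))
})

test_that("the default species tree carries the expected clade structure", {
  sp <- default_species_tree()
  expect_equal(length(sp$tip.label), 18L)
  keys <- names(tree_splits(sp))
  has_clade <- function(tips) {
    radsplit:::split_key(tips, sp$tip.label) %in% keys
  }
  expect_true(has_clade(SEMNO))                      # Semnopithecus
  expect_true(has_clade(TRACHY))                     # Trachypithecus
  expect_true(has_clade(c(SEMNO, TRACHY)))           # clade 2
  odd <- c("Nasalis_larvatus", "Pygathrix_nemaeus", "Rhinopithecus_roxellana",
           "Rhinopithecus_bieti", "Rhinopithecus_avunculus")
  expect_true(has_clade(odd))                        # odd-nosed monkeys
  expect_true(has_clade(c("Presbytis_melalophos", odd)))  # clade 1
  expect_true(has_clade(c("Colobus_guereza", "Piliocolobus_badius")))
})

test_that("pairwise coalescence in one population averages one coalescent unit", {
  sp2 <- build_species_tree(species_tree_spec("(A:0,B:0);"))
  tm <- vapply(1:3000, function(i) sum(sample_gene_tree(sp2, seed = i)$edge.length) / 2,
               numeric(1))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1), 3 * se)
})

test_that("three-taxon gene-tree concordance follows 1 - (2/3)exp(-T)", {
  cherry_pair <- function(gt) {
    ntip <- length(gt$tip.label)
    for (nd in (ntip + 1):(ntip + gt$Nnode)) {
      ch <- gt$edge[gt$edge[, 1] == nd, 2]
      if (all(ch <= ntip)) return(sort(gt$tip.label[ch]))
    }
  }
  n <- 1500
  for (T in c(0.1, 0.5, 2.0)) {
    sp <- build_species_tree(species_tree_spec(
      sprintf("((A:1,B:1):%f,C:%f);", T, 1 + T)))
    hit <- vapply(1:n, function(i) {
      identical(cherry_pair(sample_gene_tree(sp, seed = 7000 + i)), c("A", "B"))
    }, logical(1))
    expected <- 1 - (2 / 3) * exp(-T)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(hit) - expected), 3 * se, label = sprintf("T=%.1f", T))
  }
})

test_that("long internodes make gene trees match the species tree", {
  sp <- build_species_tree(species_tree_spec(
    "(((A:5,B:5):5,(C:5,D:5):5):5,E:15);"))
  match_rate <- mean(vapply(1:150, function(i) {
    topo_equal(sample_gene_tree(sp, seed = 8000 + i), sp)
  }, logical(1)))
  expect_gte(match_rate, 0.99)
})

test_that("a total introgression pulse reroutes the recipient completely", {
  sp <- default_species_tree()
  # donor with a long isolated branch: the rerouted lineages must coalesce
  # into the donor's clade before it joins anything else
  ev <- introgression_event(donor = "Macaca_sylvanus", recipient = TRACHY,
                            time = 5, proportion = 1)
  joined <- vapply(1:60, function(i) {
    gt <- sample_gene_tree(sp, event = ev, seed = 8100 + i)
    keys <- names(tree_splits(gt))
    radsplit:::split_key(c("Macaca_sylvanus", TRACHY), gt$tip.label) %in% keys
  }, logical(1))
  expect_true(all(joined))
  # event on a branch that does not span the stated time is rejected
  bad <- introgression_event(donor = SEMNO, recipient = TRACHY,
                             time = 2, proportion = 0.5)
  expect_error(sample_gene_tree(sp, event = bad, seed = 1), "does not exist")
  expect_error(introgression_event("A", "B", 1, 1.5), "proportion")
})

test_that("JC simulation matches the closed-form mismatch probability", {
  t_total <- 0.1
  tr <- read_tree(sprintf("(A:%f,B:%f);", t_total / 2, t_total / 2))
  a <- simulate_alignment(tr, substitution_model("JC69"), 50000, seed = 5)
  obs <- mean(unclass(a)[1, ] != unclass(a)[2, ])
  expected <- 0.75 * (1 - exp(-4 * t_total / 3))
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 50000))
})

test_that("zero branch lengths give identical sequences; bad inputs rejected", {
  tr <- read_tree("(A:0,B:0);")
  a <- simulate_alignment(tr, substitution_model("JC69"), 200, seed = 6)
  expect_identical(unclass(a)[1, ], unclass(a)[2, ], ignore_attr = TRUE)
  expect_error(simulate_alignment(tr, substitution_model("JC69"), 0, seed = 1),
               "positive")
  expect_error(substitution_model("JC69", alpha = 0), "alpha")
})

test_that("study bundles are reproducible and study-shaped", {
  cfg <- simulation_config(n_nuclear_loci = 3,
                           mt_partition_lengths = c(mtA = 500, mtB = 400),
                           seed = 42)
  b1 <- generate_study(cfg)
  b2 <- generate_study(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(b1, d1); write_study(b2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    if (f == "config.txt") next
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = f)
  }
  # manifest, loci and gene trees align
  expect_equal(nrow(b1$manifest), length(b1$loci))
  expect_setequal(names(b1$loci), names(b1$gene_trees))
  for (gt in b1$gene_trees) {
    expect_setequal(gt$tip.label, b1$species_tree$tip.label)
  }
  # nuclear-only and mt-only configurations
  b0 <- generate_study(simulation_config(n_nuclear_loci = 0,
                                         mt_partition_lengths = c(m1 = 300),
                                         seed = 1))
  expect_equal(unique(b0$manifest$locus_class), "mt_protein")
  # the mt sub-partitions share one gene tree
  cfg2 <- simulation_config(n_nuclear_loci = 0, seed = 3)
  b3 <- generate_study(cfg2)
  mt_names <- b3$manifest$locus[b3$manifest$locus_class != "nuclear_noncoding"]
  first <- b3$gene_trees[[mt_names[1]]]
  for (nm in mt_names[-1]) expect_identical(b3$gene_trees[[nm]], first)
})

test_that("default panel lengths span the study range", {
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$n_nuclear_loci, 44L)
  expect_equal(range(radsplit:::NUCLEAR_PANEL$length), c(337L, 868L))
  expect_equal(sum(radsplit:::MT_PANEL$length), 16527L)
})
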