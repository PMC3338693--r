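test_that("reference node enumeration matches direct counting", {
  cat5 <- read_tree("(((((A,B),C),D),E),O);")
  refs <- reference_nodes(cat5, outgroup = "O")
  expect_length(refs$nodes, 3L)
  sides <- lapply(refs$nodes, sort)
  expect_true(list(c("A", "B")) %in% sides)
  expect_true(list(c("A", "B", "C")) %in% sides)
  expect_true(list(c("A", "B", "C", "D")) %in% sides)
  # star ingroup: nothing to score
  star <- read_tree("(A,B,C,D,O);")
  expect_length(reference_nodes(star, "O")$nodes, 0L)
  # outgroup must exist
  expect_error(reference_nodes(cat5, "Z"), "not in tree")
})

test_that("a node subset overrides the default in the given order", {
  sp <- default_species_tree()
  refs_all <- reference_nodes(sp, DEFAULT_OUTGROUP)
  expect_length(refs_all$nodes, 13L)  # 14 ingroup taxa -> 13 clades of >= 2
  subset <- refs_all$nodes[c(3, 1, 7)]
  refs_sub <- reference_nodes(sp, DEFAULT_OUTGROUP, node_subset = unname(subset))
  expect_length(refs_sub$nodes, 3L)
  expect_equal(unname(refs_sub$nodes), unname(subset))
  expect_error(reference_nodes(sp, DEFAULT_OUTGROUP,
                               node_subset = list(c("Homo_sapiens", "Colobus_guereza"))),
               "not a bipartition")
})

test_that("scoring the reference against itself recovers every node strongly", {
  sp <- default_species_tree()
  sp$node.label <- rep(1, sp$Nnode)
  refs <- reference_nodes(sp, DEFAULT_OUTGROUP)
  perf <- score_gene(sp, refs, threshold = 0.95)
  expect_equal(perf$n_congruent_strong, length(refs$nodes))
  expect_equal(perf$n_congruent_weak, 0L)
  expect_equal(perf$n_total, length(refs$nodes))
})

test_that("a star gene tree recovers nothing", {
  sp <- default_species_tree()
  refs <- reference_nodes(sp, DEFAULT_OUTGROUP)
  star <- read_tree(paste0("(", paste(sp$tip.label, collapse = ","), ");"))
  expect_equal(score_gene(star, refs)$n_total, 0L)
})

test_that("scores are invariant to gene-tree rooting and edges without support count weak", {
  sp <- default_species_tree()
  refs <- reference_nodes(sp, DEFAULT_OUTGROUP)
  gt <- ape::unroot(default_species_tree())
  gt$node.label <- NULL  # no supports anywhere
  p1 <- score_gene(gt, refs)
  expect_equal(p1$n_congruent_strong, 0L)
  expect_equal(p1$n_total, length(refs$nodes))
  rerooted <- ape::root(gt, "Homo_sapiens", resolve.root = TRUE)
  p2 <- score_gene(rerooted, refs)
  expect_equal(p2$n_total, p1$n_total)
})

test_that("congruence counts agree with a brute-force bipartition tally", {
  sp <- default_species_tree()
  refs <- reference_nodes(sp, DEFAULT_OUTGROUP)
  for (s in 1:25) {
    gt <- withr::with_seed(s, {
      t <- radsplit:::random_topology(sp$tip.label)
      t$node.label <- round(runif(t$Nnode), 2)
      t
    })
    perf <- score_gene(gt, refs, threshold = 0.95)
    # oracle: direct set comparison of bipartitions
    gkeys <- names(tree_splits(gt))
    oracle_total <- sum(vapply(refs$nodes, function(side) {
      radsplit:::split_key(side, sp$tip.label) %in% gkeys
    }, logical(1)))
    expect_equal(perf$n_total, oracle_total, label = sprintf("seed %d", s))
  }
})

test_that("random NNI perturbation does not increase expected congruence", {
  sp <- default_species_tree()
  refs <- reference_nodes(sp, DEFAULT_OUTGROUP)
  base <- ape::unroot(sp)
  base_total <- score_gene(base, refs)$n_total
  perturbed <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      nb <- radsplit:::nni_neighbors(base)
      t <- nb[[sample.int(length(nb), 1)]]
      # second random NNI
      nb2 <- radsplit:::nni_neighbors(t)
      t2 <- nb2[[sample.int(length(nb2), 1)]]
      score_gene(t2, refs)$n_total
    })
  }, numeric(1))
  expect_lte(mean(perturbed), base_total)
})

test_that("a best-locus style 7-strong/1-weak/8-total row is reproduced on a fixture", {
  # a gene tree differing from the reference by two rearrangements (odd-nosed
  # interior swapped; Presbytis moved into the langur clade), with one
  # surviving scored edge weakly supported: scoring 10 nodes must give the
  # 7 / 1 / 8 row shape
  sp <- default_species_tree()
  odd <- c("Nasalis_larvatus", "Pygathrix_nemaeus", "Rhinopithecus_roxellana",
           "Rhinopithecus_bieti", "Rhinopithecus_avunculus")
  rhino <- c("Rhinopithecus_roxellana", "Rhinopithecus_bieti",
             "Rhinopithecus_avunculus")
  asian <- c(odd, "Presbytis_melalophos", SEMNO, TRACHY)
  ingroup <- c(asian, "Colobus_guereza", "Piliocolobus_badius")
  subset <- list(
    c("Pygathrix_nemaeus", rhino),      # broken by the odd-nosed swap
    c("Presbytis_melalophos", odd),     # broken by the Presbytis move
    rhino, odd, SEMNO, TRACHY, c(SEMNO, TRACHY), asian,
    c("Colobus_guereza", "Piliocolobus_badius"), ingroup
  )
  refs10 <- reference_nodes(sp, DEFAULT_OUTGROUP, node_subset = subset)
  expect_length(refs10$nodes, 10L)
  gt_txt <- paste0(
    "(((((Pygathrix_nemaeus,(Nasalis_larvatus,(Rhinopithecus_avunculus,",
    "(Rhinopithecus_roxellana,Rhinopithecus_bieti)1)1)1)1,",
    "(Presbytis_melalophos,((Semnopithecus_entellus,(Semnopithecus_johnii,",
    "Semnopithecus_vetulus)1)0.6,(Trachypithecus_hatinhensis,",
    "(Trachypithecus_germaini,Trachypithecus_shortridgei)1)1)1)1)1,",
    "(Colobus_guereza,Piliocolobus_badius)1)1,Macaca_sylvanus)1,",
    "(Pongo_abelii,(Pan_troglodytes,Homo_sapiens)1)1);")
  gt <- read_tree(gt_txt)
  perf <- score_gene(gt, refs10, threshold = 0.95, locus_name = "fixture")
  expect_equal(perf$n_congruent_strong, 7L)
  expect_equal(perf$n_congruent_weak, 1L)
  expect_equal(perf$n_total, 8L)
})

test_that("gene ranking sorts, classifies by tertiles, and permutes the input", {
  mk <- function(locus, strong, weak) {
    data.frame(locus = locus, n_congruent_strong = strong,
               n_congruent_weak = weak, n_total = strong + weak,
               recovered_ids = "", stringsAsFactors = FALSE)
  }
  tab <- rank_genes(list(mk("slow", 1, 1), mk("best", 9, 1), mk("mid", 6, 2)))
  expect_equal(tab$locus, c("best", "mid", "slow"))
  expect_equal(tab$class, c("good", "medium", "poor"))
  expect_equal(tab$rank, 1:3)
  # ties share the better class; all-equal totals are all good
  tab2 <- rank_genes(list(mk("a", 3, 0), mk("b", 2, 1), mk("c", 1, 2)))
  expect_equal(unique(tab2$class), "good")
  # ranking is a permutation
  tab3 <- rank_genes(lapply(1:7, function(i) mk(paste0("L", i), i %% 3, i %% 2)))
  expect_setequal(tab3$locus, paste0("L", 1:7))
  # strong count breaks total ties deterministically
  tab4 <- rank_genes(list(mk("x", 2, 2), mk("y", 4, 0)))
  expect_equal(tab4$locus[1], "y")
})
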