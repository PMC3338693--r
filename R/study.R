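# Study-shaped synthetic data: the default 18-taxon species tree (14 ingroup
# colobine-like taxa + 4 outgroup primates), the default marker panel (44
# slow nuclear non-coding loci, one fast non-recombining mitochondrial
# partition cut into 17 sub-partitions), and the bundle generator.

# Default nuclear locus panel: aligned lengths and observed mean pairwise
# divergences (%) of the emulated markers; relative per-locus rates follow
# the divergence column.
NUCLEAR_PANEL <- data.frame(
  name = c("chr1-4", "chr1-6", "chr2-1", "chr2-8", "chr3-2", "chr3-5",
           "chr4-2", "chr4-7", "chr5-6", "chr5-8", "chr6-5", "chr6-6",
           "chr7-6", "chr8-1", "chr8-2", "chr9-5", "chr10-1", "chr10-5",
           "chr11-2", "chr12-1", "chr12-2", "chr13-3", "chr13-6", "chr15-1",
           "chr15-3", "chr17-4", "chr17-8", "chr18-4", "chr19-1", "chr19-5",
           "chr20-4", "chr20-5", "ENC5", "ENC14", "ENC15", "ENC19", "ENC25",
           "ENC35", "X2", "X5", "X37", "X45", "X61", "X65"),
  length = c(462L, 567L, 504L, 413L, 533L, 337L, 486L, 492L, 534L, 480L,
             456L, 367L, 514L, 577L, 526L, 522L, 503L, 498L, 522L, 586L,
             439L, 401L, 472L, 862L, 398L, 788L, 497L, 504L, 550L, 458L,
             588L, 457L, 641L, 539L, 868L, 530L, 401L, 548L, 565L, 510L,
             598L, 490L, 602L, 549L),
  divergence = c(3.10, 3.40, 3.10, 3.10, 2.50, 5.10, 5.40, 2.90, 3.60, 3.80,
                 4.10, 3.30, 5.20, 4.50, 2.80, 3.20, 4.20, 1.40, 4.00, 3.50,
                 3.20, 3.00, 3.30, 22.60, 2.50, 8.60, 4.70, 2.60, 4.50, 3.70,
                 4.00, 3.70, 3.00, 2.50, 3.00, 2.90, 3.90, 2.60, 3.60, 3.50,
                 4.20, 3.00, 2.90, 2.70),
  stringsAsFactors = FALSE
)

# Default mitochondrial sub-partition panel (one linked locus).
MT_PANEL <- data.frame(
  name = c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3",
           "ND4L", "ND4", "ND5", "ND6", "CYTB", "12SrRNA", "16SrRNA",
           "tRNA", "D-loop"),
  class = c(rep("mt_protein", 13L), "mt_rRNA", "mt_rRNA", "mt_tRNA", "mt_CR"),
  length = c(957L, 1044L, 1545L, 684L, 211L, 681L, 784L, 346L, 297L, 1378L,
             1806L, 528L, 1135L, 961L, 1582L, 1573L, 1015L),
  divergence = c(19.00, 22.80, 16.90, 17.10, 28.80, 23.60, 18.60, 23.40,
                 19.80, 21.00, 22.40, 18.90, 20.70, 10.90, 12.70, 12.10,
                 24.80),
  stringsAsFactors = FALSE
)

# Calibrated substitution rates (expected substitutions/site per coalescent
# unit) that put the default bundle at ~4% mean nuclear and ~18.5% mean
# mitochondrial pairwise divergence on the default species tree.
CAL_NUC_RATE <- 0.001435
CAL_MT_RATE <- 0.01739

DEFAULT_OUTGROUP <- c("Macaca_sylvanus", "Pongo_abelii", "Pan_troglodytes",
                      "Homo_sapiens")

#' Default species tree of the emulated study
#'
#' A rooted ultrametric 18-taxon tree in coalescent units: 14 ingroup taxa
#' (two African genera; Asian clade 1 = Presbytis + the odd-nosed group with
#' Pygathrix sister to Rhinopithecus; Asian clade 2 = Semnopithecus +
#' Trachypithecus) and 4 outgroup primates. The Asian inter-generic
#' internodes are short (0.6 coalescent units), producing realistic
#' incomplete lineage sorting across the radiation.
#'
#' @return A validated species tree ([build_species_tree()] output).
#' @export
default_species_tree <- function() {
  odd <- paste0("(Nasalis_larvatus:8.6,(Pygathrix_nemaeus:8.0,",
                "(Rhinopithecus_avunculus:3.0,(Rhinopithecus_roxellana:2.0,",
                "Rhinopithecus_bieti:2.0):1.0):5.0):0.6):0.6")
  clade1 <- paste0("(Presbytis_melalophos:9.2,", odd, "):0.6")
  semno <- paste0("(Semnopithecus_entellus:3.0,(Semnopithecus_johnii:2.0,",
                  "Semnopithecus_vetulus:2.0):1.0):5.0")
  trachy <- paste0("(Trachypithecus_hatinhensis:3.0,",
                   "(Trachypithecus_germaini:2.0,",
                   "Trachypithecus_shortridgei:2.0):1.0):5.0")
  clade2 <- paste0("(", semno, ",", trachy, "):1.8")
  asian <- paste0("(", clade1, ",", clade2, "):2.2")
  african <- "(Colobus_guereza:9.0,Piliocolobus_badius:9.0):3.0"
  colobinae <- paste0("(", asian, ",", african, "):5.0")
  cerco <- paste0("(", colobinae, ",Macaca_sylvanus:17.0):8.0")
  homin <- paste0("(Pongo_abelii:11.0,(Pan_troglodytes:6.0,",
                  "Homo_sapiens:6.0):5.0):14.0")
  build_species_tree(species_tree_spec(paste0("(", cerco, ",", homin, ");")))
}

#' Default per-class substitution models of the simulator
#'
#' Nuclear non-coding loci: HKY85+G (kappa 4, alpha 0.70). Mitochondrial
#' partition: GTR+I+G with a strong transition bias, I = 0.43, alpha = 1.10.
#'
#' @return Named list with elements `nuclear` and `mt`.
#' @export
default_sim_models <- function() {
  list(
    nuclear = substitution_model("HKY85", base_freqs = c(0.28, 0.21, 0.21, 0.30),
                                 kappa = 4, alpha = 0.70),
    mt = substitution_model("GTR", base_freqs = c(0.33, 0.28, 0.12, 0.27),
                            rates = c(2, 30, 1.5, 1, 40, 1), p_inv = 0.43,
                            alpha = 1.10)
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study design: 44 nuclear non-coding loci with the
#' default panel's aligned lengths (337-868 bp) and per-locus relative rates,
#' at ~4% mean pairwise divergence; one ~16.5 kb mitochondrial partition
#' (17 sub-partitions sharing a single gene tree) at ~18.5% mean divergence.
#'
#' @param n_nuclear_loci Number of nuclear loci (default 44; the default
#'   panel is used when it is 44, otherwise lengths are drawn uniformly from
#'   `nuclear_length_range`).
#' @param nuclear_length_range Integer interval for non-default panels.
#' @param nuclear_rate_scale Target mean nuclear pairwise divergence
#'   (fraction; default 0.04).
#' @param mt_partition_lengths Named integer vector of mitochondrial
#'   sub-partition lengths (default: the 17-row default panel, total 16527).
#' @param mt_rate_scale Target mean mitochondrial divergence (default 0.185).
#' @param model_params Named list of [substitution_model()]s per locus class
#'   (`nuclear`, `mt`).
#' @param introgression Optional [introgression_event()] applied to every
#'   locus's gene tree sampling (use [generate_study()]'s `mt_introgression`
#'   for a mitochondria-only pulse).
#' @param mt_introgression Optional [introgression_event()] applied to the
#'   mitochondrial gene tree only (mito-nuclear discordance scenario).
#' @param species_tree Species tree (default [default_species_tree()]).
#' @param seed Master seed; the same configuration regenerates the bundle
#'   exactly.
#' @return An object of class `"sim_config"`.
#' @export
simulation_config <- function(n_nuclear_loci = 44L,
                              nuclear_length_range = c(337L, 868L),
                              nuclear_rate_scale = 0.04,
                              mt_partition_lengths = NULL,
                              mt_rate_scale = 0.185,
                              model_params = default_sim_models(),
                              introgression = NULL,
                              mt_introgression = NULL,
                              species_tree = NULL,
                              seed = 1L) {
  stopifnot(n_nuclear_loci >= 0L, nuclear_rate_scale > 0, mt_rate_scale > 0)
  if (any(nuclear_length_range <= 0)) stop("lengths must be positive")
  if (is.null(species_tree)) species_tree <- default_species_tree()
  structure(list(n_nuclear_loci = as.integer(n_nuclear_loci),
                 nuclear_length_range = as.integer(nuclear_length_range),
                 nuclear_rate_scale = nuclear_rate_scale,
                 mt_partition_lengths = mt_partition_lengths,
                 mt_rate_scale = mt_rate_scale,
                 model_params = model_params,
                 introgression = introgression,
                 mt_introgression = mt_introgression,
                 species_tree = species_tree,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic study bundle
#'
#' Samples one coalescent gene tree per nuclear locus and a single shared
#' gene tree for the (non-recombining) mitochondrial partition, evolves an
#' alignment per locus, and packages everything with a per-locus manifest of
#' models, lengths and seeds. Regeneration from the same configuration is
#' identical.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"study_bundle"`: list with `species_tree`,
#'   `gene_trees` (named list), `loci` (named list of [locus()]), `manifest`
#'   (data.frame), `config`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$species_tree
  nuc_model <- config$model_params$nuclear
  mt_model <- config$model_params$mt
  # nuclear panel
  if (config$n_nuclear_loci == 44L) {
    panel <- NUCLEAR_PANEL
  } else if (config$n_nuclear_loci > 0L) {
    panel <- with_seed(derive_seed(config$seed, 777L), {
      data.frame(name = sprintf("nuc%02d", seq_len(config$n_nuclear_loci)),
                 length = sample(seq(config$nuclear_length_range[1L],
                                     config$nuclear_length_range[2L]),
                                 config$n_nuclear_loci, replace = TRUE),
                 divergence = 100 * config$nuclear_rate_scale,
                 stringsAsFactors = FALSE)
    })
  } else {
    panel <- NUCLEAR_PANEL[0L, ]
  }
  mtp <- MT_PANEL
  if (!is.null(config$mt_partition_lengths)) {
    mtp <- data.frame(name = names(config$mt_partition_lengths),
                      class = "mt_protein",
                      length = as.integer(config$mt_partition_lengths),
                      divergence = 100 * config$mt_rate_scale,
                      stringsAsFactors = FALSE)
  }
  # per-locus relative rates: divergence column scaled to length-weighted
  # mean 1, overall level set by the calibrated per-coalescent-unit rates
  rel_nuc <- if (nrow(panel)) {
    panel$divergence / (sum(panel$divergence * panel$length) / sum(panel$length))
  } else numeric(0)
  rel_mt <- mtp$divergence / (sum(mtp$divergence * mtp$length) / sum(mtp$length))
  nuc_rate <- CAL_NUC_RATE * config$nuclear_rate_scale / 0.04
  mt_rate <- CAL_MT_RATE * config$mt_rate_scale / 0.185

  gene_trees <- list(); loci <- list(); man <- list()
  for (i in seq_len(nrow(panel))) {
    gseed <- derive_seed(config$seed, i)
    gt <- sample_gene_tree(sp, event = config$introgression, seed = gseed)
    st <- gt
    st$edge.length <- gt$subst.length * nuc_rate * rel_nuc[i]
    a <- simulate_alignment(st, nuc_model, panel$length[i],
                            seed = derive_seed(config$seed, 100000L + i))
    gene_trees[[panel$name[i]]] <- gt
    loci[[panel$name[i]]] <- locus(panel$name[i], a, "nuclear_noncoding")
    man[[length(man) + 1L]] <- data.frame(
      locus = panel$name[i], locus_class = "nuclear_noncoding",
      length = panel$length[i], model = model_id(nuc_model),
      rel_rate = rel_nuc[i], seed = gseed, stringsAsFactors = FALSE)
  }
  # one shared mitochondrial gene tree (non-recombining)
  mt_seed <- derive_seed(config$seed, 999999L)
  mt_event <- if (!is.null(config$mt_introgression)) config$mt_introgression
              else config$introgression
  mt_gt <- sample_gene_tree(sp, event = mt_event, seed = mt_seed)
  for (i in seq_len(nrow(mtp))) {
    st <- mt_gt
    st$edge.length <- mt_gt$subst.length * mt_rate * rel_mt[i]
    a <- simulate_alignment(st, mt_model, mtp$length[i],
                            seed = derive_seed(config$seed, 200000L + i))
    gene_trees[[mtp$name[i]]] <- mt_gt
    loci[[mtp$name[i]]] <- locus(mtp$name[i], a, mtp$class[i])
    man[[length(man) + 1L]] <- data.frame(
      locus = mtp$name[i], locus_class = mtp$class[i], length = mtp$length[i],
      model = model_id(mt_model), rel_rate = rel_mt[i], seed = mt_seed,
      stringsAsFactors = FALSE)
  }
  structure(list(species_tree = sp, gene_trees = gene_trees, loci = loci,
                 manifest = do.call(rbind, man), config = config),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  nuc <- sum(x$manifest$locus_class == "nuclear_noncoding")
  cat(sprintf("Study bundle: %d taxa, %d nuclear loci, %d mt sub-partitions\n",
              length(x$species_tree$tip.label), nuc, nrow(x$manifest) - nuc))
  invisible(x)
}

#' Write a study bundle to a directory
#'
#' One FASTA per locus (`<locus>.fasta`), the true species tree and per-locus
#' gene trees as Newick, the manifest as TSV, and the scalar configuration as
#' a flat `key=value` text file.
#'
#' @param bundle A [generate_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "loci"), showWarnings = FALSE)
  dir.create(file.path(dir, "gene_trees"), showWarnings = FALSE)
  for (nm in names(bundle$loci)) {
    write_alignment(bundle$loci[[nm]]$alignment,
                    file.path(dir, "loci", paste0(nm, ".fasta")), "fasta")
    write_tree(bundle$gene_trees[[nm]],
               file.path(dir, "gene_trees", paste0(nm, ".nwk")),
               include_support = FALSE)
  }
  write_tree(bundle$species_tree, file.path(dir, "species_tree.nwk"))
  write.table(bundle$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  writeLines(c(paste0("n_nuclear_loci=", cfg$n_nuclear_loci),
               paste0("nuclear_rate_scale=", cfg$nuclear_rate_scale),
               paste0("mt_rate_scale=", cfg$mt_rate_scale),
               paste0("seed=", cfg$seed)),
             file.path(dir, "config.txt"))
  invisible(dir)
}
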