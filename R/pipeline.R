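# End-to-end orchestration: simulate (or load) -> characterize -> infer
# per-gene and combined trees -> congruence scoring -> topology tests, with
# per-stage logging and deterministic seeding throughout.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (simulate a bundle) or `"replay"` (read
#'   per-locus FASTA alignments from `alignments_dir`).
#' @param out_dir Output directory of the run.
#' @param sim A [simulation_config()] (synthetic mode).
#' @param alignments_dir Directory of `<locus>.fasta` files (replay mode).
#' @param outgroup Outgroup taxon labels (default: the default bundle's
#'   outgroup).
#' @param gene_tree_method Per-locus inference method for
#'   [bootstrap_support()] (default `"nj"`).
#' @param bootstrap_replicates Bootstrap replicates per locus (default 100).
#' @param model_policy `"aic"` (per-locus AIC best model fills the
#'   characterization table and the combined analyses) or `"fixed"`.
#' @param fixed_model A [substitution_model()] used when
#'   `model_policy = "fixed"` (default HKY85+G alpha 0.7).
#' @param threshold Congruence support threshold (default 0.95).
#' @param test_B RELL resamples for the SH test (default 10000).
#' @param seed Master seed.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(mode = c("synthetic", "replay"), out_dir,
                       sim = simulation_config(),
                       alignments_dir = NULL,
                       outgroup = DEFAULT_OUTGROUP,
                       gene_tree_method = "nj",
                       bootstrap_replicates = 100L,
                       model_policy = c("aic", "fixed"),
                       fixed_model = NULL,
                       threshold = 0.95, test_B = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  model_policy <- match.arg(model_policy)
  if (mode == "replay") {
    if (is.null(alignments_dir) || !dir.exists(alignments_dir)) {
      stop("replay mode requires an existing alignments_dir")
    }
  }
  if (is.null(fixed_model)) {
    fixed_model <- substitution_model("HKY85", alpha = 0.7)
  }
  structure(list(mode = mode, out_dir = out_dir, sim = sim,
                 alignments_dir = alignments_dir, outgroup = outgroup,
                 gene_tree_method = gene_tree_method,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 model_policy = model_policy, fixed_model = fixed_model,
                 threshold = threshold, test_B = as.integer(test_B),
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(con, stage, locus, msg) {
  line <- sprintf("[%s] %s %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  locus, msg)
  writeLines(line, con)
  flush(con)
}

#' Run the full marker-utility pipeline
#'
#' Stages: (1) obtain loci (simulated bundle or replayed alignments);
#' (2) characterize every locus plus the combined nuclear and mitochondrial
#' concatenations; (3) infer a bootstrap majority-rule consensus tree per
#' locus, and a maximum-likelihood (NNI search) combined tree per marker
#' class with bootstrap supports; (4) score every locus's tree against its
#' class's combined tree by congruent-node counts and rank loci; (5) run SH
#' tests of the combined nuclear topology against the combined mitochondrial
#' topology on each concatenation. All outputs are written under `out_dir`
#' and the same config + seed reproduce them exactly.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (`characterization`, `gene_trees`, `combined`, `scores`, `sh`, paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  for (d in c("", "characterize", "trees", "score", "tests")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  logcon <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logcon))
  t0 <- proc.time()[3L]

  # --- stage 1: inputs -----------------------------------------------------
  stage <- "input"
  res <- tryCatch({
    if (config$mode == "synthetic") {
      bundle <- generate_study(config$sim)
      write_study(bundle, file.path(out, "bundle"))
      bundle$loci
    } else {
      files <- list.files(config$alignments_dir, pattern = "\\.fasta$",
                          full.names = TRUE)
      if (!length(files)) stop("no .fasta files in ", config$alignments_dir)
      loci <- lapply(files, function(f) {
        nm <- sub("\\.fasta$", "", basename(f))
        cls <- if (nm %in% MT_PANEL$name) {
          MT_PANEL$class[match(nm, MT_PANEL$name)]
        } else "nuclear_noncoding"
        locus(nm, read_alignment(f, "fasta"), cls)
      })
      names(loci) <- vapply(loci, `[[`, character(1L), "name")
      loci
    }
  }, error = function(e) stop("stage '", stage, "' failed: ", conditionMessage(e)))
  loci <- res
  classes <- vapply(loci, `[[`, character(1L), "locus_class")
  pipeline_log(logcon, stage, "-", sprintf("%d loci loaded", length(loci)))

  # --- stage 2: characterization ------------------------------------------
  stage <- "characterize"
  char_tab <- tryCatch(
    characterize_loci(loci, fit_models = config$model_policy == "aic"),
    error = function(e) stop("stage '", stage, "' failed: ", conditionMessage(e)))
  write.table(char_tab, file.path(out, "characterize", "characterization.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log(logcon, stage, "-", sprintf("%d rows", nrow(char_tab)))

  # --- stage 3: inference --------------------------------------------------
  stage <- "infer"
  gene_trees <- list()
  for (i in seq_along(loci)) {
    nm <- names(loci)[i]
    gt <- tryCatch({
      bt <- bootstrap_support(loci[[nm]]$alignment,
                              method = config$gene_tree_method,
                              replicates = config$bootstrap_replicates,
                              seed = derive_seed(config$seed, i),
                              keep_trees = TRUE)
      cons <- majority_rule_consensus(attr(bt, "replicates"))
      write_tree(cons, file.path(out, "trees", paste0(nm, ".nwk")))
      cons
    }, error = function(e) {
      stop("stage '", stage, "' failed at locus '", nm, "': ",
           conditionMessage(e))
    })
    gene_trees[[nm]] <- gt
    pipeline_log(logcon, stage, nm,
                 sprintf("consensus with %d splits", length(tree_splits(gt))))
  }

  combined <- list()
  for (cls in c("nuclear", "mt")) {
    sel <- if (cls == "nuclear") classes == "nuclear_noncoding" else
      classes != "nuclear_noncoding"
    if (!any(sel)) next
    cc <- concatenate(loci[sel])
    write_partition(cc$partition, file.path(out, "trees",
                                            paste0("combined_", cls, ".partition")))
    model <- if (config$model_policy == "aic") {
      fits <- select_model_aic(cc$alignment)
      fits[[1L]]$model
    } else config$fixed_model
    d <- tryCatch(pairwise_distance_matrix(cc$alignment, "k2p"),
                  error = function(e) pairwise_distance_matrix(cc$alignment, "p_distance"))
    start <- nj_tree(d)
    start$edge.length <- pmax(start$edge.length, 1e-6)
    ml <- nni_search(start, cc$alignment, model)
    annotated <- bootstrap_support(cc$alignment, method = "nj",
                                   replicates = config$bootstrap_replicates,
                                   seed = derive_seed(config$seed, 5000L + nchar(cls)),
                                   point_tree = ml)
    attr(annotated, "lnL") <- attr(ml, "lnL")
    combined[[cls]] <- list(tree = annotated, alignment = cc$alignment,
                            model = model)
    write_tree(annotated, file.path(out, "trees",
                                    paste0("combined_", cls, ".nwk")))
    pipeline_log(logcon, stage, paste0("combined_", cls),
                 sprintf("lnL=%.2f model=%s", attr(ml, "lnL"), model_id(model)))
  }

  # --- stage 4: congruence scoring ----------------------------------------
  stage <- "score"
  scores <- tryCatch({
    tabs <- list()
    for (cls in names(combined)) {
      ref <- reference_nodes(combined[[cls]]$tree, config$outgroup)
      sel <- if (cls == "nuclear") classes == "nuclear_noncoding" else
        classes != "nuclear_noncoding"
      perf <- lapply(names(loci)[sel], function(nm) {
        score_gene(gene_trees[[nm]], ref, threshold = config$threshold,
                   locus_name = nm)
      })
      tab <- rank_genes(perf)
      tab$reference <- cls
      tabs[[cls]] <- tab
    }
    do.call(rbind, tabs)
  }, error = function(e) stop("stage '", stage, "' failed: ", conditionMessage(e)))
  write.table(scores, file.path(out, "score", "gene_performance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log(logcon, stage, "-", sprintf("%d loci scored", nrow(scores)))

  # --- stage 5: topology tests --------------------------------------------
  stage <- "topotest"
  sh <- NULL
  if (length(combined) == 2L &&
      !topo_equal(combined$nuclear$tree, combined$mt$tree)) {
    sh <- list()
    for (cls in names(combined)) {
      m <- topology_site_lnls(combined[[cls]]$alignment,
                              list(nuclear_topology = combined$nuclear$tree,
                                   mt_topology = combined$mt$tree),
                              combined[[cls]]$model)
      sh[[cls]] <- sh_test(m, B = config$test_B,
                           seed = derive_seed(config$seed, 8000L + nchar(cls)))
      sh[[cls]]$data <- cls
    }
    sh <- do.call(rbind, sh)
    write.table(sh, file.path(out, "tests", "sh_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    pipeline_log(logcon, stage, "-", "SH tests written")
  } else if (length(combined) == 2L) {
    pipeline_log(logcon, stage, "-",
                 "combined topologies identical; SH test skipped")
  }

  manifest <- c(sprintf("radsplit_version=%s",
                        as.character(utils::packageVersion("radsplit"))),
                sprintf("mode=%s", config$mode),
                sprintf("seed=%d", config$seed),
                sprintf("elapsed_s=%.1f", proc.time()[3L] - t0))
  writeLines(manifest, file.path(out, "manifest.txt"))
  invisible(list(characterization = char_tab, gene_trees = gene_trees,
                 combined = combined, scores = scores, sh = sh,
                 out_dir = out))
}
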