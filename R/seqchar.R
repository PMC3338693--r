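# Per-locus sequence characterization: variable / parsimony-informative site
# counts, pairwise distances (p-distance and K2P, pairwise deletion), and the
# numt-style coding-integrity screen.

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative when it shows at least two distinct
#' unambiguous states (A, C, G, T) that are each present in at least two rows.
#' Gaps, `?`, and IUPAC ambiguity codes never count as states.
#'
#' @param alignment An [aln()] object.
#' @return Integer count of informative columns.
#' @export
count_parsimony_informative <- function(alignment) {
  if (!inherits(alignment, "aln")) alignment <- aln(alignment)
  sum(apply(unclass(alignment), 2L, function(col) {
    tab <- table(col[col %in% ALN_STATES])
    sum(tab >= 2L) >= 2L
  }))
}

#' Count variable sites
#'
#' A column is variable when it shows at least two distinct unambiguous
#' states; always at least the parsimony-informative count.
#'
#' @inheritParams count_parsimony_informative
#' @return Integer count of variable columns.
#' @export
count_variable <- function(alignment) {
  if (!inherits(alignment, "aln")) alignment <- aln(alignment)
  sum(apply(unclass(alignment), 2L, function(col) {
    length(unique(col[col %in% ALN_STATES])) >= 2L
  }))
}

#' Pairwise distance matrix
#'
#' Distances under pairwise deletion: for each pair of rows, every site where
#' either member carries a gap, `?`, or an ambiguity code is excluded before
#' comparison. `p_distance` is the mismatch proportion; `k2p` applies the
#' Kimura two-parameter correction from the transition and transversion
#' fractions.
#'
#' @param alignment An [aln()] object.
#' @param metric `"p_distance"` (default) or `"k2p"`.
#' @return A symmetric numeric matrix with zero diagonal, labeled by taxon.
#' @export
pairwise_distance_matrix <- function(alignment, metric = c("p_distance", "k2p")) {
  if (!inherits(alignment, "aln")) alignment <- aln(alignment)
  metric <- match.arg(metric)
  m <- unclass(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  labels <- rownames(m)
  purine <- m %in% c("A", "G")
  dim(purine) <- dim(m)
  valid <- m %in% ALN_STATES
  dim(valid) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- valid[i, ] & valid[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     labels[i], labels[j]))
      }
      diff <- ok & (m[i, ] != m[j, ])
      if (metric == "p_distance") {
        dij <- sum(diff) / nc
      } else {
        ts <- sum(diff & (purine[i, ] == purine[j, ])) / nc  # transitions
        tv <- sum(diff & (purine[i, ] != purine[j, ])) / nc  # transversions
        w1 <- 1 - 2 * ts - tv
        w2 <- 1 - 2 * tv
        if (w1 <= 0 || w2 <= 0) {
          stop(sprintf("K2P distance undefined (saturation) between '%s' and '%s'",
                       labels[i], labels[j]))
        }
        dij <- -0.5 * log(w1) - 0.25 * log(w2)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Characterize one locus
#'
#' Produces one row of the per-locus characterization table: aligned length,
#' variable and parsimony-informative site counts, and the unweighted mean
#' pairwise distance over all unordered taxon pairs. Model fields (`model_id`,
#' `I`, `alpha`) are left `NA` here and filled in by AIC model selection when
#' the full characterization table is built.
#'
#' @param x A [locus()] object (or an [aln()], characterized under a
#'   placeholder name).
#' @param metric Distance metric passed to [pairwise_distance_matrix()].
#' @return A one-row data.frame with columns `locus`, `aligned_length`,
#'   `variable_sites`, `pi_sites`, `mean_pairwise_distance`, `model_id`, `I`,
#'   `alpha`.
#' @export
characterize_locus <- function(x, metric = "p_distance") {
  if (inherits(x, "aln")) x <- locus("locus", x)
  stopifnot(inherits(x, "locus"))
  a <- x$alignment
  d <- pairwise_distance_matrix(a, metric)
  data.frame(
    locus = x$name,
    aligned_length = ncol(a),
    variable_sites = count_variable(a),
    pi_sites = count_parsimony_informative(a),
    mean_pairwise_distance = mean(d[upper.tri(d)]),
    model_id = NA_character_, I = NA_real_, alpha = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Genetic codes as named stop-codon sets; only stop detection is needed for
# the integrity screen.
STOP_CODONS <- list(
  standard = c("TAA", "TAG", "TGA"),
  vertebrate_mt = c("TAA", "TAG", "AGA", "AGG")
)

#' Coding-integrity check for putative protein-coding sequence
#'
#' Screens a sequence for the hallmarks of a nuclear mitochondrial pseudogene
#' (numt): premature (internal) stop codons and frameshifting indels, detected
#' as an ungapped length that is not a multiple of three. The sequence is
#' clean when neither occurs before the final codon; a stop in the terminal
#' codon position is noted but does not flag the sequence.
#'
#' @param sequence A single character string (gaps allowed; removed before
#'   translation).
#' @param genetic_code `"vertebrate_mt"` (default) or `"standard"`.
#' @param reading_frame 1, 2 or 3: offset of the first codon position.
#' @return A list with `clean` (logical), `internal_stops` (codon indices),
#'   `terminal_stop` (logical), `frameshift` (logical, ungapped length after
#'   the frame offset not divisible by 3).
#' @export
coding_integrity_check <- function(sequence,
                                   genetic_code = c("vertebrate_mt", "standard"),
                                   reading_frame = 1L) {
  genetic_code <- match.arg(genetic_code)
  if (!reading_frame %in% 1:3) stop("unknown reading frame: ", reading_frame)
  s <- toupper(gsub("[-?]", "", sequence))
  s <- gsub("U", "T", s, fixed = TRUE)
  s <- substring(s, reading_frame)
  if (nchar(s) < 3L) stop("sequence shorter than one codon after gap removal")
  n_codon <- nchar(s) %/% 3L
  frameshift <- (nchar(s) %% 3L) != 0L
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  is_stop <- codons %in% STOP_CODONS[[genetic_code]]
  internal <- which(is_stop[-n_codon])
  terminal <- is_stop[n_codon]
  list(clean = length(internal) == 0L && !frameshift,
       internal_stops = internal,
       terminal_stop = terminal,
       frameshift = frameshift)
}

#' Characterize a set of loci
#'
#' Builds the full characterization table (one row per locus plus optional
#' combined rows per locus class), and optionally runs AIC model selection per
#' locus to fill the best-fit model columns.
#'
#' @param loci A list of [locus()] objects.
#' @param metric Distance metric.
#' @param fit_models Run [select_model_aic()] per locus (on an NJ base
#'   topology) to fill `model_id`, `I`, `alpha`? Slower but mirrors the full
#'   characterization workflow.
#' @param combined Add a `Combined` row per locus class (concatenating the
#'   class members)?
#' @return A data.frame, one row per locus (plus combined rows).
#' @export
characterize_loci <- function(loci, metric = "p_distance", fit_models = FALSE,
                              combined = TRUE) {
  rows <- lapply(loci, function(lc) {
    row <- characterize_locus(lc, metric)
    if (fit_models) {
      fits <- select_model_aic(lc$alignment)
      best <- fits[[1L]]
      row$model_id <- best$model_id
      row$I <- if (is.null(best$model$p_inv)) 0 else best$model$p_inv
      row$alpha <- if (is.null(best$model$alpha)) NA_real_ else best$model$alpha
    }
    row
  })
  tab <- do.call(rbind, rows)
  if (combined) {
    classes <- vapply(loci, `[[`, character(1L), "locus_class")
    nuclear <- loci[classes == "nuclear_noncoding"]
    mt <- loci[classes != "nuclear_noncoding"]
    for (grp in list(list(nm = "Combined_nuclear", set = nuclear),
                     list(nm = "Combined_mt", set = mt))) {
      if (length(grp$set) >= 1L) {
        cc <- concatenate(grp$set)
        row <- characterize_locus(locus(grp$nm, cc$alignment), metric)
        tab <- rbind(tab, row)
      }
    }
  }
  rownames(tab) <- NULL
  tab
}
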