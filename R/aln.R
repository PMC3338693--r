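#' @useDynLib radsplit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize optim runif rexp qgamma pgamma setNames
#' @importFrom utils combn write.table read.table head
NULL

# Character sets: unambiguous states, missing markers, IUPAC ambiguity codes.
ALN_STATES <- c("A", "C", "G", "T")
ALN_MISSING <- c("-", "?")
ALN_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
ALN_ALPHABET <- c(ALN_STATES, ALN_MISSING, ALN_AMBIG)

# IUPAC code -> compatible unambiguous states (used for likelihood partials
# and parsimony state sets).
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T")
)

#' Construct a multiple sequence alignment
#'
#' An alignment is stored as a character matrix with one row per taxon
#' (rownames are the taxon labels) and one column per aligned site. Bases are
#' normalized to upper case and `U` is mapped to `T`. Both `-` and `?` are
#' accepted and treated as missing data downstream; IUPAC ambiguity codes are
#' preserved.
#'
#' @param x A character matrix (rows = taxa), or a named character vector of
#'   equal-length sequence strings.
#' @return An object of class `"aln"`: the normalized character matrix.
#' @examples
#' a <- aln(c(A = "ACGT", B = "ACGA"))
#' aln_ncol(a)
#' @export
aln <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    labels <- names(x)
    if (is.null(labels)) stop("sequences must be named with taxon labels")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L) {
      bad <- labels[lens != lens[1L]][1L]
      stop(sprintf("unequal sequence lengths: record '%s' has %d characters, expected %d",
                   bad, nchar(x[[bad]]), lens[1L]))
    }
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- labels
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) stop("alignment must be a character matrix")
  if (nrow(x) < 2L) stop("alignment must have at least 2 rows")
  labels <- rownames(x)
  if (is.null(labels) || anyNA(labels)) stop("alignment rows must be labeled")
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate taxon label: '%s'", labels[duplicated(labels)][1L]))
  }
  x[] <- toupper(x)
  x[x == "U"] <- "T"
  bad <- which(!(x %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("unknown character '%s' in record '%s' at column %d",
                 x[bad[1L]], labels[i], j))
  }
  structure(x, class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Alignment: %d taxa, %d sites\n", nrow(x), ncol(x)))
  show <- min(nrow(x), 6L)
  w <- min(ncol(x), 50L)
  for (i in seq_len(show)) {
    cat(sprintf("  %-20s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(w)], collapse = ""),
                if (ncol(x) > w) "..." else ""))
  }
  if (nrow(x) > show) cat(sprintf("  ... and %d more\n", nrow(x) - show))
  invisible(x)
}

#' Alignment dimensions and labels
#' @param x An [aln()] object.
#' @return `aln_ncol`: number of aligned columns; `aln_labels`: taxon labels.
#' @export
aln_ncol <- function(x) ncol(x)

#' @rdname aln_ncol
#' @export
aln_labels <- function(x) rownames(x)

#' Restrict an alignment to a subset of taxa
#' @param x An [aln()] object.
#' @param taxa Labels to keep, in the order given.
#' @return The restricted alignment.
#' @export
aln_subset <- function(x, taxa) {
  miss <- setdiff(taxa, rownames(x))
  if (length(miss)) stop("taxa not in alignment: ", paste(miss, collapse = ", "))
  aln(unclass(x)[taxa, , drop = FALSE])
}

#' Construct a locus
#'
#' Bundles a named alignment with its marker class, mirroring one fragment of
#' the study design (a slow nuclear non-coding region, or one mitochondrial
#' sub-partition).
#'
#' @param name Unique locus identifier.
#' @param alignment An [aln()] object.
#' @param locus_class One of `"nuclear_noncoding"`, `"mt_protein"`,
#'   `"mt_rRNA"`, `"mt_tRNA"`, `"mt_CR"`.
#' @return An object of class `"locus"`.
#' @export
locus <- function(name, alignment,
                  locus_class = c("nuclear_noncoding", "mt_protein",
                                  "mt_rRNA", "mt_tRNA", "mt_CR")) {
  locus_class <- match.arg(locus_class)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(alignment, "aln")) alignment <- aln(alignment)
  structure(list(name = name, alignment = alignment, locus_class = locus_class),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("Locus '%s' (%s): %d taxa x %d sites\n", x$name, x$locus_class,
              nrow(x$alignment), ncol(x$alignment)))
  invisible(x)
}
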