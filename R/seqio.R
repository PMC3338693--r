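# Alignment and tree IO: FASTA, relaxed PHYLIP, NEXUS data blocks, Newick
# with support labels, and concatenation with partition tables.

#' Read a multiple sequence alignment
#'
#' Supported formats: FASTA, relaxed sequential PHYLIP (whitespace-delimited
#' labels up to 64 characters), and a NEXUS `DATA` block. Bases are upper-cased
#' and `U` is normalized to `T` on read.
#'
#' @param path Path to the file.
#' @param format One of `"fasta"` (default), `"phylip_relaxed"`, `"nexus"`.
#' @return An [aln()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip_relaxed", "nexus")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  switch(format,
    fasta = read_fasta(path),
    phylip_relaxed = read_phylip_relaxed(path),
    nexus = read_nexus_aln(path)
  )
}

read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records found in ", path)
  if (hdr[1L] != which(nzchar(trimws(lines)))[1L]) {
    stop(sprintf("line %d: sequence data before first FASTA header", 1L))
  }
  labels <- trimws(sub("^>", "", lines[hdr]))
  labels <- sub("\\s.*$", "", labels)  # label = first token of the header
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    if (hdr[i] + 1L > ends[i]) "" else paste(gsub("\\s", "", body), collapse = "")
  }, character(1L))
  names(seqs) <- labels
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for record '%s'", labels[!nzchar(seqs)][1L]))
  }
  aln(seqs)
}

read_phylip_relaxed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("line 1: malformed PHYLIP header (expected '<ntaxa> <ncols>')")
  }
  n <- as.integer(hdr[1L]); L <- as.integer(hdr[2L])
  if (length(lines) - 1L != n) {
    stop(sprintf("PHYLIP header declares %d taxa but %d sequence lines found",
                 n, length(lines) - 1L))
  }
  parts <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(parts, `[`, character(1L), 1L)
  if (any(nchar(labels) > 64L)) {
    stop(sprintf("label '%s' exceeds 64 characters", labels[nchar(labels) > 64L][1L]))
  }
  seqs <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1L))
  bad <- which(nchar(seqs) != L)
  if (length(bad)) {
    stop(sprintf("line %d: record '%s' has %d characters, header declares %d",
                 bad[1L] + 1L, labels[bad[1L]], nchar(seqs[bad[1L]]), L))
  }
  names(seqs) <- labels
  aln(seqs)
}

read_nexus_aln <- function(path) {
  x <- ape::read.nexus.data(path)
  seqs <- vapply(x, function(s) paste(s, collapse = ""), character(1L))
  aln(seqs)
}

#' Write a multiple sequence alignment
#'
#' Inverse of [read_alignment()]: files written here read back to an identical
#' alignment (labels and rows).
#'
#' @param alignment An [aln()] object.
#' @param path Output path.
#' @param format One of `"fasta"`, `"phylip_relaxed"`, `"nexus"`.
#' @export
write_alignment <- function(alignment, path,
                            format = c("fasta", "phylip_relaxed", "nexus")) {
  if (!inherits(alignment, "aln")) alignment <- aln(alignment)
  format <- match.arg(format)
  labels <- rownames(alignment)
  seqs <- apply(unclass(alignment), 1L, paste, collapse = "")
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", labels), seqs))
    writeLines(out, path)
  } else if (format == "phylip_relaxed") {
    out <- c(sprintf("%d %d", nrow(alignment), ncol(alignment)),
             sprintf("%-*s  %s", max(nchar(labels)), labels, seqs))
    writeLines(out, path)
  } else {
    ape::write.nexus.data(strsplit(setNames(seqs, labels), "", fixed = TRUE),
                          path, interleaved = FALSE)
  }
  invisible(NULL)
}

#' Read a tree from Newick text or a file
#'
#' Numeric internal-node labels are interpreted as edge supports; values
#' greater than 1 are assumed to be percentages and divided by 100, so supports
#' always come back on a 0-1 scale. Absent branch lengths are left `NA`
#' (unknown), never coerced to zero.
#'
#' @param path_or_text A file path or a literal Newick string (detected by the
#'   presence of a terminal `;`).
#' @return An [ape::phylo] tree; supports, if any, are stored as a numeric
#'   `node.label` vector (NA where absent).
#' @export
read_tree <- function(path_or_text) {
  txt <- if (grepl(";", path_or_text, fixed = TRUE) && !file.exists(path_or_text)) {
    path_or_text
  } else {
    if (!file.exists(path_or_text)) stop("file not found: ", path_or_text)
    paste(readLines(path_or_text, warn = FALSE), collapse = "")
  }
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: could not parse input")
  if (anyDuplicated(tr$tip.label)) {
    stop(sprintf("duplicate leaf label: '%s'",
                 tr$tip.label[duplicated(tr$tip.label)][1L]))
  }
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (all(is.na(sup) | !nzchar(tr$node.label)) && !any(!is.na(sup))) {
      tr$node.label <- NULL  # purely textual labels: not supports
    } else {
      sup[!is.na(sup) & sup > 1] <- sup[!is.na(sup) & sup > 1] / 100
      tr$node.label <- sup
    }
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree An [ape::phylo] tree, optionally with numeric `node.label`
#'   supports on a 0-1 scale.
#' @param path Output path; if `NULL` the Newick string is returned.
#' @param include_support Emit supports as internal-node labels?
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree <- function(tree, path = NULL, include_support = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (include_support && !is.null(tree$node.label)) {
    sup <- as.numeric(tree$node.label)
    check_root_support_agreement(tree, sup)
    lab <- ifelse(is.na(sup), "", formatC(sup, format = "g", digits = 6))
    tree$node.label <- lab
  } else {
    tree$node.label <- NULL
  }
  txt <- ape::write.tree(tree, digits = 12)
  txt <- gsub(":NaN|:NA", "", txt)  # unknown lengths stay absent, not zero
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# In a rooted binary tree the two root-adjacent edges carry the same
# bipartition; if both children of the root are internal nodes with supports,
# those supports must agree.
check_root_support_agreement <- function(tree, sup) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (length(kids) != 2L) return(invisible(TRUE))
  ik <- kids[kids > ntip] - ntip
  if (length(ik) == 2L && !anyNA(sup[ik]) && abs(sup[ik[1L]] - sup[ik[2L]]) > 1e-8) {
    stop("root-adjacent supports disagree for the same bipartition: ",
         sup[ik[1L]], " vs ", sup[ik[2L]])
  }
  invisible(TRUE)
}

#' Concatenate loci into a combined alignment
#'
#' Columns are appended in the given locus order; every locus must cover the
#' identical taxon set (missing taxa are an error, never silently padded with
#' gaps).
#'
#' @param loci A list of [locus()] objects (or bare [aln()] objects, which are
#'   named `locus1`, `locus2`, ...).
#' @param taxon_order Optional row order for the result; default is the order
#'   of the first locus.
#' @return A list with elements `alignment` (the combined [aln()]) and
#'   `partition` (a data.frame with columns `name`, `start`, `end`, 1-based
#'   inclusive).
#' @export
concatenate <- function(loci, taxon_order = NULL) {
  stopifnot(length(loci) >= 1L)
  loci <- lapply(seq_along(loci), function(i) {
    x <- loci[[i]]
    if (inherits(x, "locus")) x else locus(paste0("locus", i), x)
  })
  ref <- sort(rownames(loci[[1L]]$alignment))
  for (lc in loci) {
    lab <- sort(rownames(lc$alignment))
    if (!identical(lab, ref)) {
      miss <- setdiff(ref, lab)
      extra <- setdiff(lab, ref)
      stop(sprintf("locus '%s' taxon set mismatch%s%s", lc$name,
                   if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")) else "",
                   if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")) else ""))
    }
  }
  if (is.null(taxon_order)) taxon_order <- rownames(loci[[1L]]$alignment)
  stopifnot(setequal(taxon_order, ref))
  mats <- lapply(loci, function(lc) unclass(lc$alignment)[taxon_order, , drop = FALSE])
  combined <- do.call(cbind, mats)
  lens <- vapply(loci, function(lc) ncol(lc$alignment), integer(1L))
  ends <- cumsum(lens)
  part <- data.frame(name = vapply(loci, `[[`, character(1L), "name"),
                     start = c(1L, head(ends, -1L) + 1L), end = ends,
                     stringsAsFactors = FALSE)
  list(alignment = aln(combined), partition = part)
}

#' Read and write partition tables
#'
#' One line per entry in the RAxML-style dialect `DNA, <name> = <start>-<end>`
#' with 1-based inclusive column ranges.
#'
#' @param partition A data.frame with columns `name`, `start`, `end`.
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  writeLines(sprintf("DNA, %s = %d-%d", partition$name,
                     partition$start, partition$end), path)
  invisible(NULL)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^\\s*DNA\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- which(vapply(m, length, integer(1L)) != 4L)
  if (length(bad)) stop(sprintf("line %d: malformed partition entry", bad[1L]))
  part <- data.frame(name = vapply(m, `[`, character(1L), 2L),
                     start = as.integer(vapply(m, `[`, character(1L), 3L)),
                     end = as.integer(vapply(m, `[`, character(1L), 4L)),
                     stringsAsFactors = FALSE)
  validate_partition(part)
  part
}

validate_partition <- function(part) {
  if (part$start[1L] != 1L) stop("partition must start at column 1")
  if (any(part$end < part$start)) stop("partition entry with end < start")
  if (nrow(part) > 1L && any(part$start[-1L] != part$end[-nrow(part)] + 1L)) {
    stop("partition entries must be contiguous and in order")
  }
  invisible(part)
}
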