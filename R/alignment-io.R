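# 20-letter amino acid alphabet; 'X' is treated as missing data and '-' as a
# gap throughout the package.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
MISSING_CHARS <- c("X", "-")

#' Construct a gene alignment
#'
#' A `gene_alignment` holds one gene's protein alignment over a set of focal
#' strains (the in-group whose substitutions are counted) plus optional
#' outgroup species (used only to decide which sites are variable), together
#' with the strand the gene is encoded on.
#'
#' @param gene_id Gene identifier (single string).
#' @param seqs Named character vector of aligned, equal-length amino acid
#'   strings. Allowed characters: the 20 amino acid letters, `X` (missing)
#'   and `-` (gap). Lowercase input is uppercased.
#' @param focal Character vector of sequence labels that are focal strains;
#'   must be a non-empty subset of `names(seqs)`.
#' @param strand One of `"leading"`, `"lagging"`, `"unknown"`.
#' @return An object of class `gene_alignment`: a list with elements
#'   `gene_id`, `seqs`, `focal`, `strand`.
#' @examples
#' gene_alignment("yfp", c(s1 = "MKV", s2 = "MKI"), focal = c("s1", "s2"))
#' @export
gene_alignment <- function(gene_id, seqs, focal = names(seqs),
                           strand = c("unknown", "leading", "lagging")) {
  strand <- match.arg(strand)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("'seqs' must have unique names")
  seqs <- toupper(vapply(seqs, as.character, character(1)))
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    bad <- names(seqs)[widths != widths[1L]][1L]
    stop(sprintf("ragged alignment in gene '%s': record '%s' has length %d, expected %d",
                 gene_id, bad, nchar(seqs[bad]), widths[1L]))
  }
  ok <- grepl(sprintf("^[%s]*$", paste(c(AA_ALPHABET, MISSING_CHARS), collapse = "")), seqs)
  if (!all(ok))
    stop(sprintf("gene '%s': sequence '%s' contains characters outside the amino acid alphabet",
                 gene_id, names(seqs)[!ok][1L]))
  focal <- as.character(focal)
  if (length(focal) == 0L) stop("'focal' must be non-empty")
  missing_focal <- setdiff(focal, names(seqs))
  if (length(missing_focal))
    stop(sprintf("gene '%s': focal label(s) %s not present in alignment",
                 gene_id, paste(sQuote(missing_focal), collapse = ", ")))
  structure(list(gene_id = gene_id, seqs = seqs, focal = focal, strand = strand),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s [%s]: %d rows (%d focal) x %d columns\n",
              x$gene_id, x$strand, length(x$seqs), length(x$focal),
              alignment_length(x)))
  invisible(x)
}

#' Alignment dimensions and row access
#'
#' @param aln A [gene_alignment].
#' @return `alignment_length()` returns the number of columns;
#'   `alignment_matrix()` a character matrix (rows = sequences);
#'   `outgroup_labels()` the non-focal row labels.
#' @export
alignment_length <- function(aln) {
  if (length(aln$seqs) == 0L) return(0L)
  nchar(aln$seqs[[1L]])
}

#' @rdname alignment_length
#' @export
alignment_matrix <- function(aln) {
  if (length(aln$seqs) == 0L) return(matrix(character(), 0L, 0L))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

#' @rdname alignment_length
#' @export
outgroup_labels <- function(aln) setdiff(names(aln$seqs), aln$focal)

#' Read a protein alignment from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] and validates the result as a
#' [gene_alignment]: all records must have equal length and every focal
#' label must be present.
#'
#' @param path FASTA file.
#' @param focal_labels Labels of the focal strains.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @param strand Strand label.
#' @return A [gene_alignment].
#' @export
read_fasta_alignment <- function(path, focal_labels, gene_id = NULL,
                                 strand = c("unknown", "leading", "lagging")) {
  strand <- match.arg(strand)
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # keep the FASTA id token only
  gene_alignment(gene_id, seqs, focal = focal_labels, strand = strand)
}

#' Write a gene alignment to FASTA
#'
#' @param aln A [gene_alignment].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  ss <- Biostrings::AAStringSet(aln$seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Remove alignment columns gapped in any focal strain
#'
#' Columns holding a gap in at least one focal row are dropped; columns whose
#' only gaps are in outgroup rows are kept, because an outgroup gap counts as
#' a variant when deciding whether a site is variable. Column order is
#' preserved and the original 0-based column index of each kept column is
#' returned in the `"column_map"` attribute.
#'
#' @param aln A [gene_alignment].
#' @return A [gene_alignment] restricted to the kept columns, with attribute
#'   `column_map` (integer vector, original 0-based indices).
#' @export
remove_gap_columns <- function(aln) {
  m <- alignment_matrix(aln)
  L <- ncol(m)
  if (L == 0L) {
    attr(aln, "column_map") <- integer(0)
    return(aln)
  }
  fm <- m[aln$focal, , drop = FALSE]
  keep <- colSums(fm == "-") == 0L
  m2 <- m[, keep, drop = FALSE]
  seqs <- apply(m2, 1L, paste, collapse = "")
  if (ncol(m2) == 0L) seqs <- setNames(rep("", nrow(m)), rownames(m))
  out <- gene_alignment(aln$gene_id, seqs, focal = aln$focal, strand = aln$strand)
  attr(out, "column_map") <- which(keep) - 1L
  out
}

#' Pairwise identity and coverage between two aligned rows
#'
#' Identity is matches / aligned columns where both rows are non-gap;
#' coverage is that overlap length / the shorter row's ungapped length.
#' `X` counts as a non-gap residue for coverage but never as a match.
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @return Named numeric vector `c(identity=, coverage=)`; identity is `NaN`
#'   when the non-gap overlap is empty.
#' @export
seq_identity_coverage <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  stopifnot(length(av) == length(bv))
  both <- av != "-" & bv != "-"
  n_overlap <- sum(both)
  n_match <- sum(both & av == bv & av != "X")
  shorter <- min(sum(av != "-"), sum(bv != "-"))
  c(identity = if (n_overlap) n_match / n_overlap else NaN,
    coverage = if (shorter) n_overlap / shorter else NaN)
}

#' Apply ortholog-quality filters to a set of gene alignments
#'
#' A gene is kept when its ungapped focal length exceeds `min_length`
#' (strict inequality). Within a kept gene, each outgroup row is compared to
#' the first focal row and dropped (the row, not the gene) when pairwise
#' identity or coverage falls below the thresholds.
#'
#' @param alignments List of [gene_alignment] objects.
#' @param min_length Minimum focal ungapped length, exclusive. Default 200.
#' @param min_identity,min_coverage Per-outgroup-row thresholds in `[0,1]`.
#'   Default 0.7.
#' @return A list with `kept` (filtered alignments) and `rejected`
#'   (data.frame log: gene_id, row, reason, value).
#' @export
ortholog_filter <- function(alignments, min_length = 200,
                            min_identity = 0.7, min_coverage = 0.7) {
  stopifnot(min_length >= 0, min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  log <- list()
  kept <- list()
  for (aln in alignments) {
    ref <- aln$seqs[[aln$focal[1L]]]
    focal_len <- min(vapply(aln$seqs[aln$focal], function(s)
      sum(strsplit(s, "", fixed = TRUE)[[1L]] != "-"), numeric(1)))
    if (!(focal_len > min_length)) {
      log[[length(log) + 1L]] <- data.frame(
        gene_id = aln$gene_id, row = NA_character_, reason = "short_gene",
        value = focal_len, stringsAsFactors = FALSE)
      next
    }
    drop_rows <- character(0)
    for (og in outgroup_labels(aln)) {
      ic <- seq_identity_coverage(ref, aln$seqs[[og]])
      if (is.nan(ic[["identity"]]) || ic[["identity"]] < min_identity) {
        drop_rows <- c(drop_rows, og)
        log[[length(log) + 1L]] <- data.frame(
          gene_id = aln$gene_id, row = og, reason = "low_identity",
          value = ic[["identity"]], stringsAsFactors = FALSE)
      } else if (ic[["coverage"]] < min_coverage) {
        drop_rows <- c(drop_rows, og)
        log[[length(log) + 1L]] <- data.frame(
          gene_id = aln$gene_id, row = og, reason = "low_coverage",
          value = ic[["coverage"]], stringsAsFactors = FALSE)
      }
    }
    if (length(drop_rows)) {
      aln <- gene_alignment(aln$gene_id,
                            aln$seqs[setdiff(names(aln$seqs), drop_rows)],
                            focal = aln$focal, strand = aln$strand)
    }
    kept[[aln$gene_id]] <- aln
  }
  rejected <- if (length(log)) do.call(rbind, log) else
    data.frame(gene_id = character(), row = character(),
               reason = character(), value = numeric(), stringsAsFactors = FALSE)
  list(kept = kept, rejected = rejected)
}

#' Read and write strand-assignment tables
#'
#' Two-column tab-separated table: `gene_id`, `strand` (one of
#' `leading`/`lagging`).
#'
#' @param path TSV file.
#' @return `read_strand_table()` returns a data.frame with columns `gene_id`
#'   and `strand`.
#' @export
read_strand_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("gene_id", "strand") %in% names(df)))
    stop("strand table must have columns 'gene_id' and 'strand'")
  bad <- setdiff(unique(df$strand), c("leading", "lagging"))
  if (length(bad))
    stop(sprintf("unknown strand label(s): %s", paste(sQuote(bad), collapse = ", ")))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in strand table")
  df[c("gene_id", "strand")]
}

#' @rdname read_strand_table
#' @param table Data.frame with columns `gene_id`, `strand`.
#' @export
write_strand_table <- function(table, path) {
  utils::write.table(table[c("gene_id", "strand")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a rooted strain phylogeny
#'
#' Checks that `tree` is a rooted, binary `phylo` object whose tips cover all
#' focal labels, with unique tip labels.
#'
#' @param tree An [ape::read.tree()] `phylo` object.
#' @param focal_labels Labels that must appear among the tips.
#' @return `tree`, invisibly, on success.
#' @export
validate_phylogeny <- function(tree, focal_labels = tree$tip.label) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a 'phylo' object")
  if (is.null(tree$tip.label) || anyDuplicated(tree$tip.label))
    stop("tree tip labels must be present and unique")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary (fully resolved)")
  missing <- setdiff(focal_labels, tree$tip.label)
  if (length(missing))
    stop(sprintf("focal label(s) missing from tree: %s",
                 paste(sQuote(missing), collapse = ", ")))
  invisible(tree)
}

#' Default focal-strain tree
#'
#' A rooted ladder (caterpillar) tree over `n_leaves` strains with equal
#' branch lengths, mirroring a small set of closely related conspecific
#' strains.
#'
#' @param n_leaves Number of strains (default 5).
#' @param branch_length Length of every branch, in expected substitutions
#'   per site (default 0.01).
#' @param labels Tip labels; default `s1..sn`.
#' @return A rooted binary `phylo` object.
#' @export
default_strain_tree <- function(n_leaves = 5L, branch_length = 0.01,
                                labels = paste0("s", seq_len(n_leaves))) {
  stopifnot(n_leaves >= 2L, length(labels) == n_leaves, branch_length >= 0)
  nwk <- labels[1L]
  for (i in 2L:n_leaves) nwk <- sprintf("(%s,%s)", nwk, labels[i])
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  tree
}

# Stable, human-readable edge identifiers: the child's tip label for terminal
# edges, "node<k>" for internal edges.
branch_ids <- function(tree) {
  child <- tree$edge[, 2L]
  ntip <- length(tree$tip.label)
  ifelse(child <= ntip, tree$tip.label[child], paste0("node", child))
}
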