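#' @importFrom stats optimize runif qgamma pgamma setNames
#' @importFrom utils read.table write.table packageVersion
NULL

# Amino-acid alphabet in the conventional (PAML) residue order used by the
# bundled model files.
AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
AA_GAP <- "-"
AA_UNKNOWN <- "X"

#' Construct a protein alignment object
#'
#' An `aa_alignment` holds named, equal-length, gapped amino-acid sequences.
#' Residues are upper-cased; the alphabet is the 20 amino-acid one-letter
#' codes plus `-` (gap) and `X` (totally ambiguous residue).
#'
#' @param seqs Named character vector of aligned sequences, or a character
#'   matrix (rows = sequences, one residue per cell) with rownames.
#' @param ambiguous How to treat ambiguity codes other than `X` (`B`, `Z`,
#'   `J`, `U`, `O`, `*`, `?`): `"to-x"` maps them to `X`, `"error"` rejects
#'   the alignment.
#' @return An object of class `aa_alignment`: a list with `names`,
#'   `matrix` (character matrix, sequences x columns) and `n_cols`.
#' @examples
#' aln <- aa_alignment(c(seq1 = "MK-A", seq2 = "MKQA"))
#' aln$n_cols
#' @export
aa_alignment <- function(seqs, ambiguous = c("to-x", "error")) {
  ambiguous <- match.arg(ambiguous)
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) stop("sequence matrix must have rownames")
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      bad <- which(lens != lens[1])[1]
      stop(sprintf(
        "not an alignment: record %d ('%s') has length %d, expected %d",
        bad, names(seqs)[bad], lens[bad], lens[1]))
    }
    m <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate sequence names: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (ncol(m) < 1) stop("alignment has zero columns")
  m[] <- toupper(m)
  ok <- m %in% c(AA_ALPHABET, AA_GAP, AA_UNKNOWN)
  if (!all(ok)) {
    bad_letters <- unique(m[!ok])
    if (any(bad_letters == "."))
      stop("gap character '.' is not accepted; use '-'")
    if (ambiguous == "error")
      stop("ambiguous/invalid residues: ",
           paste(bad_letters, collapse = ", "))
    m[!ok] <- AA_UNKNOWN
  }
  structure(list(names = rownames(m), matrix = m, n_cols = ncol(m)),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d sequences x %d columns\n",
              length(x$names), x$n_cols))
  show <- utils::head(x$names, 6)
  for (nm in show) {
    s <- paste(x$matrix[nm, seq_len(min(50, x$n_cols))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", nm, s, if (x$n_cols > 50) "..." else ""))
  }
  if (length(x$names) > 6) cat(sprintf("  ... and %d more\n", length(x$names) - 6))
  invisible(x)
}

#' @export
as.matrix.aa_alignment <- function(x, ...) x$matrix

#' Read an aligned protein FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @inheritParams aa_alignment
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, ambiguous = c("to-x", "error")) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- ape::read.FASTA(path, type = "AA")
  if (length(recs) == 0) stop("no FASTA records in ", path)
  chr <- lapply(as.character(recs), function(v) paste(toupper(v), collapse = ""))
  aa_alignment(unlist(chr), ambiguous = ambiguous)
}

#' Write an alignment as FASTA
#'
#' @param aln An [aa_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  lines <- character(2L * length(aln$names))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$names)
  lines[c(FALSE, TRUE)] <- apply(aln$matrix, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Drop alignment columns with too many gaps
#'
#' A column is removed iff its gap fraction is strictly greater than
#' `max_gap_frac` ("more than 10% gaps" at the default). `X` counts as a
#' residue, not a gap.
#'
#' @param aln An [aa_alignment()].
#' @param max_gap_frac Maximum tolerated gap fraction, in `[0, 1)`.
#' @return A list with `alignment` (kept columns, original order) and
#'   `mask`, a `column_mask`: list with logical `keep` and integer `map`
#'   giving, for each original 1-based column, its 1-based index in the
#'   filtered alignment (`NA` if dropped).
#' @export
filter_gap_columns <- function(aln, max_gap_frac = 0.10) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!(max_gap_frac >= 0 && max_gap_frac < 1))
    stop("max_gap_frac must be in [0, 1)")
  gap_frac <- colMeans(aln$matrix == AA_GAP)
  keep <- gap_frac <= max_gap_frac          # drop iff strictly greater
  if (!any(keep)) stop("empty alignment after filtering")
  map <- rep(NA_integer_, aln$n_cols)
  map[keep] <- seq_len(sum(keep))
  filtered <- aa_alignment(aln$matrix[, keep, drop = FALSE])
  mask <- structure(list(keep = keep, map = map), class = "column_mask")
  list(alignment = filtered, mask = mask)
}

#' @export
print.column_mask <- function(x, ...) {
  cat(sprintf("Column mask: %d of %d columns kept\n",
              sum(x$keep), length(x$keep)))
  invisible(x)
}

#' Export a column mask as TSV
#'
#' Two columns: `original_column`, `filtered_column` (`NA` when dropped),
#' both 1-based.
#' @param mask A `column_mask` from [filter_gap_columns()].
#' @param path Output path.
#' @export
write_column_mask <- function(mask, path) {
  df <- data.frame(original_column = seq_along(mask$keep),
                   filtered_column = mask$map)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map ungapped reference positions to alignment columns
#'
#' Position `p` of the reference sequence maps to the alignment column
#' holding the reference's `p`-th non-gap residue. The default positions
#' elsewhere in the package are the key ligand-binding-pocket sites 232,
#' 270 and 395 in human RARalpha numbering.
#'
#' @param aln An [aa_alignment()].
#' @param reference_name Name of the reference sequence in `aln`.
#' @param positions Integer vector of 1-based ungapped positions.
#' @return A `reference_map`: data frame with columns `position`, `column`
#'   (1-based alignment column) and `residue` (reference residue there),
#'   plus attribute `reference_name`.
#' @export
map_reference_positions <- function(aln, reference_name, positions) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (!reference_name %in% aln$names)
    stop("reference sequence not in alignment: ", reference_name)
  positions <- as.integer(positions)
  if (any(positions < 1)) stop("positions must be >= 1")
  ref <- aln$matrix[reference_name, ]
  nongap_cols <- which(ref != AA_GAP)
  if (any(positions > length(nongap_cols)))
    stop(sprintf("position %d beyond ungapped reference length %d",
                 max(positions), length(nongap_cols)))
  cols <- nongap_cols[positions]
  out <- data.frame(position = positions, column = cols,
                    residue = ref[cols], row.names = NULL)
  attr(out, "reference_name") <- reference_name
  class(out) <- c("reference_map", "data.frame")
  out
}

#' Read a newick tree
#'
#' Thin wrapper around [ape::read.tree()] with optional leaf-name
#' validation against an alignment.
#'
#' @param path Newick file path.
#' @param aln Optional [aa_alignment()]; if given, tree leaves and
#'   alignment names must coincide.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path, aln = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  if (!is.null(aln)) check_tree_alignment(tr, aln)
  tr
}

#' Write a tree as newick
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Check that tree leaves match alignment names
#' @param tree An [ape::phylo] tree.
#' @param aln An [aa_alignment()].
#' @return `TRUE` invisibly, or an error listing the symmetric difference.
#' @export
check_tree_alignment <- function(tree, aln) {
  only_tree <- setdiff(tree$tip.label, aln$names)
  only_aln <- setdiff(aln$names, tree$tip.label)
  if (length(only_tree) || length(only_aln))
    stop("tree/alignment name mismatch; only in tree: {",
         paste(only_tree, collapse = ", "), "}; only in alignment: {",
         paste(only_aln, collapse = ", "), "}")
  invisible(TRUE)
}

# Integer encoding of an alignment against a model alphabet:
# 1..S for known residues, 0 for gap or 'X' (total ambiguity).
encode_alignment <- function(aln, alphabet = AA_ALPHABET) {
  m <- match(aln$matrix, alphabet)
  m[is.na(m)] <- 0L
  matrix(as.integer(m), nrow = nrow(aln$matrix),
         dimnames = list(aln$names, NULL))
}
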