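# Ligand-binding-pocket triplet signatures at the key positions (human
# RARalpha numbering 232/270/395) and substitution/reversion event
# inference along a tree with node states.

# exact subtype-diagnostic patterns (H3-232, H5-270, H11-395)
SIGNATURE_PATTERNS <- list(alpha_like = c("S", "I", "V"),
                           beta_like  = c("A", "I", "V"),
                           gamma_like = c("A", "M", "A"))

#' Classify a pocket triplet into a subtype-like signature
#'
#' Exact, case-insensitive match against the three subtype-diagnostic
#' patterns: alpha-like Ser/Ile/Val, beta-like Ala/Ile/Val, gamma-like
#' Ala/Met/Ala. Any other triplet -- including any `X` -- is `other`
#' (partial matches are never assigned to a nearest class).
#'
#' @param triplet Character vector of three residues, ordered
#'   (232, 270, 395).
#' @return One of `"alpha_like"`, `"beta_like"`, `"gamma_like"`,
#'   `"other"`.
#' @examples
#' classify_signature(c("S", "I", "V"))   # alpha_like
#' classify_signature(c("C", "I", "V"))   # other (e.g. amphioxus RAR)
#' @export
classify_signature <- function(triplet) {
  if (length(triplet) != 3) stop("a pocket triplet has exactly 3 residues")
  t3 <- toupper(as.character(triplet))
  for (cls in names(SIGNATURE_PATTERNS))
    if (identical(t3, SIGNATURE_PATTERNS[[cls]])) return(cls)
  "other"
}

#' Pocket signature table for sequences and/or reconstructed nodes
#'
#' One row per requested owner. Sequence owners are read from the
#' alignment at the reference-mapped key columns; node owners are taken
#' from a [reconstruction_report()] data frame.
#'
#' @param owners Character vector of sequence names and/or node labels.
#' @param aln An [aa_alignment()] (for sequence owners).
#' @param refmap A `reference_map` with the three key positions.
#' @param node_report Optional data frame from [reconstruction_report()].
#' @return A `signature_table` data frame: `owner`, one residue column
#'   per position (`res_<pos>`), `class`.
#' @export
signature_table <- function(owners, aln = NULL, refmap = NULL,
                            node_report = NULL) {
  get_row <- function(ow) {
    if (!is.null(aln) && ow %in% aln$names) {
      res <- aln$matrix[ow, refmap$column]
    } else if (!is.null(node_report) && ow %in% node_report$node) {
      r <- node_report[node_report$node == ow, , drop = FALSE]
      res <- unlist(r[paste0("res_", refmap$position)], use.names = FALSE)
    } else {
      stop("owner not found in alignment or node report: ", ow)
    }
    out <- data.frame(owner = ow)
    for (i in seq_along(res)) out[[paste0("res_", refmap$position[i])]] <- res[i]
    out$class <- classify_signature(res)
    out
  }
  if (is.null(refmap)) stop("a reference map is required")
  df <- do.call(rbind, c(lapply(owners, get_row), list(make.row.names = FALSE)))
  class(df) <- c("signature_table", "data.frame")
  df
}

#' Write / read a signature table as TSV
#' @param x A `signature_table`.
#' @param path File path.
#' @export
write_signature_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_table
#' @export
read_signature_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  class(df) <- c("signature_table", "data.frame")
  df
}

#' Infer pocket substitution and reversion events along a tree
#'
#' Deterministic edge-wise comparison of parent and child states at each
#' key position. An event is recorded for every parent/child difference;
#' it is flagged as a reversion iff the new state equals the state of
#' some strict ancestor older than the most recent change at that
#' position (so multi-step histories such as Ser -> Ala -> Ser are
#' labelled correctly). Positions where either endpoint is `X` are
#' no-calls: no event is recorded and the edge is counted in the
#' `no_calls` attribute rather than guessed.
#'
#' @param tree Rooted [ape::phylo]; internal nodes must be labelled.
#' @param states Data frame with column `label` (every leaf and internal
#'   node label) and one character column per key position, named
#'   `res_<pos>` (as produced by [reconstruction_report()] /
#'   [signature_table()], with `node`/`owner` accepted for `label`).
#' @return An `event_map` data frame, ordered by tree pre-order then
#'   position: `branch` (child node label), `position`, `from`, `to`,
#'   `reversion`; attribute `no_calls` counts suppressed comparisons.
#' @export
infer_events <- function(tree, states) {
  if (!ape::is.rooted(tree)) stop("infer_events needs a rooted tree")
  lab_col <- intersect(c("label", "node", "owner"), colnames(states))[1]
  if (is.na(lab_col)) stop("states needs a 'label' column")
  pos_cols <- grep("^res_", colnames(states), value = TRUE)
  if (!length(pos_cols)) stop("states needs res_<position> columns")
  positions <- as.integer(sub("^res_", "", pos_cols))
  labels_all <- all_node_labels(tree)
  missing <- setdiff(labels_all, states[[lab_col]])
  if (length(missing))
    stop("missing node state(s) for: ", paste(missing, collapse = ", "))
  st <- as.matrix(states[match(labels_all, states[[lab_col]]), pos_cols,
                         drop = FALSE])
  st[] <- toupper(st)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parent-before-child order
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  # per-node, per-position state history from the root (collapsed runs)
  hist <- vector("list", ntip + tr$Nnode)
  hist[[root]] <- lapply(seq_along(positions), function(p) st[root, p])
  events <- list()
  no_calls <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    h <- hist[[pa]]
    for (p in seq_along(positions)) {
      s_pa <- st[pa, p]
      s_ch <- st[ch, p]
      if (s_pa == "X" || s_ch == "X") {
        if (s_pa != s_ch) no_calls <- no_calls + 1L
        if (s_ch != h[[p]][length(h[[p]])]) h[[p]] <- c(h[[p]], s_ch)
      } else if (s_ch != s_pa) {
        older <- h[[p]][-length(h[[p]])]          # states before last change
        events[[length(events) + 1L]] <- data.frame(
          branch = labels_all[ch], position = positions[p],
          from = s_pa, to = s_ch,
          reversion = s_ch %in% older)
        h[[p]] <- c(h[[p]], s_ch)
      }
      # unchanged: history (collapsed runs) stays as-is
    }
    hist[[ch]] <- h
  }
  out <- if (length(events)) {
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  } else {
    data.frame(branch = character(), position = integer(),
               from = character(), to = character(), reversion = logical())
  }
  class(out) <- c("event_map", "data.frame")
  attr(out, "no_calls") <- no_calls
  out
}

#' @export
print.event_map <- function(x, ...) {
  cat(sprintf("Pocket event map: %d event(s), %d no-call comparison(s)\n",
              nrow(x), attr(x, "no_calls")))
  if (nrow(x)) {
    for (i in seq_len(nrow(x)))
      cat(sprintf("  %-12s pos %-4d %s -> %s%s\n", x$branch[i],
                  x$position[i], x$from[i], x$to[i],
                  if (x$reversion[i]) "  (reversion)" else ""))
  }
  invisible(x)
}
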