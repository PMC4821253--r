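# Marginal empirical-Bayes ancestral sequence reconstruction on a fixed
# rooted tree: per-node, per-column posterior residue distributions and
# MAP ("best predicted") sequences.

#' Define named internal nodes as most-recent common ancestors
#'
#' @param ... Named character vectors of leaf names; each name becomes a
#'   node label and resolves to the MRCA of its leaf set (a single leaf
#'   resolves to that tip).
#' @return A `node_spec` (named list).
#' @examples
#' node_spec(node1 = c("tipA", "tipD"), node2 = c("tipB", "tipC"))
#' @export
node_spec <- function(...) {
  spec <- list(...)
  if (length(spec) == 1 && is.list(spec[[1]]) && is.null(names(spec)[1]))
    spec <- spec[[1]]
  if (is.null(names(spec)) || any(!nzchar(names(spec))))
    stop("every node must be named")
  structure(spec, class = "node_spec")
}

resolve_nodes <- function(tree, spec) {
  ntip <- length(tree$tip.label)
  vapply(names(spec), function(nm) {
    leaves <- spec[[nm]]
    miss <- setdiff(leaves, tree$tip.label)
    if (length(miss))
      stop("node '", nm, "': leaves not in tree: ",
           paste(miss, collapse = ", "))
    if (length(leaves) == 1) return(match(leaves, tree$tip.label))
    ape::getMRCA(tree, leaves)
  }, integer(1))
}

# node labels for every vertex: tips keep their names, internal nodes use
# tree$node.label when present, otherwise "node<i>" by ape numbering
all_node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab) || any(!nzchar(lab)))
    lab <- paste0("node", seq_len(tree$Nnode))
  c(tree$tip.label, lab)
}

#' Marginal ancestral sequence reconstruction
#'
#' Empirical-Bayes marginal reconstruction: for each requested node and
#' alignment column, the posterior over residues is proportional to the
#' product of the below-partial (Felsenstein down pass) and the
#' rest-of-tree partial (up pass), mixed over discrete-gamma categories
#' with site-specific category weights (the posterior of each category
#' given the column). The MAP sequence takes the per-column argmax with
#' a deterministic alphabetical tie-break; ties are flagged.
#'
#' @param tree Rooted [ape::phylo] with branch lengths (optimized or
#'   user-supplied).
#' @param aln An [aa_alignment()] (gap-filtered upstream as appropriate).
#' @param model A [rate_model()].
#' @param gamma A [discrete_gamma()].
#' @param nodes A [node_spec()], or `NULL` to reconstruct every internal
#'   node (labels from `tree$node.label`, else `node<i>`).
#' @param loglik_floor See [site_logliks()].
#' @return An `asr_result`: list of `node_reconstruction`s (each with
#'   `node_label`, `posteriors` columns x alphabet, `map_sequence`,
#'   `tie_flags`), plus the tree and per-site log-likelihoods.
#' @export
marginal_asr <- function(tree, aln, model, gamma = discrete_gamma(1, 1),
                         nodes = NULL, loglik_floor = -745) {
  if (!ape::is.rooted(tree)) stop("marginal_asr needs a rooted tree")
  pw <- make_pruning_data(tree, aln, model)
  k <- gamma$k
  S <- model$S
  dp <- down_pass(pw, model, gamma, pw$tree$edge.length)
  pls <- pattern_logliks(pw, model, gamma, dp)
  # site-specific category posteriors
  catw <- exp(pls$percat - pls$mixed) / k         # npat x k
  catw[!is.finite(catw)] <- 1 / k                 # floored sites: flat
  catw <- catw / rowSums(catw)

  # up pass: rest-of-tree partial at every node (freq folded in at root)
  kids <- split(seq_len(pw$n_edge),
                factor(pw$edge[, 1], levels = seq_len(pw$nnode)))
  freq_mat <- matrix(model$freq, pw$npat, S, byrow = TRUE)
  up <- vector("list", pw$nnode)
  up[[pw$root]] <- rep(list(freq_mat), k)
  for (e in rev(seq_len(pw$n_edge))) {          # preorder
    pa <- pw$edge[e, 1]
    ch <- pw$edge[e, 2]
    sib <- setdiff(kids[[pa]], e)
    up[[ch]] <- vector("list", k)
    for (j in seq_len(k)) {
      a <- up[[pa]][[j]]
      for (s in sib) a <- a * dp$M[[s]][[j]]
      u <- a %*% dp$Pk[[e]][[j]]
      s0 <- rowSums(u)
      s0[s0 <= 0] <- 1
      up[[ch]][[j]] <- u / s0                   # posteriors renormalize
    }
  }

  labels_all <- all_node_labels(pw$tree)
  node_idx <- if (is.null(nodes)) {
    setNames(seq.int(pw$ntip + 1L, pw$nnode), labels_all[-seq_len(pw$ntip)])
  } else {
    resolve_nodes(pw$tree, nodes)
  }
  alpha_order <- order(model$alphabet)
  recs <- lapply(names(node_idx), function(nm) {
    v <- node_idx[[nm]]
    post <- matrix(0, pw$npat, S)
    for (j in seq_len(k)) {
      pj <- up[[v]][[j]] * dp$D[[v]][[j]]
      rs <- rowSums(pj)
      rs[rs <= 0] <- 1
      post <- post + catw[, j] * (pj / rs)
    }
    post <- post / rowSums(post)
    # MAP with alphabetical tie-break
    map_idx <- integer(pw$npat)
    tie <- logical(pw$npat)
    mx <- as.vector(do.call(pmax, lapply(seq_len(S), function(j) post[, j])))
    for (i in seq_len(pw$npat)) {
      cand <- which(post[i, ] >= mx[i] - 1e-12)
      tie[i] <- length(cand) > 1L
      map_idx[i] <- alpha_order[alpha_order %in% cand][1]
    }
    idx <- pw$pat_index
    posteriors <- post[idx, , drop = FALSE]
    colnames(posteriors) <- model$alphabet
    structure(list(node_label = nm,
                   posteriors = posteriors,
                   map_sequence = paste(model$alphabet[map_idx[idx]],
                                        collapse = ""),
                   tie_flags = tie[idx]),
              class = "node_reconstruction")
  })
  names(recs) <- names(node_idx)
  structure(list(reconstructions = recs, tree = pw$tree,
                 site_logliks = {
                   ll <- pls$mixed
                   ll[!is.finite(ll)] <- loglik_floor
                   ll[pw$pat_index]
                 },
                 gamma = gamma),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("Marginal ASR: %d reconstructed node(s), %d columns\n",
              length(x$reconstructions),
              nrow(x$reconstructions[[1]]$posteriors)))
  for (r in x$reconstructions) {
    mean_max <- mean(apply(r$posteriors, 1, max))
    cat(sprintf("  %-10s mean MAP posterior %.3f, %d tied column(s)\n",
                r$node_label, mean_max, sum(r$tie_flags)))
  }
  invisible(x)
}

#' @export
print.node_reconstruction <- function(x, ...) {
  cat(sprintf("Reconstruction at %s (%d columns, %d ties)\n",
              x$node_label, nrow(x$posteriors), sum(x$tie_flags)))
  s <- substr(x$map_sequence, 1, 60)
  cat("  MAP: ", s, if (nchar(x$map_sequence) > 60) "..." else "", "\n",
      sep = "")
  invisible(x)
}

#' Key-position report across reconstructed nodes
#'
#' Restricts reconstructions to the reference-mapped key columns (by
#' default the ligand-binding-pocket positions 232/270/395 in human
#' RARalpha numbering) and reports the MAP residue and its posterior
#' probability per node and position.
#'
#' @param asr An `asr_result` from [marginal_asr()].
#' @param refmap A `reference_map` from [map_reference_positions()],
#'   expressed in the coordinates of the alignment used for the
#'   reconstruction. If the reconstruction used a gap-filtered alignment,
#'   pass `mask` to translate original columns.
#' @param mask Optional `column_mask` from [filter_gap_columns()].
#' @return Data frame with one row per node: `node`, then per position
#'   `res_<pos>` and `prob_<pos>`.
#' @export
reconstruction_report <- function(asr, refmap, mask = NULL) {
  stopifnot(inherits(asr, "asr_result"), inherits(refmap, "reference_map"))
  cols <- refmap$column
  if (!is.null(mask)) {
    newcols <- mask$map[cols]
    if (anyNA(newcols))
      stop("key position(s) ",
           paste(refmap$position[is.na(newcols)], collapse = ", "),
           " fall in gap-filtered columns; review the gap threshold")
    cols <- newcols
  }
  n_col <- nrow(asr$reconstructions[[1]]$posteriors)
  if (any(cols > n_col)) stop("reference-mapped column beyond alignment")
  rows <- lapply(asr$reconstructions, function(r) {
    res <- substring(r$map_sequence, cols, cols)
    prob <- r$posteriors[cbind(cols, match(res, colnames(r$posteriors)))]
    out <- data.frame(node = r$node_label)
    for (i in seq_along(cols)) {
      out[[paste0("res_", refmap$position[i])]] <- res[i]
      out[[paste0("prob_", refmap$position[i])]] <- prob[i]
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Export per-position posterior probabilities (logo table)
#'
#' Writes the posterior residue probabilities of one reconstruction as a
#' TSV: rows are alignment columns, columns the residue alphabet (the
#' numeric table behind a sequence-logo rendering).
#'
#' @param rec A `node_reconstruction`.
#' @param path Output path.
#' @export
export_logo_table <- function(rec, path) {
  stopifnot(inherits(rec, "node_reconstruction"))
  df <- data.frame(position = seq_len(nrow(rec$posteriors)),
                   rec$posteriors, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_logo_table
#' @export
read_logo_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(df[, -1, drop = FALSE])
}
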