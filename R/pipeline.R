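# End-to-end drivers wiring the stages into the two standard analyses:
# (i) the per-cyclostome-gene orthology screen and (ii) ancestral
# reconstruction with pocket signature and event inference.

manifest_of <- function(call_params) {
  list(package = "rarphylo",
       version = as.character(packageVersion("rarphylo")),
       parameters = call_params)
}

#' Orthology screen over several cyclostome genes
#'
#' Runs [run_orthology_assessment()] once per cyclostome gene against
#' fixed gnathostome subtype groups and outgroup, mirroring the
#' one-gene-at-a-time five-OTU design.
#'
#' @param aln An [aa_alignment()].
#' @param cyclostome_genes Character vector of cyclostome sequence names
#'   (one assessment each).
#' @param alpha_group,beta_group,gamma_group,outgroup Character vectors
#'   of sequence names shared by all assessments.
#' @param fixed_subtrees Optional per-OTU rooted newick subtrees (see
#'   [otu_scheme()]); computed once by neighbour joining when absent and
#'   needed.
#' @param seed Integer; assessment `i` uses `seed + i - 1`.
#' @inheritParams run_orthology_assessment
#' @return An `orthology_screen`: named list of `orthology_report`s plus
#'   a `manifest` attribute (parameters and package version).
#' @export
run_orthology_screen <- function(aln, cyclostome_genes, alpha_group,
                                 beta_group, gamma_group, outgroup,
                                 fixed_subtrees = list(),
                                 model = lg_model(), B = 10000L,
                                 seed = 1L, assume_fourth_paralogue = FALSE,
                                 gamma_policy = "shared-estimate", k = 4L,
                                 tol = 1e-4, max_gap_frac = 0.10) {
  all_needed <- c(cyclostome_genes, alpha_group, beta_group, gamma_group,
                  outgroup)
  miss <- setdiff(all_needed, aln$names)
  if (length(miss))
    stop("sequences missing from alignment: ", paste(miss, collapse = ", "))
  reports <- vector("list", length(cyclostome_genes))
  names(reports) <- cyclostome_genes
  for (i in seq_along(cyclostome_genes)) {
    otus <- otu_scheme(cyclostome = cyclostome_genes[i],
                       alpha_group = alpha_group, beta_group = beta_group,
                       gamma_group = gamma_group, outgroup = outgroup,
                       fixed_subtrees = fixed_subtrees)
    if (any(lengths(otus$members) > 1) &&
        length(otus$fixed_subtrees) < 4)
      otus <- nj_subtrees(otus, aln)
    reports[[i]] <- run_orthology_assessment(
      aln, otus, model = model, B = B, seed = seed + i - 1L,
      assume_fourth_paralogue = assume_fourth_paralogue,
      gamma_policy = gamma_policy, k = k, tol = tol,
      max_gap_frac = max_gap_frac)
  }
  structure(reports, class = "orthology_screen",
            manifest = manifest_of(list(
              cyclostome_genes = cyclostome_genes, B = B, seed = seed,
              assume_fourth_paralogue = assume_fourth_paralogue,
              gamma_policy = gamma_policy, k = k,
              max_gap_frac = max_gap_frac)))
}

#' @export
print.orthology_screen <- function(x, ...) {
  cat("Orthology screen:\n")
  for (r in x) {
    best <- names(which.max(r$prob))
    cat(sprintf("  %-12s -> %s (P = %.3f)\n", r$cyclostome_gene_name,
                best, max(r$prob)))
  }
  invisible(x)
}

#' Ancestral pocket reconstruction, signatures and events
#'
#' Full chain on a fixed rooted tree: gap-column filter, key-position
#' mapping, optional branch-length/gamma-shape optimization, marginal
#' ancestral reconstruction at every internal node, key-position report
#' for the named nodes, pocket-signature classification of leaves and
#' named nodes, and substitution/reversion event inference over the
#' whole tree (reconstruction ties propagate as `X` and yield no-calls
#' rather than guessed events).
#'
#' @param aln An [aa_alignment()].
#' @param tree Rooted [ape::phylo]; leaf names must match the alignment.
#'   Branch lengths are used as given unless `optimize = TRUE`.
#' @param nodes A [node_spec()] naming the ancestors of interest.
#' @param reference_name Reference sequence for key-position mapping.
#' @param positions Key positions in reference numbering (default the
#'   RARalpha pocket sites 232, 270, 395).
#' @param model A [rate_model()].
#' @param k Discrete-gamma categories.
#' @param alpha Gamma shape; `"estimate"` (default) estimates it (and
#'   branch lengths) on the fixed topology, a number fixes it.
#' @param optimize Optimize branch lengths (forced when
#'   `alpha = "estimate"`).
#' @param max_gap_frac Gap-column filter threshold.
#' @return A `pocket_ancestry`: list with `asr`, `report` (key-position
#'   table), `signatures` (leaves + named nodes), `events`, `refmap`,
#'   `mask`, `tree` (as used) and `manifest`.
#' @export
run_pocket_ancestry <- function(aln, tree, nodes, reference_name,
                                positions = c(232L, 270L, 395L),
                                model = lg_model(), k = 4L,
                                alpha = "estimate", optimize = TRUE,
                                max_gap_frac = 0.10) {
  stopifnot(inherits(aln, "aa_alignment"))
  check_tree_alignment(tree, aln)
  if (!ape::is.rooted(tree)) stop("a rooted tree is required")
  refmap <- map_reference_positions(aln, reference_name, positions)
  flt <- filter_gap_columns(aln, max_gap_frac)
  newcols <- flt$mask$map[refmap$column]
  if (anyNA(newcols))
    stop("key position(s) ",
         paste(refmap$position[is.na(newcols)], collapse = ", "),
         " fall in columns dropped by the gap filter; review the threshold")
  faln <- flt$alignment
  frefmap <- refmap
  frefmap$column <- newcols
  if (identical(alpha, "estimate")) {
    est <- estimate_alpha(tree, faln, model, k = k)
    gamma <- est$gamma
    tree <- est$tree
  } else {
    gamma <- discrete_gamma(alpha, k)
    if (optimize)
      tree <- optimize_branch_lengths(tree, faln, model, gamma)$tree
  }
  asr <- marginal_asr(tree, faln, model, gamma, nodes = NULL)
  full_report <- reconstruction_report(asr, frefmap)
  named_idx <- resolve_nodes(asr$tree, nodes)
  labels_all <- all_node_labels(asr$tree)
  named_report <- full_report[match(labels_all[named_idx],
                                    full_report$node), , drop = FALSE]
  named_report$node <- names(named_idx)
  rownames(named_report) <- NULL
  signatures <- signature_table(c(aln$names, names(named_idx)),
                                aln = faln, refmap = frefmap,
                                node_report = named_report)
  # states for event inference: observed leaves + reconstructed internals,
  # with tied reconstructions masked to 'X'
  res_cols <- paste0("res_", frefmap$position)
  leaf_states <- data.frame(label = faln$names)
  for (i in seq_along(frefmap$column))
    leaf_states[[res_cols[i]]] <- faln$matrix[, frefmap$column[i]]
  node_states <- data.frame(label = full_report$node)
  for (i in seq_along(res_cols)) {
    v <- full_report[[res_cols[i]]]
    tied <- vapply(asr$reconstructions[full_report$node], function(r)
      r$tie_flags[frefmap$column[i]], logical(1))
    v[tied] <- "X"
    node_states[[res_cols[i]]] <- v
  }
  events <- infer_events(asr$tree, rbind(leaf_states, node_states))
  structure(list(asr = asr, report = named_report, signatures = signatures,
                 events = events, refmap = refmap, mask = flt$mask,
                 tree = asr$tree,
                 manifest = manifest_of(list(
                   reference_name = reference_name, positions = positions,
                   k = k, alpha = alpha, optimize = optimize,
                   max_gap_frac = max_gap_frac,
                   gamma_alpha = gamma$alpha))),
            class = "pocket_ancestry")
}

#' @export
print.pocket_ancestry <- function(x, ...) {
  cat("Ancestral pocket reconstruction\n")
  print(x$report)
  cat("\nInferred events:\n")
  print(x$events)
  invisible(x)
}
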