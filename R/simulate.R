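# Synthetic 2R gene-family scenarios with full ground truth: duplication
# histories, sequences evolved under the substitution model, and
# deterministic pocket-column event scenarios.

#' Specify a synthetic 2R gene-family scenario
#'
#' A 1-2-4 duplication history: one ancestral gene duplicates twice,
#' giving four paralogue slots (alpha, beta, gamma, delta) arranged as a
#' balanced `((.,.),(.,.))` tree according to `pairing`; paralogues may
#' then be lost per lineage; a single cyclostome gene is grafted as
#' sister to the subtype it is orthologous to (taking the empty slot if
#' that paralogue was lost).
#'
#' @param pairing List of two character pairs partitioning
#'   `c("alpha","beta","gamma","delta")`: the sister pairs created by the
#'   second duplication round. Default pairs alpha with delta and beta
#'   with gamma, the arrangement of the vertebrate RAR family.
#' @param cyclostome_orthology Subtype the cyclostome gene is truly
#'   orthologous to.
#' @param losses Character vector of paralogues lost (from the
#'   gnathostome side); default the fourth paralogue, `"delta"`.
#' @param species_per_subtype Gnathostome species per retained subtype.
#' @param branch_length_scale Length assigned to every branch (expected
#'   substitutions per site).
#' @param alpha Gamma shape used for simulation.
#' @param n_columns Alignment length.
#' @param pocket_positions Integer labels of the three designated pocket
#'   columns; `pocket_columns` gives their alignment columns (defaults to
#'   the positions themselves when they fit, else three interior
#'   columns).
#' @param pocket_columns See `pocket_positions`.
#' @param pocket_events Data frame (`branch`, `position`, `from`, `to`)
#'   of deterministic pocket mutations; may be empty.
#' @param root_triplet Pocket states at the root, ordered by position.
#' @param seed Integer seed.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(pairing = list(c("alpha", "delta"),
                                         c("beta", "gamma")),
                          cyclostome_orthology = "gamma",
                          losses = "delta",
                          species_per_subtype = 1L,
                          branch_length_scale = 0.1,
                          alpha = 1,
                          n_columns = 2000L,
                          pocket_positions = c(232L, 270L, 395L),
                          pocket_columns = NULL,
                          pocket_events = NULL,
                          root_triplet = c("S", "I", "V"),
                          seed = 1L) {
  subtypes <- c("alpha", "beta", "gamma", "delta")
  if (!setequal(unlist(pairing), subtypes) || length(pairing) != 2 ||
      any(lengths(pairing) != 2))
    stop("pairing must split alpha/beta/gamma/delta into two pairs")
  if (!cyclostome_orthology %in% subtypes)
    stop("unknown cyclostome_orthology")
  if (!all(losses %in% subtypes)) stop("unknown paralogue in losses")
  needed <- c("alpha", "beta", "gamma")
  if (any(needed %in% losses))
    stop("losses would remove a gnathostome subtype required by the ",
         "five-OTU scheme: ", paste(intersect(needed, losses), collapse = ", "))
  if (is.null(pocket_columns)) {
    pocket_columns <- if (max(pocket_positions) <= n_columns) pocket_positions
    else round(n_columns * c(0.25, 0.5, 0.75))
  }
  if (length(pocket_columns) != 3 || any(pocket_columns > n_columns))
    stop("need 3 pocket columns within the alignment")
  structure(list(pairing = pairing,
                 cyclostome_orthology = cyclostome_orthology,
                 losses = losses,
                 species_per_subtype = as.integer(species_per_subtype),
                 branch_length_scale = branch_length_scale,
                 alpha = alpha, n_columns = as.integer(n_columns),
                 pocket_positions = as.integer(pocket_positions),
                 pocket_columns = as.integer(pocket_columns),
                 pocket_events = pocket_events,
                 root_triplet = toupper(root_triplet),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# ladder newick over leaves, optionally labelling internal nodes
.clade_newick <- function(leaves, label = "") {
  if (length(leaves) == 1) return(leaves)
  s <- leaves[length(leaves)]
  for (i in rev(seq_len(length(leaves) - 1)))
    s <- paste0("(", leaves[i], ",", s, ")",
                if (i == 1) label else "")
  s
}

#' Build the labelled scenario tree
#'
#' Realizes the 2R history of a [scenario_spec()] as a rooted,
#' node-labelled tree with all branch lengths equal to
#' `branch_length_scale`. Internal labels: `root`, `wgd1` (the
#' pre-duplication vertebrate ancestor), `pair_<x>_<y>` (post round 1),
#' `base_<subtype>` (subtype crown groups), `cherry_C` (the
#' cyclostome/orthologue cherry).
#'
#' @param spec A [scenario_spec()].
#' @return A rooted [ape::phylo] with `node.label` set.
#' @export
build_scenario_tree <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$species_per_subtype
  clade <- function(s) {
    if (s %in% spec$losses) return(NULL)
    leaves <- if (m == 1) paste0(s, "_1") else paste0(s, "_", seq_len(m))
    .clade_newick(leaves, paste0("base_", s))
  }
  parts <- lapply(setNames(nm = c("alpha", "beta", "gamma", "delta")), clade)
  co <- spec$cyclostome_orthology
  if (is.null(parts[[co]])) {
    parts[[co]] <- "cyclo"                     # lost slot: C takes it over
  } else {
    parts[[co]] <- paste0("(cyclo,", parts[[co]], ")cherry_C")
  }
  pair_nwk <- function(pr) {
    a <- parts[[pr[1]]]; b <- parts[[pr[2]]]
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    paste0("(", a, ",", b, ")pair_", pr[1], "_", pr[2])
  }
  p1 <- pair_nwk(spec$pairing[[1]])
  p2 <- pair_nwk(spec$pairing[[2]])
  ingroup <- if (is.null(p1)) p2 else if (is.null(p2)) p1
  else paste0("(", p1, ",", p2, ")wgd1")
  nwk <- paste0("(out_1,", ingroup, ")root;")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(spec$branch_length_scale, nrow(tr$edge))
  tr
}

#' Simulate sequences along a tree
#'
#' The root sequence is drawn from the model's stationary frequencies;
#' states then evolve edge-wise through [transition_matrix()], with one
#' discrete-gamma rate category sampled per column and shared by the
#' whole column. Fully reproducible from `seed`.
#'
#' @param tree Rooted [ape::phylo] with branch lengths; internal labels
#'   are used for the truth records (defaults assigned if absent).
#' @param model A [rate_model()].
#' @param gamma A [discrete_gamma()].
#' @param n_columns Number of columns to simulate.
#' @param seed Integer seed.
#' @return List with `alignment` (an [aa_alignment()] over the leaves),
#'   `node_sequences` (character matrix, internal nodes x columns,
#'   rownames = node labels; first row is the root), and `categories`
#'   (per-column sampled category index).
#' @export
simulate_alignment <- function(tree, model, gamma = discrete_gamma(1, 1),
                               n_columns = 1000L, seed = 1L) {
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  labels_all <- all_node_labels(tr)
  S <- model$S
  states <- matrix(0L, nnode, n_columns)
  with_seed(seed, {
    cats <- sample.int(gamma$k, n_columns, replace = TRUE,
                       prob = gamma$weights)
    root <- ntip + 1L
    states[root, ] <- sample.int(S, n_columns, replace = TRUE,
                                 prob = model$freq)
    for (e in seq_len(nrow(tr$edge))) {
      pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      for (j in seq_len(gamma$k)) {
        sel <- which(cats == j)
        if (!length(sel)) next
        P <- transition_matrix(model, tr$edge.length[e], gamma$rates[j])
        ps <- states[pa, sel]
        out <- integer(length(sel))
        for (s in unique(ps)) {
          idx <- ps == s
          out[idx] <- sample.int(S, sum(idx), replace = TRUE, prob = P[s, ])
        }
        states[ch, sel] <- out
      }
    }
  })
  letters_of <- function(i) model$alphabet[states[i, ]]
  leaf_mat <- t(vapply(seq_len(ntip), letters_of, character(n_columns)))
  rownames(leaf_mat) <- tr$tip.label
  node_mat <- t(vapply(seq.int(ntip + 1L, nnode), letters_of,
                       character(n_columns)))
  rownames(node_mat) <- labels_all[seq.int(ntip + 1L, nnode)]
  list(alignment = aa_alignment(leaf_mat), node_sequences = node_mat,
       categories = cats)
}

#' Overwrite pocket columns with a deterministic event scenario
#'
#' The three designated pocket columns are rewritten so that every
#' node's state equals the root state modified by the events on its
#' ancestral path; the surrounding columns keep their stochastic
#' evolution. This makes signature and event inference exactly
#' scenario-determined while the rest of the alignment exercises the
#' probabilistic machinery.
#'
#' @param sim Output of [simulate_alignment()].
#' @param tree The tree used for the simulation.
#' @param spec A [scenario_spec()] (supplies positions, columns, root
#'   triplet and events), or `NULL` to pass them directly.
#' @param events,pocket_columns,pocket_positions,root_triplet Overrides
#'   of the corresponding `spec` fields.
#' @return `sim` with pocket columns rewritten, plus `triplets`: data
#'   frame (`label`, `res_<pos>` per position) holding the true states
#'   of every leaf and internal node.
#' @export
plant_pocket_events <- function(sim, tree, spec = NULL, events = NULL,
                                pocket_columns = NULL,
                                pocket_positions = NULL,
                                root_triplet = NULL) {
  if (!is.null(spec)) {
    if (is.null(events)) events <- spec$pocket_events
    if (is.null(pocket_columns)) pocket_columns <- spec$pocket_columns
    if (is.null(pocket_positions)) pocket_positions <- spec$pocket_positions
    if (is.null(root_triplet)) root_triplet <- spec$root_triplet
  }
  if (is.null(events))
    events <- data.frame(branch = character(), position = integer(),
                         from = character(), to = character())
  tr <- ape::reorder.phylo(tree, "cladewise")
  labels_all <- all_node_labels(tr)
  ntip <- length(tr$tip.label)
  if (nrow(events)) {
    bad <- setdiff(events$branch, labels_all)
    if (length(bad)) stop("event branch(es) not in tree: ",
                          paste(bad, collapse = ", "))
    if (anyDuplicated(events[c("branch", "position")]))
      stop("conflicting duplicate events on one branch/position")
    if (!all(events$position %in% pocket_positions))
      stop("event positions must be among the designated pocket positions")
  }
  npos <- length(pocket_positions)
  st <- matrix(NA_character_, length(labels_all), npos,
               dimnames = list(labels_all, NULL))
  root <- ntip + 1L
  st[root, ] <- root_triplet
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    s <- st[pa, ]
    if (nrow(events)) {
      hit <- events[events$branch == labels_all[ch], , drop = FALSE]
      for (i in seq_len(nrow(hit))) {
        p <- match(hit$position[i], pocket_positions)
        if (!identical(toupper(hit$from[i]), s[p]))
          stop(sprintf("event on '%s' pos %d: 'from' state %s but lineage is %s",
                       hit$branch[i], hit$position[i], hit$from[i], s[p]))
        s[p] <- toupper(hit$to[i])
      }
    }
    st[ch, ] <- s
  }
  # rewrite pocket columns everywhere
  aln_mat <- sim$alignment$matrix
  for (p in seq_len(npos)) {
    aln_mat[, pocket_columns[p]] <- st[rownames(aln_mat), p]
    sim$node_sequences[, pocket_columns[p]] <-
      st[rownames(sim$node_sequences), p]
  }
  sim$alignment <- aa_alignment(aln_mat)
  trip <- data.frame(label = labels_all)
  for (i in seq_len(npos))
    trip[[paste0("res_", pocket_positions[i])]] <- unname(st[, i])
  sim$triplets <- trip
  sim
}

#' Simulate a full scenario with ground truth
#'
#' Chains [build_scenario_tree()], [simulate_alignment()] and
#' [plant_pocket_events()] into a truth bundle.
#'
#' @param spec A [scenario_spec()].
#' @param model A [rate_model()]; default LG.
#' @param k Number of discrete-gamma categories used for simulation.
#' @return A `truth_bundle`: list with `spec`, `tree`, `alignment`,
#'   `node_sequences`, `triplets`, `true_orthology`, `pocket`
#'   (positions/columns) and `otus` (the matching five-OTU scheme).
#' @export
simulate_scenario <- function(spec, model = lg_model(), k = 4L) {
  stopifnot(inherits(spec, "scenario_spec"))
  tree <- build_scenario_tree(spec)
  gamma <- discrete_gamma(spec$alpha, k)
  sim <- simulate_alignment(tree, model, gamma, spec$n_columns, spec$seed)
  sim <- plant_pocket_events(sim, tree, spec = spec)
  m <- spec$species_per_subtype
  members <- function(s) paste0(s, "_", seq_len(m))
  otus <- otu_scheme(cyclostome = "cyclo",
                     alpha_group = members("alpha"),
                     beta_group = members("beta"),
                     gamma_group = members("gamma"),
                     outgroup = "out_1")
  if (m > 1) otus <- nj_subtrees(otus, sim$alignment)
  structure(list(spec = spec, tree = tree, alignment = sim$alignment,
                 node_sequences = sim$node_sequences,
                 triplets = sim$triplets,
                 categories = sim$categories,
                 true_orthology = spec$cyclostome_orthology,
                 pocket = list(positions = spec$pocket_positions,
                               columns = spec$pocket_columns),
                 otus = otus),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic 2R bundle: %d leaves, %d columns, true orthology '%s'\n",
    length(x$alignment$names), x$alignment$n_cols, x$true_orthology))
  invisible(x)
}

#' The shipped mutation/reversion demonstration scenario
#'
#' A 19-leaf vertebrate RAR-like fixture mirroring the family's inferred
#' pocket history: cyclostome RAR3/RAR2/RAR1 clades (hagfish `Eb_` +
#' lamprey `Lj_`) associated with the gnathostome alpha/beta/gamma
#' groups, chondrichthyan/actinopterygian/sarcopterygian species per
#' subtype, amphioxus as outgroup. The planted events are: Ser->Ala at
#' 232 on the stem of the RAR2-beta/RAR1-gamma ancestor (`node3`); its
#' reversion Ala->Ser on the cyclostome RAR1 stem; Ile->Met at 270 and
#' Val->Ala at 395 on the gnathostome RARgamma stem (`node5`); and
#' Ala->Ser reversions at 232 on the actinopterygian RARgamma stem
#' (`node6`) and the frog RARgamma branch. The named ancestors `node1`
#' .. `node7` (vertebrate ancestor; bases of alpha, beta+gamma, beta,
#' gamma, actinopterygian gamma, sarcopterygian gamma) are available as
#' a [node_spec()] in the result.
#'
#' Branch lengths follow the family's documented rate profile rather
#' than a uniform value: cyclostome sequences are unusually divergent
#' (long cyclostome stems and tips), the deep post-duplication stems are
#' long, and the chondrichthyan and amniote RARgamma branches are short
#' (strongly conserved). This makes the planted event history the
#' maximum-likelihood history on the fixture, so ancestral
#' reconstruction and event inference close exactly on the generative
#' truth; under uniform branch lengths the three planted reversions
#' would be less parsimonious than independent forward changes and no
#' reconstruction method could be expected to recover them.
#'
#' @param n_columns Alignment length (>= 396 so that the key columns sit
#'   at the reference positions 232/270/395 of the gap-free reference
#'   `Hs_RARa`).
#' @param seed Integer seed for the stochastic background columns.
#' @param branch_length_scale Multiplier applied to the whole length
#'   profile (1 keeps the defaults described above).
#' @param model,k See [simulate_scenario()].
#' @param alpha Gamma shape for the background columns.
#' @return A `truth_bundle` with additional elements `nodes` (the
#'   [node_spec()] for node1..node7), `events` (the planted event table)
#'   and `reference` (name + positions).
#' @export
rar_pocket_scenario <- function(n_columns = 450L, seed = 101L,
                          branch_length_scale = 1, model = lg_model(),
                          alpha = 1, k = 4L) {
  if (n_columns < 396) stop("n_columns must be >= 396")
  nwk <- paste0(
    "(Amphioxus_RAR,",
    "(((Eb_RAR3,Lj_RAR3)cyclo3,(Sc_RARa,(Dr_RARa,Hs_RARa)sarco_a)node2)a3,",
    "(((Eb_RAR2,Lj_RAR2)cyclo2,(Sc_RARb,(Dr_RARb,Hs_RARb)sarco_b)node4)b2,",
    "((Eb_RAR1,Lj_RAR1)cyclo1,",
    "(Sc_RARg,((Lo_RARg,Dr_RARg)node6,",
    "(Xt_RARg,(Gg_RARg,Hs_RARg)amniote_g)node7)crown_g)node5)g1",
    ")node3)node1)root;")
  tree <- ape::read.tree(text = nwk)
  child <- all_node_labels(tree)[tree$edge[, 2]]
  len <- rep(0.1, nrow(tree$edge))
  len[child %in% c("cyclo1", "cyclo2", "cyclo3")] <- 0.35  # divergent
  len[grepl("^(Eb|Lj)_", child)] <- 0.3                    # cyclostomes
  len[child == "Amphioxus_RAR"] <- 0.3                     # deep outgroup
  len[child == "node3"] <- 0.25                            # long 2R stems
  len[child == "b2"] <- 0.05
  len[child == "node5"] <- 0.08
  len[child %in% c("Sc_RARg", "Gg_RARg", "Hs_RARg")] <- 0.05  # conserved
  len[child == "amniote_g"] <- 0.04
  len[child == "node6"] <- 0.25
  len[child == "Xt_RARg"] <- 0.3
  tree$edge.length <- len * branch_length_scale
  events <- data.frame(
    branch = c("node3", "cyclo1", "node5", "node5", "node6", "Xt_RARg"),
    position = c(232L, 232L, 270L, 395L, 232L, 232L),
    from = c("S", "A", "I", "V", "A", "A"),
    to = c("A", "S", "M", "A", "S", "S"))
  gamma <- discrete_gamma(alpha, k)
  sim <- simulate_alignment(tree, model, gamma, n_columns, seed)
  sim <- plant_pocket_events(sim, tree, events = events,
                             pocket_columns = c(232L, 270L, 395L),
                             pocket_positions = c(232L, 270L, 395L),
                             root_triplet = c("S", "I", "V"))
  nodes <- node_spec(
    node1 = c("Eb_RAR3", "Hs_RARg"),
    node2 = c("Sc_RARa", "Hs_RARa"),
    node3 = c("Eb_RAR2", "Hs_RARg"),
    node4 = c("Sc_RARb", "Hs_RARb"),
    node5 = c("Sc_RARg", "Hs_RARg"),
    node6 = c("Lo_RARg", "Dr_RARg"),
    node7 = c("Xt_RARg", "Hs_RARg"))
  structure(list(spec = NULL, tree = tree, alignment = sim$alignment,
                 node_sequences = sim$node_sequences,
                 triplets = sim$triplets, categories = sim$categories,
                 true_orthology = NA_character_,
                 pocket = list(positions = c(232L, 270L, 395L),
                               columns = c(232L, 270L, 395L)),
                 nodes = nodes, events = events,
                 reference = list(name = "Hs_RARa",
                                  positions = c(232L, 270L, 395L))),
            class = "truth_bundle")
}
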