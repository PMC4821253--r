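# Five-OTU topology space for orthology assessment after 2R whole-genome
# duplication: enumeration of all backbone topologies, filtering to the
# set compatible with the 1-2-4 duplication pattern, expansion of OTU
# slots into multi-sequence clades, and mapping of topologies to
# orthology hypotheses.

#' Define the five operational taxonomic units
#'
#' The orthology assessment places five leaf-slots on backbone
#' topologies: one cyclostome gene (`C`), the three gnathostome subtype
#' groups (`A` = alpha, `B` = beta, `G` = gamma) and the outgroup (`O`).
#'
#' @param cyclostome Single sequence name (exactly one cyclostome gene is
#'   assessed at a time).
#' @param alpha_group,beta_group,gamma_group,outgroup Non-empty character
#'   vectors of sequence names.
#' @param fixed_subtrees Optional named list (names among
#'   `"alpha_group"`, `"beta_group"`, `"gamma_group"`, `"outgroup"`) of
#'   rooted newick strings over the corresponding members, fixing the
#'   within-OTU topology so that only the backbone varies.
#' @return An `otu_scheme`.
#' @export
otu_scheme <- function(cyclostome, alpha_group, beta_group, gamma_group,
                       outgroup, fixed_subtrees = list()) {
  if (length(cyclostome) != 1)
    stop("exactly one cyclostome gene per scheme")
  members <- list(cyclostome_gene = cyclostome, alpha_group = alpha_group,
                  beta_group = beta_group, gamma_group = gamma_group,
                  outgroup = outgroup)
  if (any(lengths(members) == 0)) stop("every OTU needs >= 1 member")
  all_m <- unlist(members)
  if (anyDuplicated(all_m))
    stop("OTU member sets must be disjoint; duplicated: ",
         paste(unique(all_m[duplicated(all_m)]), collapse = ", "))
  if (any(all_m %in% c("C", "A", "B", "G", "O")))
    stop("single-letter sequence names C/A/B/G/O clash with slot labels")
  bad <- setdiff(names(fixed_subtrees), names(members))
  if (length(bad)) stop("unknown OTU in fixed_subtrees: ",
                        paste(bad, collapse = ", "))
  structure(list(members = members, fixed_subtrees = fixed_subtrees),
            class = "otu_scheme")
}

#' @export
print.otu_scheme <- function(x, ...) {
  cat("Five-OTU scheme:\n")
  for (nm in names(x$members))
    cat(sprintf("  %-16s %s\n", nm, paste(x$members[[nm]], collapse = ", ")))
  invisible(x)
}

# -- generic rooted-shape enumeration ---------------------------------------

# All rooted binary tree shapes on the given labels, as nested pair lists.
# Count is (2n-3)!!; built by inserting each leaf on every edge (and above
# the root) of every smaller tree.
enumerate_rooted_shapes <- function(labels) {
  insert_everywhere <- function(t, leaf) {
    res <- list(list(t, leaf))             # above the current (sub)root
    if (is.list(t)) {
      for (side in 1:2) {
        for (sub in insert_everywhere(t[[side]], leaf)) {
          t2 <- t
          t2[[side]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  trees <- list(labels[[1]])
  for (lab in labels[-1])
    trees <- unlist(lapply(trees, insert_everywhere, leaf = lab),
                    recursive = FALSE)
  trees
}

# canonical newick of a nested shape: children sorted lexicographically
canonical_newick <- function(t) {
  if (!is.list(t)) return(t)
  parts <- sort(c(canonical_newick(t[[1]]), canonical_newick(t[[2]])))
  paste0("(", parts[1], ",", parts[2], ")")
}

#' Enumerate all unrooted topologies on a label set
#'
#' Utility enumeration: all `(2n-5)!!` distinct unrooted binary
#' topologies, each reported as a canonical newick rooted at the first
#' label.
#'
#' @param labels Character vector of leaf labels (n >= 3).
#' @return Character vector of canonical newick strings (sorted, no
#'   duplicates).
#' @export
enumerate_topologies <- function(labels) {
  if (length(labels) < 3) stop("need >= 3 labels")
  shapes <- enumerate_rooted_shapes(as.list(labels[-1]))
  nwk <- vapply(shapes, function(s)
    paste0("(", labels[1], ",", canonical_newick(s), ");"), character(1))
  sort(unique(nwk))
}

# cherry partner of C in a rooted ingroup shape over slots C, A, B, G:
# the slot whose leaf is C's sibling, or "none" if C's sibling is internal
slot_cherry_partner <- function(t) {
  find <- function(t, path = integer()) {
    if (!is.list(t)) return(if (t == "C") path else NULL)
    found <- find(t[[1]], c(path, 1L))
    if (!is.null(found)) return(found)
    find(t[[2]], c(path, 2L))
  }
  path <- find(t)
  if (length(path) == 0) return("none")   # C is the whole ingroup (impossible here)
  parent <- t
  for (i in path[-length(path)]) parent <- parent[[i]]
  sib <- parent[[3L - path[length(path)]]]
  if (!is.list(sib) && sib %in% c("A", "B", "G")) sib else "none"
}

shape_class_of <- function(t) {
  # rooted 4-leaf ingroup: balanced = (2,2) split at the ingroup root
  count <- function(t) if (is.list(t)) count(t[[1]]) + count(t[[2]]) else 1L
  if (is.list(t) && count(t[[1]]) == 2L && count(t[[2]]) == 2L)
    "balanced" else "caterpillar"
}

#' Enumerate all five-OTU backbone topologies
#'
#' All 15 distinct unrooted binary topologies on the five OTU slots,
#' represented outgroup-rooted: each entry is a rooted tree
#' `(ingroup, O)` whose ingroup is a rooted 4-leaf tree over the slots
#' `C` (cyclostome), `A`, `B`, `G` (gnathostome subtype groups). Ids
#' `T01`..`T15` follow the sorted canonical ingroup newick strings.
#'
#' @param otus An [otu_scheme()].
#' @return A `topology_set`: list of entries (`id`, `newick_template`
#'   over slot letters, `cherry_partner` of `C` in `{A,B,G,none}`,
#'   `shape_class` in `{balanced, caterpillar}`), with the scheme and a
#'   `constrained` flag as attributes.
#' @export
enumerate_all <- function(otus) {
  stopifnot(inherits(otus, "otu_scheme"))
  shapes <- enumerate_rooted_shapes(list("C", "A", "B", "G"))
  canon <- vapply(shapes, canonical_newick, character(1))
  keep <- !duplicated(canon)
  shapes <- shapes[keep]
  canon <- canon[keep]
  o <- order(canon)
  shapes <- shapes[o]
  canon <- canon[o]
  entries <- lapply(seq_along(shapes), function(i) {
    list(id = sprintf("T%02d", i),
         ingroup = shapes[[i]],
         newick_template = paste0("(", canon[i], ",O);"),
         cherry_partner = slot_cherry_partner(shapes[[i]]),
         shape_class = shape_class_of(shapes[[i]]))
  })
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  structure(entries, class = "topology_set", otus = otus,
            constrained = FALSE)
}

#' Topologies compatible with the 1-2-4 duplication pattern
#'
#' Keeps exactly the outgroup-rooted topologies in which the cyclostome
#' slot `C` is sister to a single gnathostome subtype slot (a cherry with
#' `A`, `B` or `G`). Under a strict 2R history the four paralogue slots
#' form a balanced `((.,.),(.,.))` tree; a cyclostome gene orthologous to
#' one slot (or occupying the lost fourth slot) always ends up cherried
#' with one extant subtype, whereas a purely gnathostome cherry would
#' imply cyclostome divergence between the two duplication rounds. Nine
#' of the fifteen topologies survive, three per cherry partner.
#'
#' @param otus An [otu_scheme()].
#' @param pattern Duplication pattern; only `"1-2-4"` is supported.
#' @return A constrained `topology_set`; attribute `partition` gives the
#'   topology ids per cherry partner, attribute `rationale` the selection
#'   rule in words.
#' @export
enumerate_constrained <- function(otus, pattern = "1-2-4") {
  if (!identical(pattern, "1-2-4"))
    stop("unsupported duplication constraint: ", pattern)
  all15 <- enumerate_all(otus)
  keep <- vapply(all15, function(e) e$cherry_partner != "none", logical(1))
  out <- all15[keep]
  attributes(out) <- NULL
  names(out) <- vapply(out, `[[`, character(1), "id")
  partners <- vapply(out, `[[`, character(1), "cherry_partner")
  structure(out, class = "topology_set", otus = otus, constrained = TRUE,
            partition = split(names(out), factor(partners,
                                                 levels = c("A", "B", "G"))),
            rationale = paste(
              "A strict 2R (1-2-4) history makes the four paralogue slots",
              "a balanced ((.,.),(.,.)) tree; the single cyclostome gene,",
              "orthologous to one slot or occupying the lost fourth slot,",
              "must form a cherry with one extant subtype slot. Topologies",
              "whose ingroup cherry is purely gnathostome are excluded."))
}

#' @export
print.topology_set <- function(x, ...) {
  cat(sprintf("%s topology set: %d topologies\n",
              if (isTRUE(attr(x, "constrained"))) "Constrained (1-2-4)"
              else "Unconstrained", length(x)))
  for (e in x)
    cat(sprintf("  %s  %-22s cherry(C,%s)  %s\n", e$id, e$newick_template,
                e$cherry_partner, e$shape_class))
  invisible(x)
}

#' Expand OTU slots into sequence-level trees
#'
#' Replaces each slot of a backbone topology by its member subtree: a
#' singleton member directly, a multi-member OTU by its fixed rooted
#' subtree from the scheme (see [nj_subtrees()] for a fallback). Branch
#' lengths are left unset, to be optimized afterwards.
#'
#' @param topology One entry of a `topology_set`.
#' @param otus An [otu_scheme()].
#' @return A rooted [ape::phylo] over all sequence names.
#' @export
expand_otus <- function(topology, otus) {
  stopifnot(inherits(otus, "otu_scheme"))
  slot_of <- c(C = "cyclostome_gene", A = "alpha_group", B = "beta_group",
               G = "gamma_group", O = "outgroup")
  nwk <- topology$newick_template
  for (slot in names(slot_of)) {
    otu <- slot_of[[slot]]
    mem <- otus$members[[otu]]
    sub <- if (length(mem) == 1) {
      mem
    } else if (!is.null(otus$fixed_subtrees[[otu]])) {
      s <- otus$fixed_subtrees[[otu]]
      sub_members <- sort(ape::read.tree(text = if (grepl(";\\s*$", s)) s
                                         else paste0(s, ";"))$tip.label)
      if (!identical(sub_members, sort(mem)))
        stop("fixed subtree for ", otu, " does not cover its members")
      sub("\\s*;\\s*$", "", s)
    } else {
      stop("multi-member OTU '", otu, "' has no fixed subtree; ",
           "supply one or derive it with nj_subtrees()")
    }
    nwk <- sub(paste0("(?<![A-Za-z0-9_])", slot, "(?![A-Za-z0-9_])"),
               sub, nwk, perl = TRUE)
  }
  ape::read.tree(text = nwk)
}

#' Fill missing OTU subtrees by neighbour joining
#'
#' Computes, once, a neighbour-joining subtree for every multi-member OTU
#' lacking a fixed subtree, from pairwise amino-acid distances on the
#' alignment, so that topology comparison varies only the backbone.
#'
#' @param otus An [otu_scheme()].
#' @param aln An [aa_alignment()] containing all members.
#' @return The scheme with `fixed_subtrees` completed.
#' @export
nj_subtrees <- function(otus, aln) {
  stopifnot(inherits(otus, "otu_scheme"), inherits(aln, "aa_alignment"))
  for (otu in names(otus$members)) {
    mem <- otus$members[[otu]]
    if (length(mem) < 2 || !is.null(otus$fixed_subtrees[[otu]])) next
    miss <- setdiff(mem, aln$names)
    if (length(miss)) stop("members not in alignment: ",
                           paste(miss, collapse = ", "))
    if (length(mem) == 2) {
      otus$fixed_subtrees[[otu]] <- paste0("(", mem[1], ",", mem[2], ");")
      next
    }
    d <- ape::dist.aa(ape::as.AAbin(aln$matrix[mem, , drop = FALSE]),
                      scaled = TRUE)
    tr <- ape::nj(d)
    tr$edge.length <- NULL
    tr <- ape::unroot(tr)
    # root arbitrarily on the first member's pendant edge
    tr <- ape::root(tr, outgroup = mem[1], resolve.root = TRUE)
    otus$fixed_subtrees[[otu]] <- ape::write.tree(tr)
  }
  otus
}

#' Map topologies to orthology hypotheses
#'
#' Without the fourth paralogue, hypothesis "C orthologous to X" collects
#' all topologies with cherry `(C, X)` -- three per subtype, partitioning
#' the constrained set. With the fourth (RARdelta-like) paralogue
#' assumed, caterpillar topologies still support only their cherry
#' partner, while each balanced topology `((C,X),(Y,Z))` is equally
#' compatible with "C orthologous to X" and "C is the lost fourth
#' paralogue's sister, i.e. orthologous to delta"; such topologies are
#' dual-labelled and contribute to both sums, which is reported
#' explicitly.
#'
#' @param tset A constrained `topology_set` from [enumerate_constrained()].
#' @param assume_fourth_paralogue Logical; add the delta hypothesis.
#' @return A `hypothesis_map`: list with `map` (hypothesis -> topology id
#'   vector), `scheme` (`"three_subtype"` or `"four_subtype"`) and, in
#'   four-subtype mode, `dual` (data frame of dual-counted topologies).
#' @export
hypothesis_map <- function(tset, assume_fourth_paralogue = FALSE) {
  if (!isTRUE(attr(tset, "constrained")))
    stop("hypothesis_map requires a constrained topology set")
  partners <- vapply(tset, `[[`, character(1), "cherry_partner")
  shapes <- vapply(tset, `[[`, character(1), "shape_class")
  hyp_of <- c(A = "alpha", B = "beta", G = "gamma")
  base <- lapply(c(A = "A", B = "B", G = "G"),
                 function(s) names(tset)[partners == s])
  names(base) <- hyp_of[names(base)]
  if (!assume_fourth_paralogue) {
    return(structure(list(map = base, scheme = "three_subtype", dual = NULL),
                     class = "hypothesis_map"))
  }
  balanced <- names(tset)[shapes == "balanced"]
  map <- c(base, list(delta = balanced))
  dual <- data.frame(topology_id = balanced,
                     label = paste0(hyp_of[partners[balanced]], " or delta"),
                     row.names = NULL)
  structure(list(map = map, scheme = "four_subtype", dual = dual),
            class = "hypothesis_map")
}

#' Export a topology set
#'
#' Writes a multi-tree newick file (`<path>.nwk`) and a TSV
#' (`<path>.tsv` with id, newick, cherry partner, shape class).
#'
#' @param tset A `topology_set`.
#' @param path Path prefix.
#' @export
write_topology_set <- function(tset, path) {
  writeLines(vapply(tset, `[[`, character(1), "newick_template"),
             paste0(path, ".nwk"))
  df <- data.frame(
    id = vapply(tset, `[[`, character(1), "id"),
    newick = vapply(tset, `[[`, character(1), "newick_template"),
    cherry_partner = vapply(tset, `[[`, character(1), "cherry_partner"),
    shape_class = vapply(tset, `[[`, character(1), "shape_class"),
    row.names = NULL)
  write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
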