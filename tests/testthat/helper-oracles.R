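# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/posterior code paths: likelihoods are computed by
# exhaustive enumeration over all internal-node (and ambiguous-tip) state
# assignments, posteriors by exhaustive Bayes.

# random small reversible model over S states
random_rate_model <- function(S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- matrix(0, S, S)
  ex[lower.tri(ex)] <- runif(S * (S - 1) / 2, 0.2, 2)
  ex <- ex + t(ex)
  fr <- runif(S, 0.5, 2)
  fr <- fr / sum(fr)
  rate_model(ex, fr, alphabet = c("K", "R", "E", "D", "W")[seq_len(S)])
}

# exhaustive site likelihoods: sum over every assignment of states to the
# internal nodes (and to ambiguous/gap tips), multiplying the stationary
# frequency at the root and one transition probability per edge
brute_site_logliks <- function(tree, aln, model, gamma) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L
  S <- model$S
  enc <- rarphylo:::encode_alignment(aln, model$alphabet)[tr$tip.label, ,
                                                          drop = FALSE]
  Pk <- lapply(gamma$rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(e)
      transition_matrix(model, tr$edge.length[e], r)))
  sapply(seq_len(ncol(enc)), function(site) {
    tipst <- enc[, site]
    free <- c(which(tipst == 0L), seq.int(ntip + 1L, nnode))
    grid <- do.call(expand.grid, rep(list(seq_len(S)), length(free)))
    tot <- 0
    for (j in seq_along(gamma$rates)) {
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[seq_len(ntip)] <- tipst
        st[free] <- as.integer(grid[g, ])
        p <- model$freq[st[root]]
        for (e in seq_len(nrow(tr$edge)))
          p <- p * Pk[[j]][[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
        tot <- tot + gamma$weights[j] * p
      }
    }
    log(tot)
  })
}

# exhaustive marginal posterior at one internal node for one site
brute_asr_posterior <- function(tree, aln, model, gamma, node, site) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L
  S <- model$S
  enc <- rarphylo:::encode_alignment(aln, model$alphabet)[tr$tip.label, ,
                                                          drop = FALSE]
  tipst <- enc[, site]
  free <- c(which(tipst == 0L), seq.int(ntip + 1L, nnode))
  grid <- do.call(expand.grid, rep(list(seq_len(S)), length(free)))
  joint <- numeric(S)
  for (j in seq_along(gamma$rates)) {
    Pj <- lapply(seq_len(nrow(tr$edge)), function(e)
      transition_matrix(model, tr$edge.length[e], gamma$rates[j]))
    for (g in seq_len(nrow(grid))) {
      st <- integer(nnode)
      st[seq_len(ntip)] <- tipst
      st[free] <- as.integer(grid[g, ])
      p <- model$freq[st[root]]
      for (e in seq_len(nrow(tr$edge)))
        p <- p * Pj[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
      joint[st[node]] <- joint[st[node]] + gamma$weights[j] * p
    }
  }
  joint / sum(joint)
}

# random alignment over a model's alphabet (optionally with gaps)
random_alignment <- function(names, n_cols, alphabet, gap_frac = 0) {
  letters_pool <- c(alphabet, if (gap_frac > 0) "-")
  probs <- c(rep((1 - gap_frac) / length(alphabet), length(alphabet)),
             if (gap_frac > 0) gap_frac)
  m <- matrix(sample(letters_pool, length(names) * n_cols, replace = TRUE,
                     prob = probs),
              nrow = length(names), dimnames = list(names, NULL))
  aa_alignment(m)
}

# minimum number of state changes at one character given leaf states
# (small exhaustive Sankoff over all internal assignments)
brute_parsimony_min <- function(tree, leaf_states) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  sts <- sort(unique(leaf_states))
  internal <- seq.int(ntip + 1L, nnode)
  grid <- do.call(expand.grid, c(rep(list(sts), length(internal)),
                                 list(stringsAsFactors = FALSE)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- character(nnode)
    st[seq_len(ntip)] <- leaf_states[tr$tip.label]
    st[internal] <- unlist(grid[g, ])
    ch <- sum(st[tr$edge[, 1]] != st[tr$edge[, 2]])
    best <- min(best, ch)
  }
  best
}
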