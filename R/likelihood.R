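# Felsenstein pruning under a reversible amino-acid model with
# discrete-gamma rate mixing; branch-length and alpha optimization on a
# fixed topology; site-wise log-likelihood matrices for topology
# comparison by RELL resampling.

# -- internal: traversal structure + compressed site patterns ---------------

make_pruning_data <- function(tree, aln, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  miss <- setdiff(tree$tip.label, aln$names)
  if (length(miss))
    stop("missing leaf sequence(s): ", paste(miss, collapse = ", "))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]

  enc <- encode_alignment(aln, model$alphabet)[tr$tip.label, , drop = FALSE]
  key <- apply(enc, 2, paste, collapse = ",")
  pat_index <- match(key, unique(key))
  first <- !duplicated(key)
  pats <- enc[, first, drop = FALSE]
  npat <- ncol(pats)
  wts <- tabulate(pat_index, nbins = npat)

  S <- model$S
  tip_partial <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    tp <- matrix(0, npat, S)
    st <- pats[i, ]
    known <- st > 0L
    tp[cbind(which(known), st[known])] <- 1
    tp[!known, ] <- 1
    tip_partial[[i]] <- tp
  }
  n_children <- tabulate(tr$edge[, 1], nbins = nnode)
  list(tree = tr, ntip = ntip, nnode = nnode, root = root,
       edge = tr$edge, n_edge = nrow(tr$edge),
       n_children = n_children, tip_partial = tip_partial,
       npat = npat, pat_index = pat_index, pat_weights = wts, S = S)
}

edge_pmats <- function(model, lens, gamma) {
  lapply(seq_along(lens), function(e)
    lapply(gamma$rates, function(r) transition_matrix(model, lens[e], r)))
}

# Post-order pass. Returns, per node and rate category, the conditional
# partial D (npat x S), its log-scaler vector, and for every edge the
# propagated child partial M = D_child %*% t(P_edge).
down_pass <- function(pw, model, gamma, lens, Pk = NULL) {
  k <- gamma$k
  if (is.null(Pk)) Pk <- edge_pmats(model, lens, gamma)
  D <- vector("list", pw$nnode)
  scD <- vector("list", pw$nnode)
  M <- vector("list", pw$n_edge)
  scM <- vector("list", pw$n_edge)
  acc <- vector("list", pw$nnode)
  sacc <- vector("list", pw$nnode)
  remaining <- pw$n_children
  zero_sc <- matrix(0, pw$npat, k)
  for (i in seq_len(pw$ntip)) {
    D[[i]] <- rep(list(NULL), k)
    for (j in seq_len(k)) D[[i]][[j]] <- pw$tip_partial[[i]]
    scD[[i]] <- zero_sc
  }
  for (e in seq_len(pw$n_edge)) {
    ch <- pw$edge[e, 2]
    pa <- pw$edge[e, 1]
    M[[e]] <- vector("list", k)
    for (j in seq_len(k)) M[[e]][[j]] <- D[[ch]][[j]] %*% t(Pk[[e]][[j]])
    scM[[e]] <- scD[[ch]]
    if (is.null(acc[[pa]])) {
      acc[[pa]] <- M[[e]]
      sacc[[pa]] <- scM[[e]]
    } else {
      for (j in seq_len(k)) acc[[pa]][[j]] <- acc[[pa]][[j]] * M[[e]][[j]]
      sacc[[pa]] <- sacc[[pa]] + scM[[e]]
    }
    remaining[pa] <- remaining[pa] - 1L
    if (remaining[pa] == 0L) {
      # node complete: rescale to guard against underflow
      sc <- sacc[[pa]]
      for (j in seq_len(k)) {
        s <- .rowSums(acc[[pa]][[j]], pw$npat, pw$S)
        s[s <= 0] <- 1
        acc[[pa]][[j]] <- acc[[pa]][[j]] / s
        sc[, j] <- sc[, j] + log(s)
      }
      D[[pa]] <- acc[[pa]]
      scD[[pa]] <- sc
    }
  }
  list(D = D, scD = scD, M = M, scM = scM, Pk = Pk)
}

logsumexp_rows <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx[!is.finite(mx)] <- 0
  mx + log(.rowSums(exp(m - mx), nrow(m), ncol(m)))
}

# per-pattern log-likelihood (and per-category components) from a down pass
pattern_logliks <- function(pw, model, gamma, dp) {
  k <- gamma$k
  percat <- matrix(NA_real_, pw$npat, k)
  for (j in seq_len(k)) {
    v <- as.vector(dp$D[[pw$root]][[j]] %*% model$freq)
    percat[, j] <- log(v) + dp$scD[[pw$root]][, j]
  }
  list(percat = percat,
       mixed = logsumexp_rows(percat + log(1 / k)))
}

#' Per-site log-likelihoods on a fixed tree
#'
#' Felsenstein pruning under a reversible model with discrete-gamma rate
#' mixing: the site likelihood is the equal-weight average over category
#' likelihoods. Gaps and `X` contribute all-ones conditional vectors.
#' Per-node rescaling guards against underflow; a site whose likelihood is
#' exactly zero (possible only with zero-length branches and conflicting
#' states) reports `loglik_floor` instead of `-Inf` so downstream
#' resampling stays finite.
#'
#' @param tree Rooted or unrooted [ape::phylo] with branch lengths.
#' @param aln An [aa_alignment()]; tree leaves must all be present.
#' @param model A [rate_model()].
#' @param gamma A [discrete_gamma()] object.
#' @param loglik_floor Value reported for zero-likelihood sites.
#' @return Numeric vector of per-site log-likelihoods.
#' @export
site_logliks <- function(tree, aln, model, gamma = discrete_gamma(1, 1),
                         loglik_floor = -745) {
  pw <- make_pruning_data(tree, aln, model)
  dp <- down_pass(pw, model, gamma, pw$tree$edge.length)
  ll <- pattern_logliks(pw, model, gamma, dp)$mixed
  ll[!is.finite(ll)] <- loglik_floor
  ll[pw$pat_index]
}

# -- branch-length optimization ---------------------------------------------

# Likelihood of the whole tree as a function of one edge length, given the
# below-partial D_v of the child and the rest-of-tree partial A at the
# parent (stationary frequencies folded into A at the root).
# The total likelihood as a function of the edge length t is
#   sum_i sum_j A_i P_ij(t) D_j = sum_m exp(lambda_m t r) (A U)_m (D Uinv')_m
# so projecting A and D into the eigenbasis once per edge reduces every
# Brent evaluation to a matrix-vector product.
edge_loglik_fun <- function(model, gamma, Dv, scDv, A, scA, wts, floor) {
  k <- gamma$k
  np <- nrow(A[[1]])
  eig <- model$eig
  U <- eig$U
  tUinv <- t(eig$Uinv)
  Z <- lapply(seq_len(k), function(j) (A[[j]] %*% U) * (Dv[[j]] %*% tUinv))
  sc <- scA + scDv
  logw <- log(1 / k)
  function(t) {
    percat <- matrix(NA_real_, np, k)
    for (j in seq_len(k)) {
      v <- as.vector(Z[[j]] %*% exp(eig$values * (t * gamma$rates[j])))
      v[v < 0] <- 0
      percat[, j] <- log(v) + sc[, j]
    }
    ll <- logsumexp_rows(percat + logw)
    ll[!is.finite(ll)] <- floor
    sum(wts * ll)
  }
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate ascent over branches: each branch in turn is maximized by a
#' bounded one-dimensional (Brent) search on `[min_len, max_len]` while
#' all partial likelihoods are kept current, so the total log-likelihood
#' is nondecreasing across rounds. Terminates when a full round improves
#' the total by less than `tol`, or after `max_rounds` rounds.
#'
#' @inheritParams site_logliks
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_rounds Maximum number of full rounds.
#' @param min_len,max_len Branch-length search bounds.
#' @param brent_tol Absolute x-tolerance of the per-branch search.
#' @return List with `tree` (optimized lengths), `loglik` (final total)
#'   and `trace` (total log-likelihood after each round).
#' @export
optimize_branch_lengths <- function(tree, aln, model,
                                    gamma = discrete_gamma(1, 1),
                                    tol = 1e-6, max_rounds = 50,
                                    min_len = 1e-8, max_len = 20,
                                    brent_tol = 1e-6,
                                    loglik_floor = -745) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, min_len), max_len)
  pw <- make_pruning_data(tree, aln, model)
  lens <- pw$tree$edge.length
  k <- gamma$k
  wts <- pw$pat_weights
  total_ll <- function(dp) {
    ll <- pattern_logliks(pw, model, gamma, dp)$mixed
    ll[!is.finite(ll)] <- loglik_floor
    sum(wts * ll)
  }
  dp0 <- down_pass(pw, model, gamma, lens)
  cur <- total_ll(dp0)
  if (!is.finite(cur))
    stop("non-finite log-likelihood at initialization; ",
         "check data/model compatibility")
  trace <- cur
  # children (edge indices) per node, and preorder edge sequence
  kids <- split(seq_len(pw$n_edge), factor(pw$edge[, 1], levels = seq_len(pw$nnode)))
  preorder <- rev(seq_len(pw$n_edge))
  freq_mat <- matrix(model$freq, pw$npat, pw$S, byrow = TRUE)
  zero_sc <- matrix(0, pw$npat, k)
  for (round in seq_len(max_rounds)) {
    lens_round_start <- lens
    dp <- down_pass(pw, model, gamma, lens)
    up <- vector("list", pw$nnode)   # rest-of-tree partial at each node
    scU <- vector("list", pw$nnode)
    up[[pw$root]] <- rep(list(freq_mat), k)
    scU[[pw$root]] <- zero_sc
    for (e in preorder) {
      pa <- pw$edge[e, 1]
      ch <- pw$edge[e, 2]
      sib <- setdiff(kids[[pa]], e)
      A <- vector("list", k)
      scA <- scU[[pa]]
      for (j in seq_len(k)) {
        a <- up[[pa]][[j]]
        for (s in sib) a <- a * dp$M[[s]][[j]]
        A[[j]] <- a
      }
      for (s in sib) scA <- scA + dp$scM[[s]]
      f <- edge_loglik_fun(model, gamma, dp$D[[ch]], dp$scD[[ch]],
                           A, scA, wts, loglik_floor)
      opt <- optimize(f, interval = c(min_len, max_len),
                      maximum = TRUE, tol = brent_tol)
      if (opt$objective > f(lens[e])) lens[e] <- opt$maximum
      # refresh this edge's propagated partial and the child's up partial
      for (j in seq_len(k)) {
        P <- transition_matrix(model, lens[e], gamma$rates[j])
        dp$M[[e]][[j]] <- dp$D[[ch]][[j]] %*% t(P)
        if (ch > pw$ntip) up[[ch]][[j]] <- A[[j]] %*% P
      }
      dp$scM[[e]] <- dp$scD[[ch]]
      if (ch > pw$ntip) {
        # rescale the up partial
        scU[[ch]] <- scA
        for (j in seq_len(k)) {
          s <- rowSums(up[[ch]][[j]])
          s[s <= 0] <- 1
          up[[ch]][[j]] <- up[[ch]][[j]] / s
          scU[[ch]][, j] <- scU[[ch]][, j] + log(s)
        }
      }
    }
    new <- total_ll(down_pass(pw, model, gamma, lens))
    if (new < cur) {           # numerically possible only at convergence
      lens <- lens_round_start
      break
    }
    improved <- new - cur
    cur <- new
    trace <- c(trace, cur)
    if (improved < tol) break
  }
  out_tree <- pw$tree
  out_tree$edge.length <- lens
  list(tree = out_tree, loglik = cur, trace = trace)
}

#' Estimate the discrete-gamma shape parameter
#'
#' Bounded one-dimensional maximization of the total log-likelihood in
#' `log(alpha)`, alternated with branch-length optimization for
#' `cycles` outer cycles.
#'
#' @inheritParams optimize_branch_lengths
#' @param k Number of gamma categories.
#' @param bounds Search bounds for alpha.
#' @param cycles Outer alternation cycles (alpha vs branch lengths).
#' @param optimize_lengths If `FALSE`, branch lengths are held fixed.
#' @return List with `alpha`, `gamma` (the fitted [discrete_gamma()]),
#'   `tree`, `loglik`, and logical `homogeneous`: when the upper bound's
#'   likelihood is within 1.92 log units (the boundary-corrected
#'   chi-squared(1) 5% half-point) of the maximum, rate heterogeneity is
#'   unsupported, the estimate snaps to the upper bound and the flag is
#'   set.
#' @export
estimate_alpha <- function(tree, aln, model, k = 4L, bounds = c(0.05, 50),
                           cycles = 3, optimize_lengths = TRUE,
                           tol = 1e-4, loglik_floor = -745) {
  if (bounds[1] >= bounds[2]) stop("alpha bounds inverted")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  alpha <- 1
  ll <- NA_real_
  for (cyc in seq_len(cycles)) {
    gam <- discrete_gamma(alpha, k)
    if (optimize_lengths) {
      fit <- optimize_branch_lengths(tree, aln, model, gam, tol = tol,
                                     loglik_floor = loglik_floor)
      tree <- fit$tree
    }
    pw <- make_pruning_data(tree, aln, model)
    obj <- function(la) {
      g <- discrete_gamma(exp(la), k)
      lls <- pattern_logliks(pw, model, g,
                             down_pass(pw, model, g,
                                       pw$tree$edge.length))$mixed
      lls[!is.finite(lls)] <- loglik_floor
      sum(pw$pat_weights * lls)
    }
    opt <- optimize(obj, interval = log(bounds), maximum = TRUE, tol = 1e-3)
    # never return worse than the bounds themselves
    at_lo <- obj(log(bounds[1])); at_hi <- obj(log(bounds[2]))
    cand <- c(opt$maximum, log(bounds[1]), log(bounds[2]))
    vals <- c(opt$objective, at_lo, at_hi)
    best <- which.max(vals)
    alpha <- exp(cand[best])
    ll <- vals[best]
    # heterogeneity unsupported (likelihood-ratio style, chi-sq_1 at 5%,
    # boundary-corrected): snap to the upper bound and flag the data as
    # effectively rate-homogeneous
    if (at_hi >= ll - 1.92) {
      alpha <- bounds[2]
      ll <- at_hi
    }
  }
  list(alpha = alpha, gamma = discrete_gamma(alpha, k), tree = tree,
       loglik = ll, homogeneous = alpha >= bounds[2] * 0.999)
}

#' Site-wise log-likelihood matrix over a set of topologies
#'
#' For each topology, branch lengths (and, depending on `gamma_policy`,
#' the gamma shape) are optimized independently, then per-site
#' log-likelihoods are recorded. This matrix is the object resampled by
#' [rell_bootstrap()].
#'
#' @param topologies Named list of [ape::phylo] trees over the same leaf
#'   set (branch lengths optional; names are the topology ids).
#' @inheritParams optimize_branch_lengths
#' @param gamma_policy `"shared-estimate"` (default): estimate alpha once
#'   on the first topology and reuse it; `"per-topology-estimate"`:
#'   re-estimate per topology; `"fixed"`: use `alpha` as given.
#' @param alpha Gamma shape used when `gamma_policy = "fixed"`.
#' @param k Number of gamma categories.
#' @return A `site_loglik_matrix`: list with `topology_ids`, `values`
#'   (topologies x sites), `total` (per-topology sums), `alpha` (per
#'   topology), `trees` (optimized).
#' @export
site_loglik_matrix <- function(topologies, aln, model,
                               gamma_policy = c("shared-estimate",
                                                "per-topology-estimate",
                                                "fixed"),
                               alpha = 1, k = 4L, tol = 1e-4,
                               loglik_floor = -745) {
  gamma_policy <- match.arg(gamma_policy)
  ids <- names(topologies)
  if (is.null(ids) || any(!nzchar(ids))) stop("topologies must be named")
  if (anyDuplicated(ids))
    stop("duplicate topology ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  leafsets <- lapply(topologies, function(t) sort(t$tip.label))
  if (length(unique(leafsets)) != 1)
    stop("all topologies must share the same leaf set")
  shared_gamma <- NULL
  if (gamma_policy == "shared-estimate") {
    est <- estimate_alpha(topologies[[1]], aln, model, k = k, tol = tol,
                          loglik_floor = loglik_floor)
    shared_gamma <- est$gamma
  } else if (gamma_policy == "fixed") {
    shared_gamma <- discrete_gamma(alpha, k)
  }
  n_sites <- aln$n_cols
  values <- matrix(NA_real_, length(topologies), n_sites,
                   dimnames = list(ids, NULL))
  alphas <- numeric(length(topologies))
  trees <- vector("list", length(topologies))
  for (i in seq_along(topologies)) {
    gam <- shared_gamma
    if (gamma_policy == "per-topology-estimate") {
      est <- estimate_alpha(topologies[[i]], aln, model, k = k, tol = tol,
                            loglik_floor = loglik_floor)
      gam <- est$gamma
      topologies[[i]] <- est$tree
    }
    fit <- optimize_branch_lengths(topologies[[i]], aln, model, gam,
                                   tol = tol, loglik_floor = loglik_floor)
    values[i, ] <- site_logliks(fit$tree, aln, model, gam,
                                loglik_floor = loglik_floor)
    alphas[i] <- gam$alpha
    trees[[i]] <- fit$tree
  }
  structure(list(topology_ids = ids, values = values,
                 total = rowSums(values), alpha = alphas, trees = trees),
            class = "site_loglik_matrix")
}

#' @export
print.site_loglik_matrix <- function(x, ...) {
  cat(sprintf("Site log-likelihood matrix: %d topologies x %d sites\n",
              length(x$topology_ids), ncol(x$values)))
  best <- which.max(x$total)
  for (i in order(-x$total))
    cat(sprintf("  %-8s total logL = %12.4f%s\n", x$topology_ids[i],
                x$total[i], if (i == best) "  (best)" else ""))
  invisible(x)
}

#' Export / import a site log-likelihood matrix as TSV
#'
#' Rows are topologies (first column `topology_id`), remaining columns are
#' per-site log-likelihoods. This is the hand-off file between the
#' likelihood and RELL stages.
#'
#' @param m A `site_loglik_matrix`.
#' @param path File path.
#' @export
write_site_loglik_matrix <- function(m, path) {
  df <- data.frame(topology_id = m$topology_ids, m$values,
                   check.names = FALSE)
  colnames(df) <- c("topology_id", paste0("site", seq_len(ncol(m$values))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_loglik_matrix
#' @export
read_site_loglik_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  dimnames(values) <- list(df[[1]], NULL)
  structure(list(topology_ids = df[[1]], values = values,
                 total = rowSums(values), alpha = NA_real_, trees = NULL),
            class = "site_loglik_matrix")
}
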