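# RELL bootstrap probabilities over a topology set and their aggregation
# into per-hypothesis orthology probabilities.

#' RELL bootstrap probabilities
#'
#' Resampling of estimated log-likelihoods: each replicate draws site
#' indices with replacement (same number as observed), sums the resampled
#' per-site log-likelihoods per topology, and awards the replicate to the
#' topology with the highest sum. Exact ties split the replicate's mass
#' equally among the tied topologies. No re-optimization is performed.
#'
#' @param m A `site_loglik_matrix` (see [site_loglik_matrix()]).
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are fully reproducible from it.
#' @return A `rell_result`: list with `topology_ids`, `bp` (bootstrap
#'   probabilities summing to 1), `B`, `seed` and `tie_events` (number of
#'   replicates whose maximum was shared).
#' @export
rell_bootstrap <- function(m, B, seed = 1L) {
  stopifnot(inherits(m, "site_loglik_matrix"))
  B <- as.integer(B)
  if (is.na(B) || B < 1) stop("B must be >= 1")
  values <- m$values
  n_top <- nrow(values)
  n_sites <- ncol(values)
  if (n_top < 1 || n_sites < 1) stop("need >= 1 topology and >= 1 site")
  # site resampling aggregated by distinct site-loglik columns: the
  # per-pattern resample counts are multinomial with the pattern weights,
  # exactly the distribution of iid site resampling
  key <- apply(values, 2, paste, collapse = "\r")
  pat <- match(key, unique(key))
  pvalues <- values[, !duplicated(key), drop = FALSE]
  pweights <- tabulate(pat, nbins = ncol(pvalues))
  awards <- numeric(n_top)
  tie_events <- 0L
  with_seed(seed, {
    done <- 0L
    chunk <- max(1L, min(B, as.integer(2e7 / ncol(pvalues))))
    while (done < B) {
      nb <- min(chunk, B - done)
      counts <- stats::rmultinom(nb, n_sites, pweights / n_sites)
      sums <- pvalues %*% counts                    # n_top x nb
      mx <- apply(sums, 2, max)
      is_max <- sums == rep(mx, each = n_top)
      n_max <- colSums(is_max)
      tie_events <- tie_events + sum(n_max > 1L)
      awards <- awards + rowSums(is_max / rep(n_max, each = n_top))
      done <- done + nb
    }
  })
  structure(list(topology_ids = m$topology_ids, bp = awards / B,
                 B = B, seed = as.integer(seed), tie_events = tie_events),
            class = "rell_result")
}

#' @export
print.rell_result <- function(x, ...) {
  cat(sprintf("RELL bootstrap: B = %d, seed = %d, tie events = %d\n",
              x$B, x$seed, x$tie_events))
  for (i in order(-x$bp))
    cat(sprintf("  %-8s BP = %.4f\n", x$topology_ids[i], x$bp[i]))
  invisible(x)
}

#' Aggregate RELL bootstrap probabilities into orthology probabilities
#'
#' Adds up the bootstrap probabilities of the topologies supporting each
#' one-to-one orthology hypothesis. In three-subtype mode the hypothesis
#' probabilities partition the total mass; in four-subtype mode balanced
#' topologies are dual-counted towards both their cherry partner and the
#' lost fourth paralogue (delta), and the dual decomposition is reported.
#'
#' @param r A `rell_result`.
#' @param hmap A `hypothesis_map` from [hypothesis_map()].
#' @param cyclostome_gene_name Name of the assessed cyclostome gene
#'   (annotation only).
#' @return An `orthology_report`: list with `cyclostome_gene_name`,
#'   `scheme`, `prob` (named numeric), `supporting_sets`, `dual`,
#'   `bp_table` (the full `rell_result`).
#' @export
aggregate_orthology <- function(r, hmap, cyclostome_gene_name = NA_character_) {
  stopifnot(inherits(r, "rell_result"), inherits(hmap, "hypothesis_map"))
  ids <- unlist(hmap$map, use.names = FALSE)
  missing_ids <- setdiff(ids, r$topology_ids)
  if (length(missing_ids))
    stop("hypothesis map refers to unknown topology ids: ",
         paste(missing_ids, collapse = ", "))
  bp <- setNames(r$bp, r$topology_ids)
  prob <- vapply(hmap$map, function(tids) sum(bp[tids]), numeric(1))
  structure(list(cyclostome_gene_name = cyclostome_gene_name,
                 scheme = hmap$scheme, prob = prob,
                 supporting_sets = hmap$map, dual = hmap$dual,
                 bp_table = r),
            class = "orthology_report")
}

#' @export
print.orthology_report <- function(x, ...) {
  cat(sprintf("Orthology report for '%s' (%s scheme)\n",
              x$cyclostome_gene_name, x$scheme))
  for (h in names(x$prob))
    cat(sprintf("  P(orthologous to %-5s) = %.4f   [topologies %s]\n", h,
                x$prob[h], paste(x$supporting_sets[[h]], collapse = ",")))
  if (!is.null(x$dual) && nrow(x$dual)) {
    cat("  dual-counted balanced topologies:\n")
    for (i in seq_len(nrow(x$dual)))
      cat(sprintf("    %s: %s (BP %.4f)\n", x$dual$topology_id[i],
                  x$dual$label[i],
                  x$bp_table$bp[match(x$dual$topology_id[i],
                                      x$bp_table$topology_ids)]))
  }
  invisible(x)
}

#' Export an orthology report as a pie-ready TSV
#'
#' Two columns: hypothesis, probability.
#' @param report An `orthology_report`.
#' @param path Output path.
#' @export
write_orthology_report <- function(report, path) {
  df <- data.frame(hypothesis = names(report$prob),
                   probability = unname(report$prob))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end probabilistic orthology assessment
#'
#' Full chain for one cyclostome gene: gap-column filtering, constrained
#' topology enumeration, OTU expansion, per-topology branch-length (and
#' shared gamma shape) optimization, site-wise log-likelihoods, RELL
#' bootstrap, and aggregation into orthology probabilities.
#'
#' @param aln An [aa_alignment()] containing all scheme members.
#' @param otus An [otu_scheme()].
#' @param model A [rate_model()]; default LG.
#' @param B RELL bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @param assume_fourth_paralogue Aggregation scheme, see
#'   [hypothesis_map()].
#' @param gamma_policy,k,tol Passed to [site_loglik_matrix()].
#' @param max_gap_frac Gap-column filter threshold, see
#'   [filter_gap_columns()].
#' @return An `orthology_report`, with intermediates (`topology_set`,
#'   `site_loglik_matrix`, filter mask) attached as attribute
#'   `intermediates`.
#' @export
run_orthology_assessment <- function(aln, otus, model = lg_model(),
                                     B = 10000L, seed = 1L,
                                     assume_fourth_paralogue = FALSE,
                                     gamma_policy = "shared-estimate",
                                     k = 4L, tol = 1e-4,
                                     max_gap_frac = 0.10) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(otus, "otu_scheme"))
  miss <- setdiff(unlist(otus$members), aln$names)
  if (length(miss))
    stop("OTU members missing from alignment: ", paste(miss, collapse = ", "))
  flt <- filter_gap_columns(aln, max_gap_frac)
  sub <- aa_alignment(flt$alignment$matrix[unlist(otus$members), ,
                                           drop = FALSE])
  tset <- enumerate_constrained(otus)
  trees <- lapply(tset, expand_otus, otus = otus)
  names(trees) <- names(tset)
  slm <- site_loglik_matrix(trees, sub, model, gamma_policy = gamma_policy,
                            k = k, tol = tol)
  rr <- rell_bootstrap(slm, B = B, seed = seed)
  hmap <- hypothesis_map(tset, assume_fourth_paralogue)
  report <- aggregate_orthology(rr, hmap,
                                cyclostome_gene_name =
                                  otus$members$cyclostome_gene)
  attr(report, "intermediates") <- list(topology_set = tset,
                                        site_loglik_matrix = slm,
                                        mask = flt$mask)
  report
}
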