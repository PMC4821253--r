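test_that("zero-length branches force site likelihoods to frequencies", {
  lg <- lg_model()
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  aln <- aa_alignment(c(A = "KW", B = "KW", C = "KV", D = "KW"))
  ll <- site_logliks(tr, aln, lg)
  expect_equal(ll[1], log(lg$freq[match("K", lg$alphabet)]),
               tolerance = 1e-10)
  expect_equal(ll[2], -745)                    # conflicting site: floored
  expect_equal(site_logliks(tr, aln, lg, loglik_floor = -1e4)[2], -1e4)
})

test_that("a two-taxon cherry matches the closed-form likelihood", {
  lg <- lg_model()
  tr <- ape::read.tree(text = "(A:0.17,B:0.23);")
  aln <- aa_alignment(c(A = "KWM", B = "KVM"))
  ll <- site_logliks(tr, aln, lg)
  P <- transition_matrix(lg, 0.4)              # reversible: only the sum counts
  i <- match(c("K", "W", "M"), lg$alphabet)
  j <- match(c("K", "V", "M"), lg$alphabet)
  expect_equal(ll, log(lg$freq[i] * P[cbind(i, j)]), tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on random small instances", {
  set.seed(42)
  for (case in 1:40) {
    S <- sample(2:3, 1)
    n_leaf <- sample(2:4, 1)
    n_site <- sample(1:4, 1)
    model <- random_rate_model(S)
    tr <- ape::rtree(n_leaf, br = function(n) runif(n, 0.05, 1.2))
    gamma <- discrete_gamma(exp(runif(1, -1, 1)), sample(1:2, 1))
    aln <- random_alignment(tr$tip.label, n_site, model$alphabet,
                            gap_frac = if (case %% 4 == 0) 0.2 else 0)
    mine <- site_logliks(tr, aln, model, gamma)
    oracle <- brute_site_logliks(tr, aln, model, gamma)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting of a reversible model", {
  set.seed(8)
  model <- random_rate_model(3)
  tr <- ape::unroot(ape::rtree(6, br = function(n) runif(n, 0.05, 0.8)))
  aln <- random_alignment(tr$tip.label, 30, model$alphabet)
  gamma <- discrete_gamma(0.8, 3)
  base <- site_logliks(tr, aln, model, gamma)
  for (tip in c(1, 3, 5)) {
    rerooted <- ape::root(tr, outgroup = tr$tip.label[tip],
                          resolve.root = TRUE)
    expect_equal(site_logliks(rerooted, aln, model, gamma), base,
                 tolerance = 1e-8)
  }
})

test_that("branch-length optimization hits known optima", {
  lg <- lg_model()
  # identical sequences: all lengths at the lower bound
  tr <- ape::read.tree(text = "((A:0.3,B:0.2):0.1,C:0.4);")
  same <- aa_alignment(c(A = "MKWVLE", B = "MKWVLE", C = "MKWVLE"))
  fit <- optimize_branch_lengths(tr, same, lg)
  expect_true(all(fit$tree$edge.length <= 1e-6))

  # two taxa under the binary symmetric model: the ML distance has the
  # closed form -log(1 - 2p) / 2
  m2 <- rate_model(matrix(c(0, 1, 1, 0), 2), c(0.5, 0.5), c("K", "R"))
  n <- 400; ndiff <- 60
  a <- paste(rep("K", n), collapse = "")
  b <- paste(c(rep("R", ndiff), rep("K", n - ndiff)), collapse = "")
  tr2 <- ape::read.tree(text = "(x:0.05,y:0.05);")
  fit2 <- optimize_branch_lengths(tr2, aa_alignment(c(x = a, y = b)), m2)
  p <- ndiff / n
  expect_equal(sum(fit2$tree$edge.length), -log(1 - 2 * p) / 2,
               tolerance = 1e-4)
})

test_that("optimization is monotone and recovers simulated branch lengths", {
  lg <- lg_model()
  tr <- ape::read.tree(text =
    "((A:0.15,B:0.3):0.12,(C:0.2,(D:0.25,E:0.1):0.08):0.18);")
  g <- discrete_gamma(1, 4)
  sim <- simulate_alignment(tr, lg, g, 1000, seed = 77)
  init <- tr
  init$edge.length <- rep(0.1, nrow(tr$edge))
  fit <- optimize_branch_lengths(init, sim$alignment, lg, g, tol = 1e-5)
  expect_true(all(diff(fit$trace) >= -1e-9))
  # interior branches >= 0.05 within 15% relative error (seed-fixed);
  # the two root-adjacent edges are identifiable only through their sum
  # under a reversible model, so they are compared summed
  truth <- tr$edge.length
  got <- fit$tree$edge.length[match(paste(tr$edge[, 1], tr$edge[, 2]),
                                    paste(fit$tree$edge[, 1],
                                          fit$tree$edge[, 2]))]
  ntip <- length(tr$tip.label)
  at_root <- tr$edge[, 1] == ntip + 1L
  interior <- tr$edge[, 2] > ntip & !at_root
  big <- interior & truth >= 0.05
  expect_true(all(abs(got[big] - truth[big]) / truth[big] < 0.15))
  expect_lt(abs(sum(got[at_root]) - sum(truth[at_root])) /
              sum(truth[at_root]), 0.15)
  expect_error(optimize_branch_lengths(init,
    aa_alignment(setNames(rep("MK", 5), tr$tip.label[c(1, 2, 3, 4, 4)])),
    lg), "duplicate")
})

test_that("gamma shape estimation recovers truth and respects bounds", {
  lg <- lg_model()
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.2):0.1);")
  sim <- simulate_alignment(tr, lg, discrete_gamma(0.5, 8), 2000, seed = 13)
  est <- estimate_alpha(tr, sim$alignment, lg, k = 4)
  expect_gt(est$alpha, 0.35)
  expect_lt(est$alpha, 0.7)
  expect_false(est$homogeneous)
  # the returned alpha beats a 10-point grid
  pw_ll <- function(a) {
    g <- discrete_gamma(a, 4)
    sum(site_logliks(est$tree, sim$alignment, lg, g))
  }
  grid <- exp(seq(log(0.05), log(50), length.out = 10))
  expect_true(est$loglik >= max(vapply(grid, pw_ll, numeric(1))) - 1e-6)

  # rate-homogeneous data push the estimate to the upper bound
  simh <- simulate_alignment(tr, lg, discrete_gamma(1, 1), 1500, seed = 14)
  esth <- estimate_alpha(tr, simh$alignment, lg, k = 4)
  expect_true(esth$homogeneous)
  expect_error(estimate_alpha(tr, simh$alignment, lg, bounds = c(5, 1)),
               "inverted")
})

test_that("the site log-likelihood matrix is internally consistent", {
  lg <- lg_model()
  b <- simulate_scenario(scenario_spec(n_columns = 120L, seed = 21L))
  tset <- enumerate_constrained(b$otus)
  trees <- lapply(tset[1:3], expand_otus, otus = b$otus)
  names(trees) <- names(tset)[1:3]
  slm <- site_loglik_matrix(trees, b$alignment, lg, gamma_policy = "fixed",
                            alpha = 1)
  expect_equal(slm$topology_ids, names(trees))
  expect_equal(slm$total, rowSums(slm$values), tolerance = 1e-6)
  # each row equals a fresh site_logliks evaluation of the fitted tree
  for (i in 1:3)
    expect_equal(unname(slm$values[i, ]),
                 site_logliks(slm$trees[[i]], b$alignment, lg,
                              discrete_gamma(1, 4)),
                 tolerance = 1e-9)
  # single topology reduces to site_logliks
  one <- site_loglik_matrix(trees[1], b$alignment, lg,
                            gamma_policy = "fixed", alpha = 1)
  expect_equal(one$values[1, ], slm$values[1, ], tolerance = 1e-8)

  # permuting alignment columns permutes matrix columns identically
  perm <- sample(b$alignment$n_cols)
  paln <- aa_alignment(b$alignment$matrix[, perm])
  pslm <- site_loglik_matrix(trees, paln, lg, gamma_policy = "fixed",
                             alpha = 1)
  expect_equal(pslm$values, slm$values[, perm], tolerance = 1e-6)

  expect_error(site_loglik_matrix(setNames(trees, c("a", "a", "b")),
                                  b$alignment, lg), "duplicate")
})

test_that("site log-likelihood matrices round-trip through TSV", {
  lg <- lg_model()
  b <- simulate_scenario(scenario_spec(n_columns = 40L, seed = 3L))
  tset <- enumerate_constrained(b$otus)
  trees <- lapply(tset[1:2], expand_otus, otus = b$otus)
  names(trees) <- names(tset)[1:2]
  slm <- site_loglik_matrix(trees, b$alignment, lg, gamma_policy = "fixed",
                            alpha = 1)
  path <- tempfile(fileext = ".tsv")
  write_site_loglik_matrix(slm, path)
  back <- read_site_loglik_matrix(path)
  expect_equal(back$topology_ids, slm$topology_ids)
  expect_equal(unname(back$values), unname(slm$values), tolerance = 1e-8)
})
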