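test_that("marginal posteriors equal exhaustive Bayes on small instances", {
  set.seed(19)
  for (case in 1:6) {
    S <- sample(2:3, 1)
    model <- random_rate_model(S)
    tr <- ape::rtree(3, br = function(n) runif(n, 0.05, 1))
    gamma <- discrete_gamma(exp(runif(1, -0.7, 0.7)), sample(1:2, 1))
    aln <- random_alignment(tr$tip.label, 3, model$alphabet,
                            gap_frac = if (case %% 3 == 0) 0.25 else 0)
    asr <- marginal_asr(tr, aln, model, gamma)
    for (rec in asr$reconstructions) {
      node <- match(rec$node_label,
                    rarphylo:::all_node_labels(asr$tree))
      for (site in 1:3) {
        oracle <- brute_asr_posterior(asr$tree, aln, model, gamma, node,
                                      site)
        expect_equal(unname(rec$posteriors[site, ]), oracle,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("posterior rows normalize and MAP residues attain the maximum", {
  lg <- lg_model()
  b <- simulate_scenario(scenario_spec(n_columns = 80L, seed = 6L))
  asr <- marginal_asr(b$tree, b$alignment, lg, discrete_gamma(1, 4))
  for (rec in asr$reconstructions) {
    expect_equal(rowSums(rec$posteriors), rep(1, 80), tolerance = 1e-9)
    map <- strsplit(rec$map_sequence, "")[[1]]
    mx <- apply(rec$posteriors, 1, max)
    expect_true(all(abs(rec$posteriors[cbind(1:80, match(map, lg$alphabet))]
                        - mx) < 1e-9))
  }
  # the mixed per-site log-likelihood matches the pruning engine
  expect_equal(asr$site_logliks,
               site_logliks(b$tree, b$alignment, lg, discrete_gamma(1, 4)),
               tolerance = 1e-8)
})

test_that("near-zero branches force posteriors onto the observed residue", {
  lg <- lg_model()
  tr <- ape::read.tree(text = "((A:1e-8,B:1e-8):1e-8,(C:1e-8,D:1e-8):1e-8);")
  aln <- aa_alignment(c(A = "KW", B = "KW", C = "KW", D = "KW"))
  asr <- marginal_asr(tr, aln, lg)
  for (rec in asr$reconstructions) {
    expect_gte(rec$posteriors[1, "K"], 1 - 1e-6)
    expect_gte(rec$posteriors[2, "W"], 1 - 1e-6)
  }
  # a named leaf reconstructs its own observed residues with certainty
  asr2 <- marginal_asr(tr, aln, lg, nodes = node_spec(leafA = "A"))
  expect_equal(asr2$reconstructions$leafA$map_sequence, "KW")
  expect_gte(min(asr2$reconstructions$leafA$posteriors[cbind(1:2,
    match(c("K", "W"), lg$alphabet))]), 1 - 1e-9)
})

test_that("node specs resolve to MRCAs and fail informatively", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,(C:1,D:1)cd:1)r;")
  aln <- aa_alignment(c(A = "K", B = "K", C = "K", D = "K"))
  asr <- marginal_asr(tr, aln, lg_model(),
                      nodes = node_spec(anc_ab = c("A", "B"),
                                        root = c("A", "D")))
  expect_setequal(names(asr$reconstructions), c("anc_ab", "root"))
  expect_error(marginal_asr(tr, aln, lg_model(),
                            nodes = node_spec(x = c("A", "Z"))),
               "x'.*Z")
  expect_error(marginal_asr(ape::unroot(tr), aln, lg_model()), "rooted")
})

test_that("MAP root recovery is high on simulated trees with short branches", {
  lg <- lg_model()
  acc <- vapply(1:3, function(s) {
    set.seed(600 + s)
    tr <- ape::rtree(20, br = function(n) rep(0.05, n))
    sim <- simulate_alignment(tr, lg, discrete_gamma(1, 4), 300,
                              seed = 600 + s)
    asr <- marginal_asr(tr, sim$alignment, lg, discrete_gamma(1, 4))
    truth <- sim$node_sequences["node1", ]     # the root's true sequence
    got <- strsplit(asr$reconstructions$node1$map_sequence, "")[[1]]
    mean(got == truth)
  }, numeric(1))
  expect_gt(mean(acc), 0.9)
})

test_that("key-position reports carry residues and probabilities per node", {
  b <- rar_pocket_scenario(seed = 11L)
  gamma <- discrete_gamma(1, 4)
  asr <- marginal_asr(b$tree, b$alignment, lg_model(), gamma, nodes = b$nodes)
  refmap <- map_reference_positions(b$alignment, "Hs_RARa",
                                    c(232L, 270L, 395L))
  rep <- reconstruction_report(asr, refmap)
  expect_equal(rep$node, paste0("node", 1:7))
  expect_equal(rep$res_232[rep$node == "node1"], "S")
  expect_true(all(rep$prob_232 > 0 & rep$prob_232 <= 1))

  # a key column lost to the gap filter is an actionable error
  m <- b$alignment$matrix
  m[seq_len(ceiling(nrow(m) * 0.2)), 270] <- "-"
  flt <- filter_gap_columns(aa_alignment(m), 0.10)
  expect_error(reconstruction_report(asr, refmap, mask = flt$mask),
               "270.*gap")
})

test_that("logo tables round-trip and sharpen with shorter branches", {
  b <- simulate_scenario(scenario_spec(n_columns = 40L, seed = 12L))
  gamma <- discrete_gamma(1, 4)
  asr <- marginal_asr(b$tree, b$alignment, lg_model(), gamma)
  rec <- asr$reconstructions[[1]]
  path <- tempfile(fileext = ".tsv")
  export_logo_table(rec, path)
  back <- read_logo_table(path)
  expect_equal(unname(back), unname(rec$posteriors), tolerance = 1e-9)

  # deterministic posterior exports one-hot rows
  tr0 <- ape::read.tree(text = "((A:1e-8,B:1e-8):1e-8,C:1e-8);")
  aln0 <- aa_alignment(c(A = "KW", B = "KW", C = "KW"))
  rec0 <- marginal_asr(tr0, aln0, lg_model())$reconstructions[[1]]
  export_logo_table(rec0, path)
  expect_equal(sort(unique(round(as.vector(read_logo_table(path)), 6))),
               c(0, 1))

  # entropy per column decreases when all branches shrink
  short <- b$tree; short$edge.length <- short$edge.length / 10
  asr_s <- marginal_asr(short, b$alignment, lg_model(), gamma)
  ent <- function(p) -rowSums(ifelse(p > 0, p * log(p), 0))
  expect_lt(mean(ent(asr_s$reconstructions[[1]]$posteriors)),
            mean(ent(rec$posteriors)))
})

test_that("per-column posteriors are unchanged by duplicating the data", {
  # MAP stability under column duplication at a fixed tree
  b <- simulate_scenario(scenario_spec(n_columns = 30L, seed = 15L))
  gamma <- discrete_gamma(1, 4)
  asr1 <- marginal_asr(b$tree, b$alignment, lg_model(), gamma)
  dup <- aa_alignment(cbind(b$alignment$matrix, b$alignment$matrix))
  asr2 <- marginal_asr(b$tree, dup, lg_model(), gamma)
  p1 <- asr1$reconstructions[[1]]$posteriors
  p2 <- asr2$reconstructions[[1]]$posteriors[1:30, ]
  expect_true(all(apply(p2, 1, max) >= apply(p1, 1, max) - 1e-9))
})
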