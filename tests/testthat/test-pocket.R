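test_that("signature classification matches the diagnostic triplets exactly", {
  expect_equal(classify_signature(c("S", "I", "V")), "alpha_like")
  expect_equal(classify_signature(c("A", "I", "V")), "beta_like")
  expect_equal(classify_signature(c("A", "M", "A")), "gamma_like")
  expect_equal(classify_signature(c("C", "I", "V")), "other")
  # case-insensitive, total, X never classified
  expect_equal(classify_signature(c("s", "i", "v")), "alpha_like")
  expect_equal(classify_signature(c("X", "I", "V")), "other")
  expect_equal(classify_signature(c("A", "I", "A")), "other")
  set.seed(3)
  for (i in 1:30) {
    cls <- classify_signature(sample(c(rarphylo:::AA_ALPHABET, "X"), 3,
                                     replace = TRUE))
    expect_true(cls %in% c("alpha_like", "beta_like", "gamma_like", "other"))
  }
  expect_error(classify_signature(c("S", "I")), "exactly 3")
})

test_that("signature tables read planted triplets from alignments and nodes", {
  b <- rar_pocket_scenario(seed = 23L)
  refmap <- map_reference_positions(b$alignment, "Hs_RARa",
                                    c(232L, 270L, 395L))
  tab <- signature_table(b$alignment$names, aln = b$alignment,
                         refmap = refmap)
  cls <- setNames(tab$class, tab$owner)
  # cyclostome RAR1/RAR3 and gnathostome alpha leaves are alpha-like
  expect_true(all(cls[c("Eb_RAR1", "Lj_RAR1", "Eb_RAR3", "Lj_RAR3",
                        "Sc_RARa", "Dr_RARa", "Hs_RARa")] == "alpha_like"))
  # RAR2 and beta leaves are beta-like
  expect_true(all(cls[c("Eb_RAR2", "Lj_RAR2", "Sc_RARb", "Dr_RARb",
                        "Hs_RARb")] == "beta_like"))
  # mammal/bird/chondrichthyan gamma are gamma-like; actinopterygian and
  # frog gamma carry the reverted Ser in H3
  expect_true(all(cls[c("Hs_RARg", "Gg_RARg", "Sc_RARg")] == "gamma_like"))
  expect_true(all(tab$res_232[tab$owner %in%
                              c("Lo_RARg", "Dr_RARg", "Xt_RARg")] == "S"))
  expect_true(all(cls[c("Lo_RARg", "Dr_RARg", "Xt_RARg")] == "other"))

  # node rows come from a reconstruction report
  nr <- data.frame(node = "nodeZ", res_232 = "A", prob_232 = 1,
                   res_270 = "I", prob_270 = 1, res_395 = "V",
                   prob_395 = 1)
  tab2 <- signature_table(c("Hs_RARa", "nodeZ"), aln = b$alignment,
                          refmap = refmap, node_report = nr)
  expect_equal(tab2$class, c("alpha_like", "beta_like"))
  expect_error(signature_table("missing_owner", aln = b$alignment,
                               refmap = refmap), "not found")

  # TSV round-trip preserves the table
  path <- tempfile(fileext = ".tsv")
  write_signature_table(tab2, path)
  back <- read_signature_table(path)
  expect_equal(back$owner, tab2$owner)
  expect_equal(back$class, tab2$class)
})

test_that("event inference diffs edges and flags reversions via history", {
  tr <- ape::read.tree(text = "((L1:1,L2:1)n2:1,(L3:1,L4:1)n3:1)n1;")
  st <- function(...) {
    m <- rbind(...)
    data.frame(label = m[, 1], res_232 = m[, 2], res_270 = m[, 3],
               res_395 = m[, 4])
  }
  # identical states everywhere: no events
  same <- st(c("L1", "S", "I", "V"), c("L2", "S", "I", "V"),
             c("L3", "S", "I", "V"), c("L4", "S", "I", "V"),
             c("n1", "S", "I", "V"), c("n2", "S", "I", "V"),
             c("n3", "S", "I", "V"))
  expect_equal(nrow(infer_events(tr, same)), 0)

  # multi-step history S -> A -> S: the second change is a reversion
  rev <- st(c("L1", "S", "I", "V"), c("L2", "A", "I", "V"),
            c("L3", "A", "I", "V"), c("L4", "A", "I", "V"),
            c("n1", "S", "I", "V"), c("n2", "A", "I", "V"),
            c("n3", "A", "I", "V"))
  ev <- infer_events(tr, rev)
  expect_equal(nrow(ev), 3)
  back <- ev[ev$branch == "L1", ]
  expect_equal(back$from, "A"); expect_equal(back$to, "S")
  expect_true(back$reversion)
  expect_false(any(ev$reversion[ev$branch != "L1"]))

  # X poisons the comparison into a no-call instead of a guess
  xst <- rev; xst$res_232[xst$label == "n2"] <- "X"
  evx <- infer_events(tr, xst)
  expect_false("n2" %in% evx$branch[evx$position == 232])
  expect_gte(attr(evx, "no_calls"), 1)

  expect_error(infer_events(tr, rev[-1, ]), "missing node state")
})

test_that("event inference is invariant to leaf order and bounded by parsimony", {
  b <- rar_pocket_scenario(seed = 31L)
  ev1 <- infer_events(b$tree, b$triplets)
  shuffled <- b$triplets[sample(nrow(b$triplets)), ]
  ev2 <- infer_events(b$tree, shuffled)
  expect_equal(ev1, ev2, ignore_attr = TRUE)

  # per position, events on the true history >= the parsimony minimum
  for (pos in c("res_232", "res_270", "res_395")) {
    leaves <- setNames(b$triplets[[pos]], b$triplets$label)[b$tree$tip.label]
    small <- ape::keep.tip(b$tree, c("Eb_RAR1", "Sc_RARa", "Sc_RARg",
                                     "Xt_RARg"))
    minc <- brute_parsimony_min(small, leaves[small$tip.label])
    n_here <- sum(ev1$position == as.integer(sub("res_", "", pos)))
    expect_gte(n_here, minc)
  }
})

test_that("randomly planted event scenarios are recovered exactly", {
  set.seed(9)
  for (rep in 1:5) {
    spec <- scenario_spec(cyclostome_orthology =
                            sample(c("alpha", "beta", "gamma"), 1),
                          species_per_subtype = 2L, n_columns = 30L,
                          seed = 500 + rep)
    tree <- build_scenario_tree(spec)
    labs <- rarphylo:::all_node_labels(tree)
    ntip <- length(tree$tip.label)
    # plant a 3-event path-consistent scenario: root S->A somewhere deep,
    # then a reversion below, plus an independent change elsewhere
    kid_of <- function(lab) {
      v <- match(lab, labs)
      kids <- tree$edge[tree$edge[, 1] == v, 2]
      labs[kids[1]]
    }
    deep <- labs[ntip + 2L]                     # first child clade of root
    ev <- data.frame(branch = c(deep, kid_of(deep), labs[1]),
                     position = c(232L, 232L, 270L),
                     from = c("S", "A", "I"), to = c("A", "S", "L"))
    sim <- simulate_alignment(tree, lg_model(), discrete_gamma(1, 2),
                              spec$n_columns, seed = 600 + rep)
    sim <- plant_pocket_events(sim, tree, spec = spec, events = ev)
    got <- infer_events(tree, sim$triplets)
    o <- order(got$branch, got$position)
    oe <- order(ev$branch, ev$position)
    expect_equal(got[o, c("branch", "position", "from", "to")],
                 ev[oe, ], ignore_attr = TRUE)
    expect_equal(got$reversion[got$to == "S"], TRUE)
  }
})

test_that("conflicting or ill-formed planted events are rejected", {
  spec <- scenario_spec(n_columns = 20L, seed = 2L)
  tree <- build_scenario_tree(spec)
  sim <- simulate_alignment(tree, lg_model(), discrete_gamma(1, 2), 20L,
                            seed = 3L)
  dup <- data.frame(branch = c("cyclo", "cyclo"), position = c(232L, 232L),
                    from = c("S", "S"), to = c("A", "G"))
  expect_error(plant_pocket_events(sim, tree, spec = spec, events = dup),
               "conflicting duplicate")
  bad <- data.frame(branch = "nowhere", position = 232L, from = "S",
                    to = "A")
  expect_error(plant_pocket_events(sim, tree, spec = spec, events = bad),
               "not in tree")
  wrongfrom <- data.frame(branch = "cyclo", position = 232L, from = "A",
                          to = "G")
  expect_error(plant_pocket_events(sim, tree, spec = spec,
                                   events = wrongfrom), "from")
})
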