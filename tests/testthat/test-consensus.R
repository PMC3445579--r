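test_that("consensus reproduces hand-counted bipartitions", {
  # identical inputs come back unchanged
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  s <- strict_consensus(list(t1, t1, t1))
  expect_equal(rf_distance(s, t1), 0)

  # total conflict on 4 taxa collapses to the star
  ts <- list(ape::read.tree(text = "((A,B),(C,D));"),
             ape::read.tree(text = "((A,C),(B,D));"))
  star <- strict_consensus(ts)
  expect_equal(ape::Nnode(ape::unroot(star)), 1)

  # clade {A,B} in 2 of 3 trees: majority keeps it at 2/3, strict drops it
  ts3 <- list(ape::read.tree(text = "((A,B),(C,D),E);"),
              ape::read.tree(text = "((A,B),C,(D,E));"),
              ape::read.tree(text = "((A,C),(B,D),E);"))
  s3 <- strict_consensus(ts3)
  expect_equal(ape::Nnode(ape::unroot(s3)), 1)
  m3 <- majority_consensus(ts3)
  keys <- tidy_consensus_keys(m3)
  expect_true(any(vapply(keys, function(k) setequal(k, c("C", "D", "E")) ||
                           setequal(k, c("A", "B")), TRUE)))
  expect_true(any(grepl("0.67", m3$node.label)))
})

test_that("consensus agrees with the ape oracle on random tree sets", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    trees <- lapply(1:4, function(i) {
      sim_character_matrix(n_taxa = 8, n_characters = 5, seed = seed * 10 + i)$tree
    })
    s <- strict_consensus(trees)
    sa <- ape::consensus(trees, p = 1)
    expect_equal(rf_distance(s, sa), 0)
    m <- majority_consensus(trees)
    ma <- ape::consensus(trees, p = 0.5)
    expect_equal(rf_distance(m, ma), 0)
  }
})

test_that("a split at exactly 50% is excluded from the majority consensus", {
  ts <- list(ape::read.tree(text = "((A,B),(C,D),E);"),
             ape::read.tree(text = "((A,C),(B,D),E);"))
  m <- majority_consensus(ts)
  expect_equal(ape::Nnode(ape::unroot(m)), 1) # both splits at exactly 0.5
})

test_that("differing leaf sets are rejected", {
  expect_error(strict_consensus(list(ape::read.tree(text = "((A,B),(C,D));"),
                                     ape::read.tree(text = "((A,B),(C,E));"))),
               class = "validation_error")
})

test_that("Robinson-Foulds distance matches the phangorn oracle", {
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    ta <- sim_character_matrix(n_taxa = 10, n_characters = 5, seed = seed)$tree
    tb <- sim_character_matrix(n_taxa = 10, n_characters = 5, seed = seed + 100)$tree
    ta$tip.label <- paste0("t", 1:10)
    tb$tip.label <- paste0("t", sample(1:10))
    expect_equal(rf_distance(ta, tb),
                 as.integer(phangorn::RF.dist(ta, tb)))
  }
})

test_that("bootstrap support behaves at its logical extremes", {
  # homoplasy-free matrix built directly from a known tree's bipartitions,
  # 15 clean binary characters per internal edge
  ref <- sim_character_matrix(n_taxa = 6, n_characters = 5, seed = 17)$tree
  splits <- tidy_tree_keys(ref)
  taxa <- sort(ref$tip.label)
  states <- do.call(cbind, lapply(splits, function(s) {
    matrix(rep(as.integer(taxa %in% s), 15), nrow = length(taxa))
  }))
  rownames(states) <- taxa
  cm <- character_matrix(states)

  # single replicate: all supports are 0 or 1
  bs1 <- bootstrap_support(cm, pipeline_config(rng_seed = 5, n_bootstrap = 1,
                                               n_random_additions = 5))
  expect_true(all(bs1$support %in% c(0, 1)))

  # clean signal: every true clade near-unanimously supported
  bs <- bootstrap_support(cm, pipeline_config(rng_seed = 6, n_bootstrap = 25,
                                              n_random_additions = 5))
  for (k in splits) {
    hit <- bs$support[vapply(strsplit(bs$clade, ";"), setequal, TRUE, y = k)]
    expect_true(length(hit) == 1 && hit >= 0.9)
  }

  # bootstrap is deterministic under seed
  bs2 <- bootstrap_support(cm, pipeline_config(rng_seed = 6, n_bootstrap = 25,
                                               n_random_additions = 5))
  expect_identical(bs, bs2)
})
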