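test_that("tree length reproduces hand-computed Fitch and ordered cases", {
  cm <- cm_from_strings(c(A = "0", B = "0", C = "1", D = "1"))
  expect_equal(tree_length(ape::read.tree(text = "((A,B),(C,D));"), cm), 1L)
  expect_equal(tree_length(ape::read.tree(text = "((A,C),(B,D));"), cm), 2L)

  # invariant character costs nothing on any tree
  cm0 <- cm_from_strings(c(A = "0", B = "0", C = "0", D = "0"))
  expect_equal(tree_length(ape::read.tree(text = "((A,B),(C,D));"), cm0), 0L)

  # ordered state pair {0,2} costs 2 on sisters; unordered costs 1
  cmo <- cm_from_strings(c(A = "0", B = "2", C = "0", D = "0"), ordered = 1L)
  cmu <- cm_from_strings(c(A = "0", B = "2", C = "0", D = "0"))
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(tree_length(tr, cmo), 2L)
  expect_equal(tree_length(tr, cmu), 1L)

  # missing entries contribute the full state set
  cmq <- cm_from_strings(c(A = "0", B = "?", C = "1", D = "1"))
  expect_equal(tree_length(ape::read.tree(text = "((A,B),(C,D));"), cmq), 1L)

  # leaf without a matrix row
  expect_error(tree_length(ape::read.tree(text = "((A,B),(C,E));"), cm),
               class = "validation_error")
})

test_that("unit-cost Sankoff equals Fitch on random trees and characters", {
  for (seed in 1:8) {
    sim <- sim_character_matrix(n_taxa = sample(5:9, 1), n_characters = 25,
                                n_states = sample(2:5, 1), rate = 0.6,
                                missing_fraction = 0.15, fraction_ordered = 0,
                                seed = seed)
    fitch <- tree_length(sim$tree, sim$matrix)
    sank <- tree_length(sim$tree, sim$matrix, force_sankoff = TRUE)
    expect_identical(fitch, sank)
  }
})

test_that("scoring agrees with the phangorn oracle for both cost regimes", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    sim <- sim_character_matrix(n_taxa = 8, n_characters = 20, n_states = 4,
                                rate = 0.5, missing_fraction = 0.1, seed = seed)
    sym <- ifelse(is.na(sim$matrix$states), "?",
                  as.character(sim$matrix$states))
    pd <- phangorn::phyDat(sym, type = "USER", levels = as.character(0:3),
                           ambiguity = "?")
    cmu <- character_matrix(sim$matrix$states, ordered = FALSE)
    expect_equal(tree_length(sim$tree, cmu),
                 as.integer(phangorn::parsimony(sim$tree, pd, method = "fitch")))
    cost <- outer(0:3, 0:3, function(a, b) abs(a - b))
    dimnames(cost) <- list(0:3, 0:3)
    cmo <- character_matrix(sim$matrix$states, ordered = TRUE)
    expect_equal(tree_length(sim$tree, cmo),
                 as.integer(phangorn::parsimony(sim$tree, pd,
                                                method = "sankoff", cost = cost)))
  }
})

test_that("multifurcating trees score exactly via the Sankoff pass", {
  cm <- cm_from_strings(c(A = "0", B = "0", C = "1", D = "1", E = "1"))
  # on the bush the hub takes the modal state 1, leaving two changes (= g);
  # resolving (A,B) recovers the single-origin scenario
  star <- ape::read.tree(text = "(A,B,C,D,E);")
  expect_equal(tree_length(star, cm), 2L)
  part <- ape::read.tree(text = "((A,B),C,D,E);")
  expect_equal(tree_length(part, cm), 1L)
})

test_that("per-character step bounds match their definitions", {
  # unordered [0,0,1,1,1]: m = 1, g = 5 - 3 = 2
  cm <- cm_from_strings(c(A = "0", B = "0", C = "1", D = "1", E = "1"))
  b <- character_step_bounds(cm)
  expect_equal(b$min_steps, 1L)
  expect_equal(b$max_steps, 2L)
  # ordered [0,1,2]: m = range = 2
  cmo <- cm_from_strings(c(A = "0", B = "1", C = "2"), ordered = 1L)
  expect_equal(character_step_bounds(cmo)$min_steps, 2L)
  # all-identical: m = g = 0, uninformative
  cmc <- cm_from_strings(c(A = "1", B = "1", C = "1"))
  bc <- character_step_bounds(cmc)
  expect_equal(bc$min_steps, 0L)
  expect_equal(bc$max_steps, 0L)
  expect_false(bc$informative)
  # all-missing column flagged uninformative with 0/0
  cmm <- cm_from_strings(c(A = "?", B = "?", C = "?"))
  bm <- character_step_bounds(cmm)
  expect_equal(bm$min_steps, 0L)
  expect_equal(bm$max_steps, 0L)
})

test_that("ordered max-steps equals the star-tree optimum by enumeration", {
  # independent oracle: brute-force the best hub state on the bush
  set.seed(31)
  for (i in 1:20) {
    x <- sample(0:4, sample(3:8, 1), replace = TRUE)
    cm <- character_matrix(matrix(x, ncol = 1,
                                  dimnames = list(paste0("t", seq_along(x)), NULL)),
                          ordered = TRUE)
    oracle <- min(vapply(0:4, function(s) sum(abs(x - s)), 0))
    expect_equal(character_step_bounds(cm)$max_steps, as.integer(oracle))
  }
})

test_that("tree length is bracketed by the step-bound sums", {
  for (seed in 1:6) {
    sim <- sim_character_matrix(n_taxa = 7, n_characters = 30, n_states = 4,
                                rate = 0.8, fraction_ordered = 0.3,
                                missing_fraction = 0.1, seed = seed)
    b <- character_step_bounds(sim$matrix)
    len <- tree_length(sim$tree, sim$matrix)
    expect_gte(len, sum(b$min_steps))
    expect_lte(len, sum(b$max_steps))
  }
})

test_that("ensemble indices satisfy their definitions and identities", {
  sim <- sim_character_matrix(n_taxa = 8, n_characters = 40, rate = 0.5,
                              seed = 2)
  len <- tree_length(sim$tree, sim$matrix)
  idx <- ensemble_indices(len, sim$matrix)
  b <- character_step_bounds(sim$matrix)
  expect_equal(idx$ci, sum(b$min_steps) / len, tolerance = 1e-12)
  expect_equal(idx$ri, (sum(b$max_steps) - len) /
                 (sum(b$max_steps) - sum(b$min_steps)), tolerance = 1e-12)
  expect_equal(idx$rc, idx$ci * idx$ri, tolerance = 1e-12)
  # homoplasy-free limit: all three indices are 1
  cm <- cm_from_strings(c(A = "00", B = "00", C = "11", D = "11"))
  idx1 <- ensemble_indices(2L, cm)
  expect_equal(unlist(idx1), c(ci = 1, ri = 1, rc = 1))
  # no informative variation: RI undefined
  cmc <- cm_from_strings(c(A = "0", B = "0", C = "0", D = "0"))
  expect_error(ensemble_indices(0L, cmc), class = "undefined_ri_error")
})
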