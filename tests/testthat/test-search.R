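test_that("heuristic search matches exhaustive enumeration on small matrices", {
  for (seed in 1:10) {
    sim <- sim_character_matrix(n_taxa = sample(5:6, 1), n_characters = 10,
                                n_states = sample(2:4, 1), rate = 0.7,
                                fraction_ordered = 0.3, missing_fraction = 0.1,
                                seed = seed)
    heur <- suppressWarnings(
      parsimony_search(sim$matrix, pipeline_config(rng_seed = seed,
                                                   n_random_additions = 3)))
    exact <- exhaustive_search(sim$matrix)
    expect_equal(heur$length, exact$length)
  }
})

test_that("homoplasy-free simulation yields the generating tree as sole MPT", {
  sim <- sim_character_matrix(n_taxa = 5, n_characters = 40, rate = 0.05,
                              fraction_ordered = 0, seed = 12)
  b <- character_step_bounds(sim$matrix)
  exact <- exhaustive_search(sim$matrix)
  # low rate gives little homoplasy; length should be near the Farris floor
  heur <- parsimony_search(sim$matrix, pipeline_config(rng_seed = 1,
                                                       n_random_additions = 3))
  expect_equal(heur$length, exact$length)
  if (exact$length == sum(b$min_steps) && length(exact$mpt_set) == 1) {
    expect_equal(rf_distance(heur$mpt_set[[1]], sim$tree), 0)
  }
})

test_that("equally supported resolutions are all collected in the MPT pool", {
  # char 1 supports AB|CD, char 2 supports AC|BD, equally (3 steps each;
  # the third resolution AD|BC costs 4)
  cm <- cm_from_strings(c(A = "00", B = "01", C = "10", D = "11"))
  res <- parsimony_search(cm, pipeline_config(rng_seed = 3,
                                              n_random_additions = 5))
  exact <- exhaustive_search(cm)
  expect_equal(res$length, exact$length)
  expect_equal(length(res$mpt_set), 2) # the two tied resolutions
  expect_equal(length(exact$mpt_set), 2)
  # strict consensus of total conflict is the star tree
  expect_equal(ape::Nnode(res$strict_consensus), 1)
})

test_that("search is deterministic under a fixed seed", {
  sim <- sim_character_matrix(n_taxa = 8, n_characters = 30, rate = 0.4,
                              seed = 9)
  cfg <- pipeline_config(rng_seed = 123, n_random_additions = 3)
  r1 <- parsimony_search(sim$matrix, cfg)
  r2 <- parsimony_search(sim$matrix, cfg)
  expect_equal(r1$length, r2$length)
  expect_identical(lapply(r1$mpt_set, ape::write.tree),
                   lapply(r2$mpt_set, ape::write.tree))
})

test_that("the MPT pool cap truncates with a warning", {
  # 6-taxon all-missing-but-one-char matrix has many ties
  cm <- cm_from_strings(c(A = "0", B = "0", C = "0", D = "1", E = "1", F = "1"))
  expect_warning(
    res <- parsimony_search(cm, pipeline_config(rng_seed = 1,
                                                n_random_additions = 2,
                                                max_saved_trees = 3)),
    "truncated")
  expect_true(res$truncated)
  expect_lte(length(res$mpt_set), 3)
})

test_that("glance and tidy summarize a parsimony result", {
  sim <- sim_character_matrix(n_taxa = 6, n_characters = 25, seed = 4)
  res <- parsimony_search(sim$matrix, pipeline_config(rng_seed = 4,
                                                      n_random_additions = 2))
  gl <- glance(res)
  expect_identical(names(gl), c("n_mpt", "length", "ci", "ri", "rc", "truncated"))
  expect_equal(gl$rc, gl$ci * gl$ri, tolerance = 1e-12)
  td <- tidy(res)
  expect_true(all(td$frequency > 0.5))
})
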