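# Consensus trees by direct bipartition counting.
#
# Strict consensus keeps exactly the bipartitions present in every input
# tree; majority-rule keeps those in strictly more than the threshold
# fraction (default > 50%; a split at exactly 50% is excluded). Splits
# selected by either rule are pairwise compatible, so the consensus tree is
# built by nesting clades directly.

# Count bipartition keys across a list of utrees.
count_bipartitions <- function(utrees) {
  tab <- table(unlist(lapply(utrees, utree_bipartitions)))
  if (!length(tab)) return(numeric(0))
  setNames(as.numeric(tab) / length(utrees), names(tab))
}

# Build a consensus phylo from selected bipartition keys over a label set.
# keys are "\r"-joined label sets on the side away from the reference label.
consensus_tree_from_keys <- function(keys, labels, frequencies = NULL) {
  clades <- lapply(keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1]])
  sizes <- lengths(clades)
  ord <- order(-sizes)
  clades <- clades[ord]
  freq <- if (!is.null(frequencies)) frequencies[ord] else NULL
  # nodes: clade index 0 = root (all labels)
  parent <- integer(length(clades))
  root_set <- labels
  for (i in seq_along(clades)) {
    parent[i] <- 0L
    if (i > 1) {
      for (j in (i - 1):1) {
        if (all(clades[[i]] %in% clades[[j]])) { parent[i] <- j; break }
      }
    }
  }
  esc <- function(x) gsub("[ ,;:()\\[\\]]", "_", x)
  build <- function(node, members) {
    kids <- which(parent == node)
    claimed <- character(0)
    parts <- character(0)
    for (kd in kids) {
      parts <- c(parts, build(kd, clades[[kd]]))
      claimed <- c(claimed, clades[[kd]])
    }
    solo <- setdiff(members, claimed)
    parts <- c(parts, esc(solo))
    lab <- if (!is.null(freq) && node > 0) {
      formatC(freq[node], format = "f", digits = 2)
    } else {
      ""
    }
    if (node == 0L) {
      paste0("(", paste(parts, collapse = ","), ");")
    } else {
      paste0("(", paste(parts, collapse = ","), ")", lab)
    }
  }
  tree <- ape::read.tree(text = build(0L, root_set))
  fr <- if (!is.null(freq)) setNames(freq, keys[ord]) else setNames(rep(1, length(keys)), keys[ord])
  list(tree = tree, frequencies = fr)
}

consensus_from_utrees <- function(utrees, threshold = 0.5) {
  labels <- utrees[[1]]$labels
  freq <- count_bipartitions(utrees)
  if (threshold >= 1) {
    keep <- names(freq)[freq >= 1]
    fr <- freq[keep]
  } else {
    keep <- names(freq)[freq > threshold]
    fr <- freq[keep]
  }
  consensus_tree_from_keys(keep, labels, frequencies = unname(fr))
}

check_same_leafset <- function(trees) {
  if (!length(trees)) stop_input("need >= 1 tree", "validation_error")
  labs <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(labs)[-1]) {
    if (!identical(labs[[i]], labs[[1]])) {
      stop_input("input trees have differing leaf sets", "validation_error")
    }
  }
}

#' Strict consensus tree
#'
#' The (possibly multifurcating) tree whose internal edges are exactly the
#' bipartitions shared by all input trees.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`) over one leaf
#'   set.
#' @return A `phylo`.
#' @export
#' @examples
#' ts <- list(ape::read.tree(text = "((A,B),(C,D),E);"),
#'            ape::read.tree(text = "((A,B),C,(D,E));"))
#' strict_consensus(ts)
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  check_same_leafset(trees)
  consensus_from_utrees(lapply(trees, phylo_to_utree), threshold = 1)$tree
}

#' Majority-rule consensus tree
#'
#' Keeps the bipartitions occurring in strictly more than `threshold` of the
#' input trees (so a split in exactly half of them is excluded at the default
#' 0.5), annotated with their frequencies as node labels.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @param threshold Frequency threshold (default 0.5; splits must exceed it).
#' @return A `phylo` with node labels giving each retained clade's frequency.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  check_same_leafset(trees)
  if (threshold < 0.5 || threshold >= 1) {
    stop_input("`threshold` must be in [0.5, 1)", "validation_error")
  }
  consensus_from_utrees(lapply(trees, phylo_to_utree), threshold = threshold)$tree
}

#' Nonparametric bootstrap clade support
#'
#' Resamples character columns with replacement (keeping the character
#' count), reruns a reduced heuristic search on each pseudoreplicate, takes
#' the majority-rule consensus of its shortest trees, and reports for every
#' clade the fraction of replicates whose consensus contains it.
#' Deterministic under `cfg$rng_seed` (per-replicate seeds are derived by a
#' fixed splitting rule).
#'
#' @param matrix A [character_matrix()].
#' @param cfg A [pipeline_config()]; `cfg$n_bootstrap` replicates are run,
#'   each with a search reduced to
#'   `max(1, ceiling(cfg$n_random_additions / 5))` random additions.
#' @return A tibble with columns `clade` (semicolon-joined taxon labels on
#'   the side away from the alphabetically first taxon) and `support`.
#' @export
bootstrap_support <- function(matrix, cfg = pipeline_config()) {
  stopifnot(inherits(matrix, "character_matrix"))
  B <- cfg$n_bootstrap
  if (B < 1) stop_input("need n_bootstrap >= 1", "validation_error")
  cm <- matrix
  if (length(cfg$ordered_characters)) {
    cm <- character_matrix(matrix$states, ordered = cfg$ordered_characters,
                           outgroup = matrix$outgroup)
  }
  seeds <- derive_seeds(cfg$rng_seed, B, stream = 7L)
  sub_cfg <- pipeline_config(
    rng_seed = 1L, # overwritten per replicate
    n_random_additions = max(1L, ceiling(cfg$n_random_additions / 5)),
    max_saved_trees = min(cfg$max_saved_trees, 100L)
  )
  counts <- new.env(parent = emptyenv())
  nch <- ncol(cm$states)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[b], sample.int(nch, nch, replace = TRUE))
    bm <- character_matrix(
      matrix(cm$states[, idx], nrow = nrow(cm$states),
             dimnames = list(cm$taxa, NULL)),
      ordered = cm$ordered[idx], outgroup = cm$outgroup
    )
    rep_cfg <- sub_cfg
    rep_cfg$rng_seed <- seeds[b]
    res <- suppressWarnings(parsimony_search(bm, rep_cfg))
    keys <- names(res$majority_frequencies)
    for (k in keys) {
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  tibble::tibble(
    clade = vapply(keys, function(k) {
      paste(strsplit(k, "\r", fixed = TRUE)[[1]], collapse = ";")
    }, ""),
    support = vapply(keys, function(k) counts[[k]] / B, 0)
  ) |> dplyr::arrange(dplyr::desc(.data$support))
}
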