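# Heuristic and exhaustive maximum-parsimony search.
#
# The heuristic is seeded stepwise random addition followed by SPR
# hill-climbing, with a deduplicated pool of equally shortest trees
# (capped). This deliberately replaces heavyweight metaheuristics (sectorial
# search, ratchet, drift, tree fusion): at desk scale SPR search plus the
# exhaustive-enumeration oracle on small instances gives verifiable
# correctness, which is the goal here.

# -- elementary utree edits --------------------------------------------------

# Insert leaf `leaf` (with fresh internal id `newnode`) into edge row i.
insert_leaf <- function(tree, i, leaf, newnode) {
  x <- tree$edge[i, 1]; y <- tree$edge[i, 2]
  edge <- rbind(tree$edge[-i, , drop = FALSE],
                c(x, newnode), c(newnode, y), c(newnode, leaf))
  utree(edge, tree$ntip, tree$labels)
}

# All SPR neighbours of an unrooted binary utree (as a list of utrees).
spr_neighbors <- function(tree) {
  edge <- tree$edge
  ne <- nrow(edge)
  maxid <- max(edge)
  adj <- vector("list", maxid)
  for (i in seq_len(ne)) {
    a <- edge[i, 1]; b <- edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  res <- list()
  for (i in seq_len(ne)) {
    for (dir in 1:2) {
      u <- edge[i, dir]; v <- edge[i, 3 - dir]
      # prune the component on the v side; u must be internal so the
      # remaining component can absorb it
      if (u <= tree$ntip) next
      # nodes on v side (DFS avoiding u)
      inV <- logical(maxid)
      stack <- v; inV[v] <- TRUE
      while (length(stack)) {
        w <- stack[length(stack)]; stack <- stack[-length(stack)]
        for (z in adj[[w]]) {
          if (z != u && !inV[z]) { inV[z] <- TRUE; stack <- c(stack, z) }
        }
      }
      # suppress u: fuse its two remaining neighbours a, b
      nb <- setdiff(adj[[u]], v)
      if (length(nb) != 2) next
      a <- nb[1]; b <- nb[2]
      keep <- !(inV[edge[, 1]] | inV[edge[, 2]])
      keep[i] <- FALSE
      rem <- edge[keep & !((edge[, 1] == u) | (edge[, 2] == u)), , drop = FALSE]
      rem <- rbind(rem, c(a, b))
      sub <- edge[inV[edge[, 1]] & inV[edge[, 2]], , drop = FALSE]
      if (nrow(rem) < 2) next
      for (r in seq_len(nrow(rem))) {
        x <- rem[r, 1]; y <- rem[r, 2]
        if ((x == a && y == b) || (x == b && y == a)) next # original position
        newedge <- rbind(rem[-r, , drop = FALSE],
                         c(x, u), c(u, y), c(u, v), sub)
        res[[length(res) + 1]] <- utree(newedge, tree$ntip, tree$labels)
      }
    }
  }
  res
}

# Stepwise random-addition starting tree under the current RNG state.
random_addition_tree <- function(cm, taxa_order = sample(length(cm$taxa))) {
  n <- length(cm$taxa)
  labels <- cm$taxa
  t3 <- taxa_order[1:3]
  tree <- utree(cbind(rep(n + 1L, 3), t3), n, labels)
  nextnode <- n + 2L
  if (n > 3) {
    for (idx in 4:n) {
      leaf <- taxa_order[idx]
      best <- NULL; bestlen <- Inf
      for (i in seq_len(nrow(tree$edge))) {
        cand <- insert_leaf(tree, i, leaf, nextnode)
        len <- score_utree(cand, cm)
        if (len < bestlen) { bestlen <- len; best <- list(cand) }
        else if (len == bestlen) best <- c(best, list(cand))
      }
      tree <- best[[sample.int(length(best), 1)]]
      nextnode <- nextnode + 1L
    }
  }
  tree
}

# SPR hill climb: move to strictly shorter neighbours until a local optimum.
spr_climb <- function(tree, cm) {
  len <- score_utree(tree, cm)
  repeat {
    nb <- spr_neighbors(tree)
    if (!length(nb)) break
    lens <- vapply(nb, score_utree, 0L, cm = cm)
    if (min(lens) < len) {
      best <- which(lens == min(lens))
      tree <- nb[[best[sample.int(length(best), 1)]]]
      len <- min(lens)
    } else {
      break
    }
  }
  list(tree = tree, length = len)
}

# Expand a pool of equal-length trees by equal-length SPR neighbours until
# closure or the cap. Returns list(trees, truncated).
expand_plateau <- function(pool, len, cm, cap) {
  keys <- vapply(pool, utree_key, "")
  ord <- order(keys)
  pool <- pool[ord]; keys <- keys[ord]
  queue <- seq_along(pool)
  truncated <- FALSE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    if (length(pool) >= cap) { truncated <- TRUE; break }
    nb <- spr_neighbors(pool[[i]])
    lens <- vapply(nb, score_utree, 0L, cm = cm)
    for (j in which(lens == len)) {
      k <- utree_key(nb[[j]])
      if (!k %in% keys) {
        pool <- c(pool, nb[j])
        keys <- c(keys, k)
        queue <- c(queue, length(pool))
        if (length(pool) >= cap) { truncated <- TRUE; break }
      }
    }
    # a strictly shorter neighbour should not occur here (pool members are
    # local optima or plateau members reached from one); guard anyway
    if (any(lens < len)) {
      return(list(trees = nb[which.min(lens)], length = min(lens),
                  truncated = FALSE, restart = TRUE))
    }
  }
  list(trees = pool, length = len, truncated = truncated, restart = FALSE)
}

#' Heuristic maximum-parsimony search
#'
#' For each of `cfg$n_random_additions` seeded replicates, builds a stepwise
#' random-addition starting tree and hill-climbs with SPR moves; the pool of
#' equally shortest trees found across replicates is then closed under
#' equal-length SPR moves, deduplicated by unrooted topology and capped at
#' `cfg$max_saved_trees`. Deterministic under `cfg$rng_seed`.
#'
#' @param matrix A [character_matrix()].
#' @param cfg A [pipeline_config()]; the matrix's own ordered flags are used
#'   unless `cfg$ordered_characters` is non-empty, in which case those
#'   indices override.
#' @return A `parsimony_result`: list with `mpt_set` (list of `phylo`),
#'   `length`, `ci`, `ri`, `rc`, `truncated`, plus `strict_consensus` and
#'   `majority_consensus` trees.
#' @export
#' @examples
#' sim <- sim_character_matrix(n_taxa = 6, n_characters = 30, seed = 1)
#' res <- parsimony_search(sim$matrix, pipeline_config(rng_seed = 1,
#'                                                     n_random_additions = 2))
#' glance(res)
parsimony_search <- function(matrix, cfg = pipeline_config()) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(matrix$taxa) < 4) stop_input("need >= 4 taxa", "validation_error")
  cm <- matrix
  if (length(cfg$ordered_characters)) {
    cm <- character_matrix(matrix$states, ordered = cfg$ordered_characters,
                           outgroup = matrix$outgroup)
  }
  seeds <- derive_seeds(cfg$rng_seed, cfg$n_random_additions, stream = 1L)
  best_len <- Inf
  pool <- list()
  keys <- character(0)
  for (r in seq_len(cfg$n_random_additions)) {
    res <- with_seed(seeds[r], {
      start <- random_addition_tree(cm)
      spr_climb(start, cm)
    })
    if (res$length < best_len) {
      best_len <- res$length
      pool <- list(res$tree)
      keys <- utree_key(res$tree)
    } else if (res$length == best_len) {
      k <- utree_key(res$tree)
      if (!k %in% keys) {
        pool <- c(pool, list(res$tree))
        keys <- c(keys, k)
      }
    }
  }
  # plateau closure (collect additional MPTs at the best length)
  repeat {
    ex <- with_seed(derive_seeds(cfg$rng_seed, 1, stream = 2L),
                    expand_plateau(pool, best_len, cm, cfg$max_saved_trees))
    if (ex$restart) {
      pool <- ex$trees; best_len <- ex$length
    } else {
      pool <- ex$trees
      break
    }
  }
  if (ex$truncated) {
    warn(sprintf("MPT pool truncated at cap %d; distinct MPT count is >= %d",
                 cfg$max_saved_trees, length(pool)))
  }
  build_parsimony_result(pool, best_len, cm, truncated = ex$truncated)
}

build_parsimony_result <- function(pool, len, cm, truncated = FALSE) {
  mpts <- lapply(pool, utree_to_phylo)
  idx <- ensemble_indices(len, cm)
  strict <- consensus_from_utrees(pool, threshold = 1)
  maj <- consensus_from_utrees(pool, threshold = 0.5)
  structure(
    list(mpt_set = mpts, length = as.integer(len),
         ci = idx$ci, ri = idx$ri, rc = idx$rc,
         truncated = truncated,
         strict_consensus = strict$tree,
         majority_consensus = maj$tree,
         majority_frequencies = maj$frequencies,
         matrix = cm),
    class = "parsimony_result"
  )
}

#' Exhaustive maximum-parsimony search
#'
#' Enumerates every unrooted binary topology (3, 15, 105, 945 for 4..7 taxa)
#' and scores each; the independent oracle for the heuristic search on small
#' instances.
#'
#' @param matrix A [character_matrix()] with 4..8 taxa.
#' @return A `parsimony_result` whose `mpt_set` is provably complete.
#' @export
exhaustive_search <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  n <- length(matrix$taxa)
  if (n < 4 || n > 8) stop_input("exhaustive search supports 4..8 taxa", "validation_error")
  topos <- enumerate_topologies(n, matrix$taxa)
  lens <- vapply(topos, score_utree, 0L, cm = matrix)
  best <- min(lens)
  build_parsimony_result(topos[lens == best], best, matrix)
}

# All unrooted binary topologies over the given labels.
enumerate_topologies <- function(n, labels) {
  base <- utree(cbind(rep(n + 1L, 3), 1:3), n, labels)
  trees <- list(base)
  if (n > 3) {
    for (leaf in 4:n) {
      newnode <- n + leaf - 2L
      trees <- unlist(lapply(trees, function(tr) {
        lapply(seq_len(nrow(tr$edge)), function(i) {
          insert_leaf(tr, i, as.integer(leaf), as.integer(newnode))
        })
      }), recursive = FALSE)
    }
  }
  trees
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("<parsimony_result> %d MPT(s)%s, length = %d\n",
              length(x$mpt_set), if (x$truncated) " (pool truncated)" else "",
              x$length))
  cat(sprintf("  CI = %.3f  RI = %.3f  RC = %.3f\n", x$ci, x$ri, x$rc))
  invisible(x)
}

#' @rdname parsimony_search
#' @param x,object A `parsimony_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.parsimony_result <- function(x, ...) {
  tibble::tibble(
    n_mpt = length(x$mpt_set),
    length = x$length,
    ci = x$ci, ri = x$ri, rc = x$rc,
    truncated = x$truncated
  )
}

#' @rdname parsimony_search
#' @exportS3Method generics::tidy
tidy.parsimony_result <- function(x, ...) {
  freq <- x$majority_frequencies
  tibble::tibble(
    clade = names(freq) %||% character(0),
    frequency = as.numeric(freq)
  )
}

#' @rdname parsimony_search
#' @export
plot.parsimony_result <- function(x, ...) {
  ape::plot.phylo(x$strict_consensus, ...)
  invisible(x)
}
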