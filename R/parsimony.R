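# Parsimony scoring and ensemble indices.
#
# Unordered characters are scored with unit cost between distinct states
# (Fitch counting); ordered characters with linear cost |i - j| on the
# integer state scale (transformational sequences), via the Sankoff dynamic
# programme. Missing entries contribute the full state set. A generalized
# Sankoff pass (exact on multifurcating trees and for both cost regimes)
# backs the fast bit-parallel Fitch path used on binary trees.

# Fitch length on a rooted orientation of a binary utree, vectorized across
# characters with state bitmasks. leaf_masks: (maxid x nchar) integer matrix,
# rows >ntip uninitialized.
fitch_pass <- function(ori, ntip, leaf_masks) {
  masks <- leaf_masks
  total <- numeric(ncol(leaf_masks))
  for (v in ori$postorder) {
    if (v > ntip) {
      kids <- ori$children[[v]]
      acc <- masks[kids[1], ]
      for (w in kids[-1]) {
        inter <- bitwAnd(acc, masks[w, ])
        hit <- inter != 0L
        acc <- ifelse(hit, inter, bitwOr(acc, masks[w, ]))
        total <- total + !hit
      }
      masks[v, ] <- acc
    }
  }
  total
}

# Generalized Sankoff: returns total minimum cost summed over characters.
# S: (ntaxa_in_matrix x nchar) integer states with NA missing, already
# restricted to the characters being scored. leaf_rows: matrix row for each
# leaf id. ordered: single logical (all chars in this call share the regime).
sankoff_pass <- function(ori, ntip, S, leaf_rows, k, ordered) {
  nch <- ncol(S)
  maxid <- ori$maxid
  INF <- 1e9
  # cost arrays stored in a list indexed by node id
  cost <- vector("list", maxid)
  for (v in ori$postorder) {
    if (v <= ntip) {
      st <- S[leaf_rows[v], ]
      C <- matrix(INF, k, nch)
      miss <- is.na(st)
      if (any(miss)) C[, miss] <- 0
      obs <- which(!miss)
      if (length(obs)) C[cbind(st[obs] + 1L, obs)] <- 0
      cost[[v]] <- C
    } else {
      C <- matrix(0, k, nch)
      for (w in ori$children[[v]]) {
        Cw <- cost[[w]]
        if (ordered) {
          # min-plus convolution with |i-j| kernel: forward/backward sweeps
          m1 <- Cw
          if (k > 1) for (r in 2:k) m1[r, ] <- pmin(m1[r, ], m1[r - 1, ] + 1)
          m2 <- Cw
          if (k > 1) for (r in (k - 1):1) m2[r, ] <- pmin(m2[r, ], m2[r + 1, ] + 1)
          C <- C + pmin(m1, m2)
        } else {
          cmin <- Cw[1, ]
          if (k > 1) for (r in 2:k) cmin <- pmin(cmin, Cw[r, ])
          C <- C + pmin(Cw, rep(cmin + 1, each = k))
        }
        cost[w] <- list(NULL) # free child storage without shifting indices
      }
      cost[[v]] <- C
    }
  }
  Cr <- cost[[ori$root]]
  rmin <- Cr[1, ]
  if (k > 1) for (r in 2:k) rmin <- pmin(rmin, Cr[r, ])
  sum(rmin)
}

# Score a utree against a character_matrix. Uses bit-Fitch for unordered
# characters on binary trees, Sankoff otherwise.
score_utree <- function(tree, cm, force_sankoff = FALSE) {
  leaf_rows <- match(tree$labels, cm$taxa)
  if (anyNA(leaf_rows)) {
    stop_input(paste0("tree leaf without a matrix row: ",
                      tree$labels[which(is.na(leaf_rows))[1]]), "validation_error")
  }
  S <- cm$states
  k <- if (any(!is.na(S))) max(2L, max(S, na.rm = TRUE) + 1L) else 2L
  ori <- orient_utree(tree)
  binary <- nrow(tree$edge) == 2L * tree$ntip - 3L
  total <- 0
  uno <- which(!cm$ordered)
  ord <- which(cm$ordered)
  if (length(uno)) {
    if (binary && !force_sankoff) {
      full <- bitwShiftL(1L, k) - 1L
      leaf_masks <- matrix(0L, ori$maxid, length(uno))
      st <- S[, uno, drop = FALSE]
      for (v in seq_len(tree$ntip)) {
        sv <- st[leaf_rows[v], ]
        leaf_masks[v, ] <- ifelse(is.na(sv), full, bitwShiftL(1L, sv))
      }
      total <- total + sum(fitch_pass(ori, tree$ntip, leaf_masks))
    } else {
      total <- total + sankoff_pass(ori, tree$ntip, S[, uno, drop = FALSE],
                                    leaf_rows, k, ordered = FALSE)
    }
  }
  if (length(ord)) {
    total <- total + sankoff_pass(ori, tree$ntip, S[, ord, drop = FALSE],
                                  leaf_rows, k, ordered = TRUE)
  }
  as.integer(round(total))
}

#' Parsimony length of a tree
#'
#' Minimum number of character-state changes required by `tree` under the
#' matrix's scoring regime: unit cost between distinct states for unordered
#' characters (Fitch), linear cost `|i - j|` for ordered characters
#' (Sankoff). Missing entries contribute the full state set. Multifurcating
#' trees are scored exactly via the Sankoff pass.
#'
#' @param tree A `phylo` whose tip labels all occur in `matrix`.
#' @param matrix A [character_matrix()].
#' @param force_sankoff Score unordered characters with unit-cost Sankoff
#'   even on binary trees (used to cross-check the Fitch path).
#' @return Integer number of steps.
#' @export
#' @examples
#' cm <- character_matrix(
#'   matrix(c(0L, 0L, 1L, 1L), 4, 1, dimnames = list(LETTERS[1:4], NULL)))
#' tree_length(ape::read.tree(text = "((A,B),(C,D));"), cm) # 1
tree_length <- function(tree, matrix, force_sankoff = FALSE) {
  stopifnot(inherits(matrix, "character_matrix"))
  score_utree(phylo_to_utree(tree), matrix, force_sankoff = force_sankoff)
}

#' Per-character minimum and maximum steps
#'
#' Farris components of the ensemble indices. For a character column:
#' minimum steps `m` is the number of changes on the best conceivable tree
#' (unordered: observed states minus one; ordered: observed state range) and
#' maximum steps `g` the changes on the completely unresolved bush
#' (unordered: scored taxa minus the modal state frequency; ordered: the
#' minimized sum of absolute deviations from a median state). All-missing
#' columns score 0/0 and are flagged uninformative.
#'
#' @param matrix A [character_matrix()].
#' @return A tibble with one row per character: `character`, `ordered`,
#'   `min_steps`, `max_steps`, `informative` (`max_steps > min_steps`... a
#'   character is parsimony-uninformative when no tree can differ from the
#'   best, i.e. `g == m`).
#' @export
character_step_bounds <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  S <- matrix$states
  n <- ncol(S)
  m <- integer(n)
  g <- integer(n)
  for (j in seq_len(n)) {
    x <- S[, j]
    x <- x[!is.na(x)]
    if (!length(x)) {
      m[j] <- 0L; g[j] <- 0L
      next
    }
    if (matrix$ordered[j]) {
      m[j] <- max(x) - min(x)
      g[j] <- min(vapply(min(x):max(x), function(s) sum(abs(x - s)), 0))
    } else {
      tab <- table(x)
      m[j] <- length(tab) - 1L
      g[j] <- length(x) - max(tab)
    }
  }
  tibble::tibble(
    character = seq_len(n),
    ordered = matrix$ordered,
    min_steps = m,
    max_steps = g,
    informative = g > m
  )
}

#' Ensemble consistency, retention and rescaled consistency indices
#'
#' With `L` the tree length and per-character Farris components `m`
#' (minimum steps) and `g` (maximum steps): `CI = sum(m) / L`,
#' `RI = (sum(g) - L) / (sum(g) - sum(m))`, `RC = CI * RI`. By default all
#' characters are included (common TNT-style reporting); set
#' `include_uninformative = FALSE` to restrict the sums to
#' parsimony-informative characters.
#'
#' @param length Tree length in steps.
#' @param matrix A [character_matrix()].
#' @param include_uninformative Include uninformative characters in the sums
#'   (default TRUE).
#' @return A tibble with columns `ci`, `ri`, `rc` (unrounded; reports use 3
#'   decimals).
#' @export
#' @examples
#' cm <- character_matrix(
#'   matrix(c(0L, 0L, 1L, 1L), 4, 1, dimnames = list(LETTERS[1:4], NULL)))
#' ensemble_indices(1L, cm) # homoplasy-free: CI = RI = RC = 1
ensemble_indices <- function(length, matrix, include_uninformative = TRUE) {
  b <- character_step_bounds(matrix)
  if (!include_uninformative) {
    # uninformative characters realize exactly their minimum on every tree,
    # so their steps are removed from the length as well as from the sums
    length <- length - sum(b$min_steps[!b$informative])
    b <- b[b$informative, ]
  }
  sm <- sum(b$min_steps)
  sg <- sum(b$max_steps)
  if (length < sm) {
    stop_input("tree length below the sum of per-character minima", "domain_error")
  }
  if (sg == sm) {
    stop_input("no informative variation: retention index undefined",
               "undefined_ri_error")
  }
  ci <- sm / length
  ri <- (sg - length) / (sg - sm)
  tibble::tibble(ci = ci, ri = ri, rc = ci * ri)
}
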