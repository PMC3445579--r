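# Tree plumbing.
#
# Trees cross the package boundary as ape "phylo" objects (Newick on disk,
# unrooted semantics, no branch lengths required). Internally the parsimony
# engine uses a lighter representation ("utree"): an undirected edge matrix
# over node ids where leaves are 1..ntip (indexing a label vector) and
# internal nodes have ids > ntip. Every internal node of an unrooted binary
# utree has degree 3.

utree <- function(edge, ntip, labels) {
  storage.mode(edge) <- "integer"
  list(edge = edge, ntip = as.integer(ntip), labels = labels)
}

# Rooted orientation of a utree: children list + postorder node sequence.
# Root defaults to the first internal node encountered.
orient_utree <- function(tree, root = NULL) {
  edge <- tree$edge
  maxid <- max(edge)
  adj <- vector("list", maxid)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1]; b <- edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  if (is.null(root)) {
    deg <- lengths(adj)
    root <- which(deg > 1)[1]
    if (is.na(root)) root <- 1L # two-leaf tree
  }
  children <- vector("list", maxid)
  order <- integer(0)
  # iterative DFS
  stack <- c(root)
  parent <- integer(maxid)
  visited <- logical(maxid)
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visited[v] <- TRUE
    out <- c(out, v)
    for (w in adj[[v]]) {
      if (!visited[w]) {
        parent[w] <- v
        children[[v]] <- c(children[[v]], w)
        stack <- c(stack, w)
        visited[w] <- TRUE
      }
    }
  }
  list(children = children, postorder = rev(out), root = root, maxid = maxid)
}

# Leaf sets below each node under a rooted orientation; list indexed by node.
node_leafsets <- function(tree, ori = orient_utree(tree)) {
  sets <- vector("list", ori$maxid)
  for (v in ori$postorder) {
    if (v <= tree$ntip) {
      sets[[v]] <- v
    } else {
      sets[[v]] <- sort(unlist(lapply(ori$children[[v]], function(w) sets[[w]])))
    }
  }
  sets
}

# Non-trivial bipartitions as canonical keys: each internal edge yields the
# leaf-label set on the side not containing the alphabetically first label.
# Returns a character vector of keys.
utree_bipartitions <- function(tree) {
  ntip <- tree$ntip
  if (ntip < 4) return(character(0))
  ori <- orient_utree(tree)
  sets <- node_leafsets(tree, ori)
  ref <- tree$labels[order(tree$labels)][1]
  keys <- character(0)
  for (v in ori$postorder) {
    if (v > ntip && v != ori$root) {
      s <- sets[[v]]
      if (length(s) >= 2 && length(s) <= ntip - 2) {
        labs <- tree$labels[s]
        if (ref %in% labs) labs <- setdiff(tree$labels, labs)
        keys <- c(keys, paste(sort(labs), collapse = "\r"))
      }
    }
  }
  unique(keys)
}

# Canonical topology key for deduplication.
utree_key <- function(tree) {
  paste(sort(utree_bipartitions(tree)), collapse = "|")
}

# ---- conversions -----------------------------------------------------------

utree_to_newick <- function(tree) {
  ori <- orient_utree(tree)
  build <- function(v) {
    if (v <= tree$ntip) {
      gsub("[ ,;:()\\[\\]]", "_", tree$labels[v])
    } else {
      paste0("(", paste(vapply(ori$children[[v]], build, ""), collapse = ","), ")")
    }
  }
  paste0(build(ori$root), ";")
}

utree_to_phylo <- function(tree) {
  ape::read.tree(text = utree_to_newick(tree))
}

phylo_to_utree <- function(phy) {
  phy <- ape::unroot(phy)
  utree(phy$edge, length(phy$tip.label), phy$tip.label)
}

#' Read trees from a Newick file
#'
#' One tree per line; unrooted semantics. Malformed strings (e.g. unbalanced
#' parentheses) raise a parse error reporting the character offset of the
#' imbalance.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` (single tree) or `multiPhylo` (several trees).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_input(paste0("tree file not found: ", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    depth <- 0
    chars <- strsplit(ln, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1
      if (chars[i] == ")") depth <- depth - 1
      if (depth < 0) {
        stop_input(sprintf("unbalanced parenthesis at character %d of: %s", i, ln),
                   "parse_error")
      }
    }
    if (depth != 0) {
      stop_input(sprintf("unbalanced parentheses (depth %d at end) in: %s", depth, ln),
                 "parse_error")
    }
  }
  trees <- ape::read.tree(text = lines)
  trees
}

#' Write trees to a Newick file
#'
#' @param tree A `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  txt <- vapply(tree, function(t) ape::write.tree(t), "")
  writeLines(txt, path)
  invisible(path)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Counts the bipartitions present in one tree but not the other (symmetric
#' difference over non-trivial splits). 0 means identical unrooted topology.
#'
#' @param tree1,tree2 `phylo` objects over the same leaf set.
#' @return A non-negative integer.
#' @export
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
#' t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
#' rf_distance(t1, t2) # 2
rf_distance <- function(tree1, tree2) {
  u1 <- phylo_to_utree(tree1)
  u2 <- phylo_to_utree(tree2)
  if (!setequal(u1$labels, u2$labels)) {
    stop_input("trees have different leaf sets", "validation_error")
  }
  b1 <- utree_bipartitions(u1)
  b2 <- utree_bipartitions(u2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}
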