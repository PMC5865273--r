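#' Rooted taxonomy trees
#'
#' A `taxonomy_tree` is a rooted tree whose leaves are labelled by reference
#' sequences (or taxa) and whose internal nodes may carry taxonomic ranks.
#' Nodes are identified by stable integer ids; leaf labels are the external
#' handle used in all I/O. Unary (single-child) nodes are permitted: real
#' reference taxonomies such as the NCBI Taxonomy contain rank chains with a
#' single descendant lineage.
#'
#' @param parent integer vector; `parent[i]` is the parent id of node `i`,
#'   `NA` for the root.
#' @param label character vector of node labels. Leaf labels must be unique
#'   and non-empty; internal labels may be `NA` and are then auto-generated.
#' @param rank optional character vector of rank names (`NA` where unranked).
#' @return an object of class `taxonomy_tree` with components `parent`,
#'   `children`, `label`, `rank`, `depth`, `root`, `is_leaf`.
#' @export
taxonomy_tree <- function(parent, label, rank = NULL) {
  n <- length(parent)
  stopifnot(length(label) == n)
  if (is.null(rank)) rank <- rep(NA_character_, n)
  parent <- as.integer(parent)
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root, found ", length(root))
  children <- vector("list", n)
  for (v in seq_len(n)[-root]) {
    p <- parent[v]
    if (is.na(p) || p < 1L || p > n)
      stop("node ", v, " has invalid parent id ", p)
    children[[p]] <- c(children[[p]], v)
  }
  is_leaf <- lengths(children) == 0L
  # depth by BFS from the root; also detects cycles/unreachable nodes
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    kids <- children[[v]]
    depth[kids] <- depth[v] + 1L
    queue <- c(queue, kids)
  }
  if (anyNA(depth))
    stop("nodes unreachable from the root (cycle or orphan): ",
         paste(which(is.na(depth)), collapse = ", "))
  label <- as.character(label)
  lab_leaf <- label[is_leaf]
  if (anyNA(lab_leaf) || any(!nzchar(lab_leaf)))
    stop("all leaves must carry a non-empty label")
  if (anyDuplicated(lab_leaf))
    stop("duplicate leaf label: ",
         paste(unique(lab_leaf[duplicated(lab_leaf)]), collapse = ", "))
  miss <- which(is.na(label) | !nzchar(label))
  if (length(miss)) label[miss] <- paste0(".n", miss)
  # internal labels may collide (e.g. a genus name recurring under two
  # families); disambiguate deterministically, leaves keep their labels
  seen <- new.env(parent = emptyenv())
  for (lab in label[is_leaf]) assign(lab, TRUE, envir = seen)
  for (v in which(!is_leaf)) {
    lab <- label[v]
    if (exists(lab, envir = seen, inherits = FALSE)) {
      k <- 2L
      while (exists(paste0(lab, "#", k), envir = seen, inherits = FALSE))
        k <- k + 1L
      lab <- paste0(lab, "#", k)
      label[v] <- lab
    }
    assign(lab, TRUE, envir = seen)
  }
  structure(
    list(parent = parent, children = children, label = label,
         rank = as.character(rank), depth = depth, root = root,
         is_leaf = is_leaf),
    class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", sum(x$is_leaf), "leaves,",
      sum(!x$is_leaf), "internal nodes, max depth", max(x$depth), "\n")
  invisible(x)
}

#' Leaf ids of a tree
#' @param tree a `taxonomy_tree`
#' @return integer vector of leaf node ids, in id order
#' @export
leaves <- function(tree) which(tree$is_leaf)

#' Number of leaves
#' @inheritParams leaves
#' @export
n_leaves <- function(tree) sum(tree$is_leaf)

#' Map node labels to ids
#'
#' Integer input is validated and passed through, so functions taking node
#' references accept ids and labels interchangeably.
#'
#' @inheritParams leaves
#' @param x character labels or integer ids
#' @return integer node ids
#' @export
node_id <- function(tree, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    bad <- x < 1L | x > length(tree$parent) | is.na(x)
    if (any(bad)) stop("unknown node id: ", paste(x[bad], collapse = ", "))
    return(x)
  }
  id <- match(as.character(x), tree$label)
  if (anyNA(id))
    stop("unknown node label: ", paste(x[is.na(id)], collapse = ", "))
  id
}

#' Labels of nodes
#' @inheritParams node_id
#' @export
node_label <- function(tree, x) tree$label[node_id(tree, x)]

as_leaf_ids <- function(tree, m) {
  id <- node_id(tree, m)
  if (!all(tree$is_leaf[id]))
    stop("not a leaf: ",
         paste(tree$label[id[!tree$is_leaf[id]]], collapse = ", "))
  unique(id)
}

root_path <- function(tree, v) {
  # path from v up to the root, v first
  path <- integer(tree$depth[v] + 1L)
  i <- 1L
  while (!is.na(v)) { path[i] <- v; i <- i + 1L; v <- tree$parent[v] }
  path
}

#' Lowest common ancestor of a set of leaves
#'
#' The deepest node whose clade contains every given leaf; for a single leaf
#' this is the leaf itself. Computed by intersecting root paths.
#'
#' @inheritParams leaves
#' @param m leaf labels or ids (non-empty)
#' @return a node id
#' @export
lca <- function(tree, m) {
  ids <- as_leaf_ids(tree, m)
  if (!length(ids)) stop("lca of an empty leaf set is undefined")
  anc <- root_path(tree, ids[1L])
  for (v in ids[-1L]) anc <- intersect(anc, root_path(tree, v))
  anc[which.max(tree$depth[anc])]
}

#' Leaves in the clade of a node
#' @inheritParams node_id
#' @param node a single node label or id
#' @return integer vector of leaf ids under `node` (a leaf's clade is itself)
#' @export
clade_leaves <- function(tree, node) {
  v <- node_id(tree, node)
  stopifnot(length(v) == 1L)
  if (tree$is_leaf[v]) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (tree$is_leaf[u]) out <- c(out, u)
    else stack <- c(stack, tree$children[[u]])
  }
  sort(out)
}

#' Relevant nodes of a candidate leaf set
#'
#' The nodes at which an indicator-optimal annotation can occur: the
#' candidate leaves themselves plus the LCA of every pair of candidates.
#' All of them lie in the subtree rooted at `lca(tree, m)` and there are at
#' most `2 * length(m) - 1` of them.
#'
#' @inheritParams lca
#' @return sorted integer vector of node ids
#' @export
relevant_nodes <- function(tree, m) {
  ids <- as_leaf_ids(tree, m)
  if (!length(ids)) stop("empty candidate set")
  out <- ids
  if (length(ids) >= 2L) {
    paths <- lapply(ids, function(v) root_path(tree, v))
    for (i in seq_along(ids)[-1L]) for (j in seq_len(i - 1L)) {
      anc <- intersect(paths[[i]], paths[[j]])
      out <- c(out, anc[which.max(tree$depth[anc])])
    }
  }
  sort(unique(out))
}

#' Total cophenetic index
#'
#' The sum over unordered leaf pairs of the depth of their LCA; a balance
#' statistic that is minimal for maximally balanced binary trees and maximal
#' (`choose(n, 3)`) for rooted caterpillars. Computed via the identity that
#' each non-root node containing a leaf pair contributes 1 to that pair's
#' LCA depth.
#'
#' @inheritParams leaves
#' @return a non-negative number
#' @export
total_cophenetic_index <- function(tree) {
  sizes <- vapply(which(!tree$is_leaf), function(v)
    length(clade_leaves(tree, v)), integer(1))
  ids <- which(!tree$is_leaf)
  sum(choose(sizes[ids != tree$root], 2))
}

## ---- generators -----------------------------------------------------------

# build a taxonomy_tree from a recursive list-of-clades constructor that
# appends nodes; used by the generators below
grow_tree <- function(n_nodes_hint, build_root) {
  parent <- integer(0); label <- character(0)
  new_node <- function(p, lab) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- lab
    length(parent)
  }
  build_root(new_node)
  parent[parent == 0L] <- NA_integer_
  taxonomy_tree(parent, label)
}

#' Maximally balanced binary tree
#'
#' Recursively splits `n` leaves into halves of `ceiling(n/2)` and
#' `floor(n/2)` (larger half on the left). Leaves are labelled
#' `l1 ... ln` left to right; for `n` a power of two every leaf has depth
#' `log2(n)`.
#'
#' @param n number of leaves, at least 2
#' @return a `taxonomy_tree` with `n - 1` internal nodes
#' @export
complete_binary_tree <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need at least 2 leaves")
  counter <- 0L
  grow_tree(2L * n, function(new_node) {
    rec <- function(p, lo, hi) {
      if (lo == hi) { new_node(p, paste0("l", lo)); return(invisible(NULL)) }
      counter <<- counter + 1L
      v <- new_node(p, paste0("b", counter))
      k <- hi - lo + 1L
      left <- as.integer(ceiling(k / 2))
      rec(v, lo, lo + left - 1L)
      rec(v, lo + left, hi)
    }
    rec(0L, 1L, n)
  })
}

#' Rooted caterpillar tree
#'
#' The least balanced binary shape: internal nodes `c2 ... cn` where the
#' clade of `ck` is `{l1, ..., lk}` and `cn` is the root; `l1` and `l2` are
#' the deepest leaves.
#'
#' @inheritParams complete_binary_tree
#' @export
caterpillar_tree <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need at least 2 leaves")
  grow_tree(2L * n, function(new_node) {
    p <- 0L
    for (k in n:2) {
      v <- new_node(p, paste0("c", k))
      if (k > 2L) new_node(v, paste0("l", k))
      else { new_node(v, "l1"); new_node(v, "l2") }
      p <- v
    }
  })
}

#' Binary-expansion tree
#'
#' The topology family used by the enumeration benchmark. Write
#' `n = 2^a1 + ... + 2^ak` with `a1 > ... > ak`; build a perfect binary tree
#' for each block and nest them right-associatively,
#' `(B_a1, (B_a2, (..., B_ak)))`. When the expansion has exactly two blocks
#' and the smaller one has at least two leaves, a pass-through (unary) node
#' is inserted above the smaller block. For `n` a power of two this is the
#' perfect binary tree and coincides with [complete_binary_tree()].
#'
#' @inheritParams complete_binary_tree
#' @export
binary_expansion_tree <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("need at least 2 leaves")
  blocks <- which(bitwAnd(n, 2L^(30:0)) > 0L)  # exponents, descending
  blocks <- 30L:0L
  blocks <- blocks[bitwAnd(n, 2L^blocks) > 0L]
  counter <- 0L
  grow_tree(2L * n, function(new_node) {
    perfect <- function(p, lo, hi) {
      if (lo == hi) { new_node(p, paste0("l", lo)); return(invisible(NULL)) }
      counter <<- counter + 1L
      v <- new_node(p, paste0("e", counter))
      mid <- (lo + hi - 1L) %/% 2L
      perfect(v, lo, mid)
      perfect(v, mid + 1L, hi)
    }
    rec <- function(p, lo, exps) {
      size <- 2L^exps[1L]
      if (length(exps) == 1L) {
        perfect(p, lo, lo + size - 1L)
        return(invisible(NULL))
      }
      counter <<- counter + 1L
      v <- new_node(p, paste0("e", counter))
      perfect(v, lo, lo + size - 1L)
      rec(v, lo + size, exps[-1L])
    }
    if (length(blocks) == 1L) {
      perfect(0L, 1L, n)
    } else if (length(blocks) == 2L && blocks[2L] >= 1L) {
      # two-block expansion: pass-through above the smaller block
      counter <<- counter + 1L
      v <- new_node(0L, paste0("e", counter))
      perfect(v, 1L, 2L^blocks[1L])
      counter <<- counter + 1L
      u <- new_node(v, paste0("e", counter))
      perfect(u, 2L^blocks[1L] + 1L, n)
    } else {
      rec(0L, 1L, blocks)
    }
  })
}
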