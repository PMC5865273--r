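# Brute-force oracles and fixture builders, independent of the package's
# computation paths.

# random binary tree on n leaves: repeatedly join two uniformly chosen
# subtrees; labels l1..ln
random_binary_tree <- function(n, labels = paste0("l", seq_len(n))) {
  parent <- rep(NA_integer_, 2L * n - 1L)
  label <- c(labels, rep(NA_character_, n - 1L))
  open <- seq_len(n)  # roots of current forest
  nxt <- n
  while (length(open) > 1L) {
    pick <- sample(length(open), 2L)
    nxt <- nxt + 1L
    parent[open[pick]] <- nxt
    open <- c(open[-pick], nxt)
  }
  taxonomy_tree(parent[seq_len(nxt)], label[seq_len(nxt)])
}

# descendant leaves of every node, via an independent upward walk:
# leaf l is under v iff v lies on l's parent chain
oracle_clades <- function(tree) {
  n_all <- length(tree$parent)
  clades <- vector("list", n_all)
  for (l in which(tree$is_leaf)) {
    v <- l
    while (!is.na(v)) { clades[[v]] <- c(clades[[v]], l); v <- tree$parent[v] }
  }
  clades
}

# deepest node containing all given leaves
oracle_lca <- function(tree, leaf_ids) {
  clades <- oracle_clades(tree)
  holders <- which(vapply(clades, function(cl) all(leaf_ids %in% cl),
                          logical(1)))
  holders[which.max(tree$depth[holders])]
}

# sum over unordered leaf pairs of the depth of their LCA
oracle_tci <- function(tree) {
  lv <- which(tree$is_leaf)
  if (length(lv) < 2L) return(0)
  prs <- utils::combn(lv, 2L)
  sum(vapply(seq_len(ncol(prs)), function(i)
    tree$depth[oracle_lca(tree, prs[, i])], numeric(1)))
}

# all node ids in the subtree rooted at v (walking the children lists)
subtree_nodes <- function(tree, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, tree$children[[u]])
  }
  sort(out)
}

# maximum of an indicator over EVERY node of the subtree rooted at the LCA
# of m (not only relevant nodes)
oracle_best_score <- function(tree, m, kind) {
  top <- oracle_lca(tree, node_id(tree, m))
  max(vapply(subtree_nodes(tree, top), function(v)
    indicator(kind, confusion_lca_relative(tree, m, v)), numeric(1)))
}

# exhaustive exact set cover over all 2^|C| subfamilies; tie-break by
# lexicographically smallest sorted name sequence
oracle_cover <- function(inst, objective = c("size", "total")) {
  objective <- match.arg(objective)
  nm <- sort(names(inst$family))
  best <- NULL; best_obj <- Inf
  for (bits in 1:(2^length(nm) - 1L)) {
    sel <- nm[bitwAnd(bits, 2^(seq_along(nm) - 1L)) > 0L]
    if (!setequal(unlist(inst$family[sel]), inst$elements)) next
    obj <- if (objective == "size") length(sel) else
      sum(lengths(inst$family[sel]))
    key <- paste(sel, collapse = "\r")
    if (obj < best_obj || (obj == best_obj && key < best)) {
      best_obj <- obj; best <- key
    }
  }
  list(chosen = strsplit(best, "\r", fixed = TRUE)[[1L]], obj = best_obj)
}

# random set-cover instance guaranteed coverable
random_instance <- function(n_el = 8L, n_sub = 5L) {
  el <- paste0("r", seq_len(n_el))
  fam <- lapply(seq_len(n_sub), function(i)
    sample(el, sample.int(n_el, 1L)))
  names(fam) <- paste0("s", seq_len(n_sub))
  for (e in setdiff(el, unlist(fam))) {  # patch uncovered elements
    j <- sample.int(n_sub, 1L)
    fam[[j]] <- c(fam[[j]], e)
  }
  set_cover_instance(el, fam)
}

# slow reference tally of the enumeration benchmark (direct loops)
oracle_correct_count <- function(tree, kind) {
  lv <- which(tree$is_leaf)
  n <- length(lv)
  internal <- which(!tree$is_leaf)
  total <- 0
  for (bits in 1:(2^n - 1L)) {
    m <- lv[bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L]
    sc <- vapply(internal, function(j)
      indicator(kind, confusion_global(tree, m, j)), numeric(1))
    mx <- max(sc)
    for (j in internal[sc >= mx - 1e-9])
      total <- total + length(intersect(m, clade_leaves(tree, j)))
  }
  total
}

# fixture writers -----------------------------------------------------------

write_blast_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  # rows: data.frame(read, subject, evalue, bitscore)
  lines <- sprintf("%s\t%s\t98.5\t100\t1\t0\t1\t100\t1\t100\t%s\t%s",
                   rows$read, rows$subject, rows$evalue, rows$bitscore)
  writeLines(lines, path)
  path
}

example_family <- function() {
  list(y1 = paste0("x", 1:6),
       y2 = paste0("x", c(5, 6, 8, 9)),
       y3 = paste0("x", c(1, 4, 7, 10)),
       y4 = paste0("x", c(2, 5, 7, 8, 11)),
       y5 = paste0("x", c(3, 6, 9, 12)),
       y6 = paste0("x", c(10, 11)))
}

example_instance <- function() {
  set_cover_instance(paste0("x", 1:12), example_family())
}
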