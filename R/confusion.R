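#' Confusion counts for a candidate annotation
#'
#' The (TP, FP, TN, FN) quadruple of a binary classification problem in
#' which the positive class is a read's candidate sequence set and the
#' prediction is the clade of a candidate annotation node.
#'
#' @param tp,fp,tn,fn non-negative integer counts of leaves
#' @return an object of class `confusion_counts`
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(x < 0) || anyNA(x)) stop("confusion counts must be non-negative")
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Whole-tree confusion counts
#'
#' Counts over every leaf of the tree: leaves of the candidate set `m`
#' under node `j` are TP, other leaves under `j` are FP, candidates outside
#' the clade are FN, and all remaining leaves of the tree are TN. This is
#' the convention of the enumeration benchmark, where candidate nodes range
#' over every internal node of the tree.
#'
#' @param tree a `taxonomy_tree`
#' @param m candidate leaves (labels or ids), non-empty
#' @param j a node (label or id)
#' @return a `confusion_counts`
#' @export
confusion_global <- function(tree, m, j) {
  ids <- as_leaf_ids(tree, m)
  cl <- clade_leaves(tree, node_id(tree, j))
  tp <- length(intersect(ids, cl))
  confusion_counts(tp, length(cl) - tp,
                   n_leaves(tree) - length(union(ids, cl)),
                   length(ids) - tp)
}

#' LCA-relative confusion counts
#'
#' The production-annotation convention: counts are restricted to the
#' subtree rooted at the LCA of the candidate set, so annotating exactly at
#' the LCA gives no TN and no FN. `j` must lie in that subtree.
#'
#' @inheritParams confusion_global
#' @export
confusion_lca_relative <- function(tree, m, j) {
  ids <- as_leaf_ids(tree, m)
  jid <- node_id(tree, j)
  top <- lca(tree, ids)
  under <- clade_leaves(tree, top)
  cl <- clade_leaves(tree, jid)
  if (!all(cl %in% under) || !(jid %in% clade_nodes(tree, top)))
    stop("node '", tree$label[jid],
         "' is outside the subtree rooted at the LCA of the candidate set")
  tp <- length(intersect(ids, cl))
  confusion_counts(tp, length(cl) - tp,
                   length(under) - length(union(ids, cl)),
                   length(ids) - tp)
}

# all nodes (internal and leaves) of the subtree rooted at v
clade_nodes <- function(tree, v) {
  out <- integer(0); stack <- node_id(tree, v)
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    out <- c(out, u)
    stack <- c(stack, tree$children[[u]])
  }
  sort(out)
}

#' Balance ratio
#'
#' Size of the positive class over the size of the negative class,
#' `(TP + FN) / (FP + TN)`.
#'
#' @param x a `confusion_counts`
#' @return a non-negative number
#' @export
balance_ratio <- function(x) {
  neg <- x$fp + x$tn
  if (neg == 0) stop("balance ratio undefined: empty negative class")
  (x$tp + x$fn) / neg
}

#' The available classification-error indicators
#'
#' `yule_phi` is the Matthews correlation coefficient; `auc` is the
#' two-point area under the ROC curve `(TPR - FPR + 1) / 2`; `rand`,
#' `f_measure`, `jaccard` and `youden_j` are the usual set-agreement
#' statistics on the confusion quadruple.
#'
#' @return character vector of indicator names
#' @export
indicator_kinds <- function() {
  c("rand", "f_measure", "jaccard", "auc", "youden_j", "yule_phi")
}

# vectorised indicator evaluation on count vectors; whenever a denominator
# (for auc: either class total; for phi: any factor under the radical) is
# zero the score is defined to be zero
indicator_values <- function(kind, tp, fp, tn, fn) {
  switch(kind,
    rand = {
      d <- tp + fp + tn + fn
      ifelse(d == 0, 0, (tp + tn) / d)
    },
    f_measure = {
      d <- 2 * tp + fp + fn
      ifelse(d == 0, 0, 2 * tp / d)
    },
    jaccard = {
      d <- tp + fp + fn
      ifelse(d == 0, 0, tp / d)
    },
    auc = {
      p <- tp + fn; q <- fp + tn
      ifelse(p == 0 | q == 0, 0, (tp / p + tn / q) / 2)
    },
    youden_j = {
      p <- tp + fn; q <- fp + tn
      ifelse(p == 0 | q == 0, 0, (tp * tn - fp * fn) / (p * q))
    },
    yule_phi = {
      d2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      ifelse(d2 == 0, 0, (tp * tn - fp * fn) / sqrt(d2))
    },
    stop("unknown indicator: ", kind))
}

#' Evaluate a classification-error indicator
#'
#' Applies one of the six indicators to a confusion quadruple. If a
#' denominator of the chosen formula is zero the score is zero by
#' convention (for `auc` and `youden_j`, either class being empty; for
#' `yule_phi`, any factor under the radical).
#'
#' @param kind one of [indicator_kinds()]
#' @param x a `confusion_counts`
#' @return a score in `[0, 1]` (`rand`, `f_measure`, `jaccard`, `auc`) or
#'   `[-1, 1]` (`youden_j`, `yule_phi`)
#' @export
indicator <- function(kind, x) {
  kind <- match.arg(kind, indicator_kinds())
  indicator_values(kind, x$tp, x$fp, x$tn, x$fn)
}

## ---- exact score comparison ----------------------------------------------

# exact rational/radical representation of a score:
#   value = num / den          (sqrt = FALSE)
#   value = num / sqrt(den)    (sqrt = TRUE)
# zero-denominator convention already applied (num = 0, den = 1)
score_frac <- function(kind, x) {
  tp <- x$tp; fp <- x$fp; tn <- x$tn; fn <- x$fn
  zero <- list(num = 0, den = 1, sqrt = FALSE)
  switch(kind,
    rand = {
      d <- tp + fp + tn + fn
      if (d == 0) zero else list(num = tp + tn, den = d, sqrt = FALSE)
    },
    f_measure = {
      d <- 2 * tp + fp + fn
      if (d == 0) zero else list(num = 2 * tp, den = d, sqrt = FALSE)
    },
    jaccard = {
      d <- tp + fp + fn
      if (d == 0) zero else list(num = tp, den = d, sqrt = FALSE)
    },
    auc = {
      p <- tp + fn; q <- fp + tn
      if (p == 0 || q == 0) zero
      else list(num = tp * q + tn * p, den = 2 * p * q, sqrt = FALSE)
    },
    youden_j = {
      p <- tp + fn; q <- fp + tn
      if (p == 0 || q == 0) zero
      else list(num = tp * tn - fp * fn, den = p * q, sqrt = FALSE)
    },
    yule_phi = {
      d2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (d2 == 0) zero
      else list(num = tp * tn - fp * fn, den = d2, sqrt = TRUE)
    },
    stop("unknown indicator: ", kind))
}

# compare two score_frac values exactly: -1, 0, 1.
# integer arithmetic in doubles; falls back to floating comparison with a
# relative tolerance when cross products would exceed 2^53
score_compare <- function(a, b) {
  sa <- sign(a$num); sb <- sign(b$num)
  if (sa != sb) return(sign(sa - sb))
  if (sa == 0) return(0L)
  # same sign: compare squared magnitudes exactly
  Da <- if (a$sqrt) a$den else a$den^2
  Db <- if (b$sqrt) b$den else b$den^2
  lhs <- a$num^2 * Db
  rhs <- b$num^2 * Da
  if (max(lhs, rhs) < 2^53) {
    cmp <- sign(lhs - rhs)
    return(if (sa > 0) cmp else -cmp)
  }
  va <- a$num / if (a$sqrt) sqrt(a$den) else a$den
  vb <- b$num / if (b$sqrt) sqrt(b$den) else b$den
  if (abs(va - vb) <= 1e-12 * max(abs(va), abs(vb))) 0L else sign(va - vb)
}
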