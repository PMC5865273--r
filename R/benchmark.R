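## Exhaustive indicator-comparison experiments on generated topologies:
## every non-empty subset of the leaves is taken as a candidate sequence
## set and every internal node of the whole tree as a candidate annotation,
## with whole-tree confusion counts. Subsets are iterated as bit masks over
## a fixed leaf order; results are order-invariant.

# bit-population-count lookup table for masks 0 .. 2^n - 1
popcount_table <- function(n) {
  pc <- integer(2^n)
  for (b in seq_len(n)) {
    bit <- 2L^(b - 1L)
    idx <- which(bitwAnd(0:(2^n - 1), bit) > 0L)  # already mask + 1
    pc[idx] <- pc[idx] + 1L
  }
  pc
}

# per-internal-node confusion count matrices over all non-empty subsets:
# list(tp, fp, tn, fn) of (2^n - 1) x n_internal integer matrices
enum_confusion <- function(tree, max_n) {
  lv <- leaves(tree)
  n <- length(lv)
  if (n > max_n)
    stop("enumeration over ", n, " leaves exceeds the bound of ", max_n)
  internal <- which(!tree$is_leaf)
  masks <- vapply(internal, function(v)
    sum(2^(match(clade_leaves(tree, v), lv) - 1L)), numeric(1))
  pc <- popcount_table(n)
  M <- 1:(2^n - 1)
  tp <- vapply(masks, function(mk) pc[bitwAnd(M, mk) + 1L],
               integer(length(M)))
  csize <- pc[masks + 1L]
  fp <- sweep(-tp, 2L, csize, "+")
  fn <- pc[M + 1L] - tp
  tn <- n - tp - fp - fn
  list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
       internal = internal, subset_size = pc[M + 1L])
}

#' Distribution of confusion counts over all classification problems
#'
#' Tallies the whole-tree confusion quadruple over every non-empty leaf
#' subset (as candidate set) and every internal node (as candidate
#' annotation). The total count is `(2^n - 1)` times the number of internal
#' nodes.
#'
#' @param tree a `taxonomy_tree` with at most 20 leaves
#' @return data frame with columns `tp`, `fp`, `tn`, `fn`, `count`, sorted
#'   by the quadruple
#' @export
confusion_distribution <- function(tree) {
  e <- enum_confusion(tree, 20L)
  base <- e$n + 1L
  code <- as.vector(e$tp) + base * (as.vector(e$fp) + base *
            (as.vector(e$tn) + base * as.vector(e$fn)))
  tab <- table(code)
  v <- as.integer(names(tab))
  out <- data.frame(tp = v %% base,
                    fp = (v %/% base) %% base,
                    tn = (v %/% base^2) %% base,
                    fn = (v %/% base^3) %% base,
                    count = as.integer(tab))
  out[order(out$tp, out$fp, out$tn, out$fn), , drop = FALSE]
}

#' Distribution of positive-class sizes
#'
#' The marginal of [confusion_distribution()] over `tp + fn` (the candidate
#' set size): for any tree it equals `choose(n, k)` times the number of
#' internal nodes, so trees with equally many internal nodes yield equally
#' balanced classification problems regardless of shape.
#'
#' @inheritParams confusion_distribution
#' @return data frame with columns `positives` (1..n) and `count`
#' @export
positives_distribution <- function(tree) {
  e <- enum_confusion(tree, 20L)
  tab <- table(factor(rep(e$subset_size, length(e$internal)), levels = 1:e$n))
  data.frame(positives = 1:e$n, count = as.integer(tab))
}

# tie tolerance for vectorised double-precision argmax: distinct indicator
# values on integer confusion counts with totals <= 20 differ by more than
# ~3e-8, and equal values round identically, so 1e-9 separates exactly
.tie_tol <- 1e-9

#' Count correct taxonomic annotations in exhaustive enumeration
#'
#' For every non-empty leaf subset, scores every internal node with the
#' chosen indicator (whole-tree confusion counts, zero-denominator scores
#' set to zero) and counts, over all maximising nodes and all subset
#' members, the cases where the member lies in the maximiser's clade — the
#' annotation of a read coming from that member would then be correct.
#' Tied maximisers each contribute.
#'
#' @param tree a `taxonomy_tree` with at most 16 leaves
#' @param kind indicator name, see [indicator_kinds()]
#' @return a non-negative integer
#' @export
count_correct_annotations <- function(tree, kind) {
  kind <- match.arg(kind, indicator_kinds())
  e <- enum_confusion(tree, 16L)
  v <- indicator_values(kind, e$tp, e$fp, e$tn, e$fn)
  if (is.null(dim(v))) v <- matrix(v, ncol = length(e$internal))
  rowmax <- do.call(pmax, as.data.frame(v))
  sum(e$tp[v >= rowmax - .tie_tol])
}

#' Enumeration report for one topology
#'
#' Bundles the confusion distribution, the positives marginal and the
#' correct-annotation totals of all six indicators for one tree.
#'
#' @inheritParams count_correct_annotations
#' @return list of class `enumeration_report` with components `n`,
#'   `distribution`, `positives`, `correct_counts`
#' @export
enumeration_report <- function(tree) {
  structure(
    list(n = n_leaves(tree),
         distribution = confusion_distribution(tree),
         positives = positives_distribution(tree),
         correct_counts = vapply(stats::setNames(nm = indicator_kinds()),
                                 function(k)
                                   count_correct_annotations(tree, k),
                                 numeric(1))),
    class = "enumeration_report")
}

#' @export
print.enumeration_report <- function(x, ...) {
  cat("enumeration_report: n =", x$n, "\n")
  print(round(x$correct_counts))
  invisible(x)
}

#' Correct-annotation totals across tree sizes
#'
#' Runs [count_correct_annotations()] for every indicator on generated
#' topologies with 2 to `max_n` leaves. The default `"expansion"` family
#' ([binary_expansion_tree()]) is the one whose totals the benchmark is
#' calibrated on; `"complete"` and `"caterpillar"` are also available.
#'
#' @param max_n largest leaf count (between 2 and 16)
#' @param shape topology family
#' @param kinds indicators to tabulate (default all six)
#' @return integer matrix, rows = indicators, columns = `n = 2 ... max_n`
#' @export
correct_annotation_table <- function(max_n,
                                     shape = c("expansion", "complete",
                                               "caterpillar"),
                                     kinds = indicator_kinds()) {
  shape <- match.arg(shape)
  max_n <- as.integer(max_n)
  if (is.na(max_n) || max_n < 2L || max_n > 16L)
    stop("max_n must be between 2 and 16")
  gen <- switch(shape, expansion = binary_expansion_tree,
                complete = complete_binary_tree,
                caterpillar = caterpillar_tree)
  kinds <- vapply(kinds, match.arg, "", choices = indicator_kinds())
  out <- vapply(2:max_n, function(n) {
    tree <- gen(n)
    vapply(kinds, function(k) count_correct_annotations(tree, k),
           numeric(1))
  }, numeric(length(kinds)))
  out <- matrix(as.integer(round(out)), nrow = length(kinds),
                dimnames = list(kinds, paste0("n", 2:max_n)))
  out
}

#' Write an enumeration table as TSV
#' @param x a matrix or data frame (e.g. from [correct_annotation_table()]
#'   or [confusion_distribution()])
#' @param path output file path
#' @export
write_enumeration_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = is.matrix(x),
                     col.names = if (is.matrix(x)) NA else TRUE)
  invisible(path)
}
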