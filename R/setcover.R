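#' Set-cover instance for whole-sample disambiguation
#'
#' The elements are the reads of a sample and each subset, named after a
#' candidate taxonomy node, contains the reads for which that node is an
#' indicator-optimal annotation. The union of the family must equal the
#' element set and every member must be non-empty.
#'
#' @param elements character vector of element (read) ids
#' @param family named list of character vectors (subset name -> member
#'   element ids)
#' @return an object of class `set_cover_instance`
#' @export
set_cover_instance <- function(elements, family) {
  elements <- unique(as.character(elements))
  if (!length(family) || is.null(names(family)) || any(!nzchar(names(family))))
    stop("family must be a non-empty named list")
  if (anyDuplicated(names(family)))
    stop("duplicate subset names")
  family <- lapply(family, function(s) unique(as.character(s)))
  if (any(lengths(family) == 0L)) stop("empty subsets are not allowed")
  un <- unique(unlist(family, use.names = FALSE))
  if (!setequal(un, elements))
    stop("union of the family must equal the element set (missing: ",
         paste(setdiff(elements, un), collapse = ", "), ")")
  structure(list(elements = elements, family = family),
            class = "set_cover_instance")
}

#' @export
print.set_cover_instance <- function(x, ...) {
  cat("set_cover_instance:", length(x$elements), "elements,",
      length(x$family), "subsets\n")
  invisible(x)
}

#' Build the set-cover instance of a sample annotation
#'
#' Elements are read ids; for every node appearing in some argmax set, a
#' subset holds exactly the reads having it among their optimal
#' annotations.
#'
#' @param annotations a `sample_annotation`
#' @return a `set_cover_instance`
#' @export
build_instance <- function(annotations) {
  if (!length(annotations)) stop("no annotations")
  ids <- vapply(annotations, `[[`, "", "read_id")
  fam <- list()
  for (a in annotations)
    for (nd in a$nodes)
      fam[[nd]] <- c(fam[[nd]], a$read_id)
  set_cover_instance(ids, fam)
}

new_cover <- function(inst, chosen) {
  sizes <- lengths(inst$family[chosen])
  structure(
    list(chosen = chosen, size = length(chosen),
         total_size = sum(sizes),
         overlap = sum(sizes) - length(inst$elements)),
    class = "set_cover")
}

#' @export
print.set_cover <- function(x, ...) {
  cat(sprintf("set_cover: {%s} size=%d total_size=%d overlap=%d\n",
              paste(x$chosen, collapse = ", "), x$size, x$total_size,
              x$overlap))
  invisible(x)
}

#' Greedy set cover
#'
#' Johnson's logarithmic-approximation greedy algorithm: repeatedly choose
#' the subset covering the most still-uncovered elements, breaking ties by
#' lexicographically smallest subset name. `chosen` preserves pick order.
#'
#' @param inst a `set_cover_instance`
#' @return a `set_cover` with components `chosen`, `size`, `total_size`,
#'   `overlap` (total size of the chosen subsets minus the number of
#'   elements)
#' @export
greedy_cover <- function(inst) {
  uncovered <- inst$elements
  nm <- sort(names(inst$family))   # lexicographic scan order breaks ties
  chosen <- character(0)
  while (length(uncovered)) {
    gain <- vapply(inst$family[nm], function(s)
      length(intersect(s, uncovered)), integer(1))
    pick <- nm[which.max(gain)]    # first max = lexicographically smallest
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, inst$family[[pick]])
  }
  new_cover(inst, chosen)
}

# branch-and-bound exact set cover.
# objective = "size" (number of subsets) or "total" (sum of subset sizes,
# equivalently least overlap). Elements with identical coverage patterns
# are collapsed to weighted elements first; weights count in total size.
# Among optima the lexicographically smallest sorted name sequence wins.
solve_exact <- function(inst, objective = c("size", "total"),
                        max_subsets = 40L) {
  objective <- match.arg(objective)
  if (length(inst$family) > max_subsets)
    stop("instance has ", length(inst$family), " subsets, more than the ",
         "exact solver's bound (", max_subsets, "); use greedy_cover()")
  nm <- sort(names(inst$family))
  nset <- length(nm)
  # incidence: for each element, which subsets (indices into nm) contain it
  covers <- lapply(inst$elements, function(e)
    which(vapply(inst$family[nm], function(s) e %in% s, logical(1))))
  # collapse elements with identical coverage patterns; weight = count
  key <- vapply(covers, paste, "", collapse = ",")
  first <- !duplicated(key)
  weight <- as.vector(table(key)[key[first]])
  covers <- covers[first]
  nel <- length(covers)
  # subset cost: 1 for min-size; weighted cardinality for min-total-size
  cost <- if (objective == "size") rep(1, nset) else
    vapply(seq_len(nset), function(j)
      sum(weight[vapply(covers, function(cv) j %in% cv, logical(1))]),
      numeric(1))
  best_obj <- Inf
  best_sel <- NULL
  # depth-first search: cover the uncovered element with fewest options,
  # branching over its covering subsets in lexicographic order
  rec <- function(sel, covered, obj) {
    if (all(covered)) {
      cand <- sort(nm[sel])
      if (obj < best_obj ||
          (obj == best_obj && !is.null(best_sel) &&
           paste(cand, collapse = "\r") < paste(best_sel, collapse = "\r"))) {
        best_obj <<- obj
        best_sel <<- cand
      }
      return(invisible(NULL))
    }
    open <- which(!covered)
    # lower bound: every uncovered (weighted) element needs covering;
    # min-size needs at least ceil(remaining/largest-gain) more subsets
    lb <- if (objective == "size") obj + 1 else obj + sum(weight[open])
    if (lb > best_obj) return(invisible(NULL))
    pivot <- open[which.min(lengths(covers)[open])]
    for (j in covers[[pivot]]) {
      if (j %in% sel) next
      newly <- covered
      for (i in open) if (j %in% covers[[i]]) newly[i] <- TRUE
      rec(c(sel, j), newly, obj + cost[j])
    }
  }
  # preprocessing: subsets forced by elements with a single covering subset
  forced <- unique(unlist(covers[lengths(covers) == 1L]))
  covered0 <- vapply(covers, function(cv) any(forced %in% cv), logical(1))
  rec(forced, covered0, sum(cost[forced]))
  new_cover(inst, best_sel)
}

#' Exact minimum-cardinality set cover
#'
#' Provably smallest number of subsets, by branch and bound with forced-set
#' preprocessing. Deterministic tie-break: among optima, the
#' lexicographically smallest sorted name sequence.
#'
#' @inheritParams greedy_cover
#' @param max_subsets capacity bound of the exact search (default 40);
#'   larger instances raise an error suggesting [greedy_cover()]
#' @export
min_cardinality_cover <- function(inst, max_subsets = 40L) {
  solve_exact(inst, "size", max_subsets)
}

#' Exact minimum-total-size set cover
#'
#' Minimises the summed size of the chosen subsets and therefore the
#' overlap (total size minus number of elements) — the cover with the least
#' residual ambiguity. Same tie-break and capacity contract as
#' [min_cardinality_cover()].
#'
#' @inheritParams min_cardinality_cover
#' @export
min_total_size_cover <- function(inst, max_subsets = 40L) {
  solve_exact(inst, "total", max_subsets)
}

#' Pathological family separating cover size from overlap
#'
#' Over elements `1..2k` the family holds the perfect matching
#' `{1,2}, {3,4}, ..., {2k-1,2k}` plus the two near-complete sets
#' `{1..2k-1}` and `{2..2k}`. Its smallest cover has only 2 subsets but
#' overlap `2k`, while the least-total-size cover is the matching, with
#' overlap 0: minimising the number of subsets does not minimise ambiguity.
#'
#' @param k number of matched pairs, at least 3
#' @return a `set_cover_instance` with `k + 2` subsets over `2k` elements
#' @export
overlap_gap_instance <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop("k must be at least 3")
  n <- 2L * k
  el <- as.character(seq_len(n))
  fam <- stats::setNames(
    lapply(seq_len(k), function(i) as.character(c(2L * i - 1L, 2L * i))),
    sprintf("p%02d", seq_len(k)))
  fam$q1 <- as.character(seq_len(n - 1L))
  fam$q2 <- as.character(2:n)
  set_cover_instance(el, fam)
}

#' Distribute reads over a cover
#'
#' Each read's unit weight is split uniformly over the chosen subsets that
#' contain it (a read in only one chosen subset gets weight 1 there).
#'
#' @inheritParams greedy_cover
#' @param cover a `set_cover` valid for `inst`
#' @return named list: read id -> named numeric vector of weights summing
#'   to 1
#' @export
assign_reads <- function(inst, cover) {
  stopifnot(all(cover$chosen %in% names(inst$family)))
  out <- lapply(inst$elements, function(e) {
    holders <- cover$chosen[vapply(inst$family[cover$chosen],
                                   function(s) e %in% s, logical(1))]
    if (!length(holders)) stop("cover does not cover read '", e, "'")
    stats::setNames(rep(1 / length(holders), length(holders)), holders)
  })
  stats::setNames(out, inst$elements)
}

#' Relative abundance profile
#'
#' Per-node abundance as a percentage of reads: the summed weights mapped
#' to the node divided by the number of reads, times 100. Values sum to
#' 100.
#'
#' @param assignments output of [assign_reads()]
#' @return named numeric vector (percent), class `abundance_profile`
#' @export
abundance_profile <- function(assignments) {
  if (!length(assignments)) stop("no assignments")
  w <- unlist(unname(assignments))
  tot <- tapply(w, names(w), sum)
  out <- 100 * as.vector(tot) / length(assignments)
  structure(stats::setNames(out, names(tot)), class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  for (nd in names(sort(unclass(x), decreasing = TRUE)))
    cat(sprintf("%-20s %6.2f%%\n", nd, x[[nd]]))
  invisible(x)
}

#' Aggregate an abundance profile at a taxonomic rank
#'
#' Each node's abundance is added to its nearest ancestor-or-self carrying
#' the requested rank; nodes with no such ancestor aggregate under
#' `"Other"`. The total is preserved.
#'
#' @param tree a `taxonomy_tree` containing the profile's nodes
#' @param profile an `abundance_profile` (names are node labels)
#' @param rank a rank name present in the tree (case-insensitive)
#' @export
rollup_profile <- function(tree, profile, rank) {
  known <- unique(tolower(stats::na.omit(tree$rank)))
  if (!tolower(rank) %in% known)
    stop("rank '", rank, "' not present in the tree (available: ",
         paste(known, collapse = ", "), ")")
  target <- function(lab) {
    v <- node_id(tree, lab)
    while (!is.na(v)) {
      if (!is.na(tree$rank[v]) && tolower(tree$rank[v]) == tolower(rank))
        return(tree$label[v])
      v <- tree$parent[v]
    }
    "Other"
  }
  keys <- vapply(names(profile), target, "")
  tot <- tapply(as.vector(unclass(profile)), keys, sum)
  structure(stats::setNames(as.vector(tot), names(tot)),
            class = "abundance_profile")
}

#' Write a cover as TSV
#' @inheritParams assign_reads
#' @param path output file path
#' @export
write_cover <- function(inst, cover, path) {
  rows <- do.call(rbind, lapply(cover$chosen, function(nd)
    data.frame(node = nd, reads = paste(sort(inst$family[[nd]]),
                                        collapse = ","))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an abundance profile as TSV
#'
#' Percentages are printed rounded to 2 decimals alongside a full-precision
#' column.
#'
#' @param profile an `abundance_profile`
#' @param path output file path
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(node = names(profile),
                   abundance_pct = sprintf("%.2f", as.vector(profile)),
                   abundance = as.vector(unclass(profile)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
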