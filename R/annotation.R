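#' Annotate one read at its indicator-optimal taxonomy nodes
#'
#' Scores every relevant node of the candidate set (the candidates
#' themselves and the pairwise LCAs — the LCA skeleton) with the chosen
#' indicator under the LCA-relative confusion convention, and returns the
#' complete set of maximising nodes. The maximum over relevant nodes equals
#' the maximum over every node of the subtree rooted at the LCA, so nothing
#' is lost by the restriction. Ties are deliberately NOT broken: the full
#' argmax set is what the sample-wide set-cover stage disambiguates;
#' breaking ties per read is exactly the bias that stage removes.
#'
#' Scores are compared exactly (integer cross-multiplication; the phi
#' statistic via signed squares), so tie detection does not depend on
#' floating-point rounding.
#'
#' @param tree a `taxonomy_tree`
#' @param m candidate leaves (labels or ids), non-empty
#' @param kind indicator name, see [indicator_kinds()]; default `"rand"`
#' @param read_id identifier carried through to the annotation
#' @return an object of class `read_annotation`: list with `read_id`,
#'   `nodes` (labels of all maximisers), `score`, `indicator`
#' @export
annotate_read <- function(tree, m, kind = "rand", read_id = "read") {
  kind <- match.arg(kind, indicator_kinds())
  ids <- as_leaf_ids(tree, m)
  if (!length(ids)) stop("empty candidate set for read '", read_id, "'")
  cand <- relevant_nodes(tree, ids)
  best <- NULL
  best_nodes <- integer(0)
  for (v in cand) {
    fr <- score_frac(kind, confusion_lca_relative(tree, ids, v))
    if (is.null(best)) { best <- fr; best_nodes <- v; next }
    cmp <- score_compare(fr, best)
    if (cmp > 0L) { best <- fr; best_nodes <- v }
    else if (cmp == 0L) best_nodes <- c(best_nodes, v)
  }
  structure(
    list(read_id = read_id,
         nodes = tree$label[sort(best_nodes)],
         score = best$num / if (best$sqrt) sqrt(best$den) else best$den,
         indicator = kind),
    class = "read_annotation")
}

#' @export
print.read_annotation <- function(x, ...) {
  cat(sprintf("read '%s': %s = %.4f at {%s}\n", x$read_id, x$indicator,
              x$score, paste(x$nodes, collapse = ", ")))
  invisible(x)
}

#' Annotate a sample of reads
#'
#' @inheritParams annotate_read
#' @param reads named list: read id -> candidate leaf labels/ids. Ids must
#'   be unique.
#' @return list of `read_annotation`, class `sample_annotation`, in input
#'   order
#' @export
annotate_sample <- function(tree, reads, kind = "rand") {
  if (length(reads) && is.null(names(reads)))
    stop("reads must be a named list (names are read ids)")
  if (anyDuplicated(names(reads)))
    stop("duplicate read ids: ",
         paste(unique(names(reads)[duplicated(names(reads))]), collapse = ", "))
  out <- lapply(names(reads), function(id)
    annotate_read(tree, reads[[id]], kind = kind, read_id = id))
  structure(out, class = "sample_annotation")
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat("sample_annotation:", length(x), "reads\n")
  invisible(x)
}

#' @export
as.data.frame.sample_annotation <- function(x, ...) {
  data.frame(
    read_id = vapply(x, `[[`, "", "read_id"),
    score = vapply(x, `[[`, 0, "score"),
    nodes = vapply(x, function(a) paste(a$nodes, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Histogram of per-read annotation ambiguity
#'
#' Bins reads by their number of candidate annotations (size of the argmax
#' set). The values sum to the number of reads.
#'
#' @param annotations a `sample_annotation` (or list of `read_annotation`)
#' @return named integer vector: bin (as character) -> number of reads
#' @export
ambiguity_histogram <- function(annotations) {
  k <- vapply(annotations, function(a) length(a$nodes), integer(1))
  tab <- table(k)
  stats::setNames(as.integer(tab), names(tab))
}

#' Average number of candidate annotations per read
#' @inheritParams ambiguity_histogram
#' @export
average_ambiguity <- function(annotations) {
  mean(vapply(annotations, function(a) length(a$nodes), integer(1)))
}

#' Write annotations as TSV
#'
#' Columns: `read_id`, `score`, comma-separated `nodes`.
#'
#' @inheritParams ambiguity_histogram
#' @param path output file path
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(as.data.frame.sample_annotation(annotations), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read annotations from TSV
#'
#' Inverse of [write_annotations()]; the indicator column is not stored in
#' the file and is recorded as given.
#'
#' @param path TSV with columns `read_id`, `score`, `nodes`
#' @param indicator indicator name to record on the annotations
#' @return a `sample_annotation`
#' @export
read_annotations <- function(path, indicator = "rand") {
  df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                               "character"))
  out <- lapply(seq_len(nrow(df)), function(i)
    structure(list(read_id = df$read_id[i],
                   nodes = strsplit(df$nodes[i], ",", fixed = TRUE)[[1L]],
                   score = df$score[i], indicator = indicator),
              class = "read_annotation"))
  structure(out, class = "sample_annotation")
}
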