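#' Expand a term set with its ancestors (true path rule)
#'
#' Returns the union of `s` and the ancestors of every member of `s`
#' (written Sg* when `s` is a gene's direct annotation set). Extensive,
#' monotone and idempotent.
#'
#' @inheritParams ancestors
#' @param s character vector of term ids (possibly empty).
#' @return Character vector of term ids.
#' @export
expand_set <- function(g, s) {
  if (!length(s)) return(character())
  .check_terms(g, s)
  out <- s
  for (t in s) out <- union(out, .ancestors_memo(g, t))
  out
}

#' Construct an annotation corpus
#'
#' Holds each gene's direct term set in one namespace, plus the propagated
#' per-term gene counts used for information content: a gene counts
#' towards a term when its expanded annotation set contains the term
#' (implicit annotations through the subsumption hierarchy included).
#'
#' @inheritParams ancestors
#' @param gene_terms named list, gene id -> character vector of directly
#'   annotated term ids. Genes with zero terms are dropped.
#' @param namespace the namespace the annotations live in; defaults to the
#'   single namespace of `g`.
#' @return An object of class `AnnotationCorpus` with fields `gene_terms`,
#'   `namespace`, `root`, `n_genes` and `propagated_counts`.
#' @export
annotation_corpus <- function(g, gene_terms, namespace = NULL) {
  if (is.null(namespace)) {
    if (length(g$roots) != 1L)
      stop("graph has several namespaces; pass `namespace`")
    namespace <- names(g$roots)
  }
  if (!namespace %in% names(g$roots))
    stop("unknown namespace: ", namespace)
  gene_terms <- gene_terms[vapply(gene_terms, length, 1L) > 0L]
  if (!length(gene_terms)) stop("no annotated gene in the corpus")
  ns_of <- stats::setNames(g$terms$namespace, g$terms$id)
  gene_terms <- lapply(gene_terms, function(s) {
    s <- unique(resolve_ids(g, s))
    .check_terms(g, s)
    s[ns_of[s] == namespace]
  })
  gene_terms <- gene_terms[vapply(gene_terms, length, 1L) > 0L]
  if (!length(gene_terms))
    stop("no annotated gene in namespace ", namespace)

  counts <- table(unlist(lapply(gene_terms, function(s) expand_set(g, s))))
  counts <- stats::setNames(as.integer(counts), names(counts))

  structure(list(
    gene_terms = gene_terms,
    namespace = namespace,
    root = unname(g$roots[namespace]),
    n_genes = length(gene_terms),
    propagated_counts = counts
  ), class = "AnnotationCorpus")
}

#' @export
print.AnnotationCorpus <- function(x, ...) {
  cat("AnnotationCorpus:", x$n_genes, "annotated genes in namespace",
      x$namespace, "-", length(x$propagated_counts),
      "terms with nonzero propagated count\n")
  invisible(x)
}

#' Propagated annotation frequency of a term
#'
#' The probability estimate p(t) = propagated gene count of `t` divided by
#' the count at the namespace root, so p(root) = 1 exactly and p is
#' monotone non-increasing from root to leaves.
#'
#' @param corpus an [AnnotationCorpus][annotation_corpus].
#' @inheritParams ancestors
#' @return A probability in \[0,1\] (0 when no gene covers the term).
#' @export
propagated_frequency <- function(corpus, g, t) {
  .check_terms(g, t)
  n <- corpus$propagated_counts[t]
  if (is.na(n)) n <- 0L
  unname(n) / unname(corpus$propagated_counts[corpus$root])
}

#' Read gene annotations from a GAF or a two-column TSV
#'
#' Accepts GAF 2.x (comment lines starting with `!`; columns 2 = gene id,
#' 4 = qualifier, 5 = term id, 7 = evidence code, 9 = aspect) or a plain
#' two-column `gene<Tab>term` TSV. Rows whose term is absent from the
#' graph (after alt_id resolution) are skipped and counted. Evidence codes
#' are retained as metadata but never used as weights.
#'
#' @param path file path.
#' @inheritParams ancestors
#' @param namespace namespace to keep; defaults to the graph's single one.
#' @param exclude_not drop rows whose qualifier contains `NOT`
#'   (default `TRUE`).
#' @return An [AnnotationCorpus][annotation_corpus]; attributes
#'   `skipped_unknown_terms` (count) and `evidence` (data.frame gene,
#'   term, evidence_code) carry the bookkeeping.
#' @export
load_gaf <- function(path, g, namespace = NULL, exclude_not = TRUE) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) stop("no usable annotation row in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)

  gene <- term <- qual <- ev <- character(length(fields))
  ok <- logical(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) >= 15L) {            # GAF dialect
      gene[i] <- f[2L]; qual[i] <- f[4L]; term[i] <- f[5L]; ev[i] <- f[7L]
      ok[i] <- nzchar(f[2L]) && nzchar(f[5L])
    } else if (length(f) == 2L) {      # toy dialect
      gene[i] <- f[1L]; term[i] <- f[2L]; qual[i] <- ""; ev[i] <- ""
      ok[i] <- nzchar(f[1L]) && nzchar(f[2L])
    }
  }
  if (any(!ok))
    warning("skipping ", sum(!ok), " malformed annotation row(s)")
  if (exclude_not) ok <- ok & !grepl("\\bNOT\\b", qual)

  term <- resolve_ids(g, term)
  known <- term %in% g$terms$id
  skipped_unknown <- sum(ok & !known)
  if (skipped_unknown)
    warning("skipping ", skipped_unknown, " row(s) with terms absent from the graph")
  keep <- ok & known
  if (!any(keep)) stop("zero usable annotation rows in ", path)

  corpus <- annotation_corpus(
    g, split(term[keep], gene[keep]), namespace = namespace)
  attr(corpus, "skipped_unknown_terms") <- skipped_unknown
  attr(corpus, "evidence") <-
    data.frame(gene = gene[keep], term = term[keep], evidence_code = ev[keep])
  corpus
}

#' Write a corpus in the toy two-column annotation dialect
#'
#' @param corpus an [AnnotationCorpus][annotation_corpus].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(corpus, path) {
  genes <- rep(names(corpus$gene_terms), lengths(corpus$gene_terms))
  utils::write.table(
    data.frame(gene = genes, term = unlist(corpus$gene_terms, use.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
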