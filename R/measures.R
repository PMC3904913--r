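.check_one_namespace <- function(g, ...) {
  terms <- unique(unlist(list(...)))
  if (!length(terms)) return(invisible(NULL))
  .check_terms(g, terms)
  ns <- unique(g$terms$namespace[match(terms, g$terms$id)])
  if (length(ns) > 1L)
    stop("term sets mix namespaces: ", paste(ns, collapse = ", "))
  invisible(ns)
}

#' Most particular terms of one set compared to another
#'
#' MPT(Sg1, Sg2): the terms of the direct set `sg1` that have no
#' descendant inside `sg1` and are not members of the expanded set Sg2*.
#' These are the deepest Sg1 terms carrying information absent from Sg2.
#'
#' @inheritParams ancestors
#' @param sg1,sg2 character vectors of term ids (direct annotation sets,
#'   same namespace).
#' @return Character vector of term ids (possibly empty).
#' @export
most_particular_terms <- function(g, sg1, sg2) {
  .check_one_namespace(g, sg1, sg2)
  sg1 <- unique(sg1)
  sg2_star <- expand_set(g, sg2)
  keep <- vapply(sg1, function(t) {
    !any(sg1 %in% .descendants_memo(g, t)) && !(t %in% sg2_star)
  }, logical(1))
  unname(sg1[keep])
}

#' Most informative common terms of two sets
#'
#' MCT(Sg1, Sg2): the members of Sg1* intersected with Sg2* that have no
#' descendant in Sg1* and none in Sg2* — the deepest terms shared (possibly
#' implicitly) by both sets.
#'
#' @inheritParams most_particular_terms
#' @return Character vector of term ids (possibly empty).
#' @export
most_informative_common_terms <- function(g, sg1, sg2) {
  .check_one_namespace(g, sg1, sg2)
  s1 <- expand_set(g, sg1)
  s2 <- expand_set(g, sg2)
  common <- intersect(s1, s2)
  both <- union(s1, s2)
  keep <- vapply(common, function(t)
    !any(both %in% .descendants_memo(g, t)), logical(1))
  unname(common[keep])
}

#' Informativeness of the most informative common ancestor
#'
#' The MICA of a term t and a set Sg2 is the most informative member of
#' ({t} union ancestors(t)) intersected with Sg2*. Returns 0 when the
#' intersection is empty (e.g. Sg2 empty), which makes the particularity
#' of a set against the empty set come out exactly 1.
#'
#' @inheritParams most_particular_terms
#' @param model an [InformativenessModel][informativeness-models].
#' @param t a term id.
#' @return max I over the common ancestors, or 0 if there is none.
#' @export
mica_informativeness <- function(g, model, t, sg2) {
  .check_terms(g, t)
  common <- intersect(ancestors(g, t, include_self = TRUE),
                      expand_set(g, sg2))
  if (!length(common)) return(0)
  max(informativeness(model, common))
}

#' Particular informativeness of one set compared to another
#'
#' PI(Sg1, Sg2) = sum over t in MPT(Sg1, Sg2) of I(t) minus the
#' informativeness of the MICA of t and Sg2 — the information of Sg1 that
#' is not shared with Sg2. Negative summands (possible with a semantic
#' value backing on multi-relation DAGs, never with IC which is monotone)
#' are clamped at 0 with a warning, keeping the normalised particularity
#' in \[0,1\].
#'
#' @inheritParams mica_informativeness
#' @return A nonnegative real.
#' @export
particular_informativeness <- function(g, model, sg1, sg2) {
  mpt <- most_particular_terms(g, sg1, sg2)
  if (!length(mpt)) return(0)
  d <- informativeness(model, mpt) -
    vapply(mpt, function(t) mica_informativeness(g, model, t, sg2), numeric(1))
  if (any(d < 0)) {
    warning("clamped ", sum(d < 0),
            " negative particular-informativeness summand(s) at 0")
    d[d < 0] <- 0
  }
  sum(d)
}

#' Semantic particularity of one term set compared to another
#'
#' Par(Sg1, Sg2) = PI(Sg1, Sg2) / (PI(Sg1, Sg2) + sum of I(t) over
#' MCT(Sg1, Sg2)): the particular informativeness of Sg1 normalised by the
#' total informativeness of its most informative terms (specific ones plus
#' those shared with Sg2). Bounded by 0 (least particular) and 1 (most
#' particular) and non-symmetric.
#'
#' Conventions: Par(s, empty) = 1 and Par(empty, s) = 0 for nonempty s;
#' comparing two empty sets is an error. A zero denominator with both sets
#' nonempty (all informativeness zero) returns 0 with a warning.
#'
#' @inheritParams mica_informativeness
#' @return A real in \[0,1\].
#' @export
particularity <- function(g, model, sg1, sg2) {
  if (!length(sg1) && !length(sg2))
    stop("particularity of two empty sets is meaningless")
  if (!length(sg1)) return(0)
  pi12 <- particular_informativeness(g, model, sg1, sg2)
  mct <- most_informative_common_terms(g, sg1, sg2)
  denom <- pi12 + sum(informativeness(model, mct))
  if (denom == 0) {
    if (!length(sg2)) return(1)
    warning("all informativeness zero; returning particularity 0")
    return(0)
  }
  pi12 / denom
}

#' Wang pairwise term similarity
#'
#' sim(a, b) = sum over the shared ancestor-or-self terms t of
#' (S_a(t) + S_b(t)), divided by (SV(a) + SV(b)).
#'
#' @inheritParams semantic_contributions
#' @param b a second term id, same namespace as `a`.
#' @return A real in \[0,1\]; 1 when a = b.
#' @export
wang_term_similarity <- function(g, a, b) {
  .check_one_namespace(g, a, b)
  sa <- semantic_contributions(g, a)
  sb <- semantic_contributions(g, b)
  common <- intersect(names(sa), names(sb))
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

#' Lin pairwise term similarity
#'
#' sim(a, b) = 2 IC(MICA(a, b)) / (IC(a) + IC(b)), with the MICA the most
#' informative common ancestor-or-self of the two terms. Identical terms
#' get similarity 1; when both terms carry zero IC (e.g. the root with
#' itself excluded) the similarity is 0.
#'
#' @inheritParams wang_term_similarity
#' @param corpus an [AnnotationCorpus][annotation_corpus] supplying the
#'   term frequencies.
#' @param base logarithm base for IC.
#' @return A real in \[0,1\].
#' @export
lin_term_similarity <- function(g, corpus, a, b, base = exp(1)) {
  .check_one_namespace(g, a, b)
  if (a == b) return(1)
  ica <- information_content(corpus, g, a, base = base)
  icb <- information_content(corpus, g, b, base = base)
  if (ica + icb == 0) return(0)
  common <- intersect(ancestors(g, a, include_self = TRUE),
                      ancestors(g, b, include_self = TRUE))
  mica <- if (length(common))
    max(vapply(common, function(t)
      information_content(corpus, g, t, base = base), numeric(1)))
  else 0
  2 * mica / (ica + icb)
}

.term_sim_matrix <- function(g, sg1, sg2, method, corpus, base) {
  m <- matrix(0, length(sg1), length(sg2), dimnames = list(sg1, sg2))
  for (a in sg1) for (b in sg2)
    m[a, b] <- if (method == "wang") wang_term_similarity(g, a, b)
               else lin_term_similarity(g, corpus, a, b, base = base)
  m
}

#' Set-level semantic similarity
#'
#' Combines the pairwise term-similarity matrix of two annotation sets
#' into one value. `bma` (default) averages the two directional best-match
#' means; `max` takes the matrix maximum; `avg` the matrix mean.
#'
#' @inheritParams most_particular_terms
#' @param method `"wang"` (semantic-value based, corpus-free) or `"lin"`
#'   (IC based, requires `corpus`).
#' @param combine `"bma"`, `"max"` or `"avg"`.
#' @param corpus an [AnnotationCorpus][annotation_corpus], required for
#'   `method = "lin"`.
#' @param base logarithm base for IC.
#' @return A real in \[0,1\].
#' @export
set_similarity <- function(g, sg1, sg2, method = c("wang", "lin"),
                           combine = c("bma", "max", "avg"),
                           corpus = NULL, base = exp(1)) {
  method <- match.arg(method)
  combine <- match.arg(combine)
  if (!length(sg1) || !length(sg2))
    stop("set similarity is undefined for an empty annotation set")
  if (method == "lin" && is.null(corpus))
    stop("method 'lin' requires an annotation corpus")
  .check_one_namespace(g, sg1, sg2)
  m <- .term_sim_matrix(g, unique(sg1), unique(sg2), method, corpus, base)
  switch(combine,
    bma = (mean(apply(m, 1L, max)) + mean(apply(m, 2L, max))) / 2,
    max = max(m),
    avg = mean(m))
}

#' Full comparison of two annotation sets
#'
#' Assembles, in one pass, the expanded sets, the most particular terms in
#' both directions, the shared most informative common terms, the
#' particular informativeness and particularity in both directions, and
#' the set similarity. The result is the (Sim, Par12, Par21) tuple the
#' package is built around: high Sim with one high Par flags a gene that
#' carries particular functions despite being similar to the other.
#'
#' @inheritParams mica_informativeness
#' @param sim_method `"wang"`, `"lin"` or `"none"` (sim reported as `NA`,
#'   e.g. with a table-backed informativeness that supports no similarity).
#' @param combine combiner for [set_similarity()].
#' @param corpus corpus for `sim_method = "lin"`; defaults to the model's
#'   own corpus when IC-backed.
#' @return An object of class `TermSetComparison`: a list with fields
#'   `sg1`, `sg2`, `sg1_star`, `sg2_star`, `mpt12`, `mpt21`, `mct`,
#'   `pi12`, `pi21`, `par12`, `par21`, `sim`, `method`.
#' @export
compare_sets <- function(g, model, sg1, sg2,
                         sim_method = c("wang", "lin", "none"),
                         combine = "bma", corpus = NULL) {
  sim_method <- match.arg(sim_method)
  .check_one_namespace(g, sg1, sg2)
  if (sim_method == "lin" && is.null(corpus) &&
      model$kind == "information_content")
    corpus <- model$corpus
  sim <- if (sim_method == "none" || !length(sg1) || !length(sg2)) NA_real_
         else set_similarity(g, sg1, sg2, method = sim_method,
                             combine = combine, corpus = corpus)
  structure(list(
    sg1 = unique(sg1), sg2 = unique(sg2),
    sg1_star = expand_set(g, sg1), sg2_star = expand_set(g, sg2),
    mpt12 = most_particular_terms(g, sg1, sg2),
    mpt21 = most_particular_terms(g, sg2, sg1),
    mct = most_informative_common_terms(g, sg1, sg2),
    pi12 = particular_informativeness(g, model, sg1, sg2),
    pi21 = particular_informativeness(g, model, sg2, sg1),
    par12 = particularity(g, model, sg1, sg2),
    par21 = particularity(g, model, sg2, sg1),
    sim = sim,
    method = list(informativeness = model$kind, similarity = sim_method,
                  combine = combine)
  ), class = "TermSetComparison")
}

#' @export
print.TermSetComparison <- function(x, ...) {
  cat("TermSetComparison (", x$method$informativeness, " informativeness, ",
      x$method$similarity, " similarity)\n", sep = "")
  cat(sprintf("  sim = %s   par12 = %.3f   par21 = %.3f\n",
              ifelse(is.na(x$sim), "NA", sprintf("%.3f", x$sim)),
              x$par12, x$par21))
  cat("  MPT 1->2: {", paste(x$mpt12, collapse = ", "), "}\n", sep = "")
  cat("  MPT 2->1: {", paste(x$mpt21, collapse = ", "), "}\n", sep = "")
  cat("  MCT:      {", paste(x$mct, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
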