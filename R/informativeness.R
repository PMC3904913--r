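#' Semantic contributions of a term's ancestors (Wang)
#'
#' For a term `a`, the semantic contribution S_a(t) of an ancestor-or-self
#' term t is the maximum, over all descending paths from t down to `a`, of
#' the product of the edge contribution factors along the path; S_a(a) = 1.
#' Computed by dynamic programming over the sub-DAG between `a` and its
#' ancestors.
#'
#' @inheritParams ancestors
#' @param a a term id in `g`.
#' @return Named numeric vector over `{a}` and its ancestors, values in
#'   (0,1].
#' @export
semantic_contributions <- function(g, a) {
  .check_terms(g, a)
  key <- paste0("scontrib:", a)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  closure <- ancestors(g, a, include_self = TRUE)
  s <- stats::setNames(rep(NA_real_, length(closure)), closure)
  s[a] <- 1
  contrib <- function(t) {
    if (!is.na(s[t])) return(s[t])
    # children of t inside the closure carry the value upward
    cand <- intersect(unique(g$children[[t]]), closure)
    pe <- do.call(rbind, lapply(cand, function(ch) {
      rows <- g$parents[[ch]]
      rows <- rows[rows$parent == t, , drop = FALSE]
      data.frame(child = ch, weight = max(rows$weight))
    }))
    s[t] <<- max(vapply(seq_len(nrow(pe)), function(i)
      pe$weight[i] * contrib(pe$child[i]), numeric(1)))
    s[t]
  }
  for (t in closure) contrib(t)
  assign(key, s, envir = g$cache)
  s
}

#' Semantic contribution of one ancestor to a term
#'
#' @inheritParams semantic_contributions
#' @param t a term in `{a}` or among the ancestors of `a`.
#' @return S_a(t), a value in (0,1].
#' @export
semantic_contribution <- function(g, a, t) {
  s <- semantic_contributions(g, a)
  if (!t %in% names(s))
    stop(t, " is not ", a, " nor one of its ancestors")
  unname(s[t])
}

#' Wang semantic value of a term
#'
#' SV(a) is the sum of the semantic contributions of `a` and all its
#' ancestors. SV(root) = 1 (the term's own contribution); SV grows with
#' distance to the root, making it a corpus-independent informativeness.
#'
#' @inheritParams semantic_contributions
#' @return A real >= 1.
#' @export
semantic_value <- function(g, a) {
  sum(semantic_contributions(g, a))
}

#' Information content of a term
#'
#' IC(t) = -log p(t) with p(t) the propagated annotation frequency of the
#' term in the corpus. IC(root) = 0. Terms with zero propagated count have
#' undefined IC and raise an error; no smoothing is applied.
#'
#' @inheritParams propagated_frequency
#' @param base logarithm base; natural log by default.
#' @return A nonnegative real.
#' @export
information_content <- function(corpus, g, t, base = exp(1)) {
  p <- propagated_frequency(corpus, g, t)
  if (p <= 0)
    stop("IC undefined: term ", t, " has zero propagated frequency")
  -log(p, base = base)
}

#' Informativeness models
#'
#' An `InformativenessModel` maps term ids to nonnegative reals I(t). Three
#' backings exist: `sv_model()` (Wang semantic value, corpus-independent),
#' `ic_model()` (corpus information content) and `table_model()` (explicit
#' values, used for fixtures and worked examples).
#'
#' @inheritParams ancestors
#' @return An object of class `InformativenessModel`.
#' @name informativeness-models
NULL

#' @rdname informativeness-models
#' @export
sv_model <- function(g) {
  structure(list(kind = "semantic_value", graph = g),
            class = "InformativenessModel")
}

#' @rdname informativeness-models
#' @param corpus an [AnnotationCorpus][annotation_corpus].
#' @param base logarithm base for IC.
#' @export
ic_model <- function(corpus, g, base = exp(1)) {
  structure(list(kind = "information_content", graph = g, corpus = corpus,
                 base = base),
            class = "InformativenessModel")
}

#' @rdname informativeness-models
#' @param values named numeric vector, term id -> informativeness >= 0.
#' @param sealed character vector of term ids whose values are fillers:
#'   looking one up raises an error, so tests fail loudly if a computation
#'   that should never need them consults one.
#' @export
table_model <- function(values, sealed = character()) {
  stopifnot(is.numeric(values), !is.null(names(values)), all(values >= 0))
  structure(list(kind = "table", values = values, sealed = sealed),
            class = "InformativenessModel")
}

#' @export
print.InformativenessModel <- function(x, ...) {
  cat("InformativenessModel:", x$kind, "\n")
  invisible(x)
}

#' Evaluate an informativeness model on terms
#'
#' @param model an [InformativenessModel][informativeness-models].
#' @param terms character vector of term ids.
#' @return Named numeric vector of I(t) values, same order as `terms`.
#' @export
informativeness <- function(model, terms) {
  stopifnot(inherits(model, "InformativenessModel"))
  if (!length(terms)) return(stats::setNames(numeric(), character()))
  switch(model$kind,
    semantic_value = vapply(stats::setNames(terms, terms),
                            function(t) semantic_value(model$graph, t),
                            numeric(1)),
    information_content = vapply(stats::setNames(terms, terms),
      function(t) information_content(model$corpus, model$graph, t,
                                      base = model$base),
      numeric(1)),
    table = {
      hit <- terms %in% names(model$values)
      if (any(!hit))
        stop("informativeness table has no value for: ",
             paste(terms[!hit], collapse = ", "))
      bad <- intersect(terms, model$sealed)
      if (length(bad))
        stop("consulted sealed filler informativeness for: ",
             paste(bad, collapse = ", "))
      model$values[terms]
    },
    stop("unknown model kind: ", model$kind))
}

#' Export / import an informativeness table as TSV
#'
#' Two columns, `term` and `informativeness`, enabling reproducible reruns
#' with a frozen table.
#'
#' @param model a table-backed model, or any model plus `terms` to
#'   materialise.
#' @param path file path.
#' @param terms terms to materialise when `model` is not table-backed.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [table_model()].
#' @export
write_informativeness_tsv <- function(model, path, terms = NULL) {
  if (model$kind != "table") {
    stopifnot(!is.null(terms))
    model <- table_model(informativeness(model, terms))
  }
  utils::write.table(
    data.frame(term = names(model$values),
               informativeness = unname(model$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_informativeness_tsv
#' @export
read_informativeness_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric"))
  table_model(stats::setNames(d$informativeness, d$term))
}
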