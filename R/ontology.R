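#' Default semantic contribution factors per relation type
#'
#' Edge factors used when propagating semantic contributions from a term
#' towards the root: 0.8 for `is_a`, 0.6 for `part_of` and 0.7 for the
#' whole regulates family (`regulates`, `positively_regulates`,
#' `negatively_regulates`).
#'
#' @return Named numeric vector of factors in (0,1).
#' @export
default_relation_weights <- function() {
  c(is_a = 0.8, part_of = 0.6,
    regulates = 0.7, positively_regulates = 0.7, negatively_regulates = 0.7)
}

.known_relations <- function() names(default_relation_weights())

#' Construct an ontology graph
#'
#' Builds the typed DAG used by every measure in the package. Edges are
#' directed child -> parent and carry a relation type and a semantic
#' contribution factor. Terms are opaque string identifiers; GO-format ids
#' are not required, so toy ontologies are first-class.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`
#'   (character). `name` and `namespace` may be omitted; they default to
#'   the id and `"default"`.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#'   Relations outside the five supported types are dropped with a
#'   warning. May have zero rows.
#' @param weights named numeric vector of contribution factors per
#'   relation type, values in (0,1). Defaults to
#'   [default_relation_weights()].
#' @param alt_ids optional named character vector mapping alternate ids to
#'   canonical ids.
#' @return An object of class `OntologyGraph`.
#' @export
ontology_graph <- function(terms, edges,
                           weights = default_relation_weights(),
                           alt_ids = character()) {
  if (is.character(terms)) terms <- data.frame(id = terms)
  stopifnot(is.data.frame(terms), "id" %in% names(terms))
  terms$id <- as.character(terms$id)
  if (anyDuplicated(terms$id))
    stop("duplicated term ids: ", paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  if (is.null(terms$name)) terms$name <- terms$id
  if (is.null(terms$namespace)) terms$namespace <- "default"
  terms$name <- as.character(terms$name)
  terms$namespace <- as.character(terms$namespace)

  if (missing(edges) || is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character())
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  edges$relation <- as.character(edges$relation)

  stopifnot(is.numeric(weights), all(weights > 0), all(weights < 1))
  unknown_rel <- setdiff(unique(edges$relation), names(weights))
  if (length(unknown_rel)) {
    warning("ignoring edges with unsupported relation(s): ",
            paste(unknown_rel, collapse = ", "))
    edges <- edges[edges$relation %in% names(weights), , drop = FALSE]
  }

  missing_nodes <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing_nodes))
    stop("edges reference unknown terms: ", paste(missing_nodes, collapse = ", "))

  ns <- stats::setNames(terms$namespace, terms$id)
  cross <- ns[edges$child] != ns[edges$parent]
  if (any(cross)) {
    warning("dropping ", sum(cross), " cross-namespace edge(s)")
    edges <- edges[!cross, , drop = FALSE]
  }
  edges <- unique(edges)
  edges$weight <- unname(weights[edges$relation])

  parents <- split(edges[c("parent", "relation", "weight")], edges$child)
  children <- split(edges$child, edges$parent)

  g <- structure(list(
    terms = terms[c("id", "name", "namespace")],
    edges = edges,
    parents = parents,
    children = children,
    weights = weights,
    alt_ids = alt_ids,
    cache = new.env(parent = emptyenv())
  ), class = "OntologyGraph")

  cyc <- .find_cycle(g)
  if (!is.null(cyc))
    stop("ontology graph is cyclic, e.g.: ", paste(cyc, collapse = " -> "))

  roots <- vapply(split(terms$id, terms$namespace), function(ids) {
    r <- ids[!(ids %in% names(parents))]
    if (length(r) != 1L)
      stop("namespace must have exactly one root, found ", length(r), ": ",
           paste(r, collapse = ", "))
    r
  }, character(1))
  g$roots <- roots
  g
}

# Kahn's algorithm; returns NULL when acyclic, else one cycle as id path.
.find_cycle <- function(g) {
  ids <- g$terms$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (ch in names(g$parents))
    for (p in g$parents[[ch]]$parent) indeg[p] <- indeg[p] + 1L
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in unique(g$parents[[v]]$parent)) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk the residual graph to exhibit one cycle
  rem <- names(indeg)[indeg > 0L]
  v <- rem[1L]; path <- character()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(unique(g$parents[[v]]$parent), rem)[1L]
  }
  c(path[which(path == v):length(path)], v)
}

.check_terms <- function(g, t) {
  bad <- setdiff(t, g$terms$id)
  if (length(bad))
    stop("unknown term(s): ", paste(bad, collapse = ", "))
  invisible(t)
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat("OntologyGraph:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$roots), "namespace(s)\n")
  cat("  roots:", paste(names(x$roots), x$roots, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ancestors of a term
#'
#' All terms reachable from `t` along child -> parent edges. Results are
#' memoised per graph.
#'
#' @param g an [OntologyGraph][ontology_graph].
#' @param t a term id present in `g`.
#' @param include_self if `TRUE`, return the reflexive closure (`t` included).
#' @return Character vector of term ids.
#' @export
ancestors <- function(g, t, include_self = FALSE) {
  .check_terms(g, t)
  anc <- .ancestors_memo(g, t)
  if (include_self) union(t, anc) else anc
}

.ancestors_memo <- function(g, t) {
  key <- paste0("anc:", t)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  ps <- as.character(unique(g$parents[[t]]$parent))
  out <- ps
  for (p in ps) out <- union(out, .ancestors_memo(g, p))
  assign(key, out, envir = g$cache)
  out
}

#' Descendants of a term
#'
#' Mirror of [ancestors()]: all terms from which `t` is reachable.
#'
#' @inheritParams ancestors
#' @return Character vector of term ids.
#' @export
descendants <- function(g, t, include_self = FALSE) {
  .check_terms(g, t)
  desc <- .descendants_memo(g, t)
  if (include_self) union(t, desc) else desc
}

.descendants_memo <- function(g, t) {
  key <- paste0("desc:", t)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  cs <- as.character(unique(g$children[[t]]))
  out <- cs
  for (ch in cs) out <- union(out, .descendants_memo(g, ch))
  assign(key, out, envir = g$cache)
  out
}

#' Resolve alternate ids to canonical term ids
#'
#' @inheritParams ancestors
#' @param ids character vector of term or alternate ids.
#' @return Character vector of the same length with alternate ids replaced
#'   by their canonical id; ids unknown in either table are returned as-is.
#' @export
resolve_ids <- function(g, ids) {
  hit <- ids %in% names(g$alt_ids)
  ids[hit] <- unname(g$alt_ids[ids[hit]])
  ids
}

#' Read an ontology from an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file. Obsolete terms are
#' excluded, `alt_id`s are recorded for resolution, and only `is_a`,
#' `part_of` and the regulates-family relationships are retained as edges;
#' other relationship types are dropped with a warning. Cross-namespace
#' edges are dropped because all measures operate within one namespace.
#'
#' @param path path to an OBO file.
#' @param namespace optional namespace name; when given, only terms of
#'   that namespace are loaded.
#' @param weights contribution factors, see [ontology_graph()].
#' @return An [OntologyGraph][ontology_graph].
#' @export
load_obo <- function(path, namespace = NULL,
                     weights = default_relation_weights()) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)

  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanza found in ", path)
  bounds <- c(grep("^\\[", lines), length(lines) + 1L)

  ids <- nms <- nss <- character()
  e_child <- e_parent <- e_rel <- character()
  alt <- character()
  for (s in starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[s:end]
    field <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ": "))]
      sub("\\s*(!.*)?$", "", substring(v, nchar(tag) + 3L))
    }
    if (length(field("is_obsolete")) && any(field("is_obsolete") == "true"))
      next
    id <- field("id")[1L]
    if (is.na(id) || !length(id)) next
    nm <- field("name")[1L]
    ns <- field("namespace")[1L]
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm) && !is.na(nm)) nm else id)
    nss <- c(nss, if (length(ns) && !is.na(ns)) ns else "default")
    for (a in field("alt_id")) alt[a] <- id
    for (p in field("is_a")) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, p)
      e_rel <- c(e_rel, "is_a")
    }
    for (r in field("relationship")) {
      parts <- strsplit(trimws(r), "\\s+")[[1L]]
      if (length(parts) < 2L) next
      e_child <- c(e_child, id); e_parent <- c(e_parent, parts[2L])
      e_rel <- c(e_rel, parts[1L])
    }
  }

  terms <- data.frame(id = ids, name = nms, namespace = nss)
  edges <- data.frame(child = e_child, parent = e_parent, relation = e_rel)

  if (!is.null(namespace)) {
    terms <- terms[terms$namespace == namespace, , drop = FALSE]
    if (!nrow(terms)) stop("no terms in namespace ", namespace)
    keep <- edges$child %in% terms$id & edges$parent %in% terms$id
    edges <- edges[keep, , drop = FALSE]
  } else {
    # a parent may live outside the loaded set (e.g. truncated file): drop
    keep <- edges$parent %in% terms$id & edges$child %in% terms$id
    edges <- edges[keep, , drop = FALSE]
  }

  ontology_graph(terms, edges, weights = weights,
                 alt_ids = alt[!(names(alt) %in% terms$id)])
}

#' Write an ontology graph as OBO text
#'
#' Emits a minimal OBO 1.2 document that [load_obo()] parses back to an
#' identical graph. Used by the fixture generator for round-trip tests.
#'
#' @inheritParams ancestors
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(g$terms))) {
    id <- g$terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", g$terms$name[i]),
             paste0("namespace: ", g$terms$namespace[i]))
    pe <- g$parents[[id]]
    if (!is.null(pe)) for (j in seq_len(nrow(pe))) {
      out <- c(out, if (pe$relation[j] == "is_a")
        paste0("is_a: ", pe$parent[j])
      else paste0("relationship: ", pe$relation[j], " ", pe$parent[j]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
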