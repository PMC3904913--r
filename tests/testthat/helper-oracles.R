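# Brute-force oracles, deliberately independent of the package's memoised
# traversals: they follow the raw edge table step by step.

oracle_ancestors <- function(g, t) {
  edges <- g$edges
  out <- character()
  frontier <- t
  repeat {
    frontier <- setdiff(unique(edges$parent[edges$child %in% frontier]), out)
    if (!length(frontier)) break
    out <- union(out, frontier)
  }
  out
}

oracle_expand <- function(g, s) {
  out <- s
  for (t in s) out <- union(out, oracle_ancestors(g, t))
  out
}

oracle_mpt <- function(g, s1, s2) {
  s1 <- unique(s1)
  s2_star <- oracle_expand(g, s2)
  keep <- vapply(s1, function(t) {
    has_desc <- any(vapply(setdiff(s1, t),
                           function(s) t %in% oracle_ancestors(g, s),
                           logical(1)))
    !has_desc && !(t %in% s2_star)
  }, logical(1))
  unname(s1[keep])
}

oracle_mct <- function(g, s1, s2) {
  star1 <- oracle_expand(g, s1)
  star2 <- oracle_expand(g, s2)
  common <- intersect(star1, star2)
  pool <- union(star1, star2)
  keep <- vapply(common, function(t)
    !any(vapply(setdiff(pool, t),
                function(s) t %in% oracle_ancestors(g, s), logical(1))),
    logical(1))
  unname(common[keep])
}

oracle_mica <- function(g, model, t, s2) {
  cands <- intersect(union(t, oracle_ancestors(g, t)), oracle_expand(g, s2))
  if (!length(cands)) return(0)
  max(informativeness(model, cands))
}

# propagated frequency recounted per gene from scratch
oracle_propagated_frequency <- function(g, corpus, t) {
  covers <- vapply(corpus$gene_terms,
                   function(s) t %in% oracle_expand(g, s), logical(1))
  mean(covers)
}

# explicit double-loop best-match average over a term kernel
oracle_bma <- function(s1, s2, kernel) {
  best12 <- vapply(s1, function(a) max(vapply(s2, function(b)
    kernel(a, b), numeric(1))), numeric(1))
  best21 <- vapply(s2, function(b) max(vapply(s1, function(a)
    kernel(a, b), numeric(1))), numeric(1))
  (mean(best12) + mean(best21)) / 2
}

# --- graph builders ---------------------------------------------------------

# pure is_a chain: root <- t1 <- ... <- t<depth>
chain_graph <- function(depth, relation = "is_a") {
  ids <- c("root", paste0("t", seq_len(depth)))
  ontology_graph(
    data.frame(id = ids),
    data.frame(child = ids[-1L], parent = ids[-length(ids)],
               relation = relation))
}

# two independent random lobes hanging under one shared root; term sets
# drawn from different lobes share no ancestor besides the root
two_lobe_graph <- function(seed, lobe_terms = 10L) {
  mk <- function(prefix, off) {
    spec <- fixture_spec(n_terms = lobe_terms, seed = seed + off)
    g <- random_dag(spec)
    list(terms = paste0(prefix, g$terms$id),
         edges = data.frame(child = paste0(prefix, g$edges$child),
                            parent = paste0(prefix, g$edges$parent),
                            relation = g$edges$relation),
         root = paste0(prefix, unname(g$roots)))
  }
  a <- mk("A", 0L); b <- mk("B", 1000L)
  terms <- data.frame(id = c("root", a$terms, b$terms))
  edges <- rbind(
    data.frame(child = c(a$root, b$root), parent = "root",
               relation = "is_a"),
    a$edges, b$edges)
  g <- ontology_graph(terms, edges)
  list(graph = g, lobe_a = a$terms, lobe_b = b$terms)
}

sample_terms <- function(g, n, exclude_root = TRUE) {
  pool <- if (exclude_root) setdiff(g$terms$id, g$roots) else g$terms$id
  sample(pool, min(n, length(pool)))
}
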