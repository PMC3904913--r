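#' Specification for a synthetic ontology + corpus fixture
#'
#' Generated graphs are acyclic by construction (parents drawn only from
#' earlier-created terms) and deterministic under `seed`: generation
#' pins R's RNG to Mersenne-Twister with inversion sampling, which is
#' stable across platforms.
#'
#' @param n_terms number of terms including the single root (>= 1).
#' @param max_parents maximum parents drawn per non-root term (>= 1).
#' @param relation_mix named probabilities over `is_a`, `part_of`,
#'   `regulates` used when typing each edge.
#' @param n_genes number of genes for [random_corpus()].
#' @param annotations_per_gene length-2 integer range of direct
#'   annotations drawn per gene.
#' @param seed integer seed.
#' @return An object of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_terms = 30L, max_parents = 3L,
                         relation_mix = c(is_a = 0.7, part_of = 0.2,
                                          regulates = 0.1),
                         n_genes = 20L, annotations_per_gene = c(1L, 5L),
                         seed = 1L) {
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (max_parents < 1L) stop("max_parents must be >= 1")
  if (is.null(names(relation_mix)) || any(relation_mix < 0) ||
      sum(relation_mix) <= 0)
    stop("relation_mix must be named nonnegative probabilities")
  if (length(annotations_per_gene) != 2L ||
      annotations_per_gene[1L] > annotations_per_gene[2L])
    stop("annotations_per_gene must be an increasing length-2 range")
  structure(list(n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents),
                 relation_mix = relation_mix / sum(relation_mix),
                 n_genes = as.integer(n_genes),
                 annotations_per_gene = as.integer(annotations_per_gene),
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

# run fn under a locally pinned, seeded RNG without disturbing the caller's
.with_fixture_rng <- function(seed, offset, fn) {
  if (exists(".Random.seed", globalenv()))
    old <- get(".Random.seed", globalenv())
  else old <- NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(
    set.seed(seed + offset, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection"))
  fn()
}

#' Generate a random single-root ontology DAG
#'
#' Terms are created in order `T0001` (the root), `T0002`, ...; each later
#' term draws 1..`max_parents` parents uniformly among earlier terms, so
#' the graph is connected, acyclic and single-rooted by construction.
#' Relation types are drawn from `spec$relation_mix` (the two regulates
#' variants split the `regulates` mass).
#'
#' @param spec a [fixture_spec()].
#' @return An [OntologyGraph][ontology_graph] in namespace
#'   `"synthetic"`.
#' @export
random_dag <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .with_fixture_rng(spec$seed, 0L, function() {
    n <- spec$n_terms
    ids <- sprintf("T%04d", seq_len(n))
    rels <- c("is_a", "part_of", "positively_regulates",
              "negatively_regulates")
    p <- spec$relation_mix
    probs <- c(is_a = unname(p["is_a"]) %|0|% 0,
               part_of = unname(p["part_of"]) %|0|% 0,
               pos = (unname(p["regulates"]) %|0|% 0) / 2,
               neg = (unname(p["regulates"]) %|0|% 0) / 2)
    child <- parent <- relation <- character()
    for (i in seq_len(n)[-1L]) {
      k <- sample.int(min(spec$max_parents, i - 1L), 1L)
      ps <- sample(ids[seq_len(i - 1L)], k)
      child <- c(child, rep(ids[i], k))
      parent <- c(parent, ps)
      relation <- c(relation, sample(rels, k, replace = TRUE, prob = probs))
    }
    ontology_graph(
      data.frame(id = ids, name = paste("term", ids),
                 namespace = "synthetic"),
      data.frame(child = child, parent = parent, relation = relation))
  })
}

`%|0|%` <- function(x, default) if (length(x) && !is.na(x)) x else default

#' Generate a random annotation corpus on a graph
#'
#' Each of `spec$n_genes` genes is annotated to a uniform sample of
#' non-root terms, with a per-gene count drawn uniformly from
#' `spec$annotations_per_gene` (capped at the number of non-root terms).
#'
#' @inheritParams ancestors
#' @param spec a [fixture_spec()].
#' @return An [AnnotationCorpus][annotation_corpus]; gene ids are
#'   `gene01`, `gene02`, ...
#' @export
random_corpus <- function(g, spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  .with_fixture_rng(spec$seed, 1L, function() {
    pool <- setdiff(g$terms$id, g$roots)
    if (!length(pool)) pool <- unname(g$roots)
    lo <- min(spec$annotations_per_gene[1L], length(pool))
    hi <- min(spec$annotations_per_gene[2L], length(pool))
    genes <- sprintf("gene%02d", seq_len(spec$n_genes))
    annots <- lapply(genes, function(gn)
      sample(pool, lo + sample.int(hi - lo + 1L, 1L) - 1L))
    annotation_corpus(g, stats::setNames(annots, genes))
  })
}

#' Worked example: Exportin-5 molecular-function annotation sets
#'
#' A small molecular-function-like ontology holding the terms annotating
#' the Exportin-5 orthologs of human (hsa), rat (rno) and fruit fly
#' (dme), together with a table-backed informativeness model carrying the
#' published semantic values of the four terms the particularity
#' computation touches (tRNA binding 4.201, binding 1.8, protein
#' transporter activity 2.952, protein binding 2.44; the root's semantic
#' value is 1 by definition). The remaining intermediate terms get sealed
#' filler values so any computation that consulted one would fail loudly.
#'
#' Expected results on this fixture: MPT(hsa, dme) = {tRNA binding},
#' Par(hsa, dme) = 0.308, Par(hsa, rno) = 0.082, Par(rno, hsa) =
#' Par(dme, hsa) = 0 (no rat- or fly-specific term), all to 3 decimals.
#'
#' @return A list with `graph`, `sets` (named list `hsa`, `rno`, `dme` of
#'   term-id vectors) and `model` (a sealed [table_model()]).
#' @export
exportin5_example <- function() {
  mf <- "molecular_function"
  terms <- data.frame(
    id = c(mf, "binding", "protein binding", "nucleic acid binding",
           "RNA binding", "tRNA binding", "transporter activity",
           "substrate-specific transporter activity",
           "protein transporter activity"),
    namespace = "molecular_function")
  edges <- data.frame(
    child = c("binding", "protein binding", "nucleic acid binding",
              "RNA binding", "tRNA binding", "transporter activity",
              "substrate-specific transporter activity",
              "protein transporter activity"),
    parent = c(mf, "binding", "binding", "nucleic acid binding",
               "RNA binding", mf, "transporter activity",
               "substrate-specific transporter activity"),
    relation = "is_a")
  g <- ontology_graph(terms, edges)

  published <- c("tRNA binding" = 4.201, "binding" = 1.8,
                 "protein transporter activity" = 2.952,
                 "protein binding" = 2.44)
  fillers <- c("nucleic acid binding" = 2.44, "RNA binding" = 2.952,
               "transporter activity" = 1.8,
               "substrate-specific transporter activity" = 2.44)
  model <- table_model(
    c(published, stats::setNames(1, mf), fillers),
    sealed = names(fillers))

  sets <- list(
    hsa = c("tRNA binding", "protein binding",
            "protein transporter activity"),
    rno = c("tRNA binding", "protein transporter activity"),
    dme = c("protein binding", "protein transporter activity"))
  list(graph = g, sets = sets, model = model)
}

#' Materialise a fixture on disk
#'
#' Writes the generated ontology as OBO, the corpus in the two-column
#' annotation dialect, and the fixture spec as JSON, so external tools can
#' replay a fixture.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- random_dag(spec)
  corpus <- random_corpus(g, spec)
  paths <- c(obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             spec = file.path(dir, "fixture.json"))
  write_obo(g, paths["obo"])
  write_annotations_tsv(corpus, paths["annotations"])
  jsonlite::write_json(unclass(spec), paths["spec"], auto_unbox = TRUE)
  invisible(paths)
}
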