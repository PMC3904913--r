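#' Pairwise similarity/particularity matrix over a gene list
#'
#' Computes the (Sim, Par12, Par21) tuple for every unordered pair of
#' genes, in deterministic lexicographic order. A pair is valid only when
#' both genes carry at least one direct annotation in the namespace;
#' invalid pairs are reported with a reason instead of an error, mirroring
#' the validity accounting of large homolog screens.
#'
#' @inheritParams compare_sets
#' @param corpus_annotations an [AnnotationCorpus][annotation_corpus]
#'   supplying the direct gene annotation sets (and term frequencies for
#'   `sim_method = "lin"`).
#' @param genes character vector of gene ids (>= 2). Genes absent from
#'   the corpus yield invalid pairs, not errors.
#' @return A data.frame with one row per unordered pair: `gene1`, `gene2`,
#'   `namespace`, `n_annot1`, `n_annot2` (expanded-set sizes), `valid`,
#'   `reason` (`one-unannotated` | `both-unannotated` | `NA`), `sim`,
#'   `par12`, `par21`.
#' @export
pairwise_matrix <- function(g, model, corpus_annotations, genes,
                            sim_method = c("wang", "lin", "none"),
                            combine = "bma") {
  sim_method <- match.arg(sim_method)
  genes <- unique(as.character(genes))
  if (length(genes) < 2L)
    stop("need at least two genes for a pairwise matrix")
  genes <- sort(genes)
  gt <- corpus_annotations$gene_terms
  ns <- corpus_annotations$namespace

  rows <- vector("list", choose(length(genes), 2L))
  k <- 0L
  for (i in seq_len(length(genes) - 1L)) for (j in (i + 1L):length(genes)) {
    g1 <- genes[i]; g2 <- genes[j]
    s1 <- gt[[g1]]; s2 <- gt[[g2]]
    n_un <- sum(!length(s1), !length(s2))
    k <- k + 1L
    if (n_un > 0L) {
      rows[[k]] <- data.frame(
        gene1 = g1, gene2 = g2, namespace = ns,
        n_annot1 = length(expand_set(g, s1)),
        n_annot2 = length(expand_set(g, s2)),
        valid = FALSE,
        reason = if (n_un == 1L) "one-unannotated" else "both-unannotated",
        sim = NA_real_, par12 = NA_real_, par21 = NA_real_)
    } else {
      cmp <- compare_sets(g, model, s1, s2, sim_method = sim_method,
                          combine = combine, corpus = corpus_annotations)
      rows[[k]] <- data.frame(
        gene1 = g1, gene2 = g2, namespace = ns,
        n_annot1 = length(cmp$sg1_star), n_annot2 = length(cmp$sg2_star),
        valid = TRUE, reason = NA_character_,
        sim = cmp$sim, par12 = cmp$par12, par21 = cmp$par21)
    }
  }
  do.call(rbind, rows)
}

#' Particularity statistics per similarity bin
#'
#' Pools the particularity values of pairs whose similarity falls in each
#' of the bins spanning \[`lo`, `hi`\] in steps of `width` (defaults: 20
#' bins of width 0.025 over \[0.5, 0.999\]; bins are half-open on the
#' right, the last one closed at `hi`, so sim = 1 contributes nowhere).
#' Both Par directions contribute by default; `direction = "max"` keeps
#' only the larger one per pair.
#'
#' @param results a data.frame from [pairwise_matrix()].
#' @param lo,hi,width bin range and step.
#' @param direction `"both"` or `"max"`.
#' @param sd_type `"sample"` (n-1 denominator) or `"population"`.
#' @return data.frame with one row per bin: `bin_lo`, `bin_hi`, `n`,
#'   `mean`, `sd`, `min`, `max` (NA for empty bins).
#' @export
bin_particularity <- function(results, lo = 0.5, hi = 0.999, width = 0.025,
                              direction = c("both", "max"),
                              sd_type = c("sample", "population")) {
  direction <- match.arg(direction)
  sd_type <- match.arg(sd_type)
  r <- results[results$valid & !is.na(results$sim), , drop = FALSE]
  n_bins <- ceiling((hi - lo) / width)
  bin_lo <- lo + width * (seq_len(n_bins) - 1L)
  bin_hi <- pmin(bin_lo + width, hi)
  out <- data.frame(bin_lo = bin_lo, bin_hi = bin_hi, n = 0L,
                    mean = NA_real_, sd = NA_real_,
                    min = NA_real_, max = NA_real_)
  for (b in seq_len(n_bins)) {
    in_bin <- r$sim >= bin_lo[b] &
      (if (b == n_bins) r$sim <= bin_hi[b] else r$sim < bin_hi[b])
    par <- if (direction == "both")
      c(r$par12[in_bin], r$par21[in_bin])
    else pmax(r$par12[in_bin], r$par21[in_bin])
    out$n[b] <- length(par)
    if (length(par)) {
      out$mean[b] <- mean(par)
      out$sd[b] <- if (length(par) > 1L || sd_type == "population") {
        if (sd_type == "sample") stats::sd(par)
        else sqrt(mean((par - mean(par))^2))
      } else NA_real_
      out$min[b] <- min(par)
      out$max[b] <- max(par)
    }
  }
  out
}

#' Similarity/particularity profile classification
#'
#' Assigns every valid pair to exactly one of four mutually exclusive
#' profiles: similar with no particular gene (sim >= theta_sim, both Par
#' < theta_par), similar with exactly one particular gene, similar with
#' both particular, or dissimilar (sim < theta_sim). Percentages use the
#' valid-pair count as baseline. Invalid pairs are tallied by reason.
#'
#' @param results a data.frame from [pairwise_matrix()].
#' @param theta_sim,theta_par thresholds in (0,1), default 0.5.
#' @return A list with `profiles` (data.frame: profile, n, pct) and
#'   `validity` (data.frame: status, n), plus `n_valid` and `n_total`.
#' @export
classify_profiles <- function(results, theta_sim = 0.5, theta_par = 0.5) {
  stopifnot(theta_sim > 0, theta_sim < 1, theta_par > 0, theta_par < 1)
  v <- results[results$valid, , drop = FALSE]
  n_par_high <- (v$par12 >= theta_par) + (v$par21 >= theta_par)
  cls <- ifelse(v$sim < theta_sim, "dissimilar",
         ifelse(n_par_high == 0L, "similar-no-particular",
         ifelse(n_par_high == 1L, "similar-one-particular",
                                  "similar-both-particular")))
  levels <- c("similar-no-particular", "similar-one-particular",
              "similar-both-particular", "dissimilar")
  n <- vapply(levels, function(l) sum(cls == l), integer(1))
  profiles <- data.frame(
    profile = levels, n = unname(n),
    pct = if (nrow(v)) unname(100 * n / nrow(v)) else rep(NA_real_, 4L))
  inv <- results[!results$valid, , drop = FALSE]
  validity <- data.frame(
    status = c("two-annotated", "one-unannotated", "both-unannotated"),
    n = c(nrow(v),
          sum(inv$reason == "one-unannotated"),
          sum(inv$reason == "both-unannotated")))
  list(profiles = profiles, validity = validity,
       n_valid = nrow(v), n_total = nrow(results))
}

#' Write a pairwise matrix as a reproducible TSV
#'
#' Fixed column order, fixed row order (inherited from
#' [pairwise_matrix()]) and fixed float formatting (`\%.10g`), so two runs
#' on the same inputs produce byte-identical files.
#'
#' @param results a data.frame from [pairwise_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(results, path) {
  r <- results
  for (col in c("sim", "par12", "par21"))
    r[[col]] <- ifelse(is.na(r[[col]]), "NA", sprintf("%.10g", r[[col]]))
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise matrix TSV back
#'
#' @param path file written by [write_pairs_tsv()].
#' @return data.frame in [pairwise_matrix()] layout.
#' @export
read_pairs_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "integer", "integer", "logical",
                                   "character", "numeric", "numeric",
                                   "numeric"),
                    na.strings = "NA")
}
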