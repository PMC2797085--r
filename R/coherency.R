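# ---------------------------------------------------------------------------
# Complex coherency statistics: functional (minimal hypergeometric
# enrichment), expression (mean pairwise Pearson), conservation (mean
# pairwise Jaccard of phylogenetic profiles); empirical nulls from
# same-size random sets, Benjamini-Hochberg FDR across a collection.
# ---------------------------------------------------------------------------

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least the given overlap between a protein set
#' of size |complex| and an annotation term of size |term| when drawing
#' uniformly from a universe of `universe` proteins: P(X >= k).
#'
#' @param complex_size,term_size,overlap,universe counts.
#' @return upper-tail probability in \[0, 1\].
#' @export
hypergeom_tail_p <- function(overlap, complex_size, term_size, universe) {
  stopifnot(complex_size >= 1, universe >= complex_size, term_size <= universe,
            overlap <= min(complex_size, term_size))
  stats::phyper(overlap - 1, term_size, universe - term_size, complex_size,
                lower.tail = FALSE)
}

#' Minimal hypergeometric term probability of a complex
#'
#' Scans the annotation terms and returns the smallest upper-tail
#' hypergeometric probability, with the term achieving it. Annotations are
#' assumed pre-propagated (a gene annotated with a specific term also carries
#' its ancestors); see [propagate_annotations()].
#'
#' @param members character vector of complex members.
#' @param annotations a `gene_set_collection` of term -> annotated proteins.
#' @param universe character vector of all proteins eligible for annotation
#'   (the enrichment background).
#' @return list: `term`, `p` (minimal raw p; 1 with `term = NA` if no member
#'   is annotated).
#' @export
best_term_p <- function(members, annotations, universe) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("empty complex")
  members <- intersect(members, universe)
  N <- length(universe)
  best <- list(term = NA_character_, p = 1)
  for (nm in names(annotations)) {
    term <- intersect(annotations[[nm]], universe)
    k <- length(intersect(members, term))
    if (k == 0L) next
    p <- hypergeom_tail_p(k, length(members), length(term), N)
    if (p < best$p) best <- list(term = nm, p = p)
  }
  best
}

# shared machinery: empirical p of an observed statistic against same-size
# random draws; `extreme` says which tail counts as at least as extreme.
empirical_p <- function(observed, null_stats, extreme = c("low", "high")) {
  extreme <- match.arg(extreme)
  hits <- if (extreme == "low") sum(null_stats <= observed + 1e-12)
          else sum(null_stats >= observed - 1e-12)
  (1 + hits) / (1 + length(null_stats))
}

#' Functional coherency of a complex
#'
#' Finds the annotation term with minimal hypergeometric probability for the
#' complex, then computes an empirical p-value by comparing that minimal
#' probability against those of `n_null` random protein sets of the same
#' size, drawn from the annotated universe. The add-one estimator
#' (1 + hits) / (1 + n_null) avoids zero p-values.
#'
#' @param members complex member IDs.
#' @param annotations `gene_set_collection` (pre-propagated).
#' @param universe background protein IDs.
#' @param n_null number of random sets (>= 100; classical choice 10,000).
#' @param seed integer seed for the random draws.
#' @return list: `term`, `raw_p`, `empirical_p`, `flagged` (TRUE when no
#'   member is annotated, in which case `empirical_p = 1`).
#' @export
functional_coherency <- function(members, annotations, universe,
                                 n_null = 10000, seed = 1L) {
  if (n_null < 100) stop("n_null must be >= 100")
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("empty complex")
  members <- intersect(members, universe)
  annotated <- unique(unlist(annotations))
  if (!any(members %in% annotated))
    return(list(term = NA_character_, raw_p = 1, empirical_p = 1,
                flagged = TRUE))
  obs <- best_term_p(members, annotations, universe)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(n_null), function(i) {
    best_term_p(sample(universe, length(members)), annotations, universe)$p
  }, 0)
  list(term = obs$term, raw_p = obs$p,
       empirical_p = empirical_p(obs$p, nulls, "low"), flagged = FALSE)
}

mean_pairwise <- function(ids, fun) {
  n <- length(ids)
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- fun(ids[i], ids[j])
    if (!is.na(v)) vals <- c(vals, v)
  }
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

mean_pairwise_cor <- function(members, expression) {
  members <- intersect(members, rownames(expression))
  if (length(members) < 2L) return(NA_real_)
  X <- expression[members, , drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  X <- X[sds > 0, , drop = FALSE]          # constant profiles: r undefined
  if (nrow(X) < 2L) return(NA_real_)
  cm <- stats::cor(t(X))
  mean(cm[upper.tri(cm)])
}

mean_pairwise_jaccard <- function(members, profiles) {
  members <- intersect(members, rownames(profiles))
  if (length(members) < 2L) return(NA_real_)
  X <- profiles[members, , drop = FALSE] > 0
  n <- nrow(X)
  inter <- tcrossprod(X * 1)
  sizes <- rowSums(X)
  un <- outer(sizes, sizes, "+") - inter
  jac <- ifelse(un == 0, 0, inter / pmax(un, 1))  # two empty profiles -> 0
  mean(jac[upper.tri(jac)])
}

#' Expression coherency of a complex
#'
#' Statistic: mean pairwise Pearson correlation of the members' expression
#' profiles (pairs involving a constant profile are excluded). Empirical p
#' compares the observed mean against random same-size sets drawn from the
#' profiled genes.
#'
#' @param members complex member IDs.
#' @param expression gene-by-condition numeric matrix (>= 3 conditions).
#' @param n_null number of random sets.
#' @param seed integer seed.
#' @return list: `statistic` (mean r), `empirical_p`, `flagged` (TRUE if
#'   fewer than 2 members have profiles; then `empirical_p = 1`).
#' @export
expression_coherency <- function(members, expression, n_null = 10000,
                                 seed = 1L) {
  if (ncol(expression) < 3L) stop("need at least 3 conditions")
  obs <- mean_pairwise_cor(members, expression)
  if (is.na(obs))
    return(list(statistic = NA_real_, empirical_p = 1, flagged = TRUE))
  k <- length(intersect(members, rownames(expression)))
  pool <- rownames(expression)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(n_null), function(i) {
    v <- mean_pairwise_cor(sample(pool, k), expression)
    if (is.na(v)) -Inf else v
  }, 0)
  list(statistic = obs, empirical_p = empirical_p(obs, nulls, "high"),
       flagged = FALSE)
}

#' Conservation coherency of a complex
#'
#' Statistic: mean pairwise Jaccard similarity of the members' binary
#' phylogenetic profiles (presence/absence across a panel of genomes). A
#' pair of all-zero profiles has Jaccard 0. Empirical p as in
#' [expression_coherency()], drawing from the profiled genes.
#'
#' @param members complex member IDs.
#' @param profiles gene-by-species binary matrix.
#' @param n_null number of random sets.
#' @param seed integer seed.
#' @return list: `statistic` (mean Jaccard), `empirical_p`, `flagged`.
#' @export
conservation_coherency <- function(members, profiles, n_null = 10000,
                                   seed = 1L) {
  obs <- mean_pairwise_jaccard(members, profiles)
  if (is.na(obs))
    return(list(statistic = NA_real_, empirical_p = 1, flagged = TRUE))
  k <- length(intersect(members, rownames(profiles)))
  pool <- rownames(profiles)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(n_null), function(i) {
    mean_pairwise_jaccard(sample(pool, k), profiles)
  }, 0)
  list(statistic = obs, empirical_p = empirical_p(obs, nulls, "high"),
       flagged = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotone-enforced and capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values, same order as input.
#' @export
fdr_bh <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Propagate annotations up a term hierarchy
#'
#' A gene annotated with a specific term is also annotated with every
#' ancestor of that term. Given a parent-child edge table, returns the
#' collection with each term's membership augmented by all descendants'.
#'
#' @param annotations `gene_set_collection` of direct annotations.
#' @param parent_child data.frame with columns `parent`, `child` (term IDs).
#' @return augmented `gene_set_collection`.
#' @export
propagate_annotations <- function(annotations, parent_child) {
  kids <- split(as.character(parent_child$child),
                as.character(parent_child$parent))
  descend <- function(term) {
    seen <- character(0)
    queue <- term
    while (length(queue)) {
      t <- queue[[1L]]; queue <- queue[-1L]
      ch <- setdiff(kids[[t]] %||% character(0), seen)
      seen <- c(seen, ch)
      queue <- c(queue, ch)
    }
    seen
  }
  out <- lapply(names(annotations), function(nm) {
    terms <- c(nm, descend(nm))
    unique(unlist(annotations[intersect(terms, names(annotations))]))
  })
  names(out) <- names(annotations)
  gene_set_collection(out, attr(annotations, "descriptions"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coherency report for a complex collection
#'
#' Runs all three coherency statistics on every complex, corrects each
#' measure's empirical p-values across the collection with
#' Benjamini-Hochberg, and summarizes the percent of complexes deemed
#' coherent. A complex is "coherent" under a measure when its corrected
#' q-value is below `threshold`; the percent passing at raw empirical p is
#' reported alongside for calibration checks.
#'
#' @param complexes a `gene_set_collection` (or list of `complex_candidate`).
#' @param annotations `gene_set_collection` of (pre-propagated) terms.
#' @param expression gene-by-condition matrix.
#' @param profiles gene-by-species binary matrix.
#' @param universe background proteins for the functional test; defaults to
#'   the union of annotated genes.
#' @param threshold significance threshold on the corrected q (default 0.05).
#' @param n_null random sets per empirical null.
#' @param seed integer seed.
#' @return list of class `coherency_report`: `per_complex` data.frame
#'   (statistics, empirical p, q per measure) and `summary` data.frame
#'   (percent coherent per measure at q < threshold and at raw p <
#'   threshold).
#' @export
coherency_report <- function(complexes, annotations, expression, profiles,
                             universe = NULL, threshold = 0.05,
                             n_null = 10000, seed = 1L) {
  if (length(complexes) == 0L) stop("empty complex collection")
  if (inherits(complexes[[1]], "complex_candidate"))
    complexes <- complexes_to_gene_sets(complexes)
  if (is.null(universe)) universe <- sort(unique(unlist(annotations)))
  seed <- as.integer(seed)

  rows <- lapply(seq_along(complexes), function(i) {
    m <- complexes[[i]]
    fc <- functional_coherency(m, annotations, universe, n_null, seed + i)
    ec <- expression_coherency(m, expression, n_null, seed + i)
    cc <- conservation_coherency(m, profiles, n_null, seed + i)
    data.frame(complex = names(complexes)[i], size = length(m),
               functional_term = fc$term, functional_raw_p = fc$raw_p,
               functional_p = fc$empirical_p,
               expression_stat = ec$statistic, expression_p = ec$empirical_p,
               conservation_stat = cc$statistic,
               conservation_p = cc$empirical_p,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$functional_q <- fdr_bh(per$functional_p)
  per$expression_q <- fdr_bh(per$expression_p)
  per$conservation_q <- fdr_bh(per$conservation_p)

  pct <- function(x) 100 * mean(x < threshold)
  summary <- data.frame(
    measure = c("functional", "expression", "conservation"),
    percent_coherent = c(pct(per$functional_q), pct(per$expression_q),
                         pct(per$conservation_q)),
    percent_raw = c(pct(per$functional_p), pct(per$expression_p),
                    pct(per$conservation_p))
  )
  structure(list(per_complex = per, summary = summary,
                 threshold = threshold),
            class = "coherency_report")
}

#' @export
print.coherency_report <- function(x, ...) {
  cat(sprintf("coherency_report: %d complexes, q threshold %.3g\n",
              nrow(x$per_complex), x$threshold))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
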