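# ---------------------------------------------------------------------------
# Cross-validation harness: artificial linkage intervals, rank bookkeeping,
# LOO / k-fold trials, precision-recall curves.
# ---------------------------------------------------------------------------

#' Build an artificial linkage interval around a protein
#'
#' Returns the protein plus its nearest neighbours in a given genome
#' ordering, as a centered window of exactly `size` genes when the ordering
#' is long enough. Truncation at either end of the list is compensated by
#' extending the other side.
#'
#' @param protein protein ID; must occur in `genome_order`.
#' @param genome_order character vector of all proteins in genomic order.
#' @param size interval size in genes (the conventional benchmark uses 100).
#' @return a `candidate_interval` containing `protein`.
#' @export
make_artificial_interval <- function(protein, genome_order, size = 100) {
  pos <- match(protein, genome_order)
  if (is.na(pos)) stop(sprintf("protein '%s' not in genome order", protein))
  if (size < 1) stop("size must be >= 1")
  n <- length(genome_order)
  if (n <= size) {
    if (n < size) warning("genome order shorter than interval size; using all genes")
    return(candidate_interval(genome_order))
  }
  half_left <- (size - 1L) %/% 2L
  start <- pos - half_left
  start <- max(1L, min(start, n - size + 1L))
  candidate_interval(genome_order[start:(start + size - 1L)])
}

#' Competition rank of a target among candidates
#'
#' Pessimistic, deterministic ranking: candidates are ordered by decreasing
#' score with ties broken by lexicographic protein ID; the rank is the
#' target's 1-based position. Candidates missing from `scores` count as
#' `-Inf`.
#'
#' @param scores named numeric vector (or `propagation_result`).
#' @param candidates a `candidate_interval` or character vector.
#' @param target protein ID; must be among the candidates.
#' @return integer rank (1 = best).
#' @export
rank_of <- function(scores, candidates, target) {
  if (inherits(scores, "propagation_result")) scores <- scores$scores
  if (inherits(candidates, "candidate_interval")) candidates <- candidates$candidates
  if (!target %in% candidates) stop(sprintf("target '%s' not among candidates", target))
  s <- scores[candidates]
  s[is.na(s)] <- -Inf
  ord <- candidates[order(-s, candidates)]
  match(target, ord)
}

#' Run cross-validation over known gene-disease associations
#'
#' Reproduces the standard hide-and-recover benchmark. For each held-out
#' association (disease q, protein p), the prior is rebuilt with (q, p) and
#' every other association of p hidden — hiding all of p's associations
#' avoids trivially easy trials where p is also annotated to a near-identical
#' disease — the chosen scorer is run, and the rank of p inside an artificial
#' interval of `interval_size` genes around p is recorded. In k-fold mode the
#' whole held-out fold is hidden in addition to p's associations.
#'
#' @param network `weighted_network`.
#' @param sims `disease_similarity`.
#' @param associations `association_table` (the ground truth being held out).
#' @param genome_order protein ordering used to build artificial intervals;
#'   `NULL` ranks within the whole network.
#' @param folds `"loo"` (default) or an integer number of folds.
#' @param method `"prince"`, `"rwr"` or `"cipher-dn"`.
#' @param interval_size interval width in genes.
#' @param params,alpha,restart,exact scorer settings (see [score_disease()]).
#' @param seed integer seed controlling the fold shuffle.
#' @return data.frame of class `cv_trials`: one row per trial with columns
#'   `disease`, `protein`, `rank`, `n_candidates`, `flagged` (TRUE when the
#'   trial had no informative prior and the rank was set to the worst case).
#' @export
run_cv <- function(network, sims, associations, genome_order = NULL,
                   folds = "loo", method = "prince", interval_size = 100,
                   params = logistic_params(), alpha = 0.9, restart = 0.75,
                   exact = FALSE, seed = 1L) {
  assoc <- as.data.frame(associations)
  if (nrow(assoc) == 0L) stop("no associations to cross-validate")
  if (is.null(genome_order)) genome_order <- network$proteins

  n <- nrow(assoc)
  if (identical(folds, "loo") || (is.numeric(folds) && folds >= n)) {
    fold_id <- seq_len(n)
  } else {
    k <- as.integer(folds)
    if (is.na(k) || k < 2L) stop("folds must be 'loo' or an integer >= 2")
    set.seed(as.integer(seed))
    fold_id <- sample(rep_len(seq_len(k), n))
  }

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    q <- assoc$disease[i]
    p <- assoc$protein[i]
    in_fold <- fold_id == fold_id[i]
    hide <- unique(rbind(assoc[in_fold, c("disease", "protein")],
                         assoc[assoc$protein == p, c("disease", "protein")]))
    interval <- make_artificial_interval(p, genome_order, interval_size)
    surviving <- assoc[!(paste(assoc$disease, assoc$protein) %in%
                           paste(hide$disease, hide$protein)), , drop = FALSE]
    flagged <- FALSE
    if (method == "cipher-dn" && length(unique(surviving$disease)) < 2L) {
      r <- length(interval$candidates); flagged <- TRUE
    } else {
      scores <- score_disease(method, q, network, sims, assoc,
                              params = params, exclude = hide,
                              alpha = alpha, restart = restart, exact = exact,
                              candidates = interval$candidates)
      if (all(!is.finite(scores[interval$candidates]) |
              scores[interval$candidates] == 0)) flagged <- TRUE
      r <- rank_of(scores, interval, p)
    }
    trials[[i]] <- data.frame(disease = q, protein = p, rank = r,
                              n_candidates = length(interval$candidates),
                              flagged = flagged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, trials)
  attr(out, "method") <- method
  attr(out, "folds") <- folds
  class(out) <- c("cv_trials", "data.frame")
  out
}

#' Precision-recall curve over cross-validation trials
#'
#' For each rank threshold k, recall is the fraction of trials whose hidden
#' association was recovered within the top k. Precision is the fraction of
#' true associations ranked within the top k of their own trial; with one
#' hidden association per trial the two coincide, and both are reported.
#'
#' @param trials a `cv_trials` data.frame.
#' @param ks integer rank thresholds.
#' @return data.frame (class `pr_curve`) with columns `k`, `precision`,
#'   `recall`.
#' @export
precision_recall <- function(trials, ks = c(1, 2, 5, 10, 20, 50, 100)) {
  trials <- as.data.frame(trials)
  if (nrow(trials) == 0L) stop("no trials")
  ks <- sort(unique(as.integer(ks)))
  rec <- vapply(ks, function(k) mean(trials$rank <= k), 0)
  out <- data.frame(k = ks, precision = rec, recall = rec)
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Fraction of trials that ranked the hidden gene within the top k
#' @param trials a `cv_trials` data.frame.
#' @param k rank threshold (default 1: the top-1 success rate).
#' @return scalar success rate.
#' @export
top_rate <- function(trials, k = 1) mean(as.data.frame(trials)$rank <= k)
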