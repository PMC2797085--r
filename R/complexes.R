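# ---------------------------------------------------------------------------
# Disease-associated protein complex inference: seeded greedy growth over
# propagation scores, log-likelihood-ratio scoring against a degree-based
# random null, connectivity-preserving refinement, size/overlap filters.
# ---------------------------------------------------------------------------

#' Parameters of the complex model
#'
#' @param gamma assumed within-complex pairwise interaction probability.
#' @param beta minimum propagation score for a protein to enter a complex.
#'   Conventional defaults are 0.1 when the query disease has a known causal
#'   gene and 0.015 when only a linkage interval is known; see
#'   [tune_beta_to_size()] for data-driven calibration.
#' @param max_size growth cap per seed (about twice the average size of
#'   curated complexes).
#' @param seed_count number of top-scoring proteins used as seeds.
#' @param min_size smallest complex reported.
#' @param overlap_threshold candidates overlapping a higher-scoring kept
#'   candidate by at least this fraction (of the smaller set) are discarded.
#' @param eps clamp for null edge probabilities, keeping all log-ratios finite.
#' @return list of class `complex_model_params`.
#' @export
complex_model_params <- function(gamma = 0.9, beta = 0.1, max_size = 20,
                                 seed_count = 100, min_size = 4,
                                 overlap_threshold = 0.8, eps = 1e-6) {
  stopifnot(gamma > 0, gamma < 1, max_size >= min_size, min_size >= 2,
            overlap_threshold > 0, overlap_threshold <= 1, eps > 0, eps < 0.5)
  structure(list(gamma = gamma, beta = beta, max_size = as.integer(max_size),
                 seed_count = as.integer(seed_count),
                 min_size = as.integer(min_size),
                 overlap_threshold = overlap_threshold, eps = eps),
            class = "complex_model_params")
}

#' Null probability of an interaction between two proteins
#'
#' Under the random null, an edge between u and v arises with probability
#' proportional to the product of their weighted degrees:
#' p(u,v) = d(u) d(v) / (2 * total edge weight), clamped to
#' \[eps, 1 - eps\]. This is the expected-edge probability of a
#' configuration-style random graph with the observed (weighted) degree
#' sequence.
#'
#' @param network a `weighted_network`.
#' @param u,v distinct protein IDs.
#' @param eps clamp bound.
#' @return probability in \[eps, 1 - eps\].
#' @export
null_edge_prob <- function(network, u, v, eps = 1e-6) {
  stopifnot(inherits(network, "weighted_network"))
  if (identical(u, v)) stop("u and v must be distinct")
  d <- node_degrees(network)
  if (!u %in% names(d) || !v %in% names(d)) stop("protein not in network")
  total <- sum(network$edges$weight)
  pmin(pmax(d[[u]] * d[[v]] / (2 * total), eps), 1 - eps)
}

#' Log-likelihood-ratio score of a protein set as a complex
#'
#' Compares two generative models of the induced subnetwork, summing over all
#' unordered member pairs. The complex model says each pair interacts with
#' high probability `gamma`, independently of all other pairs; the null says
#' a pair interacts with the degree-based probability p(u,v) of
#' [null_edge_prob()]. Interaction status is a noisy observation: a reported
#' edge with confidence r contributes
#' log\[(gamma r + (1-gamma)(1-r)) / (p r + (1-p)(1-r))\], marginalizing over
#' whether the reported edge is real; an unreported pair contributes
#' log\[(1-gamma) / (1-p)\].
#'
#' @param members character vector of at least 2 protein IDs.
#' @param network a `weighted_network`.
#' @param params [complex_model_params()].
#' @return scalar log-likelihood ratio (natural log).
#' @export
complex_score <- function(members, network, params = complex_model_params()) {
  members <- unique(as.character(members))
  if (length(members) < 2L) stop("a complex needs at least 2 proteins")
  if (!all(members %in% network$proteins)) stop("member(s) absent from network")
  gamma <- params$gamma
  eps <- params$eps
  d <- node_degrees(network)[members]
  total <- sum(network$edges$weight)
  Wsub <- as.matrix(network$W[members, members, drop = FALSE])
  n <- length(members)
  pm <- outer(d, d) / (2 * total)
  pm <- pmin(pmax(pm, eps), 1 - eps)
  r <- Wsub
  ut <- upper.tri(r)
  rr <- r[ut]
  pp <- pm[ut]
  obs <- rr > 0
  contrib <- numeric(length(rr))
  contrib[obs] <- log((gamma * rr[obs] + (1 - gamma) * (1 - rr[obs])) /
                      (pp[obs] * rr[obs] + (1 - pp[obs]) * (1 - rr[obs])))
  contrib[!obs] <- log((1 - gamma) / (1 - pp[!obs]))
  sum(contrib)
}

complex_candidate <- function(members, seed, score, disease = NA_character_) {
  structure(list(members = sort(unique(members)), seed = seed,
                 score = score, disease = disease),
            class = "complex_candidate")
}

#' @export
print.complex_candidate <- function(x, ...) {
  cat(sprintf("complex_candidate (seed %s, score %.3f, %d proteins): %s\n",
              x$seed, x$score, length(x$members),
              paste(x$members, collapse = " ")))
  invisible(x)
}

# induced observed-edge subgraph connectivity
members_connected <- function(members, network) {
  if (length(members) <= 1L) return(TRUE)
  Wsub <- network$W[members, members, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(Wsub > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::is_connected(g)
}

#' Grow complex candidates from top-scoring seeds
#'
#' Seeds are the `seed_count` highest-scoring proteins network-wide,
#' processed in decreasing score order (ties broken by protein ID). Seeds
#' scoring below `beta`, or already contained in a previously grown candidate
#' for this disease, are skipped. From each seed, the neighbour of the
#' current set with the highest propagation score is added repeatedly, as
#' long as that score exceeds `beta` and the set holds fewer than `max_size`
#' proteins. When a linkage interval is supplied (query disease with no known
#' causal gene), candidates containing no interval member are discarded.
#'
#' @param scores named propagation score vector (or `propagation_result`).
#' @param network a `weighted_network`.
#' @param params [complex_model_params()].
#' @param interval optional `candidate_interval` membership constraint.
#' @param disease disease ID recorded on the candidates.
#' @return list of `complex_candidate` (scored, unrefined).
#' @export
grow_from_seeds <- function(scores, network, params = complex_model_params(),
                            interval = NULL, disease = NA_character_) {
  if (inherits(scores, "propagation_result")) {
    if (is.na(disease)) disease <- scores$query
    scores <- scores$scores
  }
  f <- setNames(numeric(length(network$proteins)), network$proteins)
  f[intersect(names(scores), network$proteins)] <-
    scores[intersect(names(scores), network$proteins)]
  ord <- network$proteins[order(-f, network$proteins)]
  seeds <- utils::head(ord, params$seed_count)
  if (!is.null(interval) && inherits(interval, "candidate_interval"))
    interval <- interval$candidates

  covered <- character(0)
  out <- list()
  for (seed in seeds) {
    if (f[[seed]] < params$beta) next
    if (seed %in% covered) next
    members <- seed
    repeat {
      if (length(members) >= params$max_size) break
      nb <- setdiff(network$proteins[Matrix::rowSums(
        network$W[, members, drop = FALSE]) > 0], members)
      if (length(nb) == 0L) break
      nb <- nb[order(-f[nb], nb)]
      best <- nb[1L]
      if (!(f[[best]] > params$beta)) break
      members <- c(members, best)
    }
    if (length(members) < 2L) next
    if (!is.null(interval) && !any(members %in% interval)) next
    covered <- union(covered, members)
    out[[length(out) + 1L]] <-
      complex_candidate(members, seed,
                        complex_score(members, network, params), disease)
  }
  out
}

#' Refine a complex candidate by connectivity-preserving removals
#'
#' Repeatedly removes the member whose removal increases the
#' log-likelihood-ratio score the most, among removals that keep the induced
#' observed-edge subgraph connected (and at least 2 proteins). Stops when no
#' removal strictly improves the score, so the output score is never below
#' the input score, and the operation is idempotent.
#'
#' @param candidate a `complex_candidate`.
#' @param network a `weighted_network`.
#' @param params [complex_model_params()].
#' @return refined `complex_candidate`.
#' @export
refine_complex <- function(candidate, network, params = complex_model_params()) {
  members <- candidate$members
  score <- candidate$score
  repeat {
    if (length(members) <= 2L) break
    best_gain <- 0
    best_members <- NULL
    best_score <- NA_real_
    for (m in sort(members)) {
      trial <- setdiff(members, m)
      if (!members_connected(trial, network)) next
      s <- complex_score(trial, network, params)
      if (s - score > best_gain + 1e-12) {
        best_gain <- s - score
        best_members <- trial
        best_score <- s
      }
    }
    if (is.null(best_members)) break
    members <- best_members
    score <- best_score
  }
  complex_candidate(members, candidate$seed, score, candidate$disease)
}

#' Filter complex candidates by size and mutual overlap
#'
#' Drops candidates smaller than `min_size`, sorts the rest by decreasing
#' score (ties broken by member list), and greedily keeps a candidate only if
#' its overlap |A∩B| / min(|A|, |B|) with every kept candidate is below
#' `overlap_threshold`.
#'
#' @param candidates list of `complex_candidate`.
#' @param params [complex_model_params()].
#' @return filtered list, ordered by decreasing score.
#' @export
filter_complexes <- function(candidates, params = complex_model_params()) {
  if (length(candidates) == 0L) return(list())
  sizes <- vapply(candidates, function(x) length(x$members), 0L)
  candidates <- candidates[sizes >= params$min_size]
  if (length(candidates) == 0L) return(list())
  scores <- vapply(candidates, `[[`, 0, "score")
  keys <- vapply(candidates, function(x) paste(x$members, collapse = " "), "")
  candidates <- candidates[order(-scores, keys)]
  kept <- list()
  for (cand in candidates) {
    ok <- TRUE
    for (k in kept) {
      ov <- length(intersect(cand$members, k$members)) /
        min(length(cand$members), length(k$members))
      if (ov >= params$overlap_threshold) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' Infer disease-associated protein complexes end to end
#'
#' Propagates the query disease's prior over the network, grows candidates
#' from the top-scoring seeds, refines each by connectivity-preserving
#' removals, and applies the size and overlap filters. Fully deterministic.
#'
#' @param query disease ID.
#' @param network `weighted_network`.
#' @param sims `disease_similarity`.
#' @param associations `association_table`.
#' @param params [complex_model_params()].
#' @param lparams [logistic_params()].
#' @param alpha propagation mixing parameter.
#' @param interval optional `candidate_interval` (locus-only disease case).
#' @param exclude optional association exclusions (cross-validation).
#' @return list of refined, filtered `complex_candidate`.
#' @export
infer_complexes <- function(query, network, sims, associations,
                            params = complex_model_params(),
                            lparams = logistic_params(), alpha = 0.9,
                            interval = NULL, exclude = NULL) {
  prior <- build_prior(query, network, associations, sims, lparams, exclude)
  res <- propagate_iterative(normalize_network(network), prior, alpha)
  cands <- grow_from_seeds(res, network, params, interval, disease = query)
  cands <- lapply(cands, refine_complex, network = network, params = params)
  filter_complexes(cands, params)
}

#' Calibrate beta so inferred complexes match a reference mean size
#'
#' Scans a grid of `beta` values, infers complexes for every query disease at
#' each, and returns the beta whose mean complex size is closest to the mean
#' size of a reference collection (e.g. curated complexes). This mirrors the
#' usual practice of tuning the membership threshold to reproduce the size
#' distribution of known complexes.
#'
#' @param queries character vector of disease IDs to infer over.
#' @param network,sims,associations data bundle.
#' @param reference_sizes integer vector of reference complex sizes (or a
#'   `gene_set_collection`, whose set sizes are used).
#' @param betas grid of candidate thresholds.
#' @param params base [complex_model_params()] (beta is overridden).
#' @param ... passed to [infer_complexes()].
#' @return list: `beta` (chosen), `mean_size` achieved, `table` of the scan.
#' @export
tune_beta_to_size <- function(queries, network, sims, associations,
                              reference_sizes,
                              betas = c(0.005, 0.015, 0.05, 0.1, 0.2, 0.4),
                              params = complex_model_params(), ...) {
  if (inherits(reference_sizes, "gene_set_collection"))
    reference_sizes <- lengths(reference_sizes)
  target <- mean(reference_sizes)
  rows <- lapply(betas, function(b) {
    p <- params; p$beta <- b
    sizes <- unlist(lapply(queries, function(q) {
      vapply(infer_complexes(q, network, sims, associations, p, ...),
             function(x) length(x$members), 0L)
    }))
    data.frame(beta = b, n_complexes = length(sizes),
               mean_size = if (length(sizes)) mean(sizes) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$mean_size)
  if (!any(ok)) stop("no beta on the grid produced any complex")
  best <- tab$beta[ok][which.min(abs(tab$mean_size[ok] - target))]
  list(beta = best, mean_size = tab$mean_size[tab$beta == best], table = tab)
}

#' Convert complex candidates to a gene-set collection
#' @param candidates list of `complex_candidate`.
#' @return a `gene_set_collection` named `<disease>_complex_<i>`.
#' @export
complexes_to_gene_sets <- function(candidates) {
  if (length(candidates) == 0L)
    return(gene_set_collection(structure(list(), names = character(0))))
  nm <- vapply(seq_along(candidates), function(i) {
    d <- candidates[[i]]$disease
    sprintf("%s_complex_%d", if (is.na(d)) "query" else d, i)
  }, "")
  desc <- vapply(candidates, function(x) sprintf("score=%.4f seed=%s",
                                                 x$score, x$seed), "")
  gene_set_collection(setNames(lapply(candidates, `[[`, "members"), nm),
                      descriptions = setNames(desc, nm))
}
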