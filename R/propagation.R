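# ---------------------------------------------------------------------------
# Degree-normalized network propagation, exact solver, and the two
# baseline prioritizers (random walk with restart; direct-neighbor
# phenotype-correlation).
# ---------------------------------------------------------------------------

#' Degree-normalize a weighted network
#'
#' Divides each edge weight by the square root of the product of its
#' endpoints' weighted degrees: Wn = D^(-1/2) W D^(-1/2). Wn is symmetric,
#' similar to the row-stochastic matrix D^(-1) W, so its spectrum lies in
#' \[-1, 1\], which guarantees convergence of the propagation iteration for
#' any mixing parameter alpha < 1. Wn is invariant under uniform rescaling of
#' all edge weights.
#'
#' @param network a `weighted_network` with no zero-degree nodes.
#' @return list of class `normalized_network`: `base`, `Wn` (sparse
#'   symmetric), `degrees`.
#' @export
normalize_network <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  d <- node_degrees(network)
  if (any(d <= 0))
    stop("zero-degree node encountered; isolated proteins must be dropped at load")
  inv_sqrt <- Matrix::Diagonal(x = 1 / sqrt(d))
  Wn <- inv_sqrt %*% network$W %*% inv_sqrt
  dimnames(Wn) <- dimnames(network$W)
  structure(list(base = network, Wn = Wn, degrees = d),
            class = "normalized_network")
}

propagation_result <- function(query, scores, alpha, iterations, converged,
                               residual, method = "prince") {
  structure(list(query = query, scores = scores, alpha = alpha,
                 iterations = iterations, converged = converged,
                 residual = residual, method = method),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("propagation_result [%s] query=%s alpha=%g iter=%d converged=%s\n",
              x$method, x$query, x$alpha, x$iterations, x$converged))
  invisible(x)
}

as_prior_y <- function(Y, proteins) {
  if (inherits(Y, "prior_vector")) Y <- Y$y
  if (is.null(names(Y))) {
    stopifnot(length(Y) == length(proteins))
    names(Y) <- proteins
  }
  y <- setNames(numeric(length(proteins)), proteins)
  common <- intersect(names(Y), proteins)
  y[common] <- Y[common]
  if (any(y < 0)) stop("prior values must be nonnegative")
  y
}

#' Iterative network propagation
#'
#' Runs the diffusion iteration F_t = alpha * Wn %*% F_{t-1} + (1-alpha) * Y
#' starting from F_0 = Y, until the maximum absolute change drops below `tol`
#' or `max_iter` is reached. The fixed point balances smoothness over the
#' network against fidelity to the prior; alpha weighs the two. alpha = 0 is
#' accepted as the closed prior-only limit, returning F = Y exactly.
#'
#' @param norm a `normalized_network`.
#' @param Y a `prior_vector` or named nonnegative numeric vector.
#' @param alpha mixing parameter in \[0, 1).
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the max-abs update.
#' @return a `propagation_result`.
#' @export
propagate_iterative <- function(norm, Y, alpha = 0.9, max_iter = 1000,
                                tol = 1e-6) {
  stopifnot(inherits(norm, "normalized_network"))
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  query <- if (inherits(Y, "prior_vector")) Y$query else NA_character_
  y <- as_prior_y(Y, norm$base$proteins)
  if (alpha == 0)
    return(propagation_result(query, y, alpha, 0L, TRUE, 0))
  f <- y
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f_new <- as.numeric(alpha * (norm$Wn %*% f)) + (1 - alpha) * y
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) break
  }
  names(f) <- norm$base$proteins
  propagation_result(query, f, alpha, it, resid < tol, resid)
}

#' Exact network propagation by linear solve
#'
#' Solves (I - alpha * Wn) F = (1 - alpha) Y directly. Because the spectrum
#' of Wn lies in \[-1, 1\], the system matrix is nonsingular for any
#' alpha < 1, and the solution is the limit of [propagate_iterative()].
#'
#' @inheritParams propagate_iterative
#' @return a `propagation_result` with `iterations = 0`, `converged = TRUE`.
#' @export
propagate_exact <- function(norm, Y, alpha = 0.9) {
  stopifnot(inherits(norm, "normalized_network"))
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)")
  query <- if (inherits(Y, "prior_vector")) Y$query else NA_character_
  y <- as_prior_y(Y, norm$base$proteins)
  if (alpha == 0)
    return(propagation_result(query, y, alpha, 0L, TRUE, 0))
  n <- length(y)
  A <- Matrix::Diagonal(n) - alpha * norm$Wn
  f <- tryCatch(as.numeric(Matrix::solve(A, (1 - alpha) * y)),
                error = function(e) stop("propagation system is singular: ",
                                         conditionMessage(e)))
  names(f) <- norm$base$proteins
  propagation_result(query, f, alpha, 0L, TRUE, 0)
}

#' Smoothness-plus-prior objective of a score vector
#'
#' The quadratic objective the propagation fixed point minimizes:
#' sum over edges of Wn(u,v) * (F(u)/sqrt(1) - F(v))^2 in normalized form
#' plus the squared deviation from the prior, weighted 1-alpha against alpha.
#' Exposed for diagnostics; lower is smoother/more faithful.
#'
#' @param norm a `normalized_network`.
#' @param f named score vector.
#' @param Y prior vector (same alignment).
#' @param alpha mixing parameter.
#' @return scalar objective value.
#' @export
propagation_objective <- function(norm, f, Y, alpha = 0.9) {
  y <- as_prior_y(Y, norm$base$proteins)
  f <- f[norm$base$proteins]
  smooth <- as.numeric(t(f) %*% (Matrix::Diagonal(length(f)) - norm$Wn) %*% f)
  fit <- sum((f - y)^2)
  alpha * smooth + (1 - alpha) * fit
}

#' Random walk with restart baseline
#'
#' Classic candidate-gene random walk: a walker starts from the prior
#' distribution p0 = Y / sum(Y), at each step moves along edges of the
#' column-stochastic transition matrix W D^(-1) with probability 1-r and
#' restarts from p0 with probability r. The steady state is the score
#' vector; it sums to 1. An all-zero prior returns all zeros.
#'
#' @param network a `weighted_network`.
#' @param Y `prior_vector` or named nonnegative vector.
#' @param restart restart probability in (0, 1\]; `restart = 1` returns p0.
#' @param tol,max_iter convergence controls.
#' @return a `propagation_result` with `method = "rwr"`.
#' @export
random_walk_restart <- function(network, Y, restart = 0.75, tol = 1e-10,
                                max_iter = 10000) {
  stopifnot(inherits(network, "weighted_network"))
  if (!is.numeric(restart) || restart <= 0 || restart > 1)
    stop("restart probability must lie in (0, 1]")
  query <- if (inherits(Y, "prior_vector")) Y$query else NA_character_
  y <- as_prior_y(Y, network$proteins)
  tot <- sum(y)
  if (tot == 0)
    return(propagation_result(query, y, restart, 0L, TRUE, 0, method = "rwr"))
  p0 <- y / tot
  if (restart == 1)
    return(propagation_result(query, p0, restart, 0L, TRUE, 0, method = "rwr"))
  d <- node_degrees(network)
  M <- network$W %*% Matrix::Diagonal(x = 1 / d)  # column-stochastic
  p <- p0
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p_new <- as.numeric((1 - restart) * (M %*% p)) + restart * p0
    resid <- max(abs(p_new - p))
    p <- p_new
    if (resid < tol) break
  }
  names(p) <- network$proteins
  propagation_result(query, p, restart, it, resid < tol, resid, method = "rwr")
}

#' Direct-neighbor phenotype-correlation baseline
#'
#' Scores a candidate gene by the Pearson correlation, across all diseases
#' that have at least one known gene, between (i) the phenotype similarity of
#' each disease to the query and (ii) the candidate's closeness to that
#' disease's gene set. Closeness of gene g to disease d sums, over d's known
#' genes g', 1 if g = g', the edge confidence w(g, g') if they interact, and
#' 0 otherwise (the direct-neighbor variant).
#'
#' A candidate whose closeness vector has zero variance (no contact with any
#' disease gene set) has an undefined correlation and scores `-Inf`, placing
#' it last in any ranking.
#'
#' @param network a `weighted_network`.
#' @param query disease ID present in `sims`.
#' @param sims `disease_similarity` matrix.
#' @param associations `association_table` (after any CV exclusions).
#' @param candidates character vector of candidate protein IDs.
#' @return named numeric vector of scores over `candidates`.
#' @export
cipher_dn <- function(network, query, sims, associations, candidates) {
  stopifnot(inherits(network, "weighted_network"))
  if (!query %in% rownames(sims))
    stop(sprintf("query disease '%s' absent from similarity matrix", query))
  if (!all(candidates %in% network$proteins))
    stop("candidate protein(s) absent from the network")
  assoc <- as.data.frame(associations)
  assoc <- assoc[assoc$protein %in% network$proteins &
                 assoc$disease %in% rownames(sims), , drop = FALSE]
  diseases <- sort(unique(assoc$disease))
  if (length(diseases) < 2L)
    stop("fewer than 2 diseases with known genes: correlation undefined")
  simvec <- sims[query, diseases]
  # closeness matrix: candidates x diseases
  gene_sets <- split(assoc$protein, assoc$disease)[diseases]
  Wc <- network$W[candidates, , drop = FALSE]
  closeness <- vapply(gene_sets, function(genes) {
    base <- if (length(genes) == 1L) as.numeric(Wc[, genes])
            else Matrix::rowSums(Wc[, genes, drop = FALSE])
    # self term replaces (zero) diagonal adjacency for member candidates
    base + as.numeric(candidates %in% genes)
  }, numeric(length(candidates)))
  if (length(candidates) == 1L) closeness <- matrix(closeness, nrow = 1L)
  scores <- apply(closeness, 1L, function(cl) {
    if (stats::sd(cl) == 0) -Inf else stats::cor(cl, simvec)
  })
  setNames(as.numeric(scores), candidates)
}

#' Score all proteins for a query disease with a chosen method
#'
#' Convenience front-end shared by the cross-validation harness and the
#' command line: builds the prior (honouring exclusions) and runs the
#' requested scorer over the whole network.
#'
#' @param method one of `"prince"`, `"rwr"`, `"cipher-dn"`.
#' @param query disease ID.
#' @param network `weighted_network`.
#' @param sims `disease_similarity`.
#' @param associations `association_table`.
#' @param params [logistic_params()].
#' @param exclude optional (disease, protein) exclusion pairs.
#' @param alpha mixing parameter for `"prince"`.
#' @param restart restart probability for `"rwr"`.
#' @param exact use the linear solver instead of iteration for `"prince"`.
#' @param candidates restrict `"cipher-dn"` scoring to these proteins
#'   (it is quadratic if run genome-wide); default all proteins.
#' @param tol,max_iter convergence controls.
#' @return named numeric score vector over the scored proteins.
#' @export
score_disease <- function(method, query, network, sims, associations,
                          params = logistic_params(), exclude = NULL,
                          alpha = 0.9, restart = 0.75, exact = FALSE,
                          candidates = NULL, tol = 1e-6, max_iter = 1000) {
  method <- match.arg(method, c("prince", "rwr", "cipher-dn"))
  if (method == "cipher-dn") {
    assoc <- as.data.frame(associations)
    if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0L) {
      ex <- as.data.frame(exclude)
      exkey <- paste(ex[[1]], ex[[2]], sep = "\r")
      akey <- paste(assoc$disease, assoc$protein, sep = "\r")
      assoc <- assoc[!(akey %in% exkey), , drop = FALSE]
    }
    if (is.null(candidates)) candidates <- network$proteins
    return(cipher_dn(network, query, sims, assoc, candidates))
  }
  prior <- build_prior(query, network, associations, sims, params, exclude)
  if (method == "prince") {
    norm <- normalize_network(network)
    res <- if (exact) propagate_exact(norm, prior, alpha)
           else propagate_iterative(norm, prior, alpha, max_iter, tol)
  } else {
    res <- random_walk_restart(network, prior, restart, tol = 1e-10,
                               max_iter = max_iter)
  }
  res$scores
}
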