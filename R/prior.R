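# ---------------------------------------------------------------------------
# Prior evidence: logistic transform of phenotype similarity into a
# per-protein prior vector for a query disease.
# ---------------------------------------------------------------------------

#' Logistic confidence parameters
#'
#' The confidence that two diseases share causal genes is modelled as a
#' logistic function of their phenotype similarity x:
#' L(x) = 1 / (1 + exp(c*x + d)). The slope `c` must be negative so that L
#' increases with similarity. The defaults give L(0) = 1e-4 (dissimilar
#' diseases contribute essentially nothing) and keep L below 0.01 for
#' similarities under 0.3, the range in which phenotype similarity carries no
#' signal about shared gene function.
#'
#' @param c slope coefficient (negative).
#' @param d offset; default `log(9999)` pins L(0) at 1e-4.
#' @return list of class `logistic_params`.
#' @export
logistic_params <- function(c = -15, d = log(9999)) {
  if (!is.numeric(c) || !is.numeric(d) || length(c) != 1L || length(d) != 1L)
    stop("c and d must be scalars")
  if (c >= 0) stop("logistic slope c must be negative so confidence increases with similarity")
  structure(list(c = c, d = d), class = "logistic_params")
}

#' Logistic confidence of a disease-disease similarity
#'
#' @param similarity numeric vector of similarities in \[0, 1\].
#' @param params a [logistic_params()] object.
#' @return confidence values in (0, 1), strictly increasing in similarity.
#' @export
logistic_confidence <- function(similarity, params = logistic_params()) {
  if (!inherits(params, "logistic_params")) stop("params must be logistic_params")
  if (anyNA(similarity) || any(similarity < 0 | similarity > 1))
    stop("similarity must lie in [0,1]")
  1 / (1 + exp(params$c * similarity + params$d))
}

#' Build the prior vector for a query disease
#'
#' Every protein with at least one surviving gene-disease association gets
#' prior value L(S\[query, d*\]) where d* is its associated disease most
#' similar to the query (ties broken by lexicographic disease ID); all other
#' proteins get 0. Known genes of the query disease itself take the
#' self-similarity path d* = query, so they receive L(1). The `exclude` set
#' supports cross-validation: excluded (disease, protein) pairs are removed
#' before the maximisation.
#'
#' @param query disease ID present in `sims`.
#' @param network `weighted_network` giving the protein order of the output.
#' @param associations an `association_table`.
#' @param sims a `disease_similarity` matrix.
#' @param params [logistic_params()].
#' @param exclude optional data.frame of (disease, protein) pairs to hide.
#' @return list of class `prior_vector`: `query`, `y` (named numeric aligned
#'   to `network$proteins`), `provenance` (protein, source_disease,
#'   similarity for every nonzero entry).
#' @export
build_prior <- function(query, network, associations, sims,
                        params = logistic_params(), exclude = NULL) {
  stopifnot(inherits(network, "weighted_network"))
  if (!query %in% rownames(sims))
    stop(sprintf("query disease '%s' absent from similarity matrix", query))
  assoc <- as.data.frame(associations)[, c("disease", "protein")]
  if (!is.null(exclude) && nrow(as.data.frame(exclude)) > 0L) {
    ex <- as.data.frame(exclude)
    exkey <- paste(ex[[1]], ex[[2]], sep = "\r")
    akey <- paste(assoc$disease, assoc$protein, sep = "\r")
    assoc <- assoc[!(akey %in% exkey), , drop = FALSE]
  }
  assoc <- assoc[assoc$protein %in% network$proteins &
                 assoc$disease %in% rownames(sims), , drop = FALSE]

  y <- setNames(numeric(length(network$proteins)), network$proteins)
  prov <- data.frame(protein = character(), source_disease = character(),
                     similarity = numeric(), stringsAsFactors = FALSE)
  if (nrow(assoc)) {
    assoc$sim <- sims[query, assoc$disease]
    # argmax similarity per protein, lexicographic disease ID on ties
    assoc <- assoc[order(assoc$protein, -assoc$sim, assoc$disease), , drop = FALSE]
    best <- assoc[!duplicated(assoc$protein), , drop = FALSE]
    y[best$protein] <- logistic_confidence(best$sim, params)
    prov <- data.frame(protein = best$protein, source_disease = best$disease,
                       similarity = best$sim, stringsAsFactors = FALSE)
    rownames(prov) <- NULL
  }
  structure(list(query = query, y = y, provenance = prov),
            class = "prior_vector")
}

#' Write a prior vector as 2-column TSV (protein, prior)
#' @param prior a `prior_vector`.
#' @param path output path.
#' @export
write_prior <- function(prior, path) {
  write_tsv_commented(
    data.frame(protein = names(prior$y), prior = unname(prior$y)), path,
    header = sprintf("prior vector for query disease %s", prior$query))
}
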