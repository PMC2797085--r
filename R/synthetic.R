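# ---------------------------------------------------------------------------
# Deterministic synthetic-data generators with planted structure: a
# planted-partition PPI network with hub proteins, disease families with
# block-structured phenotype similarity, and coherency side-data
# (annotations, expression, phylogenetic profiles).
# ---------------------------------------------------------------------------

#' Stratified genome ordering dispersing module genes
#'
#' Lays the proteins out in a synthetic genomic order such that two members
#' of the same planted module are always at least `spacing` genes apart —
#' members of a functional module are usually encoded at dispersed genomic
#' loci, so a linkage interval around one of them should not sweep in its
#' partners. The genome is divided into `module_size` blocks; each module
#' places one member per block at a random offset, and the remaining
#' proteins fill the free positions in random order.
#'
#' @param proteins all protein IDs.
#' @param modules planted module list (equal sizes).
#' @param spacing minimum genomic separation between same-module genes.
#' @param seed integer seed.
#' @return character vector: the proteins in synthetic genomic order.
#' @export
stratified_genome_order <- function(proteins, modules, spacing = 100,
                                    seed = 1L) {
  set.seed(as.integer(seed) + 3000L)
  n <- length(proteins)
  k <- max(lengths(modules))
  block_len <- n %/% k
  usable <- block_len - spacing
  if (usable < length(modules))
    stop("infeasible: genome too short to disperse modules at this spacing")
  order_vec <- rep(NA_character_, n)
  for (b in seq_len(k)) {
    offsets <- sample(usable, length(modules))
    for (j in seq_along(modules)) {
      m <- modules[[j]]
      if (b > length(m)) next
      pos <- (b - 1L) * block_len + offsets[j]
      order_vec[pos] <- m[b]
    }
  }
  rest <- setdiff(proteins, unlist(modules))
  order_vec[is.na(order_vec)] <- sample(rest)
  order_vec
}

# unrank the k-th unordered pair (1-based, pairs ordered (1,2),(1,3),...,
# (1,n),(2,3),...) of n items
unrank_pair <- function(k, n) {
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  cum_prev <- (i - 1) * n - (i - 1) * i / 2
  j <- i + (k - cum_prev)
  cbind(as.integer(i), as.integer(j))
}

#' Generate a planted-partition protein network
#'
#' Proteins are split into `n_modules` disjoint modules of `module_size`
#' proteins plus background. Within-module pairs interact with probability
#' `p_in` and high confidence; background pairs with probability `p_out` and
#' low confidence. Optionally, `hub_count` background proteins become hubs
#' with `hub_degree` additional low-confidence partners, emulating the
#' heavy-tailed degree distribution of real interactome maps. A
#' low-confidence chain (weight 0.1) joins disconnected components so no
#' protein is isolated.
#'
#' Weights are Beta draws clipped into (0, 1]: within-module edges use
#' `module_shapes` (default Beta(8, 2), mean 0.8 -- interactions backed by
#' complex-level evidence carry high confidence), background and hub edges
#' use `background_shapes` (default Beta(1.5, 6), mean 0.2 -- sparsely
#' supported screen interactions).
#'
#' @param n_proteins total number of proteins.
#' @param n_modules,module_size planted module layout
#'   (`n_modules * module_size <= n_proteins`).
#' @param p_in,p_out within-module and background edge probabilities.
#' @param hub_count,hub_degree number of hub proteins and their extra degree.
#' @param module_shapes,background_shapes Beta shape pairs for edge weights.
#' @param seed integer seed; same seed reproduces the network bit-identically.
#' @return list: `network` (`weighted_network`), `modules` (list of member
#'   vectors, names `M01`...), `proteins`.
#' @export
gen_network <- function(n_proteins = 2000, n_modules = 12, module_size = 8,
                        p_in = 0.6, p_out = 0.003, hub_count = 10,
                        hub_degree = 60, module_shapes = c(8, 2),
                        background_shapes = c(1.5, 6), seed = 1L) {
  if (n_modules * module_size > n_proteins)
    stop("infeasible: n_modules * module_size exceeds n_proteins")
  set.seed(as.integer(seed))
  proteins <- sprintf("P%05d", seq_len(n_proteins))
  modules <- split(proteins[seq_len(n_modules * module_size)],
                   rep(seq_len(n_modules), each = module_size))
  names(modules) <- sprintf("M%02d", seq_len(n_modules))

  edges <- list()
  for (m in modules) {
    idx <- which(upper.tri(diag(length(m))), arr.ind = TRUE)
    take <- stats::runif(nrow(idx)) < p_in
    if (any(take))
      edges[[length(edges) + 1L]] <- data.frame(
        protein_a = m[idx[take, 1L]], protein_b = m[idx[take, 2L]],
        weight = pmin(stats::rbeta(sum(take), module_shapes[1L], module_shapes[2L]), 1),
        stringsAsFactors = FALSE)
  }
  npairs <- n_proteins * (n_proteins - 1) / 2
  m_bg <- stats::rbinom(1L, npairs, p_out)
  if (m_bg > 0) {
    ks <- sample(npairs, m_bg)
    ij <- unrank_pair(ks, n_proteins)
    edges[[length(edges) + 1L]] <- data.frame(
      protein_a = proteins[ij[, 1L]], protein_b = proteins[ij[, 2L]],
      weight = pmin(stats::rbeta(m_bg, background_shapes[1L], background_shapes[2L]) + 1e-6, 1),
      stringsAsFactors = FALSE)
  }
  if (hub_count > 0) {
    background <- setdiff(proteins, unlist(modules))
    hubs <- sample(background, hub_count)
    for (h in hubs) {
      partners <- sample(setdiff(proteins, h), hub_degree)
      edges[[length(edges) + 1L]] <- data.frame(
        protein_a = h, protein_b = partners,
        weight = pmin(stats::rbeta(hub_degree, background_shapes[1L], background_shapes[2L]) + 1e-6, 1),
        stringsAsFactors = FALSE)
    }
  }
  etab <- do.call(rbind, edges)
  # join components with a low-confidence chain so no protein is isolated
  g <- igraph::graph_from_data_frame(etab[, 1:2], directed = FALSE,
                                     vertices = proteins)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    reps <- vapply(seq_len(comp$no),
                   function(cc) proteins[which(comp$membership == cc)[1L]], "")
    chain <- data.frame(protein_a = reps[-length(reps)],
                        protein_b = reps[-1L],
                        weight = 0.1, stringsAsFactors = FALSE)
    message(sprintf("connected %d components with a weight-0.1 chain", comp$no))
    etab <- rbind(etab, chain)
  }
  net <- weighted_network(etab, quiet = TRUE)
  list(network = net, modules = modules, proteins = proteins)
}

#' Generate disease families with block-structured phenotype similarity
#'
#' Diseases come in families of phenotypically similar disorders. Intra-family
#' similarities are drawn from `sim_in` (informative range), inter-family
#' similarities from `sim_out` (the uninformative range below 0.3), diagonal
#' 1. Family f's causal genes are drawn, disjointly across its diseases, from
#' one planted network module, so that the causal gene of a held-out disease
#' is a network neighbour of its family partners' genes. The truth table
#' records each disease's genes and module.
#'
#' @param modules planted modules from [gen_network()] (list of vectors).
#' @param n_families number of disease families (needs as many modules).
#' @param family_size diseases per family.
#' @param genes_per_disease causal genes per disease
#'   (`family_size * genes_per_disease <= module_size`).
#' @param sim_in,sim_out ranges (length-2) of intra-/inter-family similarity.
#' @param seed integer seed.
#' @return list: `sims` (`disease_similarity`), `associations`
#'   (`association_table`), `truth` (data.frame disease/protein/module/family).
#' @export
gen_disease_world <- function(modules, n_families = 12, family_size = 3,
                              genes_per_disease = 1, sim_in = c(0.7, 0.9),
                              sim_out = c(0.0, 0.3), seed = 1L) {
  if (n_families > length(modules))
    stop("infeasible: more families than planted modules")
  if (family_size * genes_per_disease > length(modules[[1L]]))
    stop("infeasible: family needs more genes than its module holds")
  set.seed(as.integer(seed) + 1000L)
  n_dis <- n_families * family_size
  diseases <- sprintf("D%02d", seq_len(n_dis))
  family <- rep(seq_len(n_families), each = family_size)

  S <- matrix(0, n_dis, n_dis, dimnames = list(diseases, diseases))
  for (i in seq_len(n_dis - 1L)) for (j in (i + 1L):n_dis) {
    rng <- if (family[i] == family[j]) sim_in else sim_out
    S[i, j] <- S[j, i] <- stats::runif(1, rng[1L], rng[2L])
  }
  diag(S) <- 1

  rows <- list()
  for (f in seq_len(n_families)) {
    pool <- sample(modules[[f]], family_size * genes_per_disease)
    fam_dis <- diseases[family == f]
    for (k in seq_along(fam_dis)) {
      genes <- pool[((k - 1L) * genes_per_disease + 1L):(k * genes_per_disease)]
      rows[[length(rows) + 1L]] <- data.frame(
        disease = fam_dis[k], protein = genes,
        module = names(modules)[f], family = f, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  list(sims = disease_similarity(S),
       associations = association_table(truth[, c("disease", "protein")]),
       truth = truth)
}

#' Generate coherency side-data with planted-coherent modules
#'
#' For each module in `coherent`, members share a dedicated annotation term,
#' a common expression latent factor, and a common phylogenetic-profile
#' template; `noise` controls the departure from perfect coherence
#' (expression noise standard deviation relative to the unit factor; profile
#' bit-flip probability). All remaining genes get random annotations,
#' independent expression, and independent Bernoulli(0.5) profiles.
#'
#' @param proteins all protein IDs.
#' @param modules planted module list.
#' @param coherent names (or indices) of modules planted as coherent;
#'   `character(0)` yields a fully null dataset.
#' @param n_conditions expression conditions.
#' @param n_species genomes in the phylogenetic profile panel (classically a
#'   panel of 18 eukaryotes).
#' @param n_random_terms random annotation terms drawn over all proteins.
#' @param term_size size of each random term.
#' @param noise noise level in \[0, 0.5\].
#' @param seed integer seed.
#' @return list: `annotations` (`gene_set_collection`), `expression`
#'   (matrix), `profiles` (binary matrix).
#' @export
gen_coherency_tables <- function(proteins, modules, coherent = names(modules),
                                 n_conditions = 20, n_species = 18,
                                 n_random_terms = 30, term_size = 15,
                                 noise = 0.1, seed = 1L) {
  set.seed(as.integer(seed) + 2000L)
  if (is.numeric(coherent)) coherent <- names(modules)[coherent]

  terms <- list()
  for (nm in names(modules)) {
    if (nm %in% coherent)
      terms[[paste0("T_", nm)]] <- modules[[nm]]
  }
  for (t in seq_len(n_random_terms))
    terms[[sprintf("T_rand%02d", t)]] <- sample(proteins, term_size)
  annotations <- gene_set_collection(terms)

  expr <- matrix(stats::rnorm(length(proteins) * n_conditions),
                 nrow = length(proteins),
                 dimnames = list(proteins,
                                 sprintf("cond%02d", seq_len(n_conditions))))
  for (nm in intersect(coherent, names(modules))) {
    factor_profile <- stats::rnorm(n_conditions)
    m <- modules[[nm]]
    expr[m, ] <- matrix(rep(factor_profile, each = length(m)),
                        nrow = length(m)) +
      noise * matrix(stats::rnorm(length(m) * n_conditions), nrow = length(m))
  }

  prof <- matrix(stats::rbinom(length(proteins) * n_species, 1L, 0.5),
                 nrow = length(proteins),
                 dimnames = list(proteins,
                                 sprintf("sp%02d", seq_len(n_species))))
  for (nm in intersect(coherent, names(modules))) {
    template <- stats::rbinom(n_species, 1L, 0.5)
    m <- modules[[nm]]
    flips <- matrix(stats::rbinom(length(m) * n_species, 1L, noise),
                    nrow = length(m))
    prof[m, ] <- abs(matrix(rep(template, each = length(m)),
                            nrow = length(m)) - flips)
  }
  list(annotations = annotations, expression = expr, profiles = prof)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Presets:
#' \describe{
#'   \item{easy}{2,000-protein network, 12 modules of 8, 6 families of 3
#'     diseases with 2 causal genes each, hubs present, informative
#'     similarity blocks — the planted-recovery benchmark.}
#'   \item{hard}{same layout with sparser modules, heavier background and a
#'     weaker similarity signal.}
#'   \item{null}{similarity carries no signal (identity off-block ranges) and
#'     no module is coherent — for calibration checks.}
#' }
#'
#' @param preset `"easy"`, `"hard"` or `"null"`.
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   (preset, seed).
#' @return list of class `synthetic_bundle`: `network`, `modules`, `sims`,
#'   `associations`, `truth`, `genome_order`, `annotations`, `expression`,
#'   `profiles`, `params` (record of generation settings).
#' @export
gen_bundle <- function(preset = c("easy", "hard", "null"), seed = 1L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  params <- switch(preset,
    easy = list(n_proteins = 2000, n_modules = 12, module_size = 8,
                p_in = 0.6, p_out = 0.003, hub_count = 10, hub_degree = 60,
                n_families = 12, family_size = 3, genes_per_disease = 1,
                sim_in = c(0.7, 0.9), sim_out = c(0.0, 0.3),
                coherent = sprintf("M%02d", 1:6), noise = 0.1),
    hard = list(n_proteins = 2000, n_modules = 12, module_size = 8,
                p_in = 0.45, p_out = 0.005, hub_count = 20, hub_degree = 80,
                n_families = 12, family_size = 3, genes_per_disease = 1,
                sim_in = c(0.5, 0.8), sim_out = c(0.0, 0.3),
                coherent = sprintf("M%02d", 1:6), noise = 0.3),
    null = list(n_proteins = 2000, n_modules = 12, module_size = 8,
                p_in = 0.6, p_out = 0.003, hub_count = 10, hub_degree = 60,
                n_families = 12, family_size = 3, genes_per_disease = 1,
                sim_in = c(0.0, 0.3), sim_out = c(0.0, 0.3),
                coherent = character(0), noise = 0.1))
  netgen <- gen_network(params$n_proteins, params$n_modules,
                        params$module_size, params$p_in, params$p_out,
                        params$hub_count, params$hub_degree, seed = seed)
  world <- gen_disease_world(netgen$modules, params$n_families,
                             params$family_size, params$genes_per_disease,
                             params$sim_in, params$sim_out, seed)
  tabs <- gen_coherency_tables(netgen$proteins, netgen$modules,
                               params$coherent, noise = params$noise,
                               seed = seed)
  genome_order <- stratified_genome_order(netgen$proteins, netgen$modules,
                                          spacing = 100, seed = seed)
  structure(c(netgen["network"], netgen["modules"], world,
              list(genome_order = genome_order), tabs,
              list(params = c(params, preset = preset, seed = seed))),
            class = "synthetic_bundle")
}

#' Write all bundle inputs to a directory as plain-text files
#'
#' Writes network.tsv, similarity.tsv, associations.tsv, genome_order.txt,
#' annotations.gmt, expression.tsv, profiles.tsv and truth.tsv, each readable
#' by the corresponding loader.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("generated by princer (preset=%s seed=%d)",
                 bundle$params$preset, bundle$params$seed)
  write_network(bundle$network, file.path(dir, "network.tsv"), header = hdr)
  write_similarity(bundle$sims, file.path(dir, "similarity.tsv"))
  write_associations(bundle$associations, file.path(dir, "associations.tsv"),
                     header = hdr)
  writeLines(bundle$genome_order, file.path(dir, "genome_order.txt"))
  write_gene_sets(bundle$annotations, file.path(dir, "annotations.gmt"))
  write_matrix_tsv(bundle$expression, file.path(dir, "expression.tsv"))
  write_matrix_tsv(bundle$profiles, file.path(dir, "profiles.tsv"))
  write_tsv_commented(bundle$truth, file.path(dir, "truth.tsv"), header = hdr)
  invisible(dir)
}
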