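# Shared fixtures and independent oracles, built in code.

# triangle with unit confidences: degrees 2, total weight 3
triangle_network <- function() {
  weighted_network(data.frame(
    protein_a = c("a", "a", "b"), protein_b = c("b", "c", "c"),
    weight = c(1, 1, 1)), quiet = TRUE)
}

# path a-b-c with unit weights: degrees (1, 2, 1)
path_network <- function() {
  weighted_network(data.frame(
    protein_a = c("a", "b"), protein_b = c("b", "c"),
    weight = c(1, 1)), quiet = TRUE)
}

# isolated pair with one edge
pair_network <- function(w = 1) {
  weighted_network(data.frame(protein_a = "u", protein_b = "v", weight = w),
                   quiet = TRUE)
}

# small Erdos-Renyi weighted network with guaranteed positive degrees
random_network <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  take <- runif(nrow(idx)) < p
  ids <- sprintf("g%03d", seq_len(n))
  edges <- data.frame(protein_a = ids[idx[take, 1L]],
                      protein_b = ids[idx[take, 2L]],
                      weight = runif(sum(take), 0.05, 1))
  # chain so every node has an edge
  chain <- data.frame(protein_a = ids[-n], protein_b = ids[-1L], weight = 0.1)
  weighted_network(rbind(edges, chain), quiet = TRUE)
}

# independent brute-force oracle for the complex log-likelihood-ratio score
oracle_complex_score <- function(members, network, gamma = 0.9, eps = 1e-6) {
  members <- sort(unique(members))
  d <- node_degrees(network)
  total <- sum(network$edges$weight)
  s <- 0
  for (i in seq_len(length(members) - 1L)) {
    for (j in (i + 1L):length(members)) {
      u <- members[i]; v <- members[j]
      p <- min(max(d[[u]] * d[[v]] / (2 * total), eps), 1 - eps)
      r <- network$W[u, v]
      s <- s + if (r > 0)
        log((gamma * r + (1 - gamma) * (1 - r)) /
            (p * r + (1 - p) * (1 - r)))
      else log((1 - gamma) / (1 - p))
    }
  }
  s
}

# exhaustive-enumeration oracle for the upper-tail hypergeometric probability
oracle_hypergeom <- function(overlap, complex_size, term_size, universe) {
  sets <- utils::combn(universe, complex_size)
  term <- seq_len(term_size)
  hits <- apply(sets, 2L, function(s) sum(s %in% term) >= overlap)
  mean(hits)
}

# step-up BH oracle written independently of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

# tiny planted world reused across evaluation tests
tiny_bundle <- function(seed = 1L) {
  netgen <- gen_network(n_proteins = 600, n_modules = 6, module_size = 8,
                        p_in = 0.9, p_out = 0.004, hub_count = 4,
                        hub_degree = 30, seed = seed)
  world <- gen_disease_world(netgen$modules, n_families = 6, family_size = 3,
                             genes_per_disease = 1, seed = seed)
  go <- stratified_genome_order(netgen$proteins, netgen$modules,
                                spacing = 50, seed = seed)
  c(netgen, world, list(genome_order = go))
}

# dense fully-seeded module world for complex-recovery tests
complex_bundle <- function(seed = 1L) {
  netgen <- gen_network(n_proteins = 800, n_modules = 8, module_size = 6,
                        p_in = 0.9, p_out = 0.003, hub_count = 5,
                        hub_degree = 40, seed = seed)
  world <- gen_disease_world(netgen$modules, n_families = 8, family_size = 3,
                             genes_per_disease = 2, seed = seed)
  c(netgen, world)
}

expect_quiet_bundle <- function(expr) suppressMessages(expr)
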