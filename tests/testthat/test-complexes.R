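test_that("null edge probabilities follow the degree model", {
  tri <- triangle_network()
  # unit-weight triangle: degrees 2, total weight 3 -> 4 / 6
  expect_equal(unname(null_edge_prob(tri, "a", "b")), 2/3, tolerance = 1e-12)

  star <- weighted_network(data.frame(
    protein_a = c("h", "h", "h"), protein_b = c("l1", "l2", "l3"),
    weight = c(1, 1, 1)), quiet = TRUE)
  # leaves have degree 1, total weight 3 -> 1 / 6
  expect_equal(unname(null_edge_prob(star, "l1", "l2")), 1/6,
               tolerance = 1e-12)
  # hub pair pushing the formula above 1 is clamped
  dense <- weighted_network(data.frame(
    protein_a = c(rep("h1", 5), rep("h2", 5), "h1"),
    protein_b = c(letters[1:5], letters[1:5], "h2"),
    weight = 1), quiet = TRUE)
  expect_equal(unname(null_edge_prob(dense, "h1", "h2")), 1 - 1e-6)
  expect_error(null_edge_prob(tri, "a", "a"), "distinct")
})

test_that("complex score reproduces worked examples", {
  tri <- triangle_network()
  params <- complex_model_params(gamma = 0.9)
  # three unit-reliability pairs, each log(0.9 / (2/3)) = log(1.35)
  expect_equal(complex_score(c("a", "b", "c"), tri, params), 3 * log(1.35),
               tolerance = 1e-12)
  # gamma equal to the null probability cancels the ratio exactly
  params_eq <- complex_model_params(gamma = 2/3)
  expect_equal(complex_score(c("a", "b", "c"), tri, params_eq), 0,
               tolerance = 1e-12)

  # unobserved pair with null probability 0.1 contributes log(0.1 / 0.9)
  net <- weighted_network(data.frame(
    protein_a = c("u", "v", "x"), protein_b = c("x", "y", "y"),
    weight = c(0.5, 0.5, 0.25)), quiet = TRUE)
  expect_equal(unname(null_edge_prob(net, "u", "v")), 0.1, tolerance = 1e-12)
  expect_equal(complex_score(c("u", "v"), net, params), log(0.1 / 0.9),
               tolerance = 1e-12)
  expect_error(complex_score("u", net, params), "at least 2")
})

test_that("complex score equals the brute-force pairwise oracle", {
  net <- random_network(40, p = 0.2, seed = 23)
  params <- complex_model_params(gamma = 0.9)
  set.seed(23)
  for (i in 1:300) {
    members <- sample(net$proteins, sample(2:8, 1))
    expect_equal(complex_score(members, net, params),
                 oracle_complex_score(members, net, gamma = 0.9),
                 tolerance = 1e-12)
  }
})

planted_clique_scores <- function() {
  # 6-clique of high-score proteins hanging off a low-score background
  clique <- sprintf("c%d", 1:6)
  bg <- sprintf("b%02d", 1:20)
  edges <- do.call(rbind, list(
    data.frame(protein_a = rep(clique, each = 6)[upper.tri(diag(6))],
               protein_b = rep(clique, times = 6)[upper.tri(diag(6))],
               weight = 0.9),
    data.frame(protein_a = bg[-20], protein_b = bg[-1], weight = 0.3),
    data.frame(protein_a = "c1", protein_b = "b01", weight = 0.3)))
  net <- weighted_network(edges, quiet = TRUE)
  f <- setNames(c(rep(0.5, 6), rep(0.01, 20)), c(clique, bg))
  list(net = net, f = f, clique = clique)
}

test_that("growth finds the planted clique and respects its gates", {
  w <- planted_clique_scores()
  params <- complex_model_params(beta = 0.1, seed_count = 10)
  cands <- grow_from_seeds(w$f, w$net, params)
  expect_length(cands, 1L)
  expect_setequal(cands[[1]]$members, w$clique)

  # every score below beta: nothing grows
  expect_length(grow_from_seeds(w$f * 0 + 0.01, w$net, params), 0L)

  # interval constraint excluding all members discards the candidate
  iv <- candidate_interval(c("b05", "b06"))
  expect_length(grow_from_seeds(w$f, w$net, params, interval = iv), 0L)
  iv2 <- candidate_interval(c("c3", "b05"))
  expect_length(grow_from_seeds(w$f, w$net, params, interval = iv2), 1L)

  # growth caps at max_size
  params_small <- complex_model_params(beta = 0.1, seed_count = 10,
                                       max_size = 4, min_size = 2)
  c4 <- grow_from_seeds(w$f, w$net, params_small)
  expect_true(all(vapply(c4, function(x) length(x$members), 0L) <= 4))
})

test_that("refinement removes net-negative members, keeps connectivity, and is idempotent", {
  w <- planted_clique_scores()
  params <- complex_model_params()
  # clique plus the chain b01..b03 pendant: pendant pairs are net negative
  cand <- structure(
    list(members = sort(c(w$clique, "b01", "b02")), seed = "c1",
         score = complex_score(c(w$clique, "b01", "b02"), w$net, params),
         disease = NA_character_), class = "complex_candidate")
  ref <- refine_complex(cand, w$net, params)
  expect_setequal(ref$members, w$clique)
  expect_gte(ref$score, cand$score)

  # already-optimal triangle is a fixed point
  tri <- triangle_network()
  tcand <- structure(list(members = c("a", "b", "c"), seed = "a",
                          score = complex_score(c("a", "b", "c"), tri, params),
                          disease = NA_character_),
                     class = "complex_candidate")
  expect_equal(refine_complex(tcand, tri, params)$members, tcand$members)

  # idempotence and connectivity on random candidates
  net <- random_network(30, p = 0.25, seed = 31)
  set.seed(31)
  for (i in 1:40) {
    seedp <- sample(net$proteins, 1)
    members <- unique(c(seedp, sample(net$proteins, sample(3:8, 1))))
    # restrict to the connected component of the induced subgraph
    Wsub <- net$W[members, members, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(Wsub > 0, mode = "undirected")
    comp <- igraph::components(g)
    members <- members[comp$membership == comp$membership[1]]
    if (length(members) < 2) next
    cand <- structure(list(members = sort(members), seed = members[1],
                           score = complex_score(members, net, params),
                           disease = NA_character_),
                      class = "complex_candidate")
    r1 <- refine_complex(cand, net, params)
    r2 <- refine_complex(r1, net, params)
    expect_gte(r1$score, cand$score)
    expect_identical(r1$members, r2$members)
    Wr <- net$W[r1$members, r1$members, drop = FALSE]
    gr <- igraph::graph_from_adjacency_matrix(Wr > 0, mode = "undirected")
    expect_true(igraph::is_connected(gr))
  }
})

test_that("filtering drops small and redundant candidates", {
  mk <- function(members, score) structure(
    list(members = sort(members), seed = members[1], score = score,
         disease = NA_character_), class = "complex_candidate")
  params <- complex_model_params(min_size = 4, overlap_threshold = 0.8)
  out <- filter_complexes(list(mk(c("a", "b", "c"), 10)), params)
  expect_length(out, 0L)

  same6 <- sprintf("s%d", 1:6)
  out2 <- filter_complexes(list(mk(same6, 5), mk(same6, 4)), params)
  expect_length(out2, 1L)
  expect_equal(out2[[1]]$score, 5)

  out3 <- filter_complexes(list(mk(sprintf("a%d", 1:5), 1),
                                mk(sprintf("b%d", 1:5), 2)), params)
  expect_length(out3, 2L)
  expect_equal(out3[[1]]$score, 2)  # sorted by decreasing score

  # overlap 4/5 = 0.8 >= threshold: dropped; 3/5 = 0.6 kept
  ov1 <- mk(c("x1", "x2", "x3", "x4", "x5"), 9)
  ov2 <- mk(c("x1", "x2", "x3", "x4", "y5"), 8)
  ov3 <- mk(c("x1", "x2", "x3", "z4", "z5"), 7)
  expect_length(filter_complexes(list(ov1, ov2), params), 1L)
  expect_length(filter_complexes(list(ov1, ov3), params), 2L)
})

test_that("planted disease modules are recovered end to end", {
  b <- expect_quiet_bundle(complex_bundle(seed = 4))
  for (q in c("D01", "D10")) {
    found <- infer_complexes(q, b$network, b$sims, b$associations)
    expect_gte(length(found), 1L)
    fam_module <- b$truth$module[b$truth$disease == q][1]
    jac <- max(vapply(found, function(cx) {
      length(intersect(cx$members, b$modules[[fam_module]])) /
        length(union(cx$members, b$modules[[fam_module]]))
    }, 0))
    expect_gte(jac, 0.8)
    sizes <- vapply(found, function(x) length(x$members), 0L)
    expect_true(all(sizes >= 4 & sizes <= 20))
  }
  # beta above every score: empty output
  hi <- complex_model_params(beta = 10)
  expect_length(infer_complexes("D01", b$network, b$sims, b$associations, hi),
                0L)
  # insensitivity to the number of seeds in the stated range
  got <- lapply(c(50, 100, 150), function(sc) {
    p <- complex_model_params(seed_count = sc)
    res <- infer_complexes("D01", b$network, b$sims, b$associations, p)
    lapply(res, `[[`, "members")
  })
  expect_identical(got[[1]], got[[2]])
  expect_identical(got[[2]], got[[3]])
})

test_that("planted-density candidates outscore random same-size sets", {
  b <- expect_quiet_bundle(complex_bundle(seed = 6))
  params <- complex_model_params()
  wins <- 0; n <- 200
  set.seed(6)
  for (i in seq_len(n)) {
    mod <- b$modules[[sample(8, 1)]]
    rand <- sample(b$network$proteins, length(mod))
    wins <- wins + (complex_score(mod, b$network, params) >
                      complex_score(rand, b$network, params))
  }
  expect_gte(wins / n, 0.99)
})

test_that("beta calibration targets a reference size distribution", {
  b <- expect_quiet_bundle(complex_bundle(seed = 8))
  tuned <- tune_beta_to_size(c("D01", "D04"), b$network, b$sims,
                             b$associations, reference_sizes = rep(6, 10),
                             betas = c(0.01, 0.1, 0.45))
  expect_true(tuned$beta %in% c(0.01, 0.1, 0.45))
  expect_false(is.na(tuned$mean_size))
  # the chosen beta's mean size is the closest achievable to the target
  ok <- !is.na(tuned$table$mean_size)
  expect_equal(min(abs(tuned$table$mean_size[ok] - 6)),
               abs(tuned$mean_size - 6))
})
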