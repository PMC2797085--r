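test_that("degree normalization has the expected closed forms", {
  # single edge: Wn entry w / sqrt(w * w) = 1 for any weight
  for (w in c(0.2, 0.7, 1)) {
    norm <- normalize_network(pair_network(w))
    expect_equal(norm$Wn["u", "v"], 1)
  }
  # path a-b-c with unit weights: degrees (1, 2, 1)
  norm <- normalize_network(path_network())
  expect_equal(norm$Wn["a", "b"], 1 / sqrt(2))
  expect_equal(norm$Wn["a", "c"], 0)
  expect_true(Matrix::isSymmetric(norm$Wn))
})

test_that("normalization is invariant under uniform weight rescaling", {
  net <- random_network(30, seed = 2)
  scaled <- net$edges
  scaled$weight <- scaled$weight / 10
  net10 <- weighted_network(scaled, quiet = TRUE)
  expect_equal(as.matrix(normalize_network(net)$Wn),
               as.matrix(normalize_network(net10)$Wn), tolerance = 1e-12)
})

test_that("normalized spectrum lies in [-1, 1]", {
  for (s in 1:5) {
    net <- random_network(sample(20:60, 1), seed = s)
    ev <- eigen(as.matrix(normalize_network(net)$Wn),
                symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-9)
  }
})

test_that("iterative propagation converges to the exact solution", {
  for (s in 1:10) {
    net <- random_network(sample(20:100, 1), p = 0.1, seed = 100 + s)
    norm <- normalize_network(net)
    set.seed(s)
    y <- setNames(ifelse(runif(length(net$proteins)) < 0.1, 1, 0),
                  net$proteins)
    for (alpha in c(0.5, 0.9)) {
      it <- propagate_iterative(norm, y, alpha, max_iter = 10000, tol = 1e-12)
      ex <- propagate_exact(norm, y, alpha)
      expect_true(it$converged)
      expect_lt(max(abs(it$scores - ex$scores)), 1e-8)
    }
  }
})

test_that("propagation limit identities hold exactly", {
  net <- random_network(25, seed = 9)
  norm <- normalize_network(net)
  y <- setNames(c(1, rep(0, 24)), net$proteins)
  expect_identical(propagate_iterative(norm, y, alpha = 0)$scores, y)
  expect_identical(propagate_exact(norm, y, alpha = 0)$scores, y)
  z <- setNames(rep(0, 25), net$proteins)
  expect_equal(propagate_iterative(norm, z, 0.9)$scores, z)
  expect_equal(propagate_exact(norm, z, 0.9)$scores, z)
  expect_error(propagate_iterative(norm, y, alpha = 1), "alpha")
  expect_error(propagate_exact(norm, y, alpha = -0.1), "alpha")
})

test_that("exact propagation hand example and positivity", {
  # isolated pair, normalized entry 1, Y = (1, 0), alpha = 0.5:
  # F = 0.5 (I - 0.5 Wn)^{-1} Y = (2/3, 1/3)
  norm <- normalize_network(pair_network(0.8))
  f <- propagate_exact(norm, setNames(c(1, 0), c("u", "v")), 0.5)$scores
  expect_equal(unname(f), c(2/3, 1/3), tolerance = 1e-12)

  # one positive prior entry on a connected graph reaches every node
  net <- random_network(30, seed = 11)
  y <- setNames(c(1, rep(0, 29)), net$proteins)
  f2 <- propagate_exact(normalize_network(net), y, 0.999)$scores
  expect_true(all(f2 > 0))
})

test_that("propagation is equivariant under protein relabeling", {
  net <- random_network(20, seed = 13)
  set.seed(13)
  y <- setNames(runif(20) * (runif(20) < 0.3), net$proteins)
  f <- propagate_exact(normalize_network(net), y, 0.8)$scores
  relab <- setNames(sprintf("z%03d", sample(20)), net$proteins)
  e2 <- net$edges
  e2$protein_a <- unname(relab[e2$protein_a])
  e2$protein_b <- unname(relab[e2$protein_b])
  net2 <- weighted_network(e2, quiet = TRUE)
  y2 <- setNames(y, unname(relab[names(y)]))
  f2 <- propagate_exact(normalize_network(net2), y2, 0.8)$scores
  expect_equal(unname(f2[relab[names(f)]]), unname(f), tolerance = 1e-12)
})

test_that("residuals decay geometrically and the fixed point is smoother", {
  net <- random_network(50, p = 0.1, seed = 17)
  norm <- normalize_network(net)
  set.seed(17)
  y <- setNames(ifelse(runif(50) < 0.15, 1, 0), net$proteins)
  alpha <- 0.8
  # track L2 update norms through the iteration by hand
  f <- y
  l2 <- numeric(0)
  for (t in 1:30) {
    fn <- as.numeric(alpha * (norm$Wn %*% f)) + (1 - alpha) * y
    l2 <- c(l2, sqrt(sum((fn - f)^2)))
    f <- fn
  }
  ratios <- l2[-1] / l2[-length(l2)]
  expect_true(all(ratios <= alpha + 1e-9))
  # the converged score is smoother than the raw prior under the objective
  ex <- propagate_exact(norm, y, alpha)
  expect_lte(propagation_objective(norm, ex$scores, y, alpha),
             propagation_objective(norm, setNames(y, net$proteins), y, alpha))
})

test_that("ten propagation iterations already give the exact top candidate", {
  hits <- 0; n_trials <- 40
  for (s in seq_len(n_trials)) {
    net <- random_network(80, p = 0.08, seed = 300 + s)
    norm <- normalize_network(net)
    set.seed(s)
    y <- setNames(ifelse(runif(80) < 0.1, 1, 0), net$proteins)
    if (sum(y) == 0) y[1] <- 1
    ten <- propagate_iterative(norm, y, 0.9, max_iter = 10, tol = 0)
    ex <- propagate_exact(norm, y, 0.9)
    hits <- hits + (names(which.max(ten$scores)) == names(which.max(ex$scores)))
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("random walk with restart matches hand solution and conserves mass", {
  # isolated edge, start mass on u, restart 0.5: p = (2/3, 1/3)
  net <- pair_network(0.6)
  y <- setNames(c(1, 0), c("u", "v"))
  res <- random_walk_restart(net, y, restart = 0.5)
  expect_equal(unname(res$scores), c(2/3, 1/3), tolerance = 1e-8)

  net2 <- random_network(40, seed = 19)
  set.seed(19)
  y2 <- setNames(runif(40) * (runif(40) < 0.2), net2$proteins)
  res2 <- random_walk_restart(net2, y2, restart = 0.75)
  expect_equal(sum(res2$scores), 1, tolerance = 1e-9)
  # restart 1 returns the start distribution exactly
  res3 <- random_walk_restart(net2, y2, restart = 1)
  expect_equal(res3$scores, y2 / sum(y2))
  # all-zero prior stays zero
  z <- setNames(rep(0, 40), net2$proteins)
  expect_true(all(random_walk_restart(net2, z)$scores == 0))
})

cipher_toy <- function() {
  # three diseases with one gene each; candidate x1 touches only the gene of
  # the disease most similar to the query, x2 touches only the least similar
  net <- weighted_network(data.frame(
    protein_a = c("x1", "x2", "g1", "g2"),
    protein_b = c("g1", "g3", "g2", "g3"),
    weight = c(1, 1, 0.2, 0.2)), quiet = TRUE)
  S <- disease_similarity(matrix(
    c(1, 0.9, 0.5, 0.1,
      0.9, 1, 0.4, 0.1,
      0.5, 0.4, 1, 0.2,
      0.1, 0.1, 0.2, 1), 4, byrow = TRUE,
    dimnames = list(c("q", "d1", "d2", "d3"), c("q", "d1", "d2", "d3"))))
  assoc <- association_table(data.frame(
    disease = c("d1", "d2", "d3"), protein = c("g1", "g2", "g3")))
  list(net = net, S = S, assoc = assoc)
}

test_that("direct-neighbor baseline correlates closeness with similarity", {
  w <- cipher_toy()
  sc <- cipher_dn(w$net, "q", w$S, w$assoc, c("x1", "x2"))
  # brute-force oracle: closeness vectors per candidate over (d1, d2, d3)
  cl_x1 <- c(1 * 1, 0, 0)          # adjacent only to g1
  cl_x2 <- c(0, 0, 1 * 1)          # adjacent only to g3
  simv <- unclass(w$S)["q", c("d1", "d2", "d3")]
  expect_equal(unname(sc["x1"]), cor(cl_x1, simv), tolerance = 1e-12)
  expect_equal(unname(sc["x2"]), cor(cl_x2, simv), tolerance = 1e-12)
  expect_gt(sc["x1"], sc["x2"])

  # a known gene's own closeness contribution to its disease is 1 + adjacency
  sc_g1 <- cipher_dn(w$net, "q", w$S, w$assoc, "g1")
  cl_g1 <- c(1, 0.2, 0)  # self = 1, adjacent to g2 with weight 0.2
  expect_equal(unname(sc_g1), cor(cl_g1, simv), tolerance = 1e-12)

  # isolated candidate: constant closeness, undefined correlation -> -Inf
  net2 <- weighted_network(rbind(w$net$edges,
    data.frame(protein_a = "lone", protein_b = "x1", weight = 0.01)),
    quiet = TRUE)
  sc_lone <- cipher_dn(net2, "q", w$S, w$assoc, "lone")
  expect_identical(unname(sc_lone), -Inf)

  # fewer than two diseases with genes: correlation undefined
  a1 <- association_table(data.frame(disease = "d1", protein = "g1"))
  expect_error(cipher_dn(w$net, "q", w$S, a1, "x1"), "fewer than 2")
})
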