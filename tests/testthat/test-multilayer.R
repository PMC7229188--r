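make_two_layer <- function(seed = 1) {
  A1 <- two_clique_graph()
  set.seed(seed)
  A1[A1 > 0] <- runif(sum(A1 > 0), 0.8, 1.2)
  A1 <- (A1 + t(A1)) / 2; diag(A1) <- 0
  A2 <- A1[c(1:3, 5, 4, 6:8), c(1:3, 5, 4, 6:8)]  # swap nodes 4 and 5
  list(A1 = A1, A2 = A2)
}

test_that("omega depends only on condition identity", {
  expect_equal(omega_for_pair("1-back", "1-back"), 1)
  expect_equal(omega_for_pair("1-back", "2-back"), 0.5)
  expect_equal(omega_for_pair("a", "b", omega_same = 0, omega_diff = 0), 0)
  expect_error(omega_for_pair("1-back", "3-back",
                              labels = c("1-back", "2-back")), "unknown")
})

test_that("multilayer quality matches the brute-force summation oracle", {
  # 2-node, 2-layer toy with explicit small weights
  L1 <- matrix(c(0, 0.6, 0.6, 0), 2)
  L2 <- matrix(c(0, 0.2, 0.2, 0), 2)
  net <- multilayer_network(list(L1, L2), c("a", "b"))
  for (assign in list(matrix(1, 2, 2), matrix(c(1, 2, 1, 2), 2),
                      matrix(c(1, 1, 2, 2), 2), matrix(1:4, 2))) {
    expect_equal(multilayer_quality(net, assign),
                 multilayer_quality_direct(list(L1, L2), c("a", "b"),
                                           assign),
                 tolerance = 1e-12)
  }
  # larger random stack, mixed conditions and omegas
  ls <- lapply(1:3, function(s) random_weighted_graph(6, 0.6, seed = s))
  conds <- c("x", "y", "x")
  net3 <- multilayer_network(ls, conds, omega_same = 0.8,
                             omega_diff = 0.3)
  set.seed(5)
  for (i in 1:4) {
    assign <- matrix(sample(1:3, 18, replace = TRUE), 6, 3)
    expect_equal(multilayer_quality(net3, assign),
                 multilayer_quality_direct(ls, conds, assign,
                                           omega_same = 0.8,
                                           omega_diff = 0.3),
                 tolerance = 1e-12)
  }
})

test_that("single-layer multilayer reduces exactly to static modularity", {
  for (s in 1:10) {
    G <- random_weighted_graph(8, 0.5, seed = s)
    net <- multilayer_network(list(G), "task")
    # all-in-one gives 0, matching the configuration-null identity
    expect_equal(multilayer_quality(net, matrix(1, 8, 1)), 0,
                 tolerance = 1e-12)
    part <- sample(1:3, 8, replace = TRUE)
    expect_equal(multilayer_quality(net, matrix(part, 8, 1)),
                 modularity_score(G, part), tolerance = 1e-10)
    # matched restart protocols on both routes, refereed by the
    # exhaustive optimum
    ens <- run_ensemble(net, n_opt = 20, seed = s)
    st <- best_of_runs(G, n_runs = 20, seed = s)
    q_star <- exhaustive_max_modularity(G)
    expect_equal(max(vapply(ens, `[[`, numeric(1), "Q")), q_star,
                 tolerance = 1e-10)
    expect_equal(st$Q, q_star, tolerance = 1e-10)
  }
})

test_that("zero coupling with all-in-one layers scores zero", {
  ls <- lapply(1:3, function(s) random_weighted_graph(6, 0.5, seed = s))
  net <- multilayer_network(ls, c("a", "b", "a"), omega_same = 0,
                            omega_diff = 0)
  expect_equal(multilayer_quality(net, matrix(1, 6, 3)), 0,
               tolerance = 1e-12)
})

test_that("optimizer Q is consistent with the quality function", {
  tl <- make_two_layer()
  net <- multilayer_network(list(tl$A1, tl$A2), c("a", "b"))
  for (s in 1:5) {
    gl <- generalized_louvain(net, seed = s)
    expect_equal(gl$Q, multilayer_quality(net, gl$assignment),
                 tolerance = 1e-10)
  }
})

test_that("large coupling forces column-constant assignments", {
  A <- two_clique_graph()
  net <- multilayer_network(list(A, A, A), c("a", "b", "a"),
                            omega_same = 100, omega_diff = 100)
  gl <- generalized_louvain(net, seed = 2)
  expect_true(all(apply(gl$assignment, 1,
                        function(r) length(unique(r)) == 1L)))
})

test_that("zero coupling decouples into per-layer solutions", {
  tl <- make_two_layer()
  net <- multilayer_network(list(tl$A1, tl$A2), c("a", "b"),
                            omega_same = 0, omega_diff = 0)
  gl <- generalized_louvain(net, seed = 4)
  s1 <- best_of_runs(tl$A1, n_runs = 20, seed = 1)
  s2 <- best_of_runs(tl$A2, n_runs = 20, seed = 1)
  expect_equal(adjusted_rand_index(gl$assignment[, 1], s1$partition), 1)
  expect_equal(adjusted_rand_index(gl$assignment[, 2], s2$partition), 1)
  expect_equal(gl$Q,
               multilayer_quality(net, cbind(s1$partition,
                                             s2$partition + 10L)),
               tolerance = 1e-10)
})

test_that("moderate coupling relabels exactly the swapped nodes", {
  tl <- make_two_layer()
  net <- multilayer_network(list(tl$A1, tl$A2), c("a", "a"),
                            omega_same = 0.2, omega_diff = 0.2)
  gl <- generalized_louvain(net, seed = 6)
  # layer 1 splits into the two cliques
  expect_equal(adjusted_rand_index(gl$assignment[, 1],
                                   rep(1:2, each = 4)), 1)
  # in layer 2 the planted partition swaps nodes 4 and 5 between modules
  expect_equal(adjusted_rand_index(gl$assignment[, 2],
                                   c(1, 1, 1, 2, 1, 2, 2, 2)), 1)
  changed <- which(gl$assignment[, 1] != gl$assignment[, 2])
  expect_setequal(changed, c(4L, 5L))
})

test_that("between-layer persistence is monotone in coupling", {
  tl <- make_two_layer(seed = 3)
  persistence <- vapply(c(0, 0.3, 5), function(om) {
    net <- multilayer_network(list(tl$A1, tl$A2), c("a", "a"),
                              omega_same = om, omega_diff = om)
    agree <- vapply(1:5, function(s) {
      gl <- generalized_louvain(net, seed = s)
      mean(gl$assignment[, 1] == gl$assignment[, 2])
    }, numeric(1))
    mean(agree)
  }, numeric(1))
  expect_true(all(diff(persistence) >= 0))
  expect_equal(persistence[3], 1)
})

test_that("ensembles are reproducible and bounded below by singletons", {
  tl <- make_two_layer()
  net <- multilayer_network(list(tl$A1, tl$A2), c("a", "b"))
  ens <- run_ensemble(net, n_opt = 6, seed = 11)
  expect_length(ens, 6)
  ens2 <- run_ensemble(net, n_opt = 6, seed = 11)
  expect_identical(lapply(ens, `[[`, "assignment"),
                   lapply(ens2, `[[`, "assignment"))
  q_singleton <- multilayer_quality(net, matrix(1:16, 8, 2))
  for (e in ens) expect_gte(e$Q, q_singleton)
})

test_that("assignment matrices round-trip through delimited text", {
  tl <- make_two_layer()
  net <- multilayer_network(list(tl$A1, tl$A2), c("a", "b"))
  gl <- generalized_louvain(net, seed = 1)
  path <- file.path(tempdir(), "assign.tsv")
  write_assignment(gl, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(as.matrix(df[, -1]), gl$assignment, ignore_attr = TRUE)
})
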