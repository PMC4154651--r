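test_that("edge tables carry consistent endpoint degrees and strengths", {
  ids <- c("a", "b")
  w <- matrix(c(0, 3, 0, 0), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  rec <- edge_table(functional_network(w))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$src_out_strength, 3)
  expect_equal(rec$dst_in_strength, 3)
  expect_equal(rec$src_out_degree, 1)
  expect_equal(rec$dst_in_degree, 1)

  # reciprocal pair -> two records; complete 3-node digraph -> 6 records
  w2 <- matrix(c(0, 1, 2, 0), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  expect_equal(nrow(edge_table(functional_network(w2))), 2L)
  w3 <- matrix(1, 3, 3); diag(w3) <- 0
  expect_equal(nrow(edge_table(functional_network(w3))), 6L)
})

test_that("degenerate and perfectly mixed networks behave as predicted", {
  # uniform directed ring: zero variance -> undefined
  n <- 6
  w <- matrix(0, n, n)
  w[cbind(seq_len(n), c(2:n, 1))] <- 1
  expect_error(assortativity(edge_table(functional_network(w)), "pearson-degree"),
               "zero variance")

  # two disjoint reciprocal dyads with very different weights: each node
  # pairs with an equal-strength partner -> weighted value +1
  ids <- c("a", "b", "c", "d")
  w2 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w2["a", "b"] <- w2["b", "a"] <- 10
  w2["c", "d"] <- w2["d", "c"] <- 1
  rec <- edge_table(functional_network(w2))
  expect_equal(assortativity(rec, "pearson-strength-weighted")$value, 1,
               tolerance = 1e-12)
  expect_equal(assortativity(rec, "spearman-strength-weighted")$value, 1,
               tolerance = 1e-12)
})

test_that("all four variants match the brute-force oracle to 12 digits", {
  variants <- c("pearson-degree", "spearman-degree",
                "pearson-strength-weighted", "spearman-strength-weighted")
  checked <- 0L
  for (s in 1:1000) {
    dims <- withr::with_seed(9000 + s, c(sample(4:7, 1), sample(4:10, 1)))
    net <- random_digraph_net(n = dims[1], n_edges = dims[2], seed = s)
    rec <- edge_table(net)
    for (v in variants) {
      got <- tryCatch(assortativity(rec, v)$value, error = function(e) NULL)
      if (is.null(got)) next
      want <- oracle_assortativity(rec, v)
      if (!is.finite(want)) next  # zero-variance edge case caught upstream
      expect_equal(got, want, tolerance = 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 3000)
})

test_that("degree assortativity agrees with igraph on random digraphs", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    net <- random_digraph_net(n = 12, n_edges = 40, seed = 100 + s)
    rec <- edge_table(net)
    g <- igraph::graph_from_adjacency_matrix((net$w > 0) * 1, mode = "directed")
    expect_equal(assortativity(rec, "pearson-degree")$value,
                 igraph::assortativity_degree(g, directed = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("weighted variant reduces to the plain correlation at equal weights", {
  net <- random_digraph_net(10, 35, seed = 7)
  rec <- edge_table(net)
  rec$weight <- rep(2.5, nrow(rec))   # equal weights, strengths untouched
  w_val <- assortativity(rec, "pearson-strength-weighted")$value
  expect_equal(w_val,
               stats::cor(rec$src_out_strength, rec$dst_in_strength),
               tolerance = 1e-12)
})

test_that("near-null random networks give weighted values near zero", {
  vals <- vapply(1:10, function(s) {
    net <- random_digraph_net(50, 400, seed = 200 + s)
    assortativity(edge_table(net), "pearson-strength-weighted")$value
  }, numeric(1))
  se <- vapply(1:10, function(s) {
    net <- random_digraph_net(50, 400, seed = 200 + s)
    bootstrap_error(edge_table(net), "pearson-strength-weighted",
                    n_boot = 200, seed = s)$stderr
  }, numeric(1))
  expect_true(all(abs(vals) < 3 * se))
})

test_that("bootstrap errors are deterministic, positive and flagged when degenerate", {
  net <- random_digraph_net(10, 30, seed = 5)
  rec <- edge_table(net)
  b1 <- bootstrap_error(rec, "pearson-degree", n_boot = 300, seed = 9)
  b2 <- bootstrap_error(rec, "pearson-degree", n_boot = 300, seed = 9)
  expect_identical(b1$stderr, b2$stderr)
  expect_gt(b1$stderr, 0)
  expect_false(b1$unreliable)

  b3 <- bootstrap_error(rec, "pearson-degree", n_boot = 1, seed = 9)
  expect_true(b3$unreliable)
  expect_equal(b3$stderr, 0)
})

test_that("rich-club ratio is near one on a strength-uncorrelated network", {
  # plant w_ij proportional to a_i * b_j: the analytic null is exact
  n <- 40
  net <- withr::with_seed(31, {
    a <- rlnorm(n, 0, 0.6); b <- rlnorm(n, 0, 0.6)
    w <- outer(a, b); diag(w) <- 0
    dimnames(w) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    functional_network(w)
  })
  rc <- rich_club_curve(net, n_thresholds = 30)
  expect_true(all(abs(rc$phi - 1) < 0.1))
})

test_that("a planted strong triangle among top-strength nodes yields phi > 1", {
  ids <- sprintf("n%d", 1:6)
  w <- matrix(0.05, 6, 6, dimnames = list(ids, ids)); diag(w) <- 0
  for (i in 1:3) for (j in 1:3) if (i != j) w[i, j] <- 1
  net <- functional_network(w)
  rc <- rich_club_curve(net, n_thresholds = 25)
  expect_gt(utils::tail(rc$phi, 1), 1)
  # full-graph limit: lowest threshold covers everyone, W = total weight
  expect_equal(rc$w_observed[1], total_strength(net))
})

test_that("analytic rich-club null matches the sampling null within 5%", {
  net <- withr::with_seed(33, {
    n <- 50
    a <- rlnorm(n, 0, 0.5); b <- rlnorm(n, 0, 0.5)
    w <- outer(a, b); diag(w) <- 0
    dimnames(w) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    functional_network(w)
  })
  rc <- rich_club_curve(net, n_thresholds = 20)
  emp <- rich_club_null_empirical(net, n_thresholds = 20, n_quanta = 40000,
                                  n_realizations = 30, seed = 8)
  cmp <- merge(rc, emp, by = "threshold")
  cmp <- cmp[cmp$n_nodes_above >= 5, ]
  expect_gt(nrow(cmp), 5)
  expect_true(all(abs(cmp$w_null_empirical / cmp$w_null - 1) < 0.05))
})

test_that("directed rich-club reduces to the undirected form on symmetric networks", {
  net <- withr::with_seed(35, {
    n <- 20
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    w[up] <- rlnorm(sum(up), 0, 0.8) * (runif(sum(up)) < 0.4)
    w <- w + t(w)
    dimnames(w) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    functional_network(w)
  })
  # undirected formulation: strengths s_i, W = sum of in-club weights,
  # null = (S_club^2 - sum s_i^2)/(2 S) with s the undirected strengths
  s <- out_strength(net)               # = in_strength by symmetry
  s_tot <- total_strength(net)
  rc <- rich_club_curve(net, n_thresholds = 15, ranking = "total")
  for (r in seq_len(nrow(rc))) {
    club <- which(s + s > rc$threshold[r])
    w_und <- ((sum(s[club]))^2 - sum(s[club]^2)) / s_tot
    expect_equal(rc$w_null[r], w_und, tolerance = 1e-10)
  }
})

test_that("network summaries reproduce printed-table consistency values", {
  rows <- list(A = c(38, 544, 14.32), L = c(17, 116, 6.82))
  for (r in rows) {
    net <- random_network(r[1], r[2], seed = 17)
    s <- summarize_network(net, n_boot = 100, rich_club = FALSE)
    expect_equal(s$n_nodes, r[1])
    expect_equal(s$n_edges, r[2])
    expect_equal(round(s$average_degree, 2), r[3])
  }
  # single link of weight 5 between 2 nodes
  ids <- c("a", "b")
  w <- matrix(c(0, 5, 0, 0), 2, 2, byrow = TRUE, dimnames = list(ids, ids))
  s2 <- summarize_network(functional_network(w), n_boot = 10, rich_club = FALSE)
  expect_equal(s2$average_degree, 0.5)
  expect_equal(s2$average_strength, 2.5)
})
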