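test_that("percolation threshold finds the giant-component emergence", {
  # two cliques joined by a 0.5 bridge: spanning component appears exactly
  # when the threshold drops below the bridge weight — verified against a
  # brute-force component scan over all candidate thresholds
  J <- two_clique_J(clique_size = 4, within = 1, bridge = 0.5)
  jo <- percolation_threshold(J)
  expect_lt(jo, 0.5)
  cand <- sort(unique(J[upper.tri(J)]), decreasing = TRUE)
  brute_spans <- sapply(cand, function(v) {
    A <- (J >= v) * 1; diag(A) <- 0
    gazetherm:::giant_fraction(A) > 0.5
  })
  # scanning strong -> weak, the first spanning candidate is the bridge weight
  expect_equal(cand[which(brute_spans)[1]], 0.5)
  A <- (J > jo) * 1; diag(A) <- 0
  expect_gt(gazetherm:::giant_fraction(A), 0.5)

  expect_warning(percolation_threshold(matrix(0, 4, 4)), "degenerate")
  # fully uniform couplings: degenerate by construction
  Ju <- matrix(0.7, 5, 5); diag(Ju) <- 0
  expect_warning(jo_u <- percolation_threshold(Ju), "degenerate")
  expect_equal(jo_u, 0.7)
})

test_that("percolation threshold shifts with a constant offset", {
  set.seed(90)
  J <- matrix(runif(64), 8, 8); J <- (J + t(J)) / 2; diag(J) <- 0
  j1 <- percolation_threshold(J)
  j2 <- percolation_threshold(J + 0.3 - diag(0.3, 8))
  expect_equal(j2 - j1, 0.3, tolerance = 1e-9)
})

test_that("modularity matches hand-computed closed forms", {
  # two equal disconnected cliques, labelled by clique: Q = 1/2
  A2 <- clique_adjacency(2, 4)
  expect_equal(modularity_q(A2, rep(1:2, each = 4)), 0.5)
  # complete graph as one community: Q = 0
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(modularity_q(K4, rep(1, 4)), 0)
  # cross-check against igraph on an arbitrary graph
  set.seed(91)
  A <- matrix(rbinom(100, 1, 0.4), 10, 10)
  A <- pmax(A, t(A)); diag(A) <- 0
  labels <- sample(1:3, 10, replace = TRUE)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(modularity_q(A, labels),
               igraph::modularity(g, labels), tolerance = 1e-12)
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "edgeless")
})

test_that("double-sum form equals the per-community form on random graphs", {
  per_community_q <- function(A, labels) {
    two_m <- sum(A)
    sum(sapply(unique(labels), function(c) {
      idx <- labels == c
      e_c <- sum(A[idx, idx]) / two_m
      a_c <- sum(A[idx, ]) / two_m
      e_c - a_c^2
    }))
  }
  set.seed(92)
  for (rep in 1:8) {
    A <- matrix(rbinom(64, 1, 0.5), 8, 8)
    A <- pmax(A, t(A)); diag(A) <- 0
    if (sum(A) == 0) next
    labels <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(A, labels), per_community_q(A, labels),
                 tolerance = 1e-12)
  }
})

test_that("literal Eq-normalisation flag changes the prefactor as documented", {
  A <- clique_adjacency(2, 4)
  lab <- rep(1:2, each = 4)
  q_std <- modularity_q(A, lab)
  q_lit <- modularity_q(A, lab, literal = TRUE)
  # literal reading: prefactor 1/(4m) and null term a_i a_j/(4m)
  a_i <- rowSums(A); m2 <- sum(a_i)
  same <- outer(lab, lab, `==`)
  expect_equal(q_lit, sum((A - outer(a_i, a_i) / (2 * m2)) * same) / (2 * m2))
  expect_gt(q_std, q_lit)
})

test_that("random labels on a random graph average to Q ~ 0", {
  set.seed(93)
  A <- matrix(rbinom(144, 1, 0.4), 12, 12)
  A <- pmax(A, t(A)); diag(A) <- 0
  qs <- replicate(400, modularity_q(A, sample(1:3, 12, replace = TRUE)))
  # iid uniform labels over k groups: E[Q] is not exactly 0 — the diagonal
  # null-model terms (delta always 1 for i = j) contribute an exact
  # -(1 - 1/k) * sum(a_i^2)/(2m)^2 finite-size bias
  a_i <- rowSums(A); two_m <- sum(a_i)
  expected <- -(1 - 1 / 3) * sum(a_i^2) / two_m^2
  se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - expected), 4 * se)
  expect_lt(abs(mean(qs)), 0.1)
})

test_that("community detection recovers planted structure", {
  # two disconnected cliques: unique optimum
  A <- clique_adjacency(2, 5)
  lab <- detect_communities(A, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_true(all(lab[1:5] == lab[1]) && all(lab[6:10] == lab[6]))
  expect_false(lab[1] == lab[6])

  # planted partition 2 x 8: heuristic labels match the planted split
  set.seed(94)
  n <- 16
  P <- matrix(0.05, n, n)
  P[1:8, 1:8] <- 0.9; P[9:16, 9:16] <- 0.9
  A <- matrix(rbinom(n * n, 1, P), n, n)
  A <- pmax(A, t(A)); diag(A) <- 0
  lab <- detect_communities(A, seed = 2)
  planted <- rep(1:2, each = 8)
  agreement <- max(mean(lab == planted), mean(lab == 3 - planted))
  expect_gte(agreement, 15 / 16)
  expect_error(detect_communities(matrix(0, 4, 4)), "edgeless")
})

test_that("heuristic modularity never exceeds the exhaustive optimum", {
  set.seed(95)
  for (rep in 1:5) {
    A <- matrix(rbinom(64, 1, 0.45), 8, 8)
    A <- pmax(A, t(A)); diag(A) <- 0
    if (sum(A) == 0) next
    exact <- detect_communities(A, method = "exact")
    heur <- detect_communities(A, seed = rep)
    expect_lte(attr(heur, "Q"), attr(exact, "Q") + 1e-12)
  }
})

test_that("community detection is invariant to node relabelling", {
  set.seed(96)
  A <- clique_adjacency(2, 5)
  A[2, 7] <- A[7, 2] <- 1   # one cross edge
  perm <- sample(10)
  lab <- detect_communities(A, seed = 3)
  lab_p <- detect_communities(A[perm, perm], seed = 3)
  # same partition up to label names: compare co-membership matrices
  co <- function(l) outer(l, l, `==`)
  expect_equal(co(lab_p), co(lab[perm]))
})

test_that("matrix reordering makes communities contiguous", {
  set.seed(97)
  # block matrix, then shuffled
  labels <- rep(1:3, times = c(5, 4, 3))
  M <- outer(labels, labels, function(a, b) ifelse(a == b, 0.8, 0.05))
  diag(M) <- 0
  perm0 <- sample(12)
  Ms <- M[perm0, perm0]
  p <- reorder_matrix(Ms, labels = labels[perm0])
  reordered_labels <- labels[perm0][p]
  expect_equal(rle(reordered_labels)$lengths, c(5, 4, 3))
  # identity admissible on already-ordered input
  p0 <- reorder_matrix(M, labels = labels)
  expect_equal(labels[p0], labels)
  expect_equal(reorder_matrix(matrix(1, 1, 1)), 1L)
})

test_that("viewer_network assembles threshold, communities and Q", {
  J <- two_clique_J(4, within = 1, bridge = 0.5)
  net <- viewer_network(J, seed = 4)
  expect_true(net$J_o < 0.5)
  expect_equal(dim(net$A), c(8, 8))
  expect_true(all(net$A %in% c(0, 1)))
  expect_equal(net$A, t(net$A))
  expect_equal(length(unique(net$communities)), 2)
  expect_gt(net$Q, 0.3)
})
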