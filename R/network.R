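#' Percolation threshold of the coupling matrix
#'
#' Scans candidate thresholds (the sorted unique off-diagonal couplings)
#' from strongest to weakest and returns the threshold `J_o` at which the
#' largest connected component of the graph `A = (J > J_o)` first spans a
#' majority of the nodes — the emergence of the giant component, the
#' standard percolation surrogate for "the value where the largest cluster
#' emerges". The returned `J_o` is placed halfway between the admitting
#' coupling value and the next weaker one, so that thresholding at `J_o`
#' reproduces the spanning graph.
#'
#' @param J symmetric coupling matrix (>= 3 nodes).
#' @param span_fraction fraction of nodes the largest component must exceed
#'   (default 0.5).
#' @return scalar threshold `J_o`. Degenerate inputs (all off-diagonal
#'   couplings equal) return that value with a warning.
#' @export
percolation_threshold <- function(J, span_fraction = 0.5) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (n < 3) stop("need at least 3 nodes")
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-8, check.attributes = FALSE)))
    stop("J must be symmetric")
  vals <- sort(unique(J[upper.tri(J)]), decreasing = TRUE)
  if (length(vals) == 1) {
    warning("all off-diagonal couplings equal: degenerate threshold")
    return(vals)
  }
  for (k in seq_along(vals)) {
    A <- (J >= vals[k]) * 1
    diag(A) <- 0
    if (giant_fraction(A) > span_fraction) {
      lower <- if (k < length(vals)) vals[k + 1] else vals[k] - abs(vals[k]) - 1
      return((vals[k] + lower) / 2)
    }
  }
  warning("no spanning component at any threshold")
  vals[length(vals)] - 1
}

# size fraction of the largest connected component of a binary adjacency
giant_fraction <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  max(igraph::components(g)$csize) / nrow(A)
}

#' Modularity of a community assignment
#'
#' Standard Newman-Girvan modularity of a binary undirected network,
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} -
#'   \frac{a_i a_j}{2m}\right) \delta(c_i, c_j),}
#' with \eqn{a_i} the node degrees and \eqn{m} the edge count
#' (\eqn{2m = \sum_i a_i}). `literal = TRUE` switches to the alternative
#' normalisation that reads the prefactor as \eqn{1/(2a)} with
#' \eqn{a = \sum_i a_i} (i.e. \eqn{1/(4m)}, and \eqn{a_i a_j/(4m)} inside);
#' under the standard normalisation two equal disconnected cliques score
#' exactly 0.5 and a single community scores 0.
#'
#' @param A symmetric binary adjacency matrix, zero diagonal, >= 1 edge.
#' @param labels integer/character community label per node.
#' @param literal use the literal alternative normalisation (default FALSE).
#' @return scalar Q.
#' @export
modularity_q <- function(A, labels, literal = FALSE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (length(labels) != n) stop("one label per node required")
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("A must be symmetric")
  if (any(A != 0 & A != 1)) stop("A must be binary")
  if (any(diag(A) != 0)) stop("A must have zero diagonal")
  a_i <- rowSums(A)
  two_m <- sum(a_i)
  if (two_m == 0) stop("edgeless graph: modularity undefined")
  same <- outer(labels, labels, `==`)
  norm <- if (literal) 2 * two_m else two_m
  sum((A - outer(a_i, a_i) / norm) * same) / norm
}

#' Detect communities by modularity maximisation
#'
#' Multi-level (Louvain) modularity maximisation on the binary viewer
#' network; falls back to fast-greedy agglomeration if Louvain is
#' unavailable. For small graphs (<= `exact_max` nodes) `method = "exact"`
#' enumerates all set partitions and returns the global optimum — intended
#' as a test oracle, not for routine use.
#'
#' @param A symmetric binary adjacency matrix with at least one edge.
#' @param seed integer seed (the heuristic is stochastic).
#' @param method "louvain", "greedy" or "exact".
#' @param exact_max node cap for exact enumeration (default 12).
#' @return integer community label per node (1-based, ordered by decreasing
#'   community size), with attribute `Q` holding the achieved modularity.
#' @export
detect_communities <- function(A, seed = 1L, method = c("louvain", "greedy",
                                                        "exact"),
                               exact_max = 12L) {
  method <- match.arg(method)
  A <- as.matrix(A)
  if (sum(A) == 0) stop("edgeless graph: no communities to detect")
  if (method == "exact") {
    if (nrow(A) > exact_max) stop("exact enumeration limited to small graphs")
    res <- exact_modularity_partition(A)
    labels <- res$labels
    attr(labels, "Q") <- res$Q
    return(labels)
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  labels <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed %% 2^31)
    cl <- if (method == "louvain") igraph::cluster_louvain(g)
          else igraph::cluster_fast_greedy(g)
    igraph::membership(cl)
  })
  labels <- relabel_by_size(as.integer(labels))
  attr(labels, "Q") <- modularity_q(A, labels)
  labels
}

# exhaustive search over set partitions (restricted growth strings)
exact_modularity_partition <- function(A) {
  n <- nrow(A)
  best_q <- -Inf
  best <- rep(1L, n)
  labels <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      q <- modularity_q(A, labels[seq_len(n)])
      if (q > best_q) {
        best_q <<- q
        best <<- labels[seq_len(n)]
      }
      return(invisible(NULL))
    }
    for (lab in seq_len(k + 1L)) {
      labels[i] <<- lab
      recurse(i + 1L, max(k, lab))
    }
  }
  labels[1] <- 1L
  recurse(2L, 1L)
  list(labels = relabel_by_size(best), Q = best_q)
}

relabel_by_size <- function(labels) {
  sizes <- sort(table(labels), decreasing = TRUE)
  match(as.character(labels), names(sizes))
}

#' Build the thresholded viewer network and its community structure
#'
#' Applies the percolation threshold to the coupling matrix, detects
#' communities by modularity maximisation, and returns the full network
#' summary used by the per-video pipeline.
#'
#' @param J symmetric coupling matrix.
#' @param seed integer seed for community detection.
#' @param J_o optional fixed threshold (default: [percolation_threshold]).
#' @param ... passed to [detect_communities].
#' @return object of class `viewer_network`: `J_o`, binary `A`,
#'   `communities`, `Q`, `degrees`, `subjects`.
#' @export
viewer_network <- function(J, seed = 1L, J_o = NULL, ...) {
  J <- as.matrix(J)
  if (is.null(J_o)) J_o <- percolation_threshold(J)
  A <- (J > J_o) * 1
  diag(A) <- 0
  if (sum(A) == 0) {
    communities <- seq_len(nrow(J))
    Q <- NA_real_
  } else {
    communities <- detect_communities(A, seed = seed, ...)
    Q <- attr(communities, "Q")
  }
  structure(
    list(J_o = J_o, A = A, communities = as.integer(communities), Q = Q,
         degrees = rowSums(A),
         subjects = colnames(J) %||% paste0("s", seq_len(nrow(J)))),
    class = "viewer_network"
  )
}

#' @export
print.viewer_network <- function(x, ...) {
  cat(sprintf("<viewer_network> %d nodes, %d edges (J_o = %.4g), %d communities, Q = %s\n",
              nrow(x$A), sum(x$A) / 2, x$J_o,
              length(unique(x$communities)),
              if (is.na(x$Q)) "NA" else sprintf("%.3f", x$Q)))
  invisible(x)
}

#' Display permutation grouping similar viewers together
#'
#' Returns a permutation of node indices that places members of the same
#' community contiguously (communities ordered by decreasing size, ties by
#' first appearance), for heat-map display of coupling or correlation
#' matrices.
#'
#' @param M symmetric matrix to reorder.
#' @param labels optional community labels; computed from `M` (thresholded
#'   at its percolation point) when omitted.
#' @param seed seed for community detection when labels are omitted.
#' @return integer permutation vector; `M[perm, perm]` is the display order.
#' @export
reorder_matrix <- function(M, labels = NULL, seed = 1L) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n == 1) return(1L)
  if (is.null(labels)) {
    labels <- tryCatch(
      suppressWarnings(viewer_network(M, seed = seed)$communities),
      error = function(e) rep(1L, n))
  }
  order(relabel_by_size(as.integer(labels)), seq_len(n))
}
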