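#' Build a weighted, undirected graph from a connectivity matrix
#'
#' Converts a symmetric connectivity matrix into the nonnegative weighted
#' adjacency matrix used by the efficiency measures: the diagonal is zeroed
#' and negative correlations are set to 0 by default (the weighted
#' efficiency formulas require nonnegative weights); absolute-value
#' handling is available via `negative_weights = "absolute"`.
#'
#' @param matrix A `connectivity_matrix` or plain symmetric numeric matrix.
#' @param negative_weights How to treat negative entries: `"zero"` (default)
#'   or `"absolute"`.
#' @return An object of class `weighted_graph`: list with `adjacency`
#'   (symmetric, nonnegative, zero diagonal) and `node_labels`.
#' @export
prepare_weighted_graph <- function(matrix, negative_weights = c("zero", "absolute")) {
  negative_weights <- match.arg(negative_weights)
  m <- conn_values(matrix)
  check_symmetric(m, what = "connectivity matrix")
  a <- if (negative_weights == "zero") pmax(m, 0) else abs(m)
  diag(a) <- 0
  labels <- rownames(m) %||% sprintf("ROI%03d", seq_len(nrow(m)))
  structure(
    list(adjacency = a, node_labels = labels),
    class = "weighted_graph"
  )
}

#' Threshold a weighted graph at a target sparsity
#'
#' Retains exactly `round(sparsity * n(n-1)/2)` strongest edges (rounding
#' half away from zero) and zeroes all others; surviving weights are kept
#' unchanged. Ties between equal weights are broken by ascending node-pair
#' index (row-major upper-triangle order), so thresholding is deterministic
#' and the retained edge set at a lower sparsity is always a subset of that
#' at a higher one. If the graph has fewer nonzero edges than requested,
#' all of them are kept with a warning.
#'
#' @param graph A [prepare_weighted_graph()] graph.
#' @param sparsity Proportion of possible edges to retain, in (0, 1].
#' @return A `weighted_graph` with the thresholded adjacency.
#' @export
threshold_by_sparsity <- function(graph, sparsity) {
  stopifnot(inherits(graph, "weighted_graph"))
  if (sparsity <= 0 || sparsity > 1) {
    stop("sparsity must lie in (0, 1]", call. = FALSE)
  }
  a <- graph$adjacency
  n <- nrow(a)
  pairs <- upper_tri_pairs(n)
  w <- a[cbind(pairs$i, pairs$j)]
  m_target <- as.integer(round_half_away(sparsity * nrow(pairs)))
  n_nonzero <- sum(w > 0)
  if (n_nonzero < m_target) {
    warning(
      "graph has only ", n_nonzero, " nonzero edges but sparsity ", sparsity,
      " requests ", m_target, "; keeping all nonzero edges",
      call. = FALSE
    )
    m_target <- n_nonzero
  }
  out <- matrix(0, n, n, dimnames = dimnames(a))
  if (m_target > 0L) {
    keep <- order(-w, seq_along(w))[seq_len(m_target)]
    ij <- cbind(pairs$i[keep], pairs$j[keep])
    out[ij] <- w[keep]
    out[ij[, 2:1, drop = FALSE]] <- w[keep]
  }
  structure(
    list(adjacency = out, node_labels = graph$node_labels),
    class = "weighted_graph"
  )
}

# igraph view of a weighted graph, with edge *lengths* = 1 / weight (the
# standard conversion from connection strength to travel cost).
as_igraph_lengths <- function(adjacency) {
  lengths <- ifelse(adjacency > 0, 1 / adjacency, 0)
  igraph::graph_from_adjacency_matrix(lengths,
    mode = "undirected",
    weighted = TRUE, diag = FALSE
  )
}

#' All-pairs weighted shortest path lengths
#'
#' Converts each edge weight to a length `1 / w` and computes all-pairs
#' shortest path lengths over the resulting graph (Dijkstra). Unreachable
#' pairs have distance `Inf`; the diagonal is 0.
#'
#' @param graph A `weighted_graph`.
#' @return Numeric n x n distance matrix.
#' @export
weighted_shortest_paths <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  d <- igraph::distances(as_igraph_lengths(graph$adjacency))
  dimnames(d) <- list(graph$node_labels, graph$node_labels)
  d
}

#' Weighted global efficiency
#'
#' Global efficiency measures network integration: the mean inverse weighted
#' shortest path length over all ordered node pairs,
#' \deqn{E_g = \frac{1}{n} \sum_{i} \frac{\sum_{j \ne i} (d^w_{ij})^{-1}}{n - 1}.}
#' Unreachable pairs contribute 0. A complete graph with unit weights has
#' \eqn{E_g = 1}; an edgeless graph has \eqn{E_g = 0}.
#'
#' @param graph A `weighted_graph` with at least 2 nodes.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- nrow(graph$adjacency)
  if (n < 2L) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  d <- weighted_shortest_paths(graph)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0 # diagonal (1/0) and unreachable pairs
  sum(inv) / (n * (n - 1))
}

#' Weighted local efficiency
#'
#' Local efficiency measures network segregation. For node i with neighbour
#' set \eqn{N_i} and degree \eqn{k_i},
#' \deqn{E_{loc,i} = \frac{\sum_{j \ne h \in N_i}
#'   \left(w_{ij} w_{ih} [d^w_{jh}(N_i)]^{-1}\right)^{1/3}}{k_i (k_i - 1)},}
#' where \eqn{d^w_{jh}(N_i)} is the shortest path length between j and h in
#' the subgraph induced by the neighbours of i (paths may not leave the
#' neighbour set). Nodes with fewer than 2 neighbours contribute 0, and the
#' network value is the mean over all nodes.
#'
#' @param graph A `weighted_graph` with at least 2 nodes.
#' @return Scalar local efficiency.
#' @export
local_efficiency <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  a <- graph$adjacency
  n <- nrow(a)
  if (n < 2L) stop("local efficiency needs at least 2 nodes", call. = FALSE)
  cpp_local_efficiency(a)
}

#' Efficiency across a sparsity sweep with AUC summary
#'
#' Prepares a weighted graph from a connectivity matrix, thresholds it at
#' each requested sparsity (default 5% to 50% in 5% increments), computes
#' global and local efficiency at every threshold, and summarises each
#' metric by the area under its curve over the sparsity axis (trapezoidal
#' rule), a threshold-independent scalar per subject. AUC units are metric
#' times sparsity width.
#'
#' @param matrix A `connectivity_matrix` or symmetric matrix.
#' @param sparsities Strictly increasing sparsity levels in (0, 1].
#' @param negative_weights Passed to [prepare_weighted_graph()].
#' @return An object of class `efficiency_curve`: `sparsities`, `eg_values`,
#'   `eloc_values`, `eg_auc`, `eloc_auc`.
#' @export
#' @examples
#' m <- matrix(0.5, 5, 5)
#' diag(m) <- 1
#' efficiency_curve(m, sparsities = c(0.5, 1))$eg_values
efficiency_curve <- function(matrix, sparsities = seq(0.05, 0.50, by = 0.05),
                             negative_weights = "zero") {
  if (length(sparsities) < 1L || any(sparsities <= 0) || any(sparsities > 1) ||
    is.unsorted(sparsities, strictly = TRUE)) {
    stop("sparsities must be strictly increasing values in (0, 1]", call. = FALSE)
  }
  g <- prepare_weighted_graph(matrix, negative_weights)
  eg <- numeric(length(sparsities))
  eloc <- numeric(length(sparsities))
  for (s in seq_along(sparsities)) {
    tg <- threshold_by_sparsity(g, sparsities[s])
    eg[s] <- global_efficiency(tg)
    eloc[s] <- local_efficiency(tg)
  }
  structure(
    list(
      sparsities = sparsities,
      eg_values = eg,
      eloc_values = eloc,
      eg_auc = trapezoid_auc(sparsities, eg),
      eloc_auc = trapezoid_auc(sparsities, eloc)
    ),
    class = "efficiency_curve"
  )
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf(
    "Efficiency curve over %d sparsities [%.2f, %.2f]: Eg AUC = %.4f, Eloc AUC = %.4f\n",
    length(x$sparsities), min(x$sparsities), max(x$sparsities),
    x$eg_auc, x$eloc_auc
  ))
  invisible(x)
}

#' Pooled-variance two-sample t comparison
#'
#' Student's two-sample t-test with pooled variance: with groups of sizes
#' n1 and n2 the test has n1 + n2 - 2 degrees of freedom (90 for two groups
#' of 46), and the p-value is two-sided.
#'
#' @param values_a,values_b Numeric vectors (at least 2 values each).
#' @return An object of class `group_comparison`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, and per-group means and SDs.
#' @export
compare_groups <- function(values_a, values_b) {
  n1 <- length(values_a)
  n2 <- length(values_b)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  pooled <- ((n1 - 1) * stats::var(values_a) + (n2 - 1) * stats::var(values_b)) /
    (n1 + n2 - 2)
  if (!is.finite(pooled) || pooled <= 0) {
    stop("zero pooled variance: the t statistic is undefined", call. = FALSE)
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  structure(
    list(
      t_statistic = unname(tt$statistic),
      degrees_of_freedom = unname(tt$parameter),
      p_value = tt$p.value,
      mean_a = mean(values_a), mean_b = mean(values_b),
      sd_a = stats::sd(values_a), sd_b = stats::sd(values_b)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Two-sample t (pooled): t(%d) = %.3f, p = %.4g; means %.4f vs %.4f\n",
    x$degrees_of_freedom, x$t_statistic, x$p_value, x$mean_a, x$mean_b
  ))
  invisible(x)
}
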