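# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Edge-length matrix (Inf = no edge) from a weighted adjacency matrix.
oracle_lengths <- function(adjacency) {
  lenm <- ifelse(adjacency > 0, 1 / adjacency, Inf)
  diag(lenm) <- Inf
  lenm
}

# All-pairs shortest paths by the classic Floyd-Warshall triple loop.
oracle_floyd_warshall <- function(lenm) {
  d <- lenm
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Shortest path between two nodes by exhaustive simple-path enumeration.
oracle_enum_distance <- function(lenm, from, to) {
  n <- nrow(lenm)
  best <- Inf
  visit <- function(node, dist, visited) {
    if (dist >= best) {
      return(invisible())
    }
    if (node == to) {
      best <<- dist
      return(invisible())
    }
    for (nxt in which(is.finite(lenm[node, ]) & !visited)) {
      v2 <- visited
      v2[nxt] <- TRUE
      visit(nxt, dist + lenm[node, nxt], v2)
    }
  }
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  visit(from, 0, visited)
  best
}

oracle_enum_all_distances <- function(lenm) {
  n <- nrow(lenm)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- oracle_enum_distance(lenm, i, j)
    }
  }
  d
}

# The efficiency oracles use the Floyd-Warshall distances (the enumeration
# oracle validates Floyd-Warshall itself on a separate sweep; full path
# enumeration inside the 100-graph efficiency sweeps would be exponential).
oracle_global_efficiency <- function(adjacency) {
  n <- nrow(adjacency)
  d <- oracle_floyd_warshall(oracle_lengths(adjacency))
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) total <- total + 1 / d[i, j]
    }
  }
  total / (n * (n - 1))
}

oracle_local_efficiency <- function(adjacency) {
  n <- nrow(adjacency)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adjacency[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- adjacency[nb, nb, drop = FALSE]
    dsub <- oracle_floyd_warshall(oracle_lengths(sub))
    acc <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a == b) next
        d_ab <- dsub[a, b]
        if (is.finite(d_ab)) {
          acc <- acc + (adjacency[i, nb[a]] * adjacency[i, nb[b]] / d_ab)^(1 / 3)
        }
      }
    }
    e[i] <- acc / (k * (k - 1))
  }
  mean(e)
}

# AUC as the pairwise win probability (ties count one half).
oracle_pairwise_auc <- function(scores, is_positive) {
  sp <- scores[is_positive]
  sn <- scores[!is_positive]
  wins <- 0
  for (a in sp) {
    for (b in sn) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
  }
  wins / (length(sp) * length(sn))
}

# Random connected-ish weighted graph for oracle-equivalence sweeps.
oracle_random_graph <- function(n, edge_prob = 0.5) {
  a <- matrix(0, n, n)
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < edge_prob
  w <- runif(nrow(pairs), 0.1, 1)
  a[pairs[on, , drop = FALSE]] <- w[on]
  a <- a + t(a)
  a
}

# Reference LOOCV written directly from the protocol definition (per-fold
# f_score + e1071 fit), independent of the incremental-sums engine.
oracle_naive_loocv <- function(x, y, k, positive = "patient") {
  n <- nrow(x)
  negative <- setdiff(unique(y), positive)
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    fs <- f_score(x[-i, , drop = FALSE], y[-i], positive)
    sel <- fs$ranking[seq_len(k)]
    xtr <- x[-i, sel, drop = FALSE]
    xte <- x[i, sel, drop = FALSE]
    mu <- apply(xtr, 2, mean)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xtr, factor(y[-i], levels = c(positive, negative)),
      kernel = "linear", cost = 1, scale = FALSE
    )
    pr <- predict(fit, xte, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    s <- drop(dv)[1]
    if (!startsWith(colnames(dv)[1], paste0(positive, "/"))) s <- -s
    pred[i] <- as.character(pr[1])
    score[i] <- s
  }
  data.frame(
    subject = seq_len(n), true_label = y,
    predicted_label = pred, decision_score = score,
    stringsAsFactors = FALSE
  )
}

# Deliberately leaky variant: features ranked once on ALL subjects (test
# subject included), then cross-validated. Used as a guard that the proper
# implementation does not leak.
leaky_loocv_accuracy <- function(x, y, k, positive = "patient") {
  sel <- f_score(x, y, positive)$ranking[seq_len(k)]
  negative <- setdiff(unique(y), positive)
  n <- nrow(x)
  correct <- 0
  for (i in seq_len(n)) {
    xtr <- x[-i, sel, drop = FALSE]
    mu <- apply(xtr, 2, mean)
    sdv <- apply(xtr, 2, sd)
    sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(x[i, sel, drop = FALSE], 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xtr, factor(y[-i], levels = c(positive, negative)),
      kernel = "linear", cost = 1, scale = FALSE
    )
    correct <- correct + (as.character(predict(fit, xte)) == y[i])
  }
  100 * correct / n
}

# Symmetric correlation-like matrix with random entries, unit diagonal.
random_symmetric_matrix <- function(n) {
  m <- matrix(runif(n * n, -1, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
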