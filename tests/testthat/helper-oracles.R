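# Independent reference implementations used as oracles. These deliberately
# re-derive the model from its definitions in plain R, without touching the
# package's C++ paths.

# one synchronous threshold update, straight from the update rule
oracle_step <- function(g, s, theta_zero = FALSE) {
  g <- unclass(g)
  theta <- if (theta_zero) rep(0, nrow(g)) else rowSums(g) / 2
  x <- drop(g %*% s) - theta
  out <- ifelse(x > 0, 1L, ifelse(x < 0, 0L, as.integer(s)))
  as.integer(out)
}

# brute-force trajectory tracer: store every visited state until recurrence
oracle_develop <- function(g, s0, theta_zero = FALSE) {
  seen <- list()
  keys <- character(0)
  s <- as.integer(s0)
  repeat {
    key <- paste(s, collapse = "")
    hit <- match(key, keys)
    if (!is.na(hit)) {
      cyc <- do.call(rbind, seen[seq(hit, length(seen))])
      return(list(states = cyc, period = nrow(cyc), transient = hit - 1L))
    }
    keys <- c(keys, key)
    seen <- c(seen, list(s))
    stopifnot(length(seen) <= 2^length(s) + 1)
    s <- oracle_step(g, s, theta_zero)
  }
}

# Wagner-model update on states in {-1, +1}: sign of the input, ties hold
oracle_wagner_step <- function(g, sigma) {
  x <- drop(unclass(g) %*% sigma)
  ifelse(x > 0, 1L, ifelse(x < 0, -1L, as.integer(sigma)))
}

all_states <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

random_discrete_genotype <- function(n, m) {
  g <- matrix(0, n, n)
  g[sample(n^2, m)] <- sample(c(-1, 1), m, replace = TRUE)
  grn_genotype(g)
}

# all set partitions of n elements as restricted-growth membership vectors
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx, i) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) {
      a[i] <- v
      rec(a, max(mx, v), i + 1L)
    }
  }
  rec(integer(n), 0L, 1L)
  out
}

# exhaustive maximum of Q over every partition of the graph's nodes
oracle_best_q <- function(graph, parts = NULL) {
  if (is.null(parts)) parts <- all_set_partitions(graph$n_nodes)
  max(vapply(parts, function(p) q_score(graph, p), numeric(1)))
}

# Q from first principles on the dense adjacency, independent of q_score's
# edge-list arithmetic
oracle_q <- function(graph, partition) {
  a <- adjacency_matrix(graph)
  L <- sum(a)
  q <- 0
  for (m in unique(partition)) {
    idx <- which(partition == m)
    q <- q + sum(a[idx, idx]) / L -
      sum(a[idx, ]) * sum(a[, idx]) / L^2
  }
  q
}
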