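#' Degree-preserving randomization by edge switching
#'
#' Repeatedly picks two edges `(a -> b)`, `(c -> d)` and rewires them to
#' `(a -> d)`, `(c -> b)`, rejecting any move that would duplicate an
#' existing edge or create a new self-loop. Every node's in- and out-degree
#' is preserved exactly. Existing self-loops are left untouched and excluded
#' from the swappable pool, so the degree sequences stay exact without the
#' switching moves ever involving them.
#'
#' @param graph a [grn_digraph()] (or anything [as_digraph()] accepts).
#' @param n_attempts number of attempted swaps; defaults to `100 * L`,
#'   common practice for the switching algorithm.
#' @return A randomized [grn_digraph()] with identical degree sequences.
#' @export
switch_randomize <- function(graph, n_attempts = NULL) {
  graph <- as_digraph(graph)
  if (is.null(n_attempts)) n_attempts <- 100L * n_edges(graph)
  if (n_edges(graph) < 2) return(graph)
  edges <- cpp_switch_randomize(graph$edges, graph$n_nodes,
                                as.integer(n_attempts))
  grn_digraph(graph$n_nodes, edges, labels = graph$labels)
}

#' In-/out-degree sequences of a directed graph
#' @param graph a [grn_digraph()].
#' @return List with integer vectors `in_degree` and `out_degree`.
#' @export
degree_sequences <- function(graph) {
  graph <- as_digraph(graph)
  list(in_degree = tabulate(graph$edges[, 2], nbins = graph$n_nodes),
       out_degree = tabulate(graph$edges[, 1], nbins = graph$n_nodes))
}

new_normalized_modularity <- function(raw, null_q, partition = NULL,
                                      score = c("q_p", "q_opt")) {
  score <- match.arg(score)
  null_mean <- mean(null_q)
  null_sd <- stats::sd(null_q)
  z <- if (is.na(null_sd) || null_sd == 0) {
    warning("null ensemble has zero spread; normalized score is undefined")
    NA_real_
  } else (raw - null_mean) / null_sd
  structure(list(raw = raw, null_mean = null_mean, null_sd = null_sd, z = z,
                 n_randomizations = length(null_q), score = score,
                 partition = partition),
            class = "grn_normalized_modularity")
}

#' @export
print.grn_normalized_modularity <- function(x, ...) {
  lab <- if (x$score == "q_p") "Q_P" else "Q^opt"
  cat(sprintf(
    "<grn_normalized_modularity> %s = %.4f; null %.4f +/- %.4f (n = %d); z = %.3f\n",
    lab, x$raw, x$null_mean, x$null_sd, x$n_randomizations, x$z))
  invisible(x)
}

#' Normalized partition modularity (z-score against switching nulls)
#'
#' Measures `Q_P` of the focal network for a fixed partition `P`, then the
#' same score in `n_rand` independent degree-preserving randomizations, and
#' reports the z-score `(Q_P - mean) / sd` against that null ensemble. A
#' score of 0 means the network concentrates interactions within `P`'s
#' modules no more than random networks of identical degree sequences; the
#' normalization discards the contribution of sparseness alone.
#'
#' @inheritParams q_score
#' @param n_rand number of randomized networks (1,000 by convention).
#' @param n_attempts attempted swaps per randomization; default `100 * L`.
#' @return A `grn_normalized_modularity` with fields `raw`, `null_mean`,
#'   `null_sd`, `z`, `n_randomizations`. If the null ensemble is degenerate
#'   (zero spread) the z-score is `NA` with a warning, never silently 0.
#' @export
normalized_qp <- function(graph, partition, n_rand = 1000,
                          n_attempts = NULL) {
  graph <- as_digraph(graph)
  if (n_rand < 2) stop("at least two randomizations are required")
  if (is.null(n_attempts)) n_attempts <- 100L * n_edges(graph)
  memb <- check_partition(partition, graph$n_nodes)
  raw <- q_score(graph, memb)
  null_q <- cpp_null_qp(graph$edges, graph$n_nodes, memb,
                        as.integer(n_rand), as.integer(n_attempts))
  new_normalized_modularity(raw, null_q, partition = memb, score = "q_p")
}

#' Normalized optimized modularity (z-score against switching nulls)
#'
#' As [normalized_qp()], but with no a-priori partition: the focal network's
#' `Q^opt` from [spectral_partition()] is compared against the spectral
#' optimum re-computed for each of `n_rand` degree-preserving
#' randomizations. Positive values mean the network is more modular than
#' random networks with the same degree sequences.
#'
#' @inheritParams normalized_qp
#' @return A `grn_normalized_modularity`; `partition` holds the focal
#'   network's optimal partition.
#' @export
normalized_qopt <- function(graph, n_rand = 1000, n_attempts = NULL) {
  graph <- as_digraph(graph)
  if (n_rand < 2) stop("at least two randomizations are required")
  if (is.null(n_attempts)) n_attempts <- 100L * n_edges(graph)
  opt <- spectral_partition(graph)
  null_q <- vapply(seq_len(n_rand), function(i) {
    spectral_partition(switch_randomize(graph, n_attempts))$q
  }, numeric(1))
  new_normalized_modularity(opt$q, null_q, partition = opt$partition,
                            score = "q_opt")
}

#' Uniform random directed graph with fixed edge count
#'
#' Draws `n_edges` distinct ordered pairs uniformly without replacement
#' among the possible positions. Used for the random-network ensembles that
#' calibrate how sparseness alone inflates raw modularity. Self-loops
#' (autoregulation) are allowed by default, mirroring the genotype model
#' where any matrix entry may hold an interaction; ensembles generated this
#' way reproduce the reference raw-modularity distributions.
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of distinct directed edges.
#' @param allow_self_loops permit `i -> i` edges?
#' @return A [grn_digraph()].
#' @export
random_digraph <- function(n_nodes, n_edges, allow_self_loops = TRUE) {
  max_edges <- if (allow_self_loops) n_nodes^2 else n_nodes * (n_nodes - 1)
  if (n_edges > max_edges)
    stop("requested more edges than available positions")
  pos <- if (allow_self_loops) seq_len(n_nodes^2)
         else which(diag(n_nodes) == 0)
  idx <- sample(pos, n_edges)
  # positions index an n x n matrix a[target, source] (column-major)
  tgt <- ((idx - 1L) %% n_nodes) + 1L
  src <- ((idx - 1L) %/% n_nodes) + 1L
  grn_digraph(n_nodes, cbind(src, tgt))
}

#' Generate a pair of target GAPs with a reference partition
#'
#' Builds two stationary target patterns for the two-phenotype selection
#' scenario: the first `N - n_differing` genes (set A) have the same
#' activity state in both targets, while the last `n_differing` genes (set
#' B) have complementary states. The returned partition `P = {A, B}` is the
#' mechanistic module hypothesis that the partition score `Q_P` refers to.
#' With `fixed = TRUE` (default) the ancestral target is the all-active
#' pattern, as in the reference scenario; with `fixed = FALSE` the shared
#' and differing states are drawn at random, which leaves every result
#' statistically unchanged because only the number of differing genes
#' matters for this model family.
#'
#' @param n_genes number of genes `N`.
#' @param n_differing how many genes differ between the two targets
#'   (1 to `N - 1`).
#' @param fixed use the fixed all-active ancestral pattern (`TRUE`) or draw
#'   random activity states (`FALSE`)?
#' @return List with binary vectors `target1`, `target2` and integer
#'   `partition` (1 = set A, 2 = set B).
#' @export
make_target_pair <- function(n_genes, n_differing, fixed = TRUE) {
  if (n_differing < 1 || n_differing > n_genes - 1)
    stop("n_differing must lie between 1 and n_genes - 1")
  n_same <- n_genes - n_differing
  t1 <- if (fixed) rep(1L, n_genes)
        else sample(c(0L, 1L), n_genes, replace = TRUE)
  t2 <- t1
  diff_idx <- seq(n_same + 1L, n_genes)
  t2[diff_idx] <- 1L - t2[diff_idx]
  list(target1 = t1, target2 = t2,
       partition = c(rep(1L, n_same), rep(2L, n_differing)))
}
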