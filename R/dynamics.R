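#' Gene activation thresholds
#'
#' Gene `i` switches on when the summed influence of its active regulators
#' exceeds the threshold `theta_i = sum_j g[i, j] / 2` (half the row sum of
#' its regulatory weights). This choice makes the dynamics equivalent to the
#' classic Wagner model with states in \{-1, +1\} and zero thresholds. The
#' `"zero"` variant instead fixes `theta_i = 0` for every gene.
#'
#' @param genotype a [grn_genotype()] or square matrix.
#' @param variant threshold rule, `"half_rowsum"` (default) or `"zero"`.
#' @return Numeric vector of per-gene thresholds.
#' @examples
#' threshold_values(grn_genotype(rbind(c(1, 1), c(1, -1))))
#' @export
threshold_values <- function(genotype, variant = c("half_rowsum", "zero")) {
  variant <- match.arg(variant)
  g <- as_genotype_matrix(genotype)
  if (variant == "zero") rep(0, nrow(g)) else rowSums(g) / 2
}

check_state <- function(state, n) {
  state <- as.integer(state)
  if (length(state) != n)
    stop("state length (", length(state), ") must equal the network size (", n, ")")
  if (!all(state %in% c(0L, 1L))) stop("states are strictly binary (0/1)")
  state
}

#' One synchronous update of the network state
#'
#' Applies the threshold dynamics to every gene simultaneously: gene `i`
#' becomes active when `sum_j g[i, j] * s[j] - theta_i > 0`, inactive when
#' the argument is negative, and keeps its current state on an exact tie.
#'
#' @inheritParams threshold_values
#' @param state binary vector of length `N` (1 = gene active).
#' @return The next system state (integer 0/1 vector).
#' @examples
#' g <- grn_genotype(rbind(c(0, 1), c(1, 0)))
#' grn_step(g, c(1, 0))
#' @export
grn_step <- function(genotype, state, variant = c("half_rowsum", "zero")) {
  variant <- match.arg(variant)
  g <- as_genotype_matrix(genotype)
  state <- check_state(state, nrow(g))
  cpp_step(g, state, variant == "zero")
}

#' Develop a network to its attractor (gene activity phenotype)
#'
#' Iterates the synchronous dynamics from an initial state until a previously
#' visited state recurs. Because the state space is finite this always
#' happens within `2^N` steps, and the trajectory then cycles forever through
#' `k` distinct states: the network's gene activity phenotype (GAP). `k = 1`
#' is a stationary GAP (fixed point); `k > 1` a limit cycle.
#'
#' @inheritParams grn_step
#' @param initial initial binary state vector.
#' @return A `grn_attractor`: list with `states` (a `k x N` 0/1 matrix in
#'   dynamical order, first-reached state first), `period` `k` and
#'   `transient_length` (steps from the initial state to the first attractor
#'   state).
#' @examples
#' g <- grn_genotype(rbind(c(0, 1), c(1, 0)))
#' grn_develop(g, c(1, 0))   # a 2-cycle
#' @export
grn_develop <- function(genotype, initial, variant = c("half_rowsum", "zero")) {
  variant <- match.arg(variant)
  g <- as_genotype_matrix(genotype)
  initial <- check_state(initial, nrow(g))
  res <- cpp_develop(g, initial, variant == "zero")
  structure(list(states = res$states, period = res$period,
                 transient_length = res$transient),
            class = "grn_attractor")
}

#' @export
print.grn_attractor <- function(x, ...) {
  kind <- if (x$period == 1) "stationary GAP" else paste0(x$period, "-cycle GAP")
  cat(sprintf("<grn_attractor> %s, transient %d\n", kind, x$transient_length))
  print(x$states)
  invisible(x)
}

#' Canonical rotation of an attractor's cycle
#'
#' Rotates the cycle so the lexicographically smallest state comes first;
#' used when comparing attractors for equality (the reported rotation keeps
#' the first-reached state first, so transients stay meaningful).
#'
#' @param attractor a `grn_attractor`.
#' @return A `k x N` 0/1 matrix.
#' @export
canonical_states <- function(attractor) {
  st <- attractor$states
  k <- nrow(st)
  if (k == 1) return(st)
  keys <- apply(st, 1, paste, collapse = "")
  rot <- which.min(rank(keys, ties.method = "first"))
  st[c(seq(rot, k), seq_len(rot - 1)), , drop = FALSE]
}

#' Test whether a state is a fixed point of a genotype
#' @inheritParams grn_step
#' @return Logical scalar.
#' @export
is_fixed_point <- function(genotype, state, variant = c("half_rowsum", "zero")) {
  all(grn_step(genotype, state, variant) == as.integer(state))
}

#' Randomly perturb a binary state
#'
#' Flips each entry independently with probability `kappa`, modelling
#' non-genetic perturbation (developmental noise) of the initial condition
#' from which a cell develops.
#'
#' @param state binary vector.
#' @param kappa per-gene flip probability in \[0, 1\].
#' @return Perturbed state (integer 0/1 vector).
#' @export
perturb_state <- function(state, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa < 0 || kappa > 1)
    stop("kappa must be a probability in [0, 1]")
  state <- as.integer(state)
  flip <- stats::runif(length(state)) < kappa
  ifelse(flip, 1L - state, state)
}
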