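#' Target specification for selection
#'
#' Bundles the `T` stationary target GAPs that selection favours, together
#' with the number of cells devoted to each. An individual is an organism of
#' `total_cells` cells (100 by default); `K = total_cells / T` cells are
#' required to produce each target from (possibly perturbed) initial states.
#'
#' @param targets a `T x N` 0/1 matrix (one row per target GAP) or a list of
#'   binary vectors.
#' @param total_cells total number of cells per organism.
#' @param labels optional target labels (e.g. `c("I", "II")`).
#' @return A `grn_target_spec` list with elements `targets`, `cells`,
#'   `labels`.
#' @export
target_spec <- function(targets, total_cells = 100, labels = NULL) {
  if (is.list(targets)) targets <- do.call(rbind, lapply(targets, as.integer))
  targets <- as.matrix(targets)
  storage.mode(targets) <- "integer"
  if (!all(targets %in% c(0L, 1L))) stop("target GAPs are binary patterns")
  T_ <- nrow(targets)
  if (T_ < 1) stop("at least one target GAP is required")
  if (total_cells %% T_ != 0)
    stop("total_cells must be divisible by the number of targets")
  if (is.null(labels)) labels <- as.character(as.roman(seq_len(T_)))
  structure(list(targets = targets, cells = rep(total_cells %/% T_, T_),
                 labels = labels),
            class = "grn_target_spec")
}

#' @export
print.grn_target_spec <- function(x, ...) {
  cat(sprintf("<grn_target_spec> %d target GAP(s) of %d genes, %d cell(s) each\n",
              nrow(x$targets), ncol(x$targets), x$cells[1]))
  invisible(x)
}

#' Distance between a target GAP and an attained attractor
#'
#' For a stationary attractor the distance is the Hamming count of genes
#' whose activity differs from the target. For a limit cycle it is the
#' arithmetic mean of the Hamming distances between the target and each of
#' the cycle's states, which reduces to the former when `k = 1` and
#' penalizes non-stationary phenotypes.
#'
#' @param target binary target pattern.
#' @param attained a `grn_attractor` (from [grn_develop()]) or a `k x N` 0/1
#'   matrix of cycle states.
#' @param rule `"cycle_mean"` (default) or a function
#'   `(target, states) -> distance` for custom rules.
#' @return Non-negative numeric distance; 0 iff the attained GAP is the
#'   stationary target itself.
#' @export
gap_distance <- function(target, attained, rule = "cycle_mean") {
  states <- if (inherits(attained, "grn_attractor")) attained$states
            else as.matrix(attained)
  target <- as.integer(target)
  if (ncol(states) != length(target))
    stop("target length must match the attractor's number of genes")
  if (is.function(rule)) return(rule(target, states))
  if (!identical(rule, "cycle_mean")) stop("unknown distance rule: ", rule)
  mean(colSums(abs(t(states) - target)))
}

#' Fitness contribution of one cell
#'
#' A cell whose attained GAP lies at distance `D` from its target GAP
#' contributes `w = (1 - S)^D`, where `S` is the selection coefficient
#' calibrating how deleterious deviations from the target are.
#'
#' @param distance non-negative distance `D`.
#' @param S selection coefficient in \[0, 1).
#' @return Fitness in (0, 1].
#' @examples
#' cell_fitness(2, S = 0.4)  # 0.6^2 = 0.36
#' @export
cell_fitness <- function(distance, S) {
  if (any(S < 0 | S >= 1)) stop("S must lie in [0, 1)")
  if (any(distance < 0)) stop("distances are non-negative")
  (1 - S)^distance
}

#' Organismal fitness under a target specification
#'
#' For each target GAP `X`, `K` cells develop from initial states obtained
#' by flipping each entry of `X` with probability `kappa`; each cell
#' contributes `(1 - S)^D` with `D` the distance between its attained GAP
#' and `X`. The target's contribution is the arithmetic mean over its `K`
#' cells and organismal fitness is the product over targets.
#'
#' @param genotype a [grn_genotype()].
#' @param spec a [target_spec()].
#' @param kappa perturbation rate for initial states.
#' @param S selection coefficient.
#' @param variant dynamics variant, see [grn_develop()].
#' @param rule distance rule, see [gap_distance()].
#' @return Fitness in (0, 1]; stochastic unless `kappa = 0` (seed the RNG
#'   for reproducibility).
#' @export
organism_fitness <- function(genotype, spec, kappa, S,
                             variant = c("half_rowsum", "zero"),
                             rule = "cycle_mean") {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "grn_target_spec"))
  w <- 1
  for (t in seq_len(nrow(spec$targets))) {
    x <- spec$targets[t, ]
    contrib <- vapply(seq_len(spec$cells[t]), function(cell) {
      s0 <- perturb_state(x, kappa)
      att <- grn_develop(genotype, s0, variant)
      cell_fitness(gap_distance(x, att, rule), S)
    }, numeric(1))
    w <- w * mean(contrib)
  }
  w
}

#' Mutate a genotype
#'
#' Applies one generation of mutation. Under the default `"biased"` variant,
#' each gene `i` (with `R_i` current regulators out of `N` possible) loses a
#' uniformly chosen existing interaction with probability
#' `mu * (1 - gamma) * R_i / N` and gains one at a uniformly chosen empty
#' entry (random +1/-1 sign) with probability `mu * gamma * (N - R_i) / N`;
#' the two events are mutually exclusive alternatives within a generation.
#' This pulls regulator counts towards `gamma * N`, so `gamma` tunes the
#' expected network density `gamma * N^2`. The `"unbiased"` variant mutates
#' each gene with probability `mu` and then gains or loses with equal
#' probability regardless of `R_i`. The `"continuous"` variant acts on
#' real-weight genotypes: gains draw standard-normal weights and, with
#' probability `mu * gamma * R_i / N`, an existing weight is redrawn from a
#' standard normal with its sign forced to the pre-mutation sign.
#'
#' @inheritParams organism_fitness
#' @param mu per-gene mutation probability per generation.
#' @param gamma propensity to gain interactions, in \[0, 1\].
#' @param variant `"biased"`, `"unbiased"` or `"continuous"`.
#' @return The mutated [grn_genotype()].
#' @export
mutate_genotype <- function(genotype, mu, gamma,
                            variant = c("biased", "unbiased", "continuous")) {
  variant <- match.arg(variant)
  stopifnot(mu >= 0, mu <= 1, gamma >= 0, gamma <= 1)
  g <- as_genotype_matrix(genotype)
  mode <- if (variant == "continuous") "continuous" else genotype_mode(genotype)
  out <- cpp_mutate(g, mu, gamma, match(variant, c("biased", "unbiased",
                                                   "continuous")) - 1L)
  grn_genotype(out, mode = mode)
}

#' Roulette-wheel selection
#'
#' Draws `m` parents with replacement, each individual picked with
#' probability proportional to its fitness.
#'
#' @param fitnesses non-negative fitness vector with at least one positive
#'   entry.
#' @param m number of draws.
#' @return Integer vector of `m` selected indices.
#' @export
roulette_select <- function(fitnesses, m) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  tot <- sum(fitnesses)
  if (tot <= 0) stop("all fitnesses are zero; selection is undefined")
  cs <- cumsum(fitnesses)
  findInterval(stats::runif(m) * tot, cs) + 1L
}

#' Build a founder network for a stationary target GAP
#'
#' Draws random genotypes with `round(gamma * N^2)` interactions until one
#' appears for which the target GAP is a fixed point of the unperturbed
#' dynamics (so the network produces the target exactly when development
#' starts from it). Such founders seed every individual of a population.
#'
#' @param target binary target pattern of length `N`.
#' @param gamma propensity to gain interactions; sets founder density.
#' @param mode genotype mode, see [grn_genotype()].
#' @param allow_self permit self-regulation in the founder?
#' @param variant dynamics variant.
#' @param max_attempts error out after this many rejected candidates
#'   (signals an unreachable target/`gamma` combination).
#' @return A [grn_genotype()] with attribute `"attempts"` recording how many
#'   candidates were drawn.
#' @export
build_founder <- function(target, gamma, mode = c("discrete", "continuous"),
                          allow_self = TRUE,
                          variant = c("half_rowsum", "zero"),
                          max_attempts = 100000L) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  target <- as.integer(target)
  n <- length(target)
  m <- round(gamma * n^2)
  for (attempt in seq_len(max_attempts)) {
    cand <- random_genotype(n, m, mode = mode, allow_self = allow_self)
    if (is_fixed_point(cand, target, variant)) {
      attr(cand, "attempts") <- attempt
      return(cand)
    }
  }
  stop("no founder found in ", max_attempts,
       " attempts; the target/gamma combination may be unreachable")
}

#' Evolution configuration
#'
#' Collects every parameter of a population-level simulation. The study's
#' reference values are the defaults: `N = 10` genes, `M = 200` individuals,
#' `mu = 0.01`, `gamma = 0.3`, `kappa = 0.05`, `S = 0.4`. Selection regimes
#' are expressed as consecutive `stages`, each with its own [target_spec()],
#' duration, and optional `gamma`/`kappa` overrides (used by the epoch-switch
#' experiments); the evolved population carries over between stages.
#'
#' @param stages list of stages; each a list with elements `targets` (a
#'   [target_spec()]), `generations`, and optional `gamma`, `kappa`.
#' @param pop_size population size `M`.
#' @param mu per-gene mutation rate.
#' @param gamma default gain propensity.
#' @param kappa default perturbation rate of initial states.
#' @param S selection coefficient.
#' @param mutation_variant see [mutate_genotype()].
#' @param dynamics_variant see [grn_develop()].
#' @param allow_self permit self-regulation in founders/mutants?
#' @param seed optional integer; when given, [run_population()] seeds the RNG
#'   with it before doing anything stochastic.
#' @return A `grn_evolution_config` list.
#' @export
evolution_config <- function(stages, pop_size = 200, mu = 0.01, gamma = 0.3,
                             kappa = 0.05, S = 0.4,
                             mutation_variant = c("biased", "unbiased",
                                                  "continuous"),
                             dynamics_variant = c("half_rowsum", "zero"),
                             allow_self = TRUE, seed = NULL) {
  mutation_variant <- match.arg(mutation_variant)
  dynamics_variant <- match.arg(dynamics_variant)
  stopifnot(pop_size >= 1, mu >= 0, mu <= 1, gamma >= 0, gamma <= 1,
            kappa >= 0, kappa <= 1, S >= 0, S < 1, length(stages) >= 1)
  stages <- lapply(stages, function(st) {
    stopifnot(inherits(st$targets, "grn_target_spec"),
              is.numeric(st$generations), st$generations >= 0)
    list(targets = st$targets, generations = as.integer(st$generations),
         gamma = if (is.null(st$gamma)) gamma else st$gamma,
         kappa = if (is.null(st$kappa)) kappa else st$kappa)
  })
  n <- ncol(stages[[1]]$targets$targets)
  structure(list(n_genes = n, stages = stages, pop_size = as.integer(pop_size),
                 mu = mu, gamma = gamma, kappa = kappa, S = S,
                 mutation_variant = mutation_variant,
                 dynamics_variant = dynamics_variant,
                 allow_self = allow_self, seed = seed),
            class = "grn_evolution_config")
}

#' Run one population through its selection stages
#'
#' Initializes `M` copies of a founder built for the first stage's first
#' target GAP, then iterates generations of (i) fitness evaluation of every
#' individual with freshly perturbed cell initial states, (ii)
#' roulette-wheel selection of `M` parents with replacement, and (iii)
#' mutation of every offspring. Stages run consecutively on the same evolving
#' population. At the end of each stage the resulting population is evaluated
#' once more; that snapshot determines whether the population is *adapted*
#' (maximum fitness above `adapted_threshold`) and which individual is the
#' *focal network* (one sampled uniformly among those of top fitness).
#'
#' All randomness flows from R's RNG in a fixed order (founder search; then
#' per generation: cell perturbations in individual order, selection draws,
#' mutation draws per offspring and gene; then the snapshot evaluation), so a
#' seeded run is exactly reproducible.
#'
#' @param config a [grn_evolution_config][evolution_config()].
#' @param founder optional pre-built founder genotype (skips founder search).
#' @param use_cache memoize attractors per (genotype, initial state)? Purely
#'   an optimization; traces are identical either way.
#' @param adapted_threshold fitness threshold defining adapted populations.
#' @return A `grn_population_trace`: list with `trace` (per-generation
#'   data.frame: `generation`, `stage`, `max_fitness`, `mean_fitness`,
#'   `mean_interactions`), `stage_end` (per stage: snapshot `fitness`,
#'   `n_interactions`, `genotypes`, `adapted`, `focal` index and
#'   `focal_genotype`), `founder`, and `config`.
#' @export
run_population <- function(config, founder = NULL, use_cache = TRUE,
                           adapted_threshold = 0.9) {
  stopifnot(inherits(config, "grn_evolution_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mode <- if (config$mutation_variant == "continuous") "continuous" else "discrete"
  if (is.null(founder)) {
    st1 <- config$stages[[1]]
    founder <- build_founder(st1$targets$targets[1, ], gamma = st1$gamma,
                             mode = mode, allow_self = config$allow_self,
                             variant = config$dynamics_variant)
  }
  g <- as_genotype_matrix(founder)
  if (nrow(g) != config$n_genes)
    stop("founder size does not match the configured number of genes")
  stages_cpp <- lapply(config$stages, function(st) {
    list(targets = st$targets$targets, cells = as.integer(st$targets$cells),
         generations = st$generations, gamma = st$gamma, kappa = st$kappa)
  })
  res <- cpp_run_population(g, stages_cpp, config$mu, config$S,
                            config$pop_size,
                            match(config$mutation_variant,
                                  c("biased", "unbiased", "continuous")) - 1L,
                            config$dynamics_variant == "zero", use_cache)
  stage_end <- lapply(res$stage_end, function(se) {
    fit <- se$fitness
    top <- which(fit >= max(fit) - 1e-12)
    focal <- top[sample.int(length(top), 1L)]
    list(fitness = fit, n_interactions = se$n_interactions,
         genotypes = lapply(se$genotypes, grn_genotype, mode = mode),
         adapted = max(fit) > adapted_threshold, focal = focal,
         focal_genotype = grn_genotype(se$genotypes[[focal]], mode = mode))
  })
  structure(list(trace = res$trace, stage_end = stage_end,
                 founder = grn_genotype(g, mode = mode), config = config,
                 adapted = stage_end[[length(stage_end)]]$adapted),
            class = "grn_population_trace")
}

#' @export
print.grn_population_trace <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "<grn_population_trace> %d generations, %d stage(s); final max fitness %.3f (%s)\n",
    nrow(x$trace), length(x$stage_end), last$max_fitness,
    if (x$adapted) "adapted" else "not adapted"))
  invisible(x)
}
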