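#' Paired and distributional test statistics
#'
#' Wilcoxon signed-rank test on paired scores (zero differences dropped,
#' average ranks for ties, `W` = sum of the ranks of positive differences)
#' plus the two-sample Kolmogorov-Smirnov statistic comparing the two score
#' distributions. P-values are asymptotic, suitable for the ensemble sizes
#' the experiments produce.
#'
#' @param before,after equal-length numeric vectors of paired scores.
#' @param alternative for the Wilcoxon test; default `"greater"` asks
#'   whether `after` exceeds `before`.
#' @return List with `W`, `p_wilcoxon`, `D`, `p_ks`, and `n_pairs` (usable,
#'   nonzero-difference pairs). With all differences zero, `W = 0` and
#'   `p_wilcoxon = 1` by convention.
#' @export
paired_tests <- function(before, after,
                         alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  if (length(before) != length(after))
    stop("paired samples must have equal length")
  keep <- !(is.na(before) | is.na(after))
  before <- before[keep]
  after <- after[keep]
  if (length(before) < 2) stop("fewer than 2 usable pairs")
  d <- after - before
  nz <- d != 0
  if (!any(nz)) {
    w <- 0
    p_w <- 1
  } else {
    r <- rank(abs(d[nz]))
    w <- sum(r[d[nz] > 0])
    p_w <- suppressWarnings(
      stats::wilcox.test(after, before, paired = TRUE,
                         alternative = alternative, exact = FALSE)$p.value)
  }
  ks <- suppressWarnings(stats::ks.test(after, before))
  list(W = w, p_wilcoxon = p_w, D = unname(ks$statistic),
       p_ks = ks$p.value, n_pairs = sum(nz))
}

#' Interaction-frequency map across evolved networks
#'
#' Entry `(i, j)` is the fraction of networks in which gene `j` regulates
#' gene `i` (`g[i, j] != 0`). Comparing within-module versus between-module
#' frequencies visualizes where selection concentrated interactions.
#'
#' @param networks list of genotypes sharing the same `N`.
#' @return `N x N` numeric matrix of fractions in \[0, 1\].
#' @export
interaction_frequency_map <- function(networks) {
  if (length(networks) == 0) stop("at least one network is required")
  mats <- lapply(networks, function(g) as_genotype_matrix(g) != 0)
  Reduce(`+`, mats) / length(mats)
}

#' Within- versus between-set interaction frequencies
#'
#' Summarizes an [interaction_frequency_map()] relative to a two-set
#' partition: the mean frequency of interactions whose source and target
#' genes share a set versus those crossing sets.
#'
#' @param freq frequency matrix from [interaction_frequency_map()].
#' @param partition integer module assignment of the genes.
#' @return List with `within`, `between` and their ratio.
#' @export
within_between_frequency <- function(freq, partition) {
  n <- nrow(freq)
  partition <- check_partition(partition, n)
  same <- outer(partition, partition, `==`)  # freq[i, j]: source j, target i
  w <- mean(freq[same])
  b <- mean(freq[!same])
  list(within = w, between = b, ratio = w / b)
}

measure_focal_qpn <- function(genotype, partition, n_rand) {
  normalized_qp(as_digraph(genotype), partition, n_rand = n_rand)$z
}

#' Two-stage selection experiment: an ancestral and an additional GAP
#'
#' The study's central scenario. Stage 1 evolves each population under
#' selection for a single stationary target GAP (the ancestral phenotype);
#' stage 2 continues the same populations under selection for both the
#' ancestral GAP and a second target differing in `n_differing` gene states,
#' with the organism's cells split evenly between the two. At the end of
#' each stage the partition modularity z-score ([normalized_qp()]) of a
#' focal network is recorded against the gene-set partition
#' `P = {same-state genes, differing-state genes}`.
#'
#' Measurement protocols: `"adapted"` (default) analyses one top-fitness
#' network per population and restricts aggregates and the paired test to
#' populations whose maximum fitness exceeded 0.9 at both stage ends;
#' `"all"` keeps every population; `"population_mean"` averages the z-score
#' over all population members instead of sampling a focal network (adapted
#' populations only).
#'
#' @param n_populations number of independently evolving populations.
#' @param n_genes,pop_size,mu,gamma,kappa,S model parameters (defaults are
#'   the reference values for this model family).
#' @param n_differing gene states differing between the two targets.
#' @param generations length-2 vector of stage durations.
#' @param total_cells cells per organism (split over targets within a stage).
#' @param n_rand randomizations per normalized score.
#' @param protocol measurement protocol (see above).
#' @param mutation_variant,dynamics_variant model variants.
#' @param fixed_targets use the fixed all-active ancestral pattern?
#' @param n_continue if given, only the first `n_continue` populations run
#'   stage 2 (the rest stop after stage 1); useful when the ancestral
#'   baseline needs more replicates than the costly second stage.
#' @param use_cache memoize attractors inside the engine?
#' @return A `grn_experiment_result`: list with `populations` (one row per
#'   population: adapted flags, z-scores, interaction counts, fitness),
#'   `aggregate` (filtered means/SDs and the paired Wilcoxon/KS tests),
#'   `focal_networks` (per stage), `targets`, `partition`, `params`.
#' @export
run_two_stage <- function(n_populations, n_genes = 10, n_differing = 5,
                          generations = c(2000, 8000), pop_size = 200,
                          mu = 0.01, gamma = 0.3, kappa = 0.05, S = 0.4,
                          total_cells = 100, n_rand = 1000,
                          protocol = c("adapted", "all", "population_mean"),
                          mutation_variant = "biased",
                          dynamics_variant = "half_rowsum",
                          fixed_targets = TRUE, n_continue = NULL,
                          use_cache = TRUE) {
  protocol <- match.arg(protocol)
  if (is.null(n_continue)) n_continue <- n_populations
  pair <- make_target_pair(n_genes, n_differing, fixed = fixed_targets)
  spec1 <- target_spec(rbind(pair$target1), total_cells = total_cells,
                       labels = "I")
  spec2 <- target_spec(rbind(pair$target1, pair$target2),
                       total_cells = total_cells, labels = c("I", "II"))
  rows <- vector("list", n_populations)
  focal1 <- vector("list", n_populations)
  focal2 <- vector("list", n_populations)
  for (i in seq_len(n_populations)) {
    stages <- list(list(targets = spec1, generations = generations[1]))
    two_stage <- i <= n_continue
    if (two_stage)
      stages <- c(stages, list(list(targets = spec2,
                                    generations = generations[2])))
    cfg <- evolution_config(stages, pop_size = pop_size, mu = mu,
                            gamma = gamma, kappa = kappa, S = S,
                            mutation_variant = mutation_variant,
                            dynamics_variant = dynamics_variant)
    tr <- run_population(cfg, use_cache = use_cache)
    meas <- lapply(tr$stage_end, function(se) {
      z <- if (protocol == "population_mean") {
        mean(vapply(se$genotypes, measure_focal_qpn, numeric(1),
                    partition = pair$partition, n_rand = n_rand))
      } else {
        measure_focal_qpn(se$focal_genotype, pair$partition, n_rand)
      }
      list(z = z, adapted = se$adapted, max_fitness = max(se$fitness),
           n_interactions = n_interactions(se$focal_genotype),
           focal = se$focal_genotype)
    })
    focal1[[i]] <- meas[[1]]$focal
    focal2[[i]] <- if (two_stage) meas[[2]]$focal else NULL
    rows[[i]] <- data.frame(
      population = i,
      adapted_stage1 = meas[[1]]$adapted,
      adapted_stage2 = if (two_stage) meas[[2]]$adapted else NA,
      qpn_stage1 = meas[[1]]$z,
      qpn_stage2 = if (two_stage) meas[[2]]$z else NA_real_,
      max_fitness_stage1 = meas[[1]]$max_fitness,
      max_fitness_stage2 = if (two_stage) meas[[2]]$max_fitness else NA_real_,
      n_interactions_stage1 = meas[[1]]$n_interactions,
      n_interactions_stage2 = if (two_stage) meas[[2]]$n_interactions
                              else NA_integer_)
  }
  populations <- do.call(rbind, rows)
  if (is.null(populations))
    populations <- data.frame(population = integer(0))
  structure(list(populations = populations,
                 aggregate = aggregate_two_stage(populations, protocol),
                 focal_networks = list(stage1 = focal1, stage2 = focal2),
                 targets = pair, partition = pair$partition,
                 params = list(n_genes = n_genes, n_differing = n_differing,
                               generations = generations, pop_size = pop_size,
                               mu = mu, gamma = gamma, kappa = kappa, S = S,
                               n_rand = n_rand, protocol = protocol)),
            class = "grn_experiment_result")
}

aggregate_two_stage <- function(populations, protocol) {
  if (nrow(populations) == 0) return(list(n_populations = 0L))
  has2 <- !is.na(populations$qpn_stage2)
  use <- if (protocol == "all") has2
         else has2 & populations$adapted_stage1 & populations$adapted_stage2
  use1 <- if (protocol == "all") rep(TRUE, nrow(populations))
          else populations$adapted_stage1
  out <- list(n_populations = nrow(populations),
              n_adapted = sum(populations$adapted_stage1 &
                                (populations$adapted_stage2 %in% TRUE)),
              mean_qpn_stage1 = mean(populations$qpn_stage1[use1]),
              sd_qpn_stage1 = stats::sd(populations$qpn_stage1[use1]),
              mean_qpn_stage2 = mean(populations$qpn_stage2[use]),
              sd_qpn_stage2 = stats::sd(populations$qpn_stage2[use]),
              mean_interactions_stage2 =
                mean(populations$n_interactions_stage2[use]),
              sd_interactions_stage2 =
                stats::sd(populations$n_interactions_stage2[use]))
  if (sum(use) >= 2) {
    out$paired <- paired_tests(populations$qpn_stage1[use],
                               populations$qpn_stage2[use])
  }
  out
}

#' @export
print.grn_experiment_result <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<grn_experiment_result> %d population(s)\n",
              a$n_populations %||% nrow(x$populations)))
  if (!is.null(a$mean_qpn_stage1))
    cat(sprintf("  stage 1 mean z = %.3f (SD %.3f); stage 2 mean z = %.3f (SD %.3f)\n",
                a$mean_qpn_stage1, a$sd_qpn_stage1,
                a$mean_qpn_stage2, a$sd_qpn_stage2))
  if (!is.null(a$paired))
    cat(sprintf("  paired Wilcoxon W = %.1f, p = %.3g\n",
                a$paired$W, a$paired$p_wilcoxon))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep the interaction-gain propensity
#'
#' Runs the two-stage scenario of [run_two_stage()] at each value of
#' `gamma`, tracking how sparseness modulates both adaptation success and
#' the modularity gained from selection for an additional GAP.
#'
#' @param gammas gain-propensity values to sweep.
#' @param n_populations populations per value.
#' @param ... passed to [run_two_stage()].
#' @return List with `runs` (one `grn_experiment_result` per value) and
#'   `summary` (data.frame: gamma, adapted count, stage means, interaction
#'   counts).
#' @export
run_gamma_sweep <- function(gammas, n_populations, ...) {
  runs <- lapply(gammas, function(g)
    run_two_stage(n_populations, gamma = g, ...))
  summary <- do.call(rbind, Map(function(g, r) {
    a <- r$aggregate
    data.frame(gamma = g, n_populations = a$n_populations,
               n_adapted = a$n_adapted %||% NA,
               mean_qpn_stage1 = a$mean_qpn_stage1 %||% NA,
               mean_qpn_stage2 = a$mean_qpn_stage2 %||% NA,
               mean_interactions_stage2 = a$mean_interactions_stage2 %||% NA)
  }, gammas, runs))
  list(runs = runs, summary = summary)
}

#' Sweep the initial-state perturbation rate
#'
#' As [run_gamma_sweep()] but varying `kappa` in both stages; interaction
#' counts are reported too (perturbation rate is expected to leave network
#' density untouched).
#'
#' @param kappas perturbation rates to sweep.
#' @inheritParams run_gamma_sweep
#' @export
run_kappa_sweep <- function(kappas, n_populations, ...) {
  runs <- lapply(kappas, function(k)
    run_two_stage(n_populations, kappa = k, ...))
  summary <- do.call(rbind, Map(function(k, r) {
    a <- r$aggregate
    data.frame(kappa = k, n_populations = a$n_populations,
               n_adapted = a$n_adapted %||% NA,
               mean_qpn_stage1 = a$mean_qpn_stage1 %||% NA,
               mean_qpn_stage2 = a$mean_qpn_stage2 %||% NA,
               mean_interactions_stage2 = a$mean_interactions_stage2 %||% NA)
  }, kappas, runs))
  list(runs = runs, summary = summary)
}

#' Epoch-switch experiment: change one parameter mid-evolution
#'
#' Evolves populations under a single, constant selection regime (either
#' two-GAP selection for an ancestral and an additional target, or single-GAP
#' selection for the ancestral target alone) while one parameter --- the
#' gain propensity `gamma` or the perturbation rate `kappa` --- switches
#' from `values[1]` to `values[2]` at the epoch boundary. Per-population
#' modularity is scored at both epoch ends: the partition z-score
#' ([normalized_qp()]) under two-GAP selection, and the optimized z-score
#' ([normalized_qopt()]) under single-GAP selection, where no partition
#' hypothesis exists.
#'
#' @param parameter `"gamma"` or `"kappa"`.
#' @param values length-2 vector: epoch-1 and epoch-2 value.
#' @param selection `"two_gap"` or `"single_gap"`.
#' @param generations_per_epoch generations in each epoch.
#' @param n_populations number of populations.
#' @inheritParams run_two_stage
#' @return A `grn_experiment_result` (stage 1/2 columns refer to the two
#'   epoch ends; the z column holds the selection-appropriate score).
#' @export
run_epoch_switch <- function(parameter = c("gamma", "kappa"), values,
                             selection = c("two_gap", "single_gap"),
                             generations_per_epoch, n_populations,
                             n_genes = 10, n_differing = 5, pop_size = 200,
                             mu = 0.01, gamma = 0.3, kappa = 0.05, S = 0.4,
                             total_cells = 100, n_rand = 1000,
                             fixed_targets = TRUE, use_cache = TRUE) {
  parameter <- match.arg(parameter)
  selection <- match.arg(selection)
  stopifnot(length(values) == 2)
  pair <- make_target_pair(n_genes, n_differing, fixed = fixed_targets)
  spec <- if (selection == "two_gap") {
    target_spec(rbind(pair$target1, pair$target2), total_cells = total_cells,
                labels = c("I", "II"))
  } else {
    target_spec(rbind(pair$target1), total_cells = total_cells, labels = "I")
  }
  mk_stage <- function(v) {
    st <- list(targets = spec, generations = generations_per_epoch)
    st[[parameter]] <- v
    st
  }
  rows <- vector("list", n_populations)
  focal1 <- vector("list", n_populations)
  focal2 <- vector("list", n_populations)
  for (i in seq_len(n_populations)) {
    cfg <- evolution_config(list(mk_stage(values[1]), mk_stage(values[2])),
                            pop_size = pop_size, mu = mu, gamma = gamma,
                            kappa = kappa, S = S)
    tr <- run_population(cfg, use_cache = use_cache)
    meas <- lapply(tr$stage_end, function(se) {
      graph <- as_digraph(se$focal_genotype)
      z <- if (selection == "two_gap") {
        normalized_qp(graph, pair$partition, n_rand = n_rand)$z
      } else {
        normalized_qopt(graph, n_rand = n_rand)$z
      }
      list(z = z, adapted = se$adapted, max_fitness = max(se$fitness),
           n_interactions = n_interactions(se$focal_genotype),
           focal = se$focal_genotype)
    })
    focal1[[i]] <- meas[[1]]$focal
    focal2[[i]] <- meas[[2]]$focal
    rows[[i]] <- data.frame(
      population = i,
      adapted_stage1 = meas[[1]]$adapted,
      adapted_stage2 = meas[[2]]$adapted,
      qpn_stage1 = meas[[1]]$z, qpn_stage2 = meas[[2]]$z,
      max_fitness_stage1 = meas[[1]]$max_fitness,
      max_fitness_stage2 = meas[[2]]$max_fitness,
      n_interactions_stage1 = meas[[1]]$n_interactions,
      n_interactions_stage2 = meas[[2]]$n_interactions)
  }
  populations <- do.call(rbind, rows)
  if (is.null(populations)) populations <- data.frame(population = integer(0))
  structure(list(populations = populations,
                 aggregate = aggregate_two_stage(populations, "adapted"),
                 focal_networks = list(stage1 = focal1, stage2 = focal2),
                 targets = pair, partition = pair$partition,
                 params = list(parameter = parameter, values = values,
                               selection = selection,
                               generations_per_epoch = generations_per_epoch,
                               n_genes = n_genes, pop_size = pop_size,
                               mu = mu, gamma = gamma, kappa = kappa, S = S,
                               n_rand = n_rand)),
            class = "grn_experiment_result")
}

#' Analyze an empirical network from an edge list
#'
#' Reads a TSV edge list (see [read_edge_list()]), computes the optimized
#' modularity of the network and its z-score against `n_rand`
#' degree-preserving randomizations, and returns the row of summary columns
#' used for tables of empirical networks: raw `Q`, null mean, null SD and
#' the normalized score `Q^N`.
#'
#' @param path edge-list file path (or a [grn_digraph()] directly).
#' @param n_rand randomizations for the null ensemble.
#' @return One-row data.frame: `n_nodes`, `n_edges`, `q`, `null_mean`,
#'   `null_sd`, `q_n`.
#' @export
analyze_empirical_network <- function(path, n_rand = 1000) {
  graph <- if (inherits(path, "grn_digraph")) path else read_edge_list(path)
  if (n_edges(graph) < 2)
    stop("network has fewer than 2 edges; the null ensemble is degenerate")
  res <- normalized_qopt(graph, n_rand = n_rand)
  data.frame(n_nodes = graph$n_nodes, n_edges = n_edges(graph),
             q = res$raw, null_mean = res$null_mean, null_sd = res$null_sd,
             q_n = res$z)
}
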