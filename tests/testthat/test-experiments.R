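test_that("Wilcoxon W follows the signed-rank definition", {
  # diffs (+1, +2, +3, -1): |d| ranks (1.5, 3, 4, 1.5), W = 1.5 + 3 + 4
  before <- c(0, 0, 0, 0)
  after <- c(1, 2, 3, -1)
  res <- paired_tests(before, after)
  expect_equal(res$W, 8.5)
  expect_equal(res$n_pairs, 4)
  # agrees with the base-R V statistic on tie-free data
  set.seed(901)
  b <- rnorm(25)
  a <- b + rnorm(25)
  res2 <- paired_tests(b, a)
  v <- suppressWarnings(wilcox.test(a, b, paired = TRUE)$statistic)
  expect_equal(res2$W, unname(v))
  # exact enumeration oracle: under H0 every sign pattern of the |d| ranks
  # is equally likely; the one-sided p of the observed W matches
  d <- a[1:8] - b[1:8]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  w_null <- signs %*% r
  p_exact <- mean(w_null >= w_obs)
  res3 <- paired_tests(b[1:8], a[1:8])
  expect_lt(abs(res3$p_wilcoxon - p_exact), 0.05)
})

test_that("degenerate paired inputs follow the stated conventions", {
  x <- c(1, 2, 3)
  res <- paired_tests(x, x)
  expect_equal(res$W, 0)
  expect_equal(res$p_wilcoxon, 1)
  expect_equal(res$D, 0)
  expect_error(paired_tests(1, 1), "2 usable")
  # disjoint supports give KS D = 1
  res2 <- paired_tests(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res2$D, 1)
})

test_that("interaction frequency maps average network structure", {
  g1 <- grn_genotype(rbind(c(1, 0), c(0, 1)))
  g2 <- grn_genotype(rbind(c(-1, 0), c(1, 0)))
  f <- interaction_frequency_map(list(g1, g2))
  expect_equal(f, rbind(c(1, 0), c(0.5, 0.5)))
  fid <- interaction_frequency_map(list(g1, g1, g1))
  expect_true(all(fid %in% c(0, 1)))
  expect_error(interaction_frequency_map(list()), "at least one")
  wb <- within_between_frequency(f, c(1, 2))
  expect_equal(wb$within, mean(c(1, 0.5)))
  expect_equal(wb$between, mean(c(0, 0.5)))
})

test_that("two-stage runner emits coherent per-population records", {
  # tiny smoke profile: structure and internal consistency, not effect sizes
  set.seed(902)
  res <- run_two_stage(2, n_genes = 8, n_differing = 4,
                       generations = c(40, 60), pop_size = 25,
                       total_cells = 20, n_rand = 60)
  expect_s3_class(res, "grn_experiment_result")
  expect_equal(nrow(res$populations), 2)
  expect_true(all(c("qpn_stage1", "qpn_stage2", "adapted_stage1",
                    "n_interactions_stage2") %in% names(res$populations)))
  expect_length(res$focal_networks$stage2, 2)
  expect_equal(res$partition, rep(1:2, each = 4))
  # aggregates are recomputable from the per-population rows
  p <- res$populations
  use <- !is.na(p$qpn_stage2) & p$adapted_stage1 & p$adapted_stage2
  if (any(use)) {
    expect_equal(res$aggregate$mean_qpn_stage2, mean(p$qpn_stage2[use]))
    expect_equal(res$aggregate$mean_interactions_stage2,
                 mean(p$n_interactions_stage2[use]))
  }
  expect_equal(res$aggregate$mean_qpn_stage1,
               mean(p$qpn_stage1[p$adapted_stage1]))
})

test_that("an empty experiment yields an empty result, not an error", {
  res <- run_two_stage(0)
  expect_equal(nrow(res$populations), 0)
  expect_equal(res$aggregate$n_populations, 0)
})

test_that("stage-1-only populations are marked, not dropped", {
  set.seed(903)
  res <- run_two_stage(3, n_genes = 8, n_differing = 4,
                       generations = c(30, 30), pop_size = 20,
                       total_cells = 10, n_rand = 50, n_continue = 1)
  expect_equal(sum(!is.na(res$populations$qpn_stage2)), 1)
  expect_equal(sum(!is.na(res$populations$qpn_stage1)), 3)
})

test_that("sweeps tabulate one row per parameter value", {
  set.seed(908)
  sw <- run_kappa_sweep(c(0, 0.05), n_populations = 1, n_genes = 8,
                        n_differing = 4, generations = c(15, 15),
                        pop_size = 15, total_cells = 10, n_rand = 40)
  expect_equal(sw$summary$kappa, c(0, 0.05))
  expect_equal(nrow(sw$summary), 2)
  expect_length(sw$runs, 2)
  expect_true(all(c("n_adapted", "mean_qpn_stage2") %in% names(sw$summary)))
})

test_that("alternative measurement protocols are honoured", {
  set.seed(909)
  res_all <- run_two_stage(2, n_genes = 8, n_differing = 4,
                           generations = c(10, 10), pop_size = 10,
                           total_cells = 10, n_rand = 40, protocol = "all")
  # under "all", aggregates ignore adaptation flags
  p <- res_all$populations
  expect_equal(res_all$aggregate$mean_qpn_stage1, mean(p$qpn_stage1))
  expect_equal(res_all$aggregate$mean_qpn_stage2, mean(p$qpn_stage2))
  set.seed(910)
  res_pm <- run_two_stage(1, n_genes = 8, n_differing = 4,
                          generations = c(10, 10), pop_size = 8,
                          total_cells = 10, n_rand = 40,
                          protocol = "population_mean")
  expect_equal(nrow(res_pm$populations), 1)
  expect_true(is.finite(res_pm$populations$qpn_stage1))
})

test_that("epoch-switch runner wires parameter changes into the stages", {
  set.seed(904)
  res <- run_epoch_switch("gamma", c(0.4, 0.2), selection = "two_gap",
                          generations_per_epoch = 30, n_populations = 2,
                          n_genes = 8, n_differing = 4, pop_size = 20,
                          total_cells = 10, n_rand = 50)
  expect_equal(nrow(res$populations), 2)
  expect_true(all(is.finite(res$populations$qpn_stage1)))
  res1 <- run_epoch_switch("kappa", c(0.01, 0.05), selection = "single_gap",
                           generations_per_epoch = 25, n_populations = 1,
                           n_genes = 8, pop_size = 15, total_cells = 10,
                           n_rand = 40)
  expect_equal(nrow(res1$populations), 1)
  expect_true(is.finite(res1$populations$qpn_stage2))
})

test_that("empirical-network analysis returns a full table row", {
  set.seed(905)
  within <- rbind(as.matrix(expand.grid(1:5, 1:5)),
                  as.matrix(expand.grid(6:10, 6:10)))
  within <- within[within[, 1] != within[, 2], ]
  keep <- within[sample(nrow(within), 24), ]
  planted <- grn_digraph(10, rbind(keep, c(1, 6), c(7, 2)))
  path <- tempfile(fileext = ".tsv")
  write_edge_list(planted, path)
  row <- analyze_empirical_network(path, n_rand = 150)
  expect_equal(names(row),
               c("n_nodes", "n_edges", "q", "null_mean", "null_sd", "q_n"))
  expect_equal(row$n_nodes, 10)
  expect_equal(row$n_edges, 26)
  expect_gt(row$q_n, 0)  # planted modules stand out from their nulls
  # degenerate networks are refused
  single <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "a\tb"), single)
  expect_error(analyze_empirical_network(single), "fewer than 2")
})

test_that("the bundled synthetic network yields a complete table row", {
  fixture <- system.file("extdata", "synthetic-planted-network.tsv",
                         package = "grnmod")
  set.seed(907)
  row <- analyze_empirical_network(fixture, n_rand = 200)
  expect_equal(row$n_nodes, 15)
  expect_equal(row$n_edges, 43)
  expect_true(all(is.finite(unlist(row))))
  # three planted 5-gene modules stand far above the null
  expect_gt(row$q_n, 3)
  expect_equal(row$q_n, (row$q - row$null_mean) / row$null_sd)
})
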