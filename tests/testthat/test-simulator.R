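scaled_params <- function(seed, ...) {
  # the published screen's regime scaled tenfold down: ~2,990 lethals over
  # 144 essential genes preserves the ~21 expected hits per gene
  simulation_params(arms_screened = 4600, lethal_rate_per_arm = 0.65,
                    n_essential_genes = 144, n_pathway_genes = 30,
                    seed = seed, ...)
}

test_that("simulation parameters are validated", {
  expect_error(simulation_params(seed = 1, n_pathway_genes = 2000),
               class = "mosaicsat_validation_error")
  expect_error(simulation_params(seed = 1, p_recover = 1.2),
               class = "mosaicsat_validation_error")
  expect_error(simulation_params(), class = "mosaicsat_validation_error")
  expect_error(simulation_params(seed = 1, gene_weights = c(1, 2)),
               class = "mosaicsat_validation_error")
})

test_that("zero recovery probability yields an empty screen", {
  sim <- simulate_screen(scaled_params(seed = 5, p_recover = 0))
  expect_equal(sim$spectrum$n_loci, 0)
  expect_equal(sim$spectrum$n_mutations, 0)
  expect_false(any(sim$mutations$fate %in% c("retained", "recovered_weak")))
  expect_equal(length(sim$matrix$mutation_ids), 0L)
})

test_that("fates are consistent: retained implies recovered implies detected", {
  sim <- simulate_screen(scaled_params(seed = 9, p_f1_detect = 0.8))
  f <- sim$mutations$fate
  expect_true(all(f %in% c("not_detected", "lost_f1", "recovered_weak", "retained")))
  # non-pathway mutations can never be detected
  expect_true(all(f[!sim$mutations$is_pathway_gene] == "not_detected"))
  # the spectrum recounts exactly the retained mutations
  expect_equal(sim$spectrum$n_mutations, sum(f == "retained"))
  expect_equal(sort(unlist(sim$truth$true_partition, use.names = FALSE)),
               sort(sim$mutations$mutation_id[f == "retained"]))
})

test_that("retained counts follow the thinned-Poisson law", {
  # thinning a Poisson(arms x rate) by gene-assignment, detection, recovery
  # and penetrance leaves Poisson(mu) with mu the product of all factors
  p <- simulation_params(arms_screened = 4600, lethal_rate_per_arm = 0.65,
                         n_essential_genes = 1440, n_pathway_genes = 30,
                         p_recover = 0.077, p_penetrant = 0.62, seed = 101)
  mu <- 4600 * 0.65 * (30 / 1440) * 1 * 0.077 * 0.62
  sim <- simulate_screen(p)
  expect_lt(abs(sim$spectrum$n_mutations - mu), 3 * sqrt(mu) + 1e-9)

  # mean and variance over replicates agree with the law within MC error
  ns <- vapply(1:150, function(i) {
    p$seed <- 1000L + i
    simulate_screen(p)$spectrum$n_mutations
  }, numeric(1))
  expect_lt(abs(mean(ns) - mu), 4 * sqrt(mu / 150))
  expect_lt(abs(var(ns) - mu), 0.5 * mu)
})

test_that("gene weights bias the hit distribution", {
  w <- c(rep(10, 5), rep(1, 139))  # five large-target genes
  p <- simulation_params(arms_screened = 4600, lethal_rate_per_arm = 0.65,
                         n_essential_genes = 144, n_pathway_genes = 30,
                         gene_weights = w, p_recover = 1, p_penetrant = 1,
                         seed = 40)
  sim <- simulate_screen(p)
  hits <- sim$truth$pathway_gene_hits
  expect_gt(mean(hits[1:5]), 3 * mean(hits[6:30]))
})

test_that("noiseless complementation recovers the true partition exactly", {
  for (s in 1:5) {
    sim <- simulate_screen(scaled_params(seed = 300 + s))
    part <- build_groups(sim$matrix)
    expect_equal(canonical_groups(part$groups),
                 canonical_groups(sim$truth$true_partition))
  }
})

test_that("grouping accuracy degrades monotonically with test error", {
  acc <- vapply(c(0, 0.01, 0.05), function(pe) {
    mean(vapply(1:30, function(s) {
      sim <- simulate_screen(scaled_params(seed = 7000 + s, p_test_error = pe))
      partition_agreement(build_groups(sim$matrix)$groups,
                          sim$truth$true_partition)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_gte(acc[1], acc[2])
  expect_gt(acc[2], acc[3] - 0.005)
  expect_lt(acc[3], 1)
})

test_that("hypomorphic alleles break same-gene noncomplementation", {
  sim <- simulate_screen(scaled_params(seed = 77, p_hypomorph = 0.5))
  ret <- sim$mutations[sim$mutations$fate == "retained", ]
  hypo <- ret$mutation_id[ret$is_hypomorph]
  gene_of <- stats::setNames(ret$true_gene, ret$mutation_id)
  if (length(hypo) && nrow(ret) >= 2) {
    pr <- sim$matrix$pairs
    same_gene <- gene_of[pr$mutation_a] == gene_of[pr$mutation_b]
    with_hypo <- pr$mutation_a %in% hypo | pr$mutation_b %in% hypo
    expect_true(all(pr$result[same_gene & with_hypo] == "complements"))
    expect_true(all(pr$result[same_gene & !with_hypo] == "fails"))
  }
})

test_that("the whole simulation pipeline is seed-deterministic", {
  p <- scaled_params(seed = 11)
  s1 <- simulate_screen(p)
  s2 <- simulate_screen(p)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$spectrum, s2$spectrum)
  expect_identical(s1$matrix, s2$matrix)
  s3 <- simulate_screen(scaled_params(seed = 12))
  expect_false(identical(s1$mutations, s3$mutations))
})

test_that("validate_estimators summarizes parameter recovery reproducibly", {
  p <- scaled_params(seed = 1)
  v1 <- validate_estimators(p, n_reps = 50, seed = 123)
  v2 <- validate_estimators(p, n_reps = 50, seed = 123)
  expect_identical(v1$summary, v2$summary)
  expect_equal(nrow(v1$replicates), 50)
  expect_equal(v1$summary$true_loci, 30)
  expect_true(is.finite(v1$summary$ztp_mle$mean))
  # the plug-in estimator sits below the ZTP-corrected one (downward bias)
  expect_lt(v1$summary$plug_in$mean, v1$summary$ztp_mle$mean)
  expect_error(validate_estimators(p, n_reps = 10, seed = 1),
               class = "mosaicsat_validation_error")
})

test_that("degenerate replicates are counted and excluded with a warning", {
  # tiny screen: most replicates retain almost nothing
  p <- simulation_params(arms_screened = 100, lethal_rate_per_arm = 0.65,
                         n_essential_genes = 144, n_pathway_genes = 30,
                         seed = 1)
  expect_warning(v <- validate_estimators(p, n_reps = 50, seed = 55),
                 "degenerate")
  expect_gt(v$summary$n_degenerate, 0)
  expect_equal(v$summary$ztp_mle$n + v$summary$n_degenerate, 50)
})

test_that("bootstrap coverage is measured when requested", {
  v <- validate_estimators(scaled_params(seed = 1), n_reps = 50, seed = 9,
                           n_boot = 100)
  expect_true(v$summary$coverage >= 0 && v$summary$coverage <= 1)
})
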