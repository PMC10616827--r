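test_that("the exact test reproduces published carrier-table p-values", {
  expect_equal(signif(fisher_two_sided(contingency_table(2, 51, 3, 8980)), 3),
               3.34e-4)
  expect_equal(signif(fisher_two_sided(contingency_table(2, 51, 1, 8982)), 3),
               1.01e-4)
  expect_equal(signif(fisher_two_sided(contingency_table(3, 50, 14, 8969)), 3),
               1.22e-4)
  expect_equal(fisher_two_sided(contingency_table(0, 53, 0, 8983)), 1)
})

test_that("the exact test agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:250) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    cc <- sample(0:30, 1); d <- sample(0:30, 1)
    p1 <- fisher_two_sided(contingency_table(a, b, cc, d))
    p2 <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
    expect_equal(p1, p2, tolerance = 1e-9,
                 label = sprintf("table %d,%d,%d,%d", a, b, cc, d))
  }
})

test_that("p is invariant under simultaneous row and column swaps", {
  set.seed(8)
  for (i in 1:50) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    expect_equal(fisher_two_sided(tab), fisher_two_sided(tab[2:1, 2:1]))
  }
})

test_that("odds ratios are the unadjusted cross-products", {
  expect_equal(round_half_up(odds_ratio(contingency_table(2, 51, 3, 8980)), 2),
               117.39)
  expect_equal(round_half_up(odds_ratio(contingency_table(2, 51, 1, 8982)), 2),
               352.24)
  expect_equal(odds_ratio(contingency_table(1, 1, 1, 1)), 1)
  expect_true(is.infinite(odds_ratio(contingency_table(2, 51, 0, 8983))))
  expect_true(is.nan(odds_ratio(contingency_table(0, 53, 0, 8983))))
  # Haldane correction only as an explicit option
  expect_equal(odds_ratio(contingency_table(2, 2, 0, 4), haldane = TRUE),
               (2.5 * 4.5) / (2.5 * 0.5))
})

test_that("Bonferroni thresholds match the genome-wide scan conventions", {
  # published figures truncate to three significant digits
  trunc3 <- function(x) { m <- 10^(floor(log10(x)) - 2); floor(x / m) * m }
  expect_equal(trunc3(bonferroni_threshold(0.05, 18666)), 2.67e-6)
  expect_equal(trunc3(bonferroni_threshold(0.05, 18666, 9)), 2.97e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  # decreasing in both counts
  expect_lt(bonferroni_threshold(0.05, 200), bonferroni_threshold(0.05, 100))
  expect_lt(bonferroni_threshold(0.05, 100, 9), bonferroni_threshold(0.05, 100, 2))
})

test_that("carrier tables are recovered uniquely from printed odds ratios", {
  tabs <- recover_counts_from_or(117.39, 53, 8983, 30)
  expect_length(tabs, 1)
  expect_equal(tabs[[1]]["case", "carrier"], 2)
  expect_equal(tabs[[1]]["control", "carrier"], 3)
  tabs2 <- recover_counts_from_or(70.42, 53, 8983, 30)
  expect_length(tabs2, 1)
  expect_equal(tabs2[[1]]["case", "carrier"], 2)
  expect_equal(tabs2[[1]]["control", "carrier"], 5)
  # OR = 1 on balanced groups is deliberately non-unique
  tabs3 <- recover_counts_from_or(1.0, 10, 10, 10)
  expect_gt(length(tabs3), 1)
  expect_true(all(vapply(tabs3, function(t) t[1, 1] == t[2, 1], TRUE)))
  expect_error(recover_counts_from_or(1e6, 10, 10, 2), "no carrier table")
})

test_that("collapse_gene tabulates analyzed samples against phenotype", {
  man <- data.frame(sample_id = c(sprintf("ca%02d", 1:53),
                                  sprintf("co%04d", 1:8983)),
                    phenotype = c(rep("case", 53), rep("control", 8983)),
                    stringsAsFactors = FALSE)
  states <- setNames(integer(nrow(man)), man$sample_id)
  states[c("ca01", "ca07", "co0002", "co0100", "co5000")] <- 1L
  tab <- collapse_gene(states, man)
  expect_equal(unclass(tab)[1:4], c(2, 3, 51, 8980))  # column-major
  states0 <- setNames(integer(nrow(man)), man$sample_id)
  expect_equal(collapse_gene(states0, man)["case", "carrier"], 0)
  expect_error(collapse_gene(c(states, ghost = 1L), man), "absent")
})

test_that("the scan reports every gene with a stable schema", {
  co <- generate_cohort(small_config(seed = 77))
  sc <- collapsing_scan(co, models = c("ultra_rare", "ptv"))
  expect_s3_class(sc, "collapsing_scan")
  expect_equal(nrow(sc), 2 * length(unique(co$variants$gene)))
  expect_true(all(sc$p_value >= 0 & sc$p_value <= 1))
  # zero-carrier genes are retained with p = 1 and undefined OR
  zero <- sc$case_carriers == 0 & sc$control_carriers == 0
  if (any(zero)) {
    expect_true(all(sc$p_value[zero] == 1))
    expect_true(all(is.nan(sc$odds_ratio[zero])))
  }
  expect_output(print(sc), "collapsing scan")
  expect_s3_class(summary(sc), "summary.collapsing_scan")
})

test_that("permutation expectation is deterministic and well-formed", {
  co <- generate_cohort(sim_config(n_case_families = 15, n_control = 150,
                                   n_genes = 40, seed = 81))
  sc <- collapsing_scan(co, models = "flexible_no_score")
  q1 <- permutation_expected(sc, n_permutations = 100, seed = 11)
  q2 <- permutation_expected(sc, n_permutations = 100, seed = 11)
  expect_identical(q1$observed_p, q2$observed_p)
  expect_identical(q1$expected_p, q2$expected_p)
  expect_identical(q1$lambda, q2$lambda)
  expect_false(is.unsorted(q1$expected_p))
  expect_false(is.unsorted(q1$observed_p))
  expect_true(all(q1$expected_p >= 0 & q1$expected_p <= 1))
  expect_gt(q1$lambda, 0)
  expect_error(permutation_expected(sc, n_permutations = 0, seed = 1), ">= 1")
})

test_that("lambda is the ratio of median chi-squared quantiles", {
  obs <- sort(runif(101, 0.01, 0.99))
  expect_equal(rarecollapse:::qq_lambda(obs, obs), 1)
  # more significant observed median inflates lambda
  expect_gt(rarecollapse:::qq_lambda(obs^2, obs), 1)
})

test_that("removing spiked genes returns lambda toward 1", {
  cfg <- sim_config(n_case_families = 50, n_control = 1000, n_genes = 120,
                    sites_per_gene = 5, seed = 91)
  co <- generate_cohort(cfg)
  spiked <- sprintf("G%04d", 1:20)
  for (g in spiked) {
    co <- spike_risk_gene(co, spike_spec(g, 4, 0), seed = 91 + match(g, spiked))
  }
  sc <- collapsing_scan(co, models = "ultra_rare")
  qq_all <- permutation_expected(sc, n_permutations = 300, seed = 13)
  # rebuild the scan without the spiked genes and compare inflation
  keep <- !co$variants$gene %in% spiked
  co2 <- rarecollapse:::new_rv_cohort(
    co$variants[keep, ], co$geno[, keep, drop = FALSE],
    co$manifest, co$coverage[keep, ], co$config)
  sc2 <- collapsing_scan(co2, models = "ultra_rare")
  qq_rest <- permutation_expected(sc2, n_permutations = 300, seed = 13)
  expect_gte(qq_all$lambda, qq_rest$lambda)
  expect_true(qq_rest$lambda >= 0.8 && qq_rest$lambda <= 1.2)
})

test_that("gene-set restriction mirrors the full scan", {
  co <- generate_cohort(small_config(seed = 101))
  sc <- collapsing_scan(co, models = c("ultra_rare", "flexible_no_score"))
  # genes absent from the cohort
  gs0 <- geneset_test(sc, c("NOT_A_GENE", "ALSO_NOT"))
  expect_equal(nrow(gs0$results), 0)
  expect_equal(gs0$n_significant, 0)
  # a single-gene list equals that gene's rows from the full scan
  g1 <- unique(co$variants$gene)[1]
  gs1 <- geneset_test(sc, g1)
  expect_equal(gs1$results[order(gs1$results$model), "p_value"],
               sc[sc$gene == g1, ][order(sc$model[sc$gene == g1]), "p_value"])
  expect_error(geneset_test(sc, character()), "non-empty")
})

test_that("strongly spiked members of a gene set are recovered", {
  cfg <- sim_config(n_case_families = 53, n_control = 2000, n_genes = 60,
                    seed = 107)
  co <- generate_cohort(cfg)
  members <- sprintf("G%04d", c(5, 15, 25, 35))
  for (i in seq_along(members)) {
    co <- spike_risk_gene(co, spike_spec(members[i], 3, 1), seed = 200 + i)
  }
  sc <- collapsing_scan(co, models = "ultra_rare")
  gene_list <- sprintf("G%04d", seq(1, 48))   # 48-gene candidate list
  gs <- geneset_test(sc, gene_list)
  expect_gte(gs$n_significant, 4)
})
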