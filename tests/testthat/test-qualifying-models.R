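test_that("the built-in model set encodes the nine-model grid", {
  m <- builtin_models()
  expect_length(m, 9)
  expect_equal(m$ultra_rare$loo_af_max, 0.0005)
  expect_equal(m$ultra_rare$external_af_max, 0)
  expect_true(m$ultra_rare$polyphen_required)
  expect_equal(m$recessive$inheritance, "compound_het")
  expect_equal(m$recessive$loo_af_max, 0.01)
  expect_equal(m$synonymous$function_class, "synonymous")
  expect_equal(m$ptv$function_class, "ptv")
  expect_equal(m$rare_damaging_revel$revel_min, 0.5)
  expect_equal(m$rare_damaging_revel$external_af_max, 0.00005)
  expect_equal(m$flexible_no_score$loo_af_max, 0.001)
  expect_true(all(vapply(m[-9], function(x) x$inheritance, "") == "dominant"))
})

test_that("leave-one-out frequency removes the evaluated sample's alleles", {
  expect_equal(leave_one_out_af(1, 18072, 1), 0)
  expect_equal(leave_one_out_af(10, 18072, 1), 9 / 18070)
  expect_lte(leave_one_out_af(10, 18072, 1), 0.0005)   # carrier passes
  expect_gt(leave_one_out_af(10, 18072, 0), 0.0005)    # non-carrier fails
  # a non-carrier's LOO AF is never below a carrier's at the same site
  expect_gte(leave_one_out_af(5, 1000, 0), leave_one_out_af(5, 1000, 1))
  expect_error(leave_one_out_af(1, 2, 1), "exceed")
  expect_error(leave_one_out_af(0, 100, 1), "dose")
})

test_that("the qualifying filter applies class, score and frequency gates", {
  m <- builtin_models()
  ptv <- vrow("v1", "G1", effect = "ptv")
  expect_true(variant_qualifies(ptv, 0, m$ultra_rare))
  # missense without a probably-damaging call fails the PolyPhen-gated model
  mis <- vrow("v2", "G1", effect = "missense", polyphen = "other", revel = 0.9)
  expect_false(variant_qualifies(mis, 0, m$ultra_rare))
  # PolyPhen gate applies to missense only: inframe indels pass ungated
  ifi <- vrow("v3", "G1", effect = "inframe_indel")
  expect_true(variant_qualifies(ifi, 0, m$ultra_rare))
  # external AF ceiling separates the flexible and rare-damaging REVEL models
  mis2 <- vrow("v4", "G1", effect = "missense", revel = 0.6,
               gnomad_af = 0.0008, exac_af = 0)
  expect_true(variant_qualifies(mis2, 0, m$flexible_revel))
  expect_false(variant_qualifies(mis2, 0, m$rare_damaging_revel))
  # REVEL gate is strict
  mis3 <- vrow("v5", "G1", effect = "missense", revel = 0.5)
  expect_false(variant_qualifies(mis3, 0, m$flexible_revel))
  # a missing required score disqualifies without error
  mis4 <- vrow("v6", "G1", effect = "missense")
  expect_false(variant_qualifies(mis4, 0, m$flexible_revel))
  expect_false(variant_qualifies(mis4, 0, m$flexible_polyphen))
  # both external sources must pass (max of the two is compared)
  mis5 <- vrow("v7", "G1", effect = "missense", revel = 0.9,
               gnomad_af = 0, exac_af = 0.01)
  expect_false(variant_qualifies(mis5, 0, m$flexible_revel))
  # synonymous-class model accepts synonymous only
  syn <- vrow("v8", "G1", effect = "synonymous")
  expect_true(variant_qualifies(syn, 0, m$synonymous))
  expect_false(variant_qualifies(ptv, 0, m$synonymous))
  expect_false(variant_qualifies(syn, 0, m$ultra_rare))
  # leave-one-out ceiling
  expect_false(variant_qualifies(ptv, 0.0006, m$ultra_rare))
})

test_that("carrier state collapses doses by inheritance mode", {
  m <- builtin_models()
  expect_equal(sample_gene_state(c(0, 1), m$ultra_rare), 1L)
  expect_equal(sample_gene_state(c(0, 0), m$ultra_rare), 0L)
  expect_equal(sample_gene_state(NA_integer_, m$ultra_rare), 0L)
  expect_equal(sample_gene_state(1, m$recessive), 0L)
  expect_equal(sample_gene_state(c(1, 1), m$recessive), 1L)
  expect_equal(sample_gene_state(2, m$recessive), 1L)
  expect_equal(sample_gene_state(c(NA, 1), m$recessive), 0L)
})

test_that("the carrier-state engine matches a brute-force per-variant oracle", {
  # 50-variant toy cohort with known genotypes; the oracle evaluates each
  # model definition literally, variant by variant and sample by sample
  set.seed(99)
  nv <- 50
  v <- do.call(rbind, lapply(seq_len(nv), function(i) {
    eff <- sample(c("synonymous", "missense", "inframe_indel", "ptv"), 1)
    vrow(sprintf("v%02d", i), sample(sprintf("G%d", 1:5), 1), effect = eff,
         polyphen = if (eff == "missense")
           sample(c("probably_damaging", "other", NA), 1) else NA,
         revel = if (eff == "missense") round(runif(1), 2) else NA,
         gnomad_af = sample(c(0, 0.00003, 0.0008, 0.01), 1),
         exac_af = sample(c(0, 0.00003, 0.0008, 0.01), 1))
  }))
  n <- 30
  geno <- matrix(rbinom(n * nv, 2, 0.05), n, nv)
  geno[sample(length(geno), 20)] <- NA
  co <- manual_cohort(v, geno, 5, n - 10)
  analyzed <- prune_one_case_per_family(co$manifest)
  g <- co$geno[analyzed$sample_id, , drop = FALSE]

  oracle_state <- function(model) {
    ac <- colSums(g, na.rm = TRUE); an <- 2 * colSums(!is.na(g))
    genes <- sort(unique(v$gene))
    st <- matrix(FALSE, nrow(g), length(genes),
                 dimnames = list(rownames(g), genes))
    for (s in seq_len(nrow(g))) for (gn in genes) {
      doses <- integer(0)
      for (j in which(v$gene == gn)) {
        d <- g[s, j]; if (is.na(d) || d == 0) next
        loo <- if (an[j] > 2) (ac[j] - d) / (an[j] - 2) else 0
        if (variant_qualifies(v[j, ], loo, model)) doses <- c(doses, d)
      }
      st[s, gn] <- sample_gene_state(if (length(doses)) doses else 0L,
                                     model) == 1L
    }
    st
  }
  for (mn in names(builtin_models())) {
    model <- builtin_models()[[mn]]
    expect_identical(carrier_states(g, v, model), oracle_state(model),
                     label = mn)
  }
})

test_that("tightening a model never creates a carrier", {
  co <- generate_cohort(sim_config(n_case_families = 20, n_control = 150,
                                   n_genes = 40, sites_per_gene = 6,
                                   external_absent_prob = 0.4, seed = 55))
  analyzed <- prune_one_case_per_family(co$manifest)
  g <- co$geno[analyzed$sample_id, , drop = FALSE]
  base <- qv_model("base", "dominant", "all_functional",
                   loo_af_max = 0.01, external_af_max = 0.01)
  tighter <- list(
    qv_model("loo", "dominant", "all_functional",
             loo_af_max = 0.0005, external_af_max = 0.01),
    qv_model("ext", "dominant", "all_functional",
             loo_af_max = 0.01, external_af_max = 0.00005),
    qv_model("pp", "dominant", "all_functional", polyphen_required = TRUE,
             loo_af_max = 0.01, external_af_max = 0.01),
    qv_model("rv", "dominant", "all_functional", revel_min = 0.5,
             loo_af_max = 0.01, external_af_max = 0.01))
  st0 <- carrier_states(g, co$variants, base)
  for (tm in tighter) {
    st1 <- carrier_states(g, co$variants, tm)
    expect_true(all(st0 | !st1), label = tm$name)  # st1 subset of st0
  }
})
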