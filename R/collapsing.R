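#' Carrier 2x2 contingency table
#'
#' The per-gene collapsing table: carriers and non-carriers of a qualifying
#' variant among cases (first row) and controls (second row).
#'
#' @param case_carriers,case_noncarriers,control_carriers,control_noncarriers
#'   non-negative integer counts.
#' @return an object of class `contingency_table` (a named integer 2x2
#'   matrix, rows = case/control, columns = carrier/non-carrier).
#' @export
#' @examples
#' contingency_table(2, 51, 3, 8980)
contingency_table <- function(case_carriers, case_noncarriers,
                              control_carriers, control_noncarriers) {
  counts <- c(case_carriers, case_noncarriers,
              control_carriers, control_noncarriers)
  stop_if(any(counts < 0), "counts must be non-negative")
  m <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non_carrier")))
  class(m) <- c("contingency_table", class(m))
  m
}

#' Two-sided Fisher exact test p-value
#'
#' Exact two-sided p for a carrier 2x2 table under the minimum-likelihood
#' definition: with margins fixed, the hypergeometric probabilities of all
#' tables no more probable than the observed one (within relative tolerance
#' `1e-7`) are summed. This is the standard two-tailed Fisher exact test and
#' reproduces published collapsing-test p-values.
#'
#' @param table a [contingency_table()] (or any 2x2 matrix of counts,
#'   rows = groups, columns = carrier/non-carrier).
#' @return the exact two-sided p-value.
#' @export
#' @examples
#' fisher_two_sided(contingency_table(2, 51, 3, 8980)) # 3.34e-4
fisher_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  stop_if(any(table < 0), "counts must be non-negative")
  fisher_p(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
}

## scalar workhorse: a,b = case carriers/non-carriers; c,d = control
fisher_p <- function(a, b, cc, d) {
  n1 <- a + b          # cases
  k  <- a + cc         # total carriers
  n  <- a + b + cc + d
  if (n == 0 || k == 0 || k == n || n1 == 0 || n1 == n) return(1)
  lo <- max(0, k - (n - n1))
  hi <- min(k, n1)
  support <- lo:hi
  dens <- stats::dhyper(support, n1, n - n1, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  min(1, p)
}

#' Cross-product odds ratio of a carrier table
#'
#' The unadjusted cross-product odds ratio `(a*d)/(b*c)` for a carrier 2x2
#' table, the convention behind printed gene-level odds ratios. No continuity
#' correction is applied by default: a table with control carriers `c = 0`
#' and case carriers `a > 0` yields `Inf`, and a table with no carriers in
#' either group is undefined (`NaN`). Set `haldane = TRUE` to add 0.5 to
#' every cell (display-only convention for zero cells).
#'
#' @param table a [contingency_table()] or 2x2 count matrix.
#' @param haldane apply the Haldane-Anscombe 0.5 correction.
#' @return the odds ratio (possibly `Inf` or `NaN`).
#' @export
#' @examples
#' odds_ratio(contingency_table(2, 51, 3, 8980)) # 117.3856...
odds_ratio <- function(table, haldane = FALSE) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  if (haldane) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  if (a == 0 && cc == 0) return(NaN)
  if (cc == 0 && a > 0) return(Inf)
  if (b == 0 && d > 0) return(Inf)
  (a * d) / (b * cc)
}

#' Bonferroni significance threshold
#'
#' Study-wide multiplicity threshold for the gene-based scan: `alpha /
#' n_genes` for a single qualifying-variant model, or `alpha / (n_genes *
#' n_models)` across models. With the study's 18,666 CCDS genes these are
#' 2.67e-6 (one model) and 2.97e-7 (nine models).
#'
#' @param alpha family-wise significance level.
#' @param n_genes number of genes tested.
#' @param n_models number of qualifying-variant models corrected for
#'   (1 = per-model threshold).
#' @return the p-value threshold.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 18666)      # 2.67e-6
#' bonferroni_threshold(0.05, 18666, 9)   # 2.97e-7
bonferroni_threshold <- function(alpha = 0.05, n_genes, n_models = 1) {
  stop_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  stop_if(n_genes < 1 || n_models < 1, "counts must be >= 1")
  alpha / (n_genes * n_models)
}

#' Recover integer carrier counts from a printed odds ratio
#'
#' Enumerates candidate carrier tables `a` cases of `n_case` versus `b`
#' controls of `n_control` (each up to `max_carriers`) and returns every
#' table whose cross-product odds ratio, rounded half-up to two decimals,
#' equals the printed value. Used to pin published OR/p pairs to the integer
#' 2x2 tables that produced them when only the rounded statistics are
#' reported.
#'
#' @param printed_or the published odds ratio (2 d.p.).
#' @param n_case,n_control group sizes.
#' @param max_carriers upper bound on carriers searched in each group.
#' @return a list of [contingency_table()] objects (length 1 when the
#'   printed value pins a unique table).
#' @export
#' @examples
#' recover_counts_from_or(117.39, 53, 8983, 30)
recover_counts_from_or <- function(printed_or, n_case, n_control,
                                   max_carriers = 30) {
  stop_if(printed_or <= 0, "printed_or must be positive")
  out <- list()
  for (a in 0:min(max_carriers, n_case)) {
    for (b in 0:min(max_carriers, n_control)) {
      tab <- contingency_table(a, n_case - a, b, n_control - b)
      or <- odds_ratio(tab)
      if (is.finite(or) && round_half_up(or, 2) == printed_or) {
        out[[length(out) + 1L]] <- tab
      }
    }
  }
  stop_if(length(out) == 0,
          sprintf("no carrier table with OR %.2f in range", printed_or))
  out
}

#' Collapse carrier states for one gene to its 2x2 table
#'
#' Tabulates the 0/1 carrier states of the analyzed samples against the
#' case/control phenotype in the manifest.
#'
#' @param states named 0/1 (or logical) vector of carrier states, names =
#'   sample ids; one entry per analyzed sample.
#' @param manifest sample manifest restricted to the analyzed samples
#'   (columns `sample_id`, `phenotype`).
#' @return a [contingency_table()].
#' @export
collapse_gene <- function(states, manifest) {
  check_columns(manifest, c("sample_id", "phenotype"), "manifest")
  missing <- setdiff(names(states), manifest$sample_id)
  stop_if(length(missing) > 0,
          "carrier states refer to samples absent from the manifest: ",
          paste(utils::head(missing, 5), collapse = ", "))
  pheno <- manifest$phenotype[match(names(states), manifest$sample_id)]
  s <- as.integer(states) > 0
  contingency_table(sum(s[pheno == "case"]), sum(!s[pheno == "case"]),
                    sum(s[pheno == "control"]), sum(!s[pheno == "control"]))
}

#' Gene-based collapsing scan
#'
#' The central analysis: for each gene and each qualifying-variant model,
#' every analyzed sample is reduced to a 0/1 indicator for carrying at least
#' one qualifying variant (two qualifying alleles under the recessive model),
#' the carrier rates of cases and controls are compared with a two-sided
#' Fisher exact test, and the cross-product odds ratio is reported. The
#' analyzed sample set is the manifest after one-case-per-family pruning
#' (cases from multiplex families are related; only one enters the test);
#' sites failing case/control coverage harmonization are removed before any
#' model is applied.
#'
#' @param cohort an `rv_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param models `"all"`, a character vector of built-in model names, a
#'   [qv_model()], or a list of them.
#' @param coverage_config a [coverage_config()]; `NULL` skips site pruning
#'   (e.g. when the cohort's coverage table is already harmonized).
#' @param prune_families apply [prune_one_case_per_family()] (default TRUE).
#' @param alpha,n_genes_tested,n_models_correction multiplicity settings for
#'   the Bonferroni flags; `n_genes_tested` defaults to the number of genes
#'   in the scan and `n_models_correction` to 9 (the full model set).
#' @param keep_states retain the per-model carrier-state matrices (needed by
#'   [permutation_expected()]).
#' @return an object of class `collapsing_scan`: a data frame with one row
#'   per gene x model (`gene`, `model`, `case_carriers`, `case_n`,
#'   `control_carriers`, `control_n`, `odds_ratio`, `p_value`,
#'   `passes_single_model_bonferroni`, `passes_nine_model_bonferroni`), with
#'   the analyzed manifest, carrier states and settings in attributes.
#' @seealso [permutation_expected()], [geneset_test()], [filtered_analysis()]
#' @export
collapsing_scan <- function(cohort, models = "all",
                            coverage_config = NULL,
                            prune_families = TRUE,
                            alpha = 0.05, n_genes_tested = NULL,
                            n_models_correction = 9,
                            keep_states = TRUE) {
  stopifnot(inherits(cohort, "rv_cohort"))
  models <- resolve_models(models)

  manifest <- if (prune_families) prune_one_case_per_family(cohort$manifest)
              else cohort$manifest
  variants <- cohort$variants
  if (!is.null(coverage_config)) {
    pr <- prune_sites(cohort$coverage, coverage_config, variants)
    variants <- variants[variants$variant_id %in% pr$kept_variant_ids, ,
                         drop = FALSE]
  }
  geno <- cohort$geno[manifest$sample_id, variants$variant_id, drop = FALSE]

  genes <- sort(unique(cohort$variants$gene))
  n_genes_tested <- n_genes_tested %||% length(genes)
  thr1 <- bonferroni_threshold(alpha, n_genes_tested, 1)
  thr9 <- bonferroni_threshold(alpha, n_genes_tested, n_models_correction)

  is_case <- manifest$phenotype == "case"
  n_case <- sum(is_case); n_control <- sum(!is_case)
  cache <- new.env(parent = emptyenv())

  res <- list(); states_by_model <- list()
  for (mn in names(models)) {
    st <- carrier_states(geno, variants, models[[mn]], genes = genes)
    a <- colSums(st[is_case, , drop = FALSE])
    b <- colSums(st[!is_case, , drop = FALSE])
    p <- cached_fisher(a, n_case - a, b, n_control - b, cache)
    or <- mapply(function(ai, bi) odds_ratio(
      contingency_table(ai, n_case - ai, bi, n_control - bi)), a, b)
    res[[mn]] <- data.frame(
      gene = genes, model = mn,
      case_carriers = a, case_n = n_case,
      control_carriers = b, control_n = n_control,
      odds_ratio = or, p_value = p,
      passes_single_model_bonferroni = p < thr1,
      passes_nine_model_bonferroni = p < thr9,
      row.names = NULL, stringsAsFactors = FALSE)
    if (keep_states) states_by_model[[mn]] <- st
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            class = c("collapsing_scan", "data.frame"),
            manifest = manifest, models = models,
            n_case = n_case, n_control = n_control,
            n_genes_tested = n_genes_tested,
            states = if (keep_states) states_by_model)
}

## vectorized fisher with memoisation on (a, b, c, d); carrier tables repeat
## heavily across genes, so the cache collapses a genome scan to the distinct
## tables actually observed.
cached_fisher <- function(a, b, cc, d, cache = new.env(parent = emptyenv())) {
  key <- paste(a, b, cc, d, sep = ",")
  p <- numeric(length(a))
  for (i in seq_along(a)) {
    k <- key[i]
    hit <- cache[[k]]
    if (is.null(hit)) {
      hit <- fisher_p(a[i], b[i], cc[i], d[i])
      cache[[k]] <- hit
    }
    p[i] <- hit
  }
  p
}

#' @export
#' @method print collapsing_scan
print.collapsing_scan <- function(x, n = 5, ...) {
  cat(sprintf("gene-based collapsing scan: %d genes x %d model(s), %d cases vs %d controls\n",
              length(unique(x$gene)), length(attr(x, "models")),
              attr(x, "n_case"), attr(x, "n_control")))
  ord <- order(x$p_value)
  cat(sprintf("top %d gene/model results:\n", n))
  print.data.frame(utils::head(x[ord, c("gene", "model", "case_carriers",
                                        "control_carriers", "odds_ratio",
                                        "p_value")], n),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
#' @method summary collapsing_scan
summary.collapsing_scan <- function(object, alpha = 0.05, ...) {
  by_model <- split(object, object$model)
  tab <- do.call(rbind, lapply(names(by_model), function(mn) {
    m <- by_model[[mn]]
    top <- m[which.min(m$p_value), ]
    data.frame(model = mn,
               genes_with_carriers = sum(m$case_carriers + m$control_carriers > 0),
               genes_p_lt_alpha = sum(m$p_value < alpha),
               top_gene = top$gene,
               top_or = top$odds_ratio, top_p = top$p_value,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha,
                 n_case = attr(object, "n_case"),
                 n_control = attr(object, "n_control")),
            class = "summary.collapsing_scan")
}

#' @export
#' @method print summary.collapsing_scan
print.summary.collapsing_scan <- function(x, ...) {
  cat(sprintf("collapsing scan summary (%d cases vs %d controls; alpha = %g)\n",
              x$n_case, x$n_control, x$alpha))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Permutation-expected QQ distribution and inflation lambda
#'
#' Shuffles case/control labels (group sizes preserved) over the fixed
#' carrier-state matrix of one model, recomputes every gene's two-sided
#' Fisher exact p under each permutation, and averages the sorted p-vectors:
#' `expected_p[i]` is the permutation mean of the i-th order statistic. The
#' genomic inflation factor lambda is the ratio of the median chi-squared
#' (1 df) quantile of the observed p-values to that of the permutation
#' expectation; values near 1 indicate no exome-wide inflation. Because the
#' per-gene margins are fixed under label permutation, each permuted p is an
#' exact lookup by (total carriers, permuted case carriers), so the full
#' permutation distribution is computed, not approximated.
#'
#' @param scan a [collapsing_scan()] run with `keep_states = TRUE`.
#' @param model model name within the scan (defaults to its first model).
#' @param n_permutations number of label permutations.
#' @param seed integer seed controlling the permutations.
#' @return an object of class `qq_result`: list with sorted `observed_p`,
#'   `expected_p` (permutation-mean order statistics), `lambda`,
#'   `n_permutations` and `seed`.
#' @export
permutation_expected <- function(scan, model = NULL, n_permutations = 1000,
                                 seed) {
  stopifnot(inherits(scan, "collapsing_scan"))
  stop_if(n_permutations < 1, "n_permutations must be >= 1")
  states <- attr(scan, "states")
  stop_if(is.null(states), "scan must be run with keep_states = TRUE")
  model <- model %||% names(states)[1]
  st <- states[[model]]
  manifest <- attr(scan, "manifest")
  is_case <- manifest$phenotype[match(rownames(st), manifest$sample_id)] == "case"
  n_case <- sum(is_case); n <- length(is_case)

  obs <- scan$p_value[scan$model == model]
  K <- colSums(st)                       # margins fixed under permutation

  ## exact p lookup per distinct carrier total K: p_tab[[K]][a + 1]
  cache <- new.env(parent = emptyenv())
  p_tab <- lapply(sort(unique(K)), function(k) {
    amax <- min(k, n_case)
    cached_fisher(0:amax, n_case - (0:amax),
                  k - (0:amax), (n - n_case) - (k - (0:amax)), cache)
  })
  names(p_tab) <- sort(unique(K))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  carriers <- which(st, arr.ind = TRUE)  # sample x gene incidences
  G <- ncol(st)
  pm <- matrix(1, n_permutations, G)
  for (r in seq_len(n_permutations)) {
    case_idx <- sample.int(n, n_case)
    in_case <- logical(n); in_case[case_idx] <- TRUE
    a <- tabulate(carriers[in_case[carriers[, 1]], 2], nbins = G)
    pm[r, ] <- vapply(seq_len(G), function(g) p_tab[[as.character(K[g])]][a[g] + 1],
                      numeric(1))
  }
  pm <- t(apply(pm, 1, sort))
  expected <- colMeans(pm)
  lambda <- qq_lambda(sort(obs), expected)
  structure(list(observed_p = sort(obs), expected_p = expected,
                 lambda = lambda, n_permutations = n_permutations,
                 seed = seed, model = model),
            class = "qq_result")
}

## Fisher p-values are discrete with an atom at 1; when both medians sit on
## that atom the chi-square quantiles are both 0 and the ratio is taken as 1
## (the distributions agree at the median, so no inflation is measurable).
qq_lambda <- function(observed_sorted, expected_sorted) {
  num <- stats::median(stats::qchisq(observed_sorted, df = 1, lower.tail = FALSE))
  den <- stats::median(stats::qchisq(expected_sorted, df = 1, lower.tail = FALSE))
  if (den == 0) {
    if (num == 0) return(1)
    return(Inf)
  }
  num / den
}

#' @export
#' @method print qq_result
print.qq_result <- function(x, ...) {
  cat(sprintf("permutation QQ for model '%s': %d genes, %d permutations, lambda = %.3f\n",
              x$model, length(x$observed_p), x$n_permutations, x$lambda))
  invisible(x)
}

#' QQ plot of observed against permutation-expected p-values
#'
#' @param x a [collapsing_scan()].
#' @param qq a `qq_result` from [permutation_expected()]; if `NULL`, one is
#'   computed with `n_permutations` permutations.
#' @param model model name to plot.
#' @param n_permutations,seed forwarded to [permutation_expected()] when
#'   `qq` is `NULL`.
#' @param ... further arguments to [graphics::plot()].
#' @return the `qq_result`, invisibly.
#' @export
#' @method plot collapsing_scan
plot.collapsing_scan <- function(x, qq = NULL, model = NULL,
                                 n_permutations = 1000, seed = 1, ...) {
  qq <- qq %||% permutation_expected(x, model = model,
                                     n_permutations = n_permutations,
                                     seed = seed)
  ex <- -log10(pmax(qq$expected_p, 1e-300))
  ob <- -log10(pmax(qq$observed_p, 1e-300))
  graphics::plot(rev(ex), rev(ob),
                 xlab = expression(-log[10] * " expected p (permutation)"),
                 ylab = expression(-log[10] * " observed p"),
                 main = sprintf("model '%s' (lambda = %.2f)", qq$model, qq$lambda),
                 ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  invisible(qq)
}

#' Gene-set restriction of a collapsing scan
#'
#' Restricts a multi-model scan to a candidate gene list (for example, genes
#' reported by an earlier association study), reports every gene x model
#' OR/p pair, the best (smallest-p) model per gene, and the number of listed
#' genes significant at `alpha` under any model.
#'
#' @param scan a [collapsing_scan()] covering one or more models.
#' @param genes character vector of gene identifiers.
#' @param alpha significance level for the tally.
#' @return list with `results` (scan rows for listed genes), `best_per_gene`
#'   (one row per listed gene present in the scan, its minimum-p model), and
#'   `n_significant` (genes with p < alpha in any model).
#' @export
geneset_test <- function(scan, genes, alpha = 0.05) {
  stopifnot(inherits(scan, "collapsing_scan"))
  stop_if(length(genes) == 0, "gene list must be non-empty")
  res <- scan[scan$gene %in% genes, , drop = FALSE]
  res <- as.data.frame(res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (nrow(res) == 0) {
    return(list(results = res, best_per_gene = res, n_significant = 0L))
  }
  best <- do.call(rbind, lapply(split(res, res$gene),
                                function(g) g[which.min(g$p_value), ]))
  rownames(best) <- NULL
  list(results = res, best_per_gene = best,
       n_significant = sum(best$p_value < alpha))
}
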