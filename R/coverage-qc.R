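#' Coverage-harmonization configuration
#'
#' @param depth_threshold read-depth threshold defining "covered" (the
#'   per-site group fractions are fractions of samples at or above this
#'   depth; 10x by convention).
#' @param site_diff_max a site is kept only if the absolute difference
#'   between the case and control covered fractions is strictly below this
#'   value (default 0.10: sites where the groups differ by 10 percentage
#'   points or more are excluded).
#' @param cohort_min_fraction minimum mean covered fraction each group must
#'   achieve for the cohort-level check to pass (default 0.95).
#' @return an object of class `coverage_config`.
#' @export
coverage_config <- function(depth_threshold = 10, site_diff_max = 0.10,
                            cohort_min_fraction = 0.95) {
  stop_if(site_diff_max <= 0 || site_diff_max >= 1,
          "site_diff_max must lie in (0, 1)")
  stop_if(cohort_min_fraction <= 0 || cohort_min_fraction > 1,
          "cohort_min_fraction must lie in (0, 1]")
  structure(list(depth_threshold = depth_threshold,
                 site_diff_max = site_diff_max,
                 cohort_min_fraction = cohort_min_fraction),
            class = "coverage_config")
}

#' Prune sites with imbalanced case/control coverage
#'
#' Where sequencing coverage differs between groups, the less well covered
#' group under-calls variants, biasing carrier counts toward the better
#' covered group. A site is therefore kept only when
#' `|frac_case - frac_control| < site_diff_max`. Retained bases count one bp
#' per SNV and `max(nchar(ref), 1)` bp per indel record (the ref-allele
#' length), giving a deterministic retained-sequence accounting.
#'
#' @param coverage coverage table (`variant_id`, `frac_case_ge10x`,
#'   `frac_control_ge10x`).
#' @param config a [coverage_config()].
#' @param variants optional variant table supplying `ref` allele lengths for
#'   the base accounting (1 bp per site if omitted).
#' @return an object of class `pruned_sites`: list with `kept_variant_ids`,
#'   `removed_variant_ids` and `retained_bases`.
#' @export
prune_sites <- function(coverage, config = coverage_config(), variants = NULL) {
  check_columns(coverage, c("variant_id", "frac_case_ge10x",
                            "frac_control_ge10x"), "coverage table")
  fr <- c(coverage$frac_case_ge10x, coverage$frac_control_ge10x)
  stop_if(any(is.na(fr)) || any(fr < 0 | fr > 1),
          "coverage fractions must lie in [0, 1]")
  ## strict keep condition |diff| < threshold, with a 1e-9 numeric guard so
  ## a difference of exactly the threshold (e.g. 1.0 vs 0.9) is excluded
  ## despite floating-point representation
  diffs <- abs(coverage$frac_case_ge10x - coverage$frac_control_ge10x)
  keep <- (config$site_diff_max - diffs) > 1e-9
  len <- rep(1L, nrow(coverage))
  if (!is.null(variants)) {
    m <- match(coverage$variant_id, variants$variant_id)
    len <- ifelse(is.na(m), 1L, pmax(nchar(variants$ref[m]), 1L))
  }
  structure(list(kept_variant_ids = coverage$variant_id[keep],
                 removed_variant_ids = coverage$variant_id[!keep],
                 retained_bases = sum(len[keep])),
            class = "pruned_sites")
}

#' @export
#' @method print pruned_sites
print.pruned_sites <- function(x, ...) {
  cat(sprintf("coverage pruning: %d sites kept, %d removed (%.3f Mbp retained)\n",
              length(x$kept_variant_ids), length(x$removed_variant_ids),
              x$retained_bases / 1e6))
  invisible(x)
}

#' Cohort-level coverage check
#'
#' Reports the mean per-site fraction of samples at or above the depth
#' threshold for each group, and whether both groups reach the cohort
#' minimum (by convention, at least 10-fold coverage over >= 95% of the
#' tested sequence).
#'
#' @param coverage coverage table.
#' @param config a [coverage_config()].
#' @return list with `pass`, `case_fraction`, `control_fraction` and the
#'   per-group fraction of individual sites meeting `cohort_min_fraction`.
#' @export
cohort_coverage_check <- function(coverage, config = coverage_config()) {
  check_columns(coverage, c("variant_id", "frac_case_ge10x",
                            "frac_control_ge10x"), "coverage table")
  stop_if(nrow(coverage) == 0, "coverage table is empty")
  case_fr <- mean(coverage$frac_case_ge10x)
  ctl_fr <- mean(coverage$frac_control_ge10x)
  list(pass = case_fr >= config$cohort_min_fraction &&
         ctl_fr >= config$cohort_min_fraction,
       case_fraction = case_fr, control_fraction = ctl_fr,
       case_sites_ok = mean(coverage$frac_case_ge10x >= config$cohort_min_fraction),
       control_sites_ok = mean(coverage$frac_control_ge10x >= config$cohort_min_fraction))
}

#' Synonymous-burden QC: neutral-variation comparability check
#'
#' Tallies, per analyzed sample, the number of rare autosomal synonymous
#' variants carried (presumed neutral; leave-one-out allele frequency at or
#' below `loo_af_max`) and compares case and control counts with a
#' two-sided Wilcoxon rank-sum test. A significant difference would indicate
#' residual technical stratification (e.g. differential coverage or calling)
#' between the groups; a non-significant result certifies comparability for
#' the collapsing analysis.
#'
#' @param cohort an `rv_cohort` (sites should already be coverage-pruned:
#'   pass `kept_variant_ids` or prune beforehand).
#' @param loo_af_max internal leave-one-out allele-frequency ceiling
#'   defining "rare".
#' @param kept_variant_ids optional site subset (e.g. from [prune_sites()]).
#' @param prune_families apply one-case-per-family pruning (default TRUE).
#' @return list with `per_sample` (sample_id, phenotype, count), `statistic`
#'   and `p_value` of the rank-sum test, and `case_mean`/`control_mean`.
#' @export
synonymous_burden_qc <- function(cohort, loo_af_max = 0.0005,
                                 kept_variant_ids = NULL,
                                 prune_families = TRUE) {
  stopifnot(inherits(cohort, "rv_cohort"))
  manifest <- if (prune_families) prune_one_case_per_family(cohort$manifest)
              else cohort$manifest
  variants <- cohort$variants
  if (!is.null(kept_variant_ids)) {
    variants <- variants[variants$variant_id %in% kept_variant_ids, ,
                         drop = FALSE]
  }
  syn <- variants[variants$effect == "synonymous", , drop = FALSE]
  stop_if(nrow(syn) == 0, "no synonymous variants available for the tally")
  geno <- cohort$geno[manifest$sample_id, syn$variant_id, drop = FALSE]

  ac <- colSums(geno, na.rm = TRUE)
  an <- 2L * colSums(!is.na(geno))
  idx <- which(geno > 0, arr.ind = TRUE)
  counts <- stats::setNames(integer(nrow(manifest)), manifest$sample_id)
  if (nrow(idx) > 0) {
    d <- geno[idx]
    denom <- an[idx[, 2]] - 2
    num <- ac[idx[, 2]] - d
    loo <- ifelse(denom > 0, num / denom, ifelse(num == 0, 0, 1))
    qual <- idx[loo <= loo_af_max, 1]
    if (length(qual) > 0) {
      tab <- tabulate(qual, nbins = nrow(manifest))
      counts[] <- tab
    }
  }
  is_case <- manifest$phenotype == "case"
  wt <- stats::wilcox.test(counts[is_case], counts[!is_case], exact = FALSE)
  ## degenerate tally (all counts tied) carries no evidence of a difference
  if (is.nan(wt$p.value)) wt$p.value <- 1
  list(per_sample = data.frame(sample_id = manifest$sample_id,
                               phenotype = manifest$phenotype,
                               count = as.integer(counts),
                               stringsAsFactors = FALSE),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       case_mean = mean(counts[is_case]),
       control_mean = mean(counts[!is_case]))
}
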