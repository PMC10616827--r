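#' Synthetic-cohort configuration
#'
#' Parameters for [generate_cohort()]. Defaults emulate the structure of a
#' multiplex-family case/control exome study: 53 case families each
#' contributing a pair of affected siblings (so one-case-per-family pruning
#' is meaningful), 8,983 unrelated controls, an ultra-rare-dominated site
#' frequency spectrum (a point mass of singletons plus a low-frequency Beta
#' tail), exome-like functional-effect proportions, and a small fraction of
#' sites with case/control coverage imbalance.
#'
#' @param n_case_families number of multiplex families (each contributes two
#'   affected siblings, one flagged as the proband).
#' @param n_control number of unrelated controls (0 allowed).
#' @param n_genes number of genes.
#' @param sites_per_gene mean sites per gene (per-gene counts are
#'   `1 + Poisson(sites_per_gene - 1)`).
#' @param af_spectrum list with `singleton_prop` (probability a site is a
#'   cohort singleton: exactly one alternate allele), and `shape1`, `shape2`
#'   of the Beta distribution for the remaining sites' allele frequencies
#'   (truncated to (0, 0.5]).
#' @param effect_mix named probabilities over effect classes
#'   `synonymous`, `missense`, `inframe_indel`, `ptv`; must sum to 1.
#' @param polyphen_damaging_rate probability a missense variant is PolyPhen
#'   "probably damaging".
#' @param revel_shape `shape1`, `shape2` of the Beta distribution of REVEL
#'   scores for missense variants.
#' @param n_populations number of discrete ancestry strata.
#' @param population_af_divergence Balding-Nichols differentiation parameter
#'   F in `[0, 1)`; 0 gives identical per-population allele frequencies.
#' @param coverage_imbalance_fraction fraction of sites whose control
#'   >=10x-coverage fraction is depressed relative to cases.
#' @param coverage_imbalance_amount size of that depression (absolute
#'   difference in group fractions; the default 0.2 exceeds the usual 0.10
#'   harmonization threshold so imbalanced sites are prunable).
#' @param external_absent_prob probability a variant is absent from both
#'   gnomAD and ExAC (external AF 0); present variants draw a log-uniform
#'   external frequency in `[1e-6, 1e-2]`.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer seed; the same seed and config give a bit-identical
#'   cohort.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_case_families = 53, n_control = 8983,
                       n_genes = 200, sites_per_gene = 8,
                       af_spectrum = list(singleton_prop = 0.5,
                                          shape1 = 0.3, shape2 = 400),
                       effect_mix = c(synonymous = 0.35, missense = 0.52,
                                      inframe_indel = 0.03, ptv = 0.10),
                       polyphen_damaging_rate = 0.35,
                       revel_shape = c(shape1 = 1.2, shape2 = 3),
                       n_populations = 1,
                       population_af_divergence = 0,
                       coverage_imbalance_fraction = 0.02,
                       coverage_imbalance_amount = 0.2,
                       external_absent_prob = 0.6,
                       missing_rate = 0,
                       seed = 1) {
  stop_if(n_case_families < 1, "n_case_families must be positive")
  stop_if(n_control < 0, "n_control must be non-negative")
  stop_if(n_genes < 1 || sites_per_gene < 1, "gene/site counts must be positive")
  stop_if(population_af_divergence < 0 || population_af_divergence >= 1,
          "population_af_divergence must lie in [0, 1)")
  stop_if(n_populations < 1, "n_populations must be positive")
  probs <- c(af_spectrum$singleton_prop, polyphen_damaging_rate,
             coverage_imbalance_fraction, external_absent_prob, missing_rate,
             effect_mix)
  stop_if(any(probs < 0 | probs > 1), "all probabilities must lie in [0, 1]")
  stop_if(abs(sum(effect_mix) - 1) > 1e-8, "effect_mix must sum to 1")
  stop_if(!all(EFFECT_CLASSES %in% names(effect_mix)),
          "effect_mix must name all four effect classes")
  structure(as.list(environment()), class = "sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate a synthetic case/control exome cohort
#'
#' Simulates a cohort with the statistical structure the collapsing analysis
#' assumes: multiplex families of two affected siblings (genotypes built
#' from simulated parental haplotypes, so sibs share each parental allele
#' with probability 1/2 independently per variant), unrelated controls,
#' per-population allele frequencies under a Balding-Nichols model,
#' annotation fields (effect class, PolyPhen call, REVEL score, external
#' allele frequencies) for every variant, and per-site case/control
#' >=10x-coverage fractions with a configurable imbalanced subset. Autosomes
#' only.
#'
#' @param config a [sim_config()].
#' @return an object of class `rv_cohort`: list with `variants` (annotation
#'   table), `geno` (sample x variant dose matrix, `NA` = missing),
#'   `manifest`, `coverage` and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_case_families = 3, n_control = 20,
#'                                      n_genes = 5, seed = 42))
#' dim(cohort$geno)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ## --- variant scaffold -------------------------------------------------
    spg <- 1L + stats::rpois(config$n_genes, config$sites_per_gene - 1)
    gene <- rep(sprintf("G%04d", seq_len(config$n_genes)), spg)
    nvar <- length(gene)
    gene_chrom <- sample(1:22, config$n_genes, replace = TRUE)
    chrom <- rep(gene_chrom, spg)
    pos <- integer(nvar)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      pos[i] <- sort(sample.int(5e7, length(i)))
    }
    ord <- order(chrom, pos)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nvar, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

    ## --- allele-frequency spectrum ---------------------------------------
    singleton <- stats::runif(nvar) < config$af_spectrum$singleton_prop
    p0 <- stats::rbeta(nvar, config$af_spectrum$shape1, config$af_spectrum$shape2)
    p0 <- pmin(pmax(p0, 1e-6), 0.5)

    ## per-population frequencies (Balding-Nichols)
    F <- config$population_af_divergence
    npop <- config$n_populations
    pop_p <- matrix(p0, nvar, npop)
    if (F > 0 && npop > 1) {
      for (k in seq_len(npop)) {
        pop_p[, k] <- stats::rbeta(nvar, p0 * (1 - F) / F,
                                   (1 - p0) * (1 - F) / F)
      }
      pop_p <- pmin(pmax(pop_p, 0), 0.5)
    }

    ## --- samples ----------------------------------------------------------
    fam_ids <- sprintf("FAM%03d", seq_len(config$n_case_families))
    case_ids <- as.vector(t(outer(fam_ids, c("_P", "_S"), paste0)))
    ctl_ids <- if (config$n_control > 0)
      sprintf("CTL%05d", seq_len(config$n_control)) else character()
    n_case <- length(case_ids)
    fam_pop <- sample.int(npop, config$n_case_families, replace = TRUE)
    ctl_pop <- if (config$n_control > 0)
      sample.int(npop, config$n_control, replace = TRUE) else integer()

    manifest <- data.frame(
      sample_id = c(case_ids, ctl_ids),
      family_id = c(rep(fam_ids, each = 2),
                    rep("CONTROLS", config$n_control)),
      phenotype = c(rep("case", n_case), rep("control", config$n_control)),
      ancestry = paste0("pop", c(rep(fam_pop, each = 2), ctl_pop)),
      is_proband = c(rep(c(1L, 0L), config$n_case_families),
                     rep(0L, config$n_control)),
      stringsAsFactors = FALSE)

    ## --- genotypes ---------------------------------------------------------
    geno <- matrix(0L, nrow(manifest), nvar,
                   dimnames = list(manifest$sample_id, NULL))
    for (f in seq_len(config$n_case_families)) {
      p <- pop_p[, fam_pop[f]]
      fa <- cbind(stats::rbinom(nvar, 1, p), stats::rbinom(nvar, 1, p))
      mo <- cbind(stats::rbinom(nvar, 1, p), stats::rbinom(nvar, 1, p))
      for (s in 1:2) {   # each sib draws one allele per parent, per variant
        fi <- sample(1:2, nvar, replace = TRUE)
        mi <- sample(1:2, nvar, replace = TRUE)
        geno[(f - 1) * 2 + s, ] <-
          fa[cbind(seq_len(nvar), fi)] + mo[cbind(seq_len(nvar), mi)]
      }
    }
    if (config$n_control > 0) {
      for (k in seq_len(npop)) {
        rows <- n_case + which(ctl_pop == k)
        if (length(rows) > 0) {
          geno[rows, ] <- matrix(
            stats::rbinom(length(rows) * nvar, 2, rep(pop_p[, k], each = length(rows))),
            nrow = length(rows))
        }
      }
    }
    ## singleton sites: exactly one alternate allele in the whole cohort
    if (any(singleton)) {
      geno[, singleton] <- 0L
      owner <- sample.int(nrow(manifest), sum(singleton), replace = TRUE)
      geno[cbind(owner, which(singleton))] <- 1L
    }
    if (config$missing_rate > 0) {
      geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
    }

    ## --- annotations --------------------------------------------------------
    effect <- sample(names(config$effect_mix), nvar, replace = TRUE,
                     prob = config$effect_mix)
    is_mis <- effect == "missense"
    polyphen <- ifelse(is_mis,
                       ifelse(stats::runif(nvar) < config$polyphen_damaging_rate,
                              "probably_damaging", "other"),
                       NA_character_)
    revel <- ifelse(is_mis,
                    stats::rbeta(nvar, config$revel_shape[["shape1"]],
                                 config$revel_shape[["shape2"]]),
                    NA_real_)
    absent <- stats::runif(nvar) < config$external_absent_prob
    gnomad <- ifelse(absent, 0, 10^stats::runif(nvar, -6, -2))
    exac <- ifelse(absent, 0, 10^stats::runif(nvar, -6, -2))

    variants <- data.frame(
      variant_id = sprintf("V%06d", seq_len(nvar)),
      chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
      gene = gene, effect = effect, polyphen = polyphen,
      revel = revel, gnomad_af = gnomad, exac_af = exac,
      stringsAsFactors = FALSE)[ord, , drop = FALSE]
    rownames(variants) <- NULL
    geno <- geno[, ord, drop = FALSE]
    colnames(geno) <- variants$variant_id

    ## --- coverage ------------------------------------------------------------
    frac_case <- stats::runif(nvar, 0.95, 1)
    frac_control <- pmin(pmax(frac_case + stats::runif(nvar, -0.03, 0.03), 0), 1)
    imb <- stats::runif(nvar) < config$coverage_imbalance_fraction
    frac_control[imb] <- pmax(frac_case[imb] - config$coverage_imbalance_amount, 0)
    coverage <- data.frame(variant_id = variants$variant_id,
                           frac_case_ge10x = frac_case[ord],
                           frac_control_ge10x = frac_control[ord],
                           stringsAsFactors = FALSE)

    new_rv_cohort(variants, geno, manifest, coverage, config)
  })
}

new_rv_cohort <- function(variants, geno, manifest, coverage, config = NULL) {
  stopifnot(nrow(variants) == ncol(geno), nrow(manifest) == nrow(geno),
            ncol(geno) == 0 || identical(variants$variant_id, colnames(geno)),
            nrow(geno) == 0 || identical(manifest$sample_id, rownames(geno)))
  structure(list(variants = variants, geno = geno, manifest = manifest,
                 coverage = coverage, config = config),
            class = "rv_cohort")
}

#' @export
#' @method print rv_cohort
print.rv_cohort <- function(x, ...) {
  cat(sprintf(
    "rv_cohort: %d samples (%d cases, %d controls), %d variants in %d genes\n",
    nrow(x$manifest), sum(x$manifest$phenotype == "case"),
    sum(x$manifest$phenotype == "control"),
    nrow(x$variants), length(unique(x$variants$gene))))
  invisible(x)
}

#' Risk-gene spike specification
#'
#' @param gene gene identifier to spike.
#' @param case_carrier_count,control_carrier_count exact number of analyzed
#'   cases / controls that will carry a qualifying variant of the targeted
#'   model in `gene` after spiking.
#' @param effect_class effect class of the injected variants (defaults to a
#'   class compatible with the targeted model).
#' @param model_targeted built-in model name or [qv_model()].
#' @return an object of class `spike_spec`.
#' @export
spike_spec <- function(gene, case_carrier_count, control_carrier_count,
                       effect_class = NULL, model_targeted = "ultra_rare") {
  stop_if(case_carrier_count < 0 || control_carrier_count < 0,
          "carrier counts must be non-negative")
  structure(list(gene = gene,
                 case_carrier_count = as.integer(case_carrier_count),
                 control_carrier_count = as.integer(control_carrier_count),
                 effect_class = effect_class,
                 model_targeted = model_targeted),
            class = "spike_spec")
}

#' Spike a risk gene into a synthetic cohort
#'
#' Injects carrier enrichment for one gene: after spiking, exactly
#' `case_carrier_count` analyzed cases (probands surviving
#' one-case-per-family pruning) and `control_carrier_count` controls carry a
#' qualifying variant of the targeted model in the gene. Each chosen carrier
#' receives a private singleton variant satisfying the model's filters by
#' construction (leave-one-out frequency 0, absent from external databases,
#' model-compatible effect class; homozygous under compound-het models), and
#' any pre-existing carriers of model-candidate variants in the gene are
#' reset to non-carrier so the counts are exact. Carriers are chosen without
#' replacement using `seed` (default: the cohort's config seed). A 0/0 spike
#' is a no-op.
#'
#' @param cohort an `rv_cohort`.
#' @param spec a [spike_spec()].
#' @param seed integer seed for carrier selection.
#' @return the modified `rv_cohort`.
#' @export
spike_risk_gene <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(cohort, "rv_cohort"), inherits(spec, "spike_spec"))
  stop_if(!spec$gene %in% cohort$variants$gene,
          "gene not present in cohort: ", spec$gene)
  if (spec$case_carrier_count == 0 && spec$control_carrier_count == 0) {
    return(cohort)
  }
  model <- if (inherits(spec$model_targeted, "qv_model")) spec$model_targeted
           else resolve_models(spec$model_targeted)[[1]]

  analyzed <- prune_one_case_per_family(cohort$manifest)
  cases <- analyzed$sample_id[analyzed$phenotype == "case"]
  controls <- analyzed$sample_id[analyzed$phenotype == "control"]
  stop_if(spec$case_carrier_count > length(cases),
          "infeasible spike: more case carriers than analyzed cases")
  stop_if(spec$control_carrier_count > length(controls),
          "infeasible spike: more control carriers than controls")

  effect <- spec$effect_class %||% switch(model$function_class,
    synonymous = "synonymous", ptv = "ptv", all_functional = "ptv")
  stop_if(!effect %in% EFFECT_CLASSES, "unknown effect class: ", effect)

  ## reset pre-existing candidate carriers of this gene under the model
  in_gene <- cohort$variants$gene == spec$gene
  cand <- in_gene & annotation_gate(cohort$variants, model)
  if (any(cand)) cohort$geno[, cand][cohort$geno[, cand] > 0] <- 0L

  with_seed(seed %||% (cohort$config$seed %||% 1L), {
    carriers <- c(sample(cases, spec$case_carrier_count),
                  sample(controls, spec$control_carrier_count))
    n_new <- length(carriers)
    if (n_new > 0) {
      gi <- which(in_gene)
      chrom <- cohort$variants$chrom[gi[1]]
      pos0 <- max(cohort$variants$pos[gi])
      newv <- data.frame(
        variant_id = sprintf("%s_spike%02d", spec$gene, seq_len(n_new)),
        chrom = chrom, pos = pos0 + seq_len(n_new),
        ref = "A", alt = "T", gene = spec$gene, effect = effect,
        polyphen = if (effect == "missense") "probably_damaging" else NA_character_,
        revel = if (effect == "missense") 0.9 else NA_real_,
        gnomad_af = 0, exac_af = 0, stringsAsFactors = FALSE)
      dose <- if (model$inheritance == "compound_het") 2L else 1L
      newg <- matrix(0L, nrow(cohort$geno), n_new,
                     dimnames = list(rownames(cohort$geno), newv$variant_id))
      newg[cbind(match(carriers, rownames(cohort$geno)), seq_len(n_new))] <- dose
      newc <- data.frame(variant_id = newv$variant_id,
                         frac_case_ge10x = 0.99, frac_control_ge10x = 0.99,
                         stringsAsFactors = FALSE)

      variants <- rbind(cohort$variants, newv)
      geno <- cbind(cohort$geno, newg)
      coverage <- rbind(cohort$coverage, newc)
      ord <- order(as.integer(factor(variants$chrom,
                                     levels = unique(variants$chrom))),
                   variants$pos)
      variants <- variants[ord, , drop = FALSE]
      rownames(variants) <- NULL
      geno <- geno[, ord, drop = FALSE]
      coverage <- coverage[match(variants$variant_id, coverage$variant_id), ,
                           drop = FALSE]
      rownames(coverage) <- NULL
      cohort <- new_rv_cohort(variants, geno, cohort$manifest, coverage,
                              cohort$config)
    }
    cohort
  })
}

#' Write a cohort to its on-disk file set
#'
#' Emits `cohort.vcf` (VCF v4.2, GT field, one ALT per record),
#' `annotations.tsv`, `coverage.tsv` and `manifest.tsv` in `dir`, readable
#' by [read_cohort()] with lossless round-trip of genotype codes and
#' annotations. Output is deterministic: the same cohort writes identical
#' bytes.
#'
#' @param cohort an `rv_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  paths <- file.path(dir, c("cohort.vcf", "annotations.tsv",
                            "coverage.tsv", "manifest.tsv"))

  gt <- matrix("./.", nrow(v), nrow(cohort$manifest))
  g <- t(cohort$geno)   # variants x samples
  gt[which(g == 0L)] <- "0/0"
  gt[which(g == 1L)] <- "0/1"
  gt[which(g == 2L)] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=rarecollapse",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$manifest$sample_id), collapse = "\t"))
  body <- if (nrow(v) == 0) character(0) else
    paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths[1])

  fmt17 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ann <- v[, c("variant_id", "gene", "effect", "polyphen", "revel",
               "gnomad_af", "exac_af")]
  for (col in c("revel", "gnomad_af", "exac_af")) ann[[col]] <- fmt17(ann[[col]])
  cov <- cohort$coverage
  for (col in c("frac_case_ge10x", "frac_control_ge10x"))
    cov[[col]] <- fmt17(cov[[col]])
  utils::write.table(ann, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(cov, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(cohort$manifest, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(paths)
}
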