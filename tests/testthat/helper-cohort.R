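# small cohort builders used across test files; everything is generated in
# code, no fixtures on disk

small_config <- function(seed = 1, ...) {
  args <- list(n_case_families = 5, n_control = 40, n_genes = 10,
               sites_per_gene = 5, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# hand-built cohort with fully known genotypes, for oracle-style tests:
# n_case families of two sibs + n_control controls, genotypes supplied as a
# samples x variants matrix
manual_cohort <- function(variants, geno, n_case_fam, n_control,
                          coverage = NULL) {
  fam <- sprintf("FAM%02d", seq_len(n_case_fam))
  ids <- c(as.vector(t(outer(fam, c("_P", "_S"), paste0))),
           if (n_control > 0) sprintf("CTL%03d", seq_len(n_control)))
  manifest <- data.frame(
    sample_id = ids,
    family_id = c(rep(fam, each = 2), rep("CONTROLS", n_control)),
    phenotype = c(rep("case", 2 * n_case_fam), rep("control", n_control)),
    ancestry = "pop1",
    is_proband = c(rep(c(1L, 0L), n_case_fam), rep(0L, n_control)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(geno) == length(ids))
  dimnames(geno) <- list(ids, variants$variant_id)
  if (is.null(coverage)) {
    coverage <- data.frame(variant_id = variants$variant_id,
                           frac_case_ge10x = rep(0.99, nrow(variants)),
                           frac_control_ge10x = rep(0.99, nrow(variants)),
                           stringsAsFactors = FALSE)
  }
  rarecollapse:::new_rv_cohort(variants, geno, manifest, coverage)
}

# a variant annotation row builder with sensible defaults
vrow <- function(variant_id, gene, effect = "ptv", polyphen = NA_character_,
                 revel = NA_real_, gnomad_af = 0, exac_af = 0,
                 chrom = "1", pos = 100) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             ref = "A", alt = "T", gene = gene, effect = effect,
             polyphen = polyphen, revel = revel,
             gnomad_af = gnomad_af, exac_af = exac_af,
             stringsAsFactors = FALSE)
}
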