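#' Read a multi-sample VCF into a variant table and dose matrix
#'
#' Parses a VCF v4.x with a GT field (via \pkg{vcfR}), decomposing
#' multi-allelic sites into one row per (site, alternate allele). Diploid
#' genotypes are mapped to the allele-dose codes 0/1/2 for each alternate
#' allele separately; missing genotypes (`./.` or `.`) map to `NA`.
#'
#' @param path path to an uncompressed or gzipped VCF.
#' @param allow_haploid if `TRUE`, single-allele (hemizygous) genotypes are
#'   accepted and coded on the 0/2 dose scale; the default is an error for
#'   any non-diploid genotype.
#' @return list with `variants` (data frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`) and `geno` (sample x variant integer dose matrix).
#' @export
read_vcf <- function(path, allow_haploid = FALSE) {
  stop_if(!file.exists(path), "no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(list(variants = data.frame(variant_id = character(),
                                      chrom = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      stringsAsFactors = FALSE),
                geno = matrix(integer(), 0, 0)))
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)

  ## split each GT into its alleles; validate ploidy
  alleles <- strsplit(as.vector(gt_raw), "[/|]")
  nal <- lengths(alleles)
  missing_gt <- vapply(alleles, function(a) {
    length(a) == 0 || any(is.na(a)) || any(a == ".")
  }, TRUE)
  bad <- !missing_gt & nal != 2
  if (any(bad) && !allow_haploid) {
    stop("non-diploid genotype(s) found (e.g. '",
         gt_raw[which(bad)[1]], "'); set allow_haploid = TRUE to accept",
         call. = FALSE)
  }

  rows <- list(); doses <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    idx <- (seq_along(samples) - 1) * nrow(fix) + i   # gt_raw is site x sample
    al <- alleles[idx]
    miss <- missing_gt[idx]
    for (k in seq_along(alts)) {
      d <- vapply(al, function(a) sum(a == as.character(k)), 0L)
      if (allow_haploid) d <- ifelse(nal[idx] == 1, d * 2L, d)
      d[miss] <- NA_integer_
      id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") {
        if (length(alts) > 1) paste0(fix$ID[i], "_alt", k) else fix$ID[i]
      } else {
        paste(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k], sep = ":")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = id, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], stringsAsFactors = FALSE)
      doses[[length(doses) + 1L]] <- d
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(cbind, doses)
  dimnames(geno) <- list(samples, variants$variant_id)
  list(variants = variants, geno = geno)
}

read_tsv <- function(path, what) {
  stop_if(!file.exists(path), "no such file: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read a variant annotation table
#'
#' Tab-separated, columns `variant_id`, `gene`, `effect`, `polyphen`,
#' `revel`, `gnomad_af`, `exac_af`. Empty `revel`/`polyphen` fields are kept
#' as missing values with the row retained.
#'
#' @param path path to the TSV.
#' @return typed data frame.
#' @export
read_annotations <- function(path) {
  ann <- read_tsv(path)
  check_columns(ann, c("variant_id", "gene", "effect", "polyphen", "revel",
                       "gnomad_af", "exac_af"), "annotation table")
  bad <- setdiff(unique(ann$effect), EFFECT_CLASSES)
  stop_if(length(bad) > 0, "unknown effect class(es): ",
          paste(bad, collapse = ", "))
  ann$revel <- as.numeric(ann$revel)
  ann$gnomad_af <- as.numeric(ann$gnomad_af)
  ann$exac_af <- as.numeric(ann$exac_af)
  stop_if(any(stats::na.omit(c(ann$gnomad_af, ann$exac_af)) < 0) ||
          any(stats::na.omit(c(ann$gnomad_af, ann$exac_af)) > 1),
          "external allele frequencies must lie in [0, 1]")
  ann
}

#' Read a per-site coverage table
#'
#' Tab-separated, columns `variant_id`, `frac_case_ge10x`,
#' `frac_control_ge10x`: the fraction of cases / controls with at least
#' 10-fold read depth at the site.
#'
#' @param path path to the TSV.
#' @return typed data frame with fractions validated to `[0, 1]`.
#' @export
read_coverage <- function(path) {
  cov <- read_tsv(path)
  check_columns(cov, c("variant_id", "frac_case_ge10x", "frac_control_ge10x"),
                "coverage table")
  cov$frac_case_ge10x <- as.numeric(cov$frac_case_ge10x)
  cov$frac_control_ge10x <- as.numeric(cov$frac_control_ge10x)
  fr <- c(cov$frac_case_ge10x, cov$frac_control_ge10x)
  stop_if(any(is.na(fr)) || any(fr < 0 | fr > 1),
          "coverage fractions must lie in [0, 1]")
  cov
}

#' Read a sample manifest
#'
#' Tab-separated, columns `sample_id`, `family_id`, `phenotype`
#' (`case`/`control`), `ancestry`, `is_proband` (0/1). Sample ids must be
#' unique; unknown ancestry is preserved as its own label.
#'
#' @param path path to the TSV.
#' @return typed data frame.
#' @export
read_manifest <- function(path) {
  man <- read_tsv(path)
  check_columns(man, c("sample_id", "family_id", "phenotype", "ancestry",
                       "is_proband"), "manifest")
  stop_if(anyDuplicated(man$sample_id) > 0, "duplicate sample_id in manifest")
  bad <- setdiff(unique(man$phenotype), c("case", "control"))
  stop_if(length(bad) > 0, "phenotype must be 'case' or 'control'")
  man$ancestry[is.na(man$ancestry)] <- "unknown"
  man$is_proband <- as.integer(man$is_proband)
  man
}

#' Read a cohort directory
#'
#' Assembles an `rv_cohort` from the file set written by [write_cohort()]:
#' `cohort.vcf`, `annotations.tsv`, `coverage.tsv`, `manifest.tsv`.
#' Genotype columns are aligned to the annotation table and rows to the
#' manifest; every annotated variant must be present in the VCF and vice
#' versa.
#'
#' @param dir directory containing the four files.
#' @return an `rv_cohort`.
#' @export
read_cohort <- function(dir) {
  vc <- read_vcf(file.path(dir, "cohort.vcf"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  cov <- read_coverage(file.path(dir, "coverage.tsv"))
  man <- read_manifest(file.path(dir, "manifest.tsv"))

  stop_if(!setequal(ann$variant_id, vc$variants$variant_id),
          "annotation table and VCF disagree on variant ids")
  stop_if(!setequal(man$sample_id, rownames(vc$geno)),
          "manifest and VCF disagree on sample ids")
  variants <- cbind(
    vc$variants[match(ann$variant_id, vc$variants$variant_id),
                c("variant_id", "chrom", "pos", "ref", "alt")],
    ann[, c("gene", "effect", "polyphen", "revel", "gnomad_af", "exac_af")])
  rownames(variants) <- NULL
  geno <- vc$geno[man$sample_id, ann$variant_id, drop = FALSE]
  cov <- cov[match(ann$variant_id, cov$variant_id), , drop = FALSE]
  rownames(cov) <- NULL
  new_rv_cohort(variants, geno, man, cov)
}

#' One case per family: the analyzed sample set
#'
#' Cases from the same multiplex family are genetically related, which would
#' distort a test built on unrelated carriers; the manifest is therefore
#' pruned to exactly one case per `family_id`. Within a family, the
#' lowest-sorted sample flagged `is_proband = 1` is kept; if no case in the
#' family carries the flag, the lowest-sorted case is kept. All controls are
#' retained. The operation is deterministic and idempotent.
#'
#' @param manifest a sample manifest data frame.
#' @return the manifest restricted to analyzed samples (original row order).
#' @export
#' @examples
#' m <- data.frame(sample_id = c("a", "b", "c"),
#'                 family_id = c("F1", "F1", "CTL"),
#'                 phenotype = c("case", "case", "control"),
#'                 ancestry = "pop1", is_proband = c(0, 1, 0))
#' prune_one_case_per_family(m)$sample_id  # "b", "c"
prune_one_case_per_family <- function(manifest) {
  check_columns(manifest, c("sample_id", "family_id", "phenotype", "is_proband"),
                "manifest")
  cases <- manifest[manifest$phenotype == "case", , drop = FALSE]
  keep_case <- vapply(split(cases, cases$family_id), function(fam) {
    pro <- fam$sample_id[fam$is_proband == 1]
    if (length(pro) > 0) min(pro) else min(fam$sample_id)
  }, "")
  keep <- manifest$phenotype == "control" | manifest$sample_id %in% keep_case
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
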