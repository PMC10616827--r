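#' Qualifying-variant model
#'
#' A qualifying-variant (QV) model is the rule set that decides which variants
#' count toward a sample's per-gene carrier state: an inheritance mode, a
#' functional-class restriction, optional missense deleteriousness gates
#' (PolyPhen "probably damaging" or a REVEL score threshold), an internal
#' leave-one-out allele-frequency ceiling and an external reference
#' (gnomAD/ExAC) allele-frequency ceiling.
#'
#' At most one of `revel_min` / `polyphen_required` is active in any of the
#' built-in models; custom models may combine them (both gates then apply to
#' missense variants).
#'
#' @param name model label.
#' @param inheritance `"dominant"` (carrier = at least one qualifying variant)
#'   or `"compound_het"` (carrier = two qualifying alleles in the gene).
#' @param function_class `"synonymous"`, `"all_functional"` (missense,
#'   inframe indel, PTV) or `"ptv"`.
#' @param revel_min REVEL threshold applied to missense variants (strict
#'   `>`), or `NA` for no REVEL gate.
#' @param polyphen_required if `TRUE`, missense variants must be PolyPhen
#'   "probably damaging". Applies to missense only: PTVs and inframe indels
#'   pass a damaging gate regardless.
#' @param loo_af_max ceiling on the internal leave-one-out allele frequency.
#' @param external_af_max ceiling on both gnomAD and ExAC allele frequencies
#'   (0 means absent from both).
#' @return an object of class `qv_model`.
#' @seealso [builtin_models()], [variant_qualifies()], [sample_gene_state()]
#' @export
qv_model <- function(name, inheritance = c("dominant", "compound_het"),
                     function_class = c("all_functional", "synonymous", "ptv"),
                     revel_min = NA_real_, polyphen_required = FALSE,
                     loo_af_max, external_af_max) {
  inheritance <- match.arg(inheritance)
  function_class <- match.arg(function_class)
  stop_if(!is.numeric(loo_af_max) || loo_af_max < 0 || loo_af_max > 1,
          "loo_af_max must lie in [0, 1]")
  stop_if(!is.numeric(external_af_max) || external_af_max < 0 || external_af_max > 1,
          "external_af_max must lie in [0, 1]")
  structure(
    list(name = name, inheritance = inheritance,
         function_class = function_class,
         revel_min = as.numeric(revel_min),
         polyphen_required = isTRUE(polyphen_required),
         loo_af_max = loo_af_max, external_af_max = external_af_max),
    class = "qv_model")
}

#' @export
#' @method print qv_model
print.qv_model <- function(x, ...) {
  gate <- if (!is.na(x$revel_min)) sprintf("REVEL > %g", x$revel_min)
          else if (x$polyphen_required) "PolyPhen probably damaging"
          else "none"
  cat(sprintf(
    "qualifying-variant model '%s'\n  inheritance: %s\n  function:    %s\n  missense gate: %s\n  leave-one-out AF <= %g; external (gnomAD/ExAC) AF <= %g\n",
    x$name, x$inheritance, x$function_class, gate,
    x$loo_af_max, x$external_af_max))
  invisible(x)
}

#' The nine built-in qualifying-variant models
#'
#' Returns the nine standard model definitions used for the collapsing
#' analysis: a synonymous negative-control model, an ultra-rare model
#' (leave-one-out AF <= 0.0005, absent from gnomAD and ExAC), rare-damaging
#' models gated by REVEL or PolyPhen, three "flexible" rare models
#' (AF <= 0.001) with and without deleteriousness gates, a
#' protein-truncating-variant model, and an autosomal recessive
#' (compound-heterozygote) model.
#'
#' @return a named list of nine [qv_model()] objects.
#' @export
#' @examples
#' names(builtin_models())
#' builtin_models()$ultra_rare
builtin_models <- function() {
  list(
    synonymous = qv_model("synonymous", "dominant", "synonymous",
                          loo_af_max = 0.0005, external_af_max = 0),
    ultra_rare = qv_model("ultra_rare", "dominant", "all_functional",
                          polyphen_required = TRUE,
                          loo_af_max = 0.0005, external_af_max = 0),
    rare_damaging_revel = qv_model("rare_damaging_revel", "dominant",
                                   "all_functional", revel_min = 0.5,
                                   loo_af_max = 0.0005, external_af_max = 0.00005),
    rare_damaging_polyphen = qv_model("rare_damaging_polyphen", "dominant",
                                      "all_functional", polyphen_required = TRUE,
                                      loo_af_max = 0.0005, external_af_max = 0.00005),
    flexible_revel = qv_model("flexible_revel", "dominant", "all_functional",
                              revel_min = 0.5,
                              loo_af_max = 0.001, external_af_max = 0.001),
    flexible_polyphen = qv_model("flexible_polyphen", "dominant", "all_functional",
                                 polyphen_required = TRUE,
                                 loo_af_max = 0.001, external_af_max = 0.001),
    flexible_no_score = qv_model("flexible_no_score", "dominant", "all_functional",
                                 loo_af_max = 0.001, external_af_max = 0.001),
    ptv = qv_model("ptv", "dominant", "ptv",
                   loo_af_max = 0.001, external_af_max = 0.001),
    recessive = qv_model("recessive", "compound_het", "all_functional",
                         loo_af_max = 0.01, external_af_max = 0.01)
  )
}

resolve_models <- function(models) {
  if (inherits(models, "qv_model")) return(stats::setNames(list(models), models$name))
  if (is.character(models)) {
    bm <- builtin_models()
    if (identical(models, "all")) return(bm)
    unknown <- setdiff(models, names(bm))
    stop_if(length(unknown) > 0,
            "unknown built-in model(s): ", paste(unknown, collapse = ", "))
    return(bm[models])
  }
  stop_if(!is.list(models) || !all(vapply(models, inherits, TRUE, "qv_model")),
          "models must be a qv_model, a list of qv_model, or model names")
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Leave-one-out internal allele frequency
#'
#' Frequency of a variant allele in the combined case+control cohort
#' excluding the two alleles of the sample being evaluated: `(AC - dose) /
#' (AN - 2)`. A singleton evaluated in its own carrier therefore has
#' leave-one-out frequency 0, while the same site evaluated in a non-carrier
#' retains its full internal frequency — the asymmetry that lets a carrier of
#' a genuinely ultra-rare allele qualify while common alleles are excluded
#' for everyone.
#'
#' @param ac internal allele count (copies of the alternate allele among
#'   genotyped samples).
#' @param an internal allele number (2 x number of genotyped samples).
#' @param dose the evaluated sample's allele dose (0, 1 or 2).
#' @return the leave-one-out allele frequency.
#' @export
#' @examples
#' leave_one_out_af(1, 18072, 1)      # singleton carrier -> 0
#' leave_one_out_af(10, 18072, 1)     # 9/18070
leave_one_out_af <- function(ac, an, dose) {
  stop_if(any(dose < 0 | dose > 2), "dose must be 0, 1 or 2")
  stop_if(any(ac < dose), "allele count cannot be smaller than the sample's dose")
  stop_if(any(an <= 2), "allele number must exceed 2")
  (ac - dose) / (an - 2)
}

## Sample-independent part of the model filter: functional class, missense
## deleteriousness gates, external AF ceilings. Returns a logical per variant.
annotation_gate <- function(variants, model) {
  eff <- variants$effect
  ok <- switch(model$function_class,
    synonymous = eff == "synonymous",
    ptv        = eff == "ptv",
    all_functional = eff %in% c("missense", "inframe_indel", "ptv"))
  is_mis <- eff == "missense"
  if (model$polyphen_required) {
    pp <- variants$polyphen
    ok <- ok & (!is_mis | (!is.na(pp) & pp == "probably_damaging"))
  }
  if (!is.na(model$revel_min)) {
    rv <- variants$revel
    ok <- ok & (!is_mis | (!is.na(rv) & rv > model$revel_min))
  }
  ext <- pmax(ifelse(is.na(variants$gnomad_af), 0, variants$gnomad_af),
              ifelse(is.na(variants$exac_af), 0, variants$exac_af))
  ok & ext <= model$external_af_max
}

#' Does a variant qualify under a model?
#'
#' Applies the full qualifying-variant filter for one or more variants given
#' their leave-one-out allele frequencies: the internal AF ceiling, the
#' external (gnomAD and ExAC, jointly) ceiling, the functional-class
#' restriction, and any missense deleteriousness gate. A missense variant
#' lacking the score a gated model requires does not qualify (no error).
#'
#' @param variants a data frame of variant annotations with columns
#'   `effect`, `polyphen`, `revel`, `gnomad_af`, `exac_af`.
#' @param loo_af leave-one-out allele frequency (recycled against rows of
#'   `variants`), as from [leave_one_out_af()].
#' @param model a [qv_model()].
#' @return logical vector, one element per variant row.
#' @export
variant_qualifies <- function(variants, loo_af, model) {
  stopifnot(inherits(model, "qv_model"))
  check_columns(variants, c("effect", "polyphen", "revel", "gnomad_af", "exac_af"),
                "variant table")
  annotation_gate(variants, model) & loo_af <= model$loo_af_max
}

#' Per-sample per-gene carrier state
#'
#' Collapses a sample's doses over a gene's qualifying variants to the 0/1
#' carrier indicator. Dominant models: state 1 iff at least one qualifying
#' variant is carried (dose >= 1). Compound-heterozygote models: state 1 iff
#' two qualifying alleles are present — at least two distinct qualifying
#' variants each with dose >= 1 (assumed in trans, the standard unphased
#' approximation) or one qualifying variant homozygous (dose 2). Missing
#' genotypes count as dose 0.
#'
#' @param doses integer vector of allele doses over the gene's qualifying
#'   variants for one sample (`NA` = missing).
#' @param model a [qv_model()].
#' @return 0 or 1.
#' @export
#' @examples
#' m <- builtin_models()
#' sample_gene_state(c(0, 1), m$ultra_rare)  # 1
#' sample_gene_state(1, m$recessive)         # 0: one het allele
#' sample_gene_state(2, m$recessive)         # 1: homozygous counts as biallelic
sample_gene_state <- function(doses, model) {
  stopifnot(inherits(model, "qv_model"))
  doses[is.na(doses)] <- 0L
  if (model$inheritance == "dominant") {
    as.integer(any(doses >= 1))
  } else {
    as.integer(sum(doses >= 1) >= 2 || any(doses == 2))
  }
}

## Engine: qualifying (sample, variant) pairs over the analyzed cohort.
## Returns a data.frame sample_id / variant_id / gene / dose restricted to
## carriers of annotation-passing variants whose leave-one-out AF passes.
## AC/AN are computed on the analyzed samples only (the combined internal
## case+control test population); samples with a missing genotype at a site
## contribute nothing to AN there and are treated as dose 0.
qualifying_pairs <- function(geno, variants, model) {
  stopifnot(is.matrix(geno), nrow(variants) == ncol(geno))
  ann <- annotation_gate(variants, model)
  if (!any(ann)) {
    return(data.frame(sample_id = character(), variant_id = character(),
                      gene = character(), dose = integer(),
                      stringsAsFactors = FALSE))
  }
  g <- geno[, ann, drop = FALSE]
  v <- variants[ann, , drop = FALSE]
  ac <- colSums(g, na.rm = TRUE)
  an <- 2L * colSums(!is.na(g))
  idx <- which(g > 0, arr.ind = TRUE)   # NA never satisfies > 0
  if (nrow(idx) == 0) {
    return(data.frame(sample_id = character(), variant_id = character(),
                      gene = character(), dose = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- g[idx]
  denom <- an[idx[, 2]] - 2
  num <- ac[idx[, 2]] - d
  loo <- ifelse(denom > 0, num / denom, ifelse(num == 0, 0, 1))
  keep <- loo <= model$loo_af_max
  data.frame(sample_id = rownames(g)[idx[keep, 1]],
             variant_id = v$variant_id[idx[keep, 2]],
             gene = v$gene[idx[keep, 2]],
             dose = as.integer(d[keep]),
             stringsAsFactors = FALSE)
}

#' Carrier-state matrix for one model
#'
#' Evaluates the qualifying-variant filter for every analyzed sample at every
#' variant and collapses to the sample x gene 0/1 carrier-state matrix used
#' by the collapsing test. Internal allele counts for the leave-one-out
#' frequency are computed over the supplied (analyzed) samples only.
#'
#' @param geno sample x variant integer dose matrix (rownames = sample ids,
#'   colnames = variant ids; `NA` = missing genotype, treated as dose 0 for
#'   carrier status and excluded from the internal allele number).
#' @param variants variant annotation data frame (rows aligned with `geno`
#'   columns) with columns `variant_id`, `gene`, `effect`, `polyphen`,
#'   `revel`, `gnomad_af`, `exac_af`.
#' @param model a [qv_model()].
#' @param genes optional character vector fixing the gene set (and column
#'   order); defaults to the genes present in `variants`.
#' @return logical matrix, samples x genes: `TRUE` where the sample is a
#'   carrier under the model.
#' @export
carrier_states <- function(geno, variants, model, genes = NULL) {
  genes <- genes %||% sort(unique(variants$gene))
  states <- matrix(FALSE, nrow(geno), length(genes),
                   dimnames = list(rownames(geno), genes))
  qp <- qualifying_pairs(geno, variants, model)
  if (nrow(qp) == 0) return(states)
  if (model$inheritance == "dominant") {
    carrier <- unique(qp[, c("sample_id", "gene")])
  } else {
    key <- paste(qp$sample_id, qp$gene, sep = "\r")
    nvar <- tapply(qp$variant_id, key, function(v) length(unique(v)))
    hom <- tapply(qp$dose, key, max) == 2
    ok <- names(nvar)[nvar >= 2 | hom]
    if (length(ok) == 0) return(states)
    parts <- strsplit(ok, "\r", fixed = TRUE)
    carrier <- data.frame(sample_id = vapply(parts, `[`, "", 1),
                          gene = vapply(parts, `[`, "", 2))
  }
  states[cbind(match(carrier$sample_id, rownames(geno)),
               match(carrier$gene, genes))] <- TRUE
  states
}
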