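#' Genotype features for ancestry inference
#'
#' Builds per-sample feature vectors from common variation: variants with
#' combined-cohort alternate-allele frequency at or above `min_af` are
#' mean-imputed, centered, scaled, and reduced to the top principal axes.
#' Rare variation is deliberately excluded — ancestry signal lives in common
#' allele-frequency differentiation.
#'
#' @param geno sample x variant dose matrix.
#' @param min_af minimum combined-cohort allele frequency (default 0.05).
#' @param k number of principal axes retained (default 10).
#' @return numeric matrix, samples x `min(k, available axes)`, with
#'   per-axis variance shares in attribute `"var_share"`.
#' @export
genotype_features <- function(geno, min_af = 0.05, k = 10) {
  af <- colSums(geno, na.rm = TRUE) / (2 * colSums(!is.na(geno)))
  common <- which(!is.na(af) & af >= min_af & af <= 1 - min_af)
  stop_if(length(common) == 0, "no variants with AF >= min_af")
  g <- geno[, common, drop = FALSE]
  ## mean-impute missing doses, then center/scale each variant
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- mu[na_idx[, 2]]
  }
  sds <- apply(g, 2, stats::sd)
  g <- g[, sds > 0, drop = FALSE]
  stop_if(ncol(g) == 0, "no polymorphic common variants")
  pc <- stats::prcomp(g, center = TRUE, scale. = TRUE)
  k <- min(k, ncol(pc$x))
  out <- pc$x[, seq_len(k), drop = FALSE]
  attr(out, "var_share") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Embed and cluster samples by genetic ancestry
#'
#' Projects the genotype features to a 2-d embedding (the two leading
#' principal axes) and assigns every sample to an ancestry cluster with a
#' Gaussian-mixture model (\pkg{mclust}), the number of clusters selected by
#' BIC over `1:max_clusters`. The procedure is deterministic given `seed`;
#' every sample receives a label, labels are contiguous from 0 and ordered
#' by decreasing cluster size.
#'
#' @param features feature matrix from [genotype_features()].
#' @param seed integer seed.
#' @param max_clusters largest number of clusters considered.
#' @return an object of class `ancestry_clustering`: list with `cluster`
#'   (named integer vector, 0-based), `n_clusters`, `embedding` (samples x
#'   2) and `seed`.
#' @export
embed_and_cluster <- function(features, seed = 1, max_clusters = 10) {
  stopifnot(is.matrix(features))
  stop_if(nrow(features) < 2, "need at least two samples")
  emb <- features[, seq_len(min(2, ncol(features))), drop = FALSE]
  if (ncol(emb) == 1) emb <- cbind(emb, 0)
  colnames(emb) <- c("dim1", "dim2")
  fit <- with_seed(seed, {
    bic <- mclust::mclustBIC(emb, G = seq_len(min(max_clusters, nrow(emb))),
                             verbose = FALSE)
    mclust::Mclust(emb, x = bic, verbose = FALSE)
  })
  cl <- fit$classification
  ## relabel 0-based by decreasing size
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cl <- relabel[as.character(cl)]
  names(cl) <- rownames(features)
  structure(list(cluster = cl, n_clusters = length(sizes),
                 embedding = emb, seed = seed),
            class = "ancestry_clustering")
}

#' @export
#' @method print ancestry_clustering
print.ancestry_clustering <- function(x, ...) {
  cat(sprintf("ancestry clustering: %d samples in %d cluster(s)\n",
              length(x$cluster), x$n_clusters))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Cluster-size table for an ancestry clustering
#'
#' Tabulates cases and controls per ancestry cluster (the shape used to pick
#' a matched-comparison cluster).
#'
#' @param clustering an `ancestry_clustering`.
#' @param manifest the sample manifest.
#' @return data frame with `cluster`, `n_cases`, `n_controls`.
#' @export
cluster_sizes <- function(clustering, manifest) {
  pheno <- manifest$phenotype[match(names(clustering$cluster),
                                    manifest$sample_id)]
  tab <- table(cluster = clustering$cluster, phenotype = pheno)
  out <- data.frame(cluster = as.integer(rownames(tab)),
                    n_cases = as.integer(if ("case" %in% colnames(tab))
                      tab[, "case"] else 0),
                    n_controls = as.integer(if ("control" %in% colnames(tab))
                      tab[, "control"] else 0))
  rownames(out) <- NULL
  out[order(out$cluster), ]
}

#' Ancestry-filtered collapsing rerun
#'
#' Restricts the cohort to the members of one ancestry cluster and reruns
#' the full collapsing analysis there — qualifying-variant evaluation
#' (internal leave-one-out allele frequencies recomputed within the
#' restricted cohort), carrier collapsing, Fisher exact test and odds
#' ratio. This is the matched-ancestry comparison that guards the primary
#' scan against population stratification.
#'
#' @param cohort an `rv_cohort`.
#' @param clustering an `ancestry_clustering` over (a superset of) the
#'   cohort samples.
#' @param cluster_id cluster label to analyze.
#' @param ... further arguments to [collapsing_scan()] (models, coverage
#'   config, multiplicity settings).
#' @return a [collapsing_scan()] over the cluster members only.
#' @export
filtered_analysis <- function(cohort, clustering, cluster_id, ...) {
  stopifnot(inherits(cohort, "rv_cohort"),
            inherits(clustering, "ancestry_clustering"))
  members <- names(clustering$cluster)[clustering$cluster == cluster_id]
  stop_if(length(members) == 0, "no samples in cluster ", cluster_id)
  keep <- cohort$manifest$sample_id %in% members
  manifest <- cohort$manifest[keep, , drop = FALSE]
  rownames(manifest) <- NULL
  stop_if(!any(manifest$phenotype == "case"),
          "cluster ", cluster_id, " contains no cases")
  stop_if(!any(manifest$phenotype == "control"),
          "cluster ", cluster_id, " contains no controls")
  sub <- new_rv_cohort(cohort$variants,
                       cohort$geno[manifest$sample_id, , drop = FALSE],
                       manifest, cohort$coverage, cohort$config)
  collapsing_scan(sub, ...)
}
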