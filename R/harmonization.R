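#' Keep clinical rows of one sample type
#'
#' TCGA barcodes carry a sample type code; `"01"` denotes primary solid
#' tumor, `"11"` solid tissue normal. Only the requested code is retained.
#'
#' @param clinical A [clinical_table()].
#' @param code Sample type code to keep, default `"01"`.
#' @return The filtered clinical table (possibly empty, with a warning).
#' @export
filter_sample_type <- function(clinical, code = "01") {
  if (is.null(clinical$sample_type_code)) {
    stopf("clinical table has no sample_type_code column")
  }
  keep <- clinical$sample_type_code == code
  out <- clinical[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warnf("no samples with sample_type_code == \"%s\"", code)
  }
  rownames(out) <- NULL
  out
}

#' Remove genes with too many missing values
#'
#' A gene row is dropped when its missing fraction exceeds
#' `max_missing_frac` (strictly greater than, so a gene missing in exactly
#' 5% of samples is kept at the default). Residual missing entries in the
#' surviving rows are imputed by the gene-row mean.
#'
#' @param layer An [omics_layer()].
#' @param max_missing_frac Maximum tolerated missing fraction, default 0.05.
#' @return The filtered, imputed layer.
#' @export
filter_missing <- function(layer, max_missing_frac = 0.05) {
  stopifnot(inherits(layer, "omics_layer"))
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    stopf("max_missing_frac must be in [0, 1]")
  }
  v <- layer$values
  miss_frac <- rowMeans(is.na(v))
  v <- v[miss_frac <= max_missing_frac, , drop = FALSE]
  if (anyNA(v)) {
    means <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- means[idx[, 1]]
  }
  out <- layer
  out$values <- v
  out
}

#' Expression-level abundance filters for GE and ME layers
#'
#' Gene expression rows are kept when the value exceeds 0 in more than 50%
#' of samples; miRNA expression rows when the value exceeds 1 in more than
#' 10% of samples (strict inequalities). Other layer kinds pass through
#' unchanged.
#'
#' @param layer An [omics_layer()].
#' @return The filtered layer.
#' @export
filter_expression <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  v <- layer$values
  n <- ncol(v)
  keep <- switch(layer$kind,
    GE = rowSums(v > 0, na.rm = TRUE) > 0.5 * n,
    ME = rowSums(v > 1, na.rm = TRUE) > 0.1 * n,
    rep(TRUE, nrow(v))
  )
  out <- layer
  out$values <- v[keep, , drop = FALSE]
  out
}

#' Average duplicate probe rows into one gene row
#'
#' When several probes report the same gene in a sample, the final signal is
#' their per-sample arithmetic mean. Gene order of first appearance is kept.
#'
#' @param layer An [omics_layer()].
#' @return A layer with unique gene ids.
#' @export
aggregate_duplicates <- function(layer) {
  stopifnot(inherits(layer, "omics_layer"))
  ids <- gene_ids(layer)
  if (!anyDuplicated(ids)) return(layer)
  v <- layer$values
  uniq <- unique(ids)
  agg <- rowsum(v, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  agg <- agg[uniq, , drop = FALSE]
  out <- layer
  out$values <- agg
  out
}

#' Map miRNA expression onto target genes
#'
#' miRNAs repress their mRNA targets, so miRNA expression is attributed to
#' genes through a curated interaction table. Interactions are first filtered
#' to those with at least `min_experiments` supporting experiments and
#' anti-correlation observed in at least `min_anticorr` cancer types. Each
#' target gene with at least one surviving interaction whose miRNA is present
#' in the matrix receives the per-sample mean over its bound miRNAs; genes
#' with no surviving interaction are absent from the output.
#'
#' @param me An [omics_layer()] of kind `"ME"` with miRNA ids as rows.
#' @param interactions data.frame with columns `mirna_id`, `gene_id`,
#'   `n_experiments`, `n_anticorrelated_cancers`.
#' @param min_experiments Minimum supporting experiments, default 5.
#' @param min_anticorr Minimum anti-correlated cancer types, default 1.
#' @return An `"ME"` layer keyed by gene ids.
#' @export
map_mirna_to_genes <- function(me, interactions, min_experiments = 5,
                               min_anticorr = 1) {
  stopifnot(inherits(me, "omics_layer"))
  if (me$kind != "ME") stopf("map_mirna_to_genes expects an ME layer")
  need <- c("mirna_id", "gene_id", "n_experiments", "n_anticorrelated_cancers")
  if (!all(need %in% names(interactions))) {
    stopf("interaction table needs columns: %s", paste(need, collapse = ", "))
  }
  keep <- interactions$n_experiments >= min_experiments &
    interactions$n_anticorrelated_cancers >= min_anticorr
  ints <- interactions[keep, , drop = FALSE]
  if (nrow(ints) == 0) {
    stopf(paste0("no interactions survive the thresholds ",
                 "(min_experiments = %d, min_anticorr = %d)"),
          min_experiments, min_anticorr)
  }
  ints <- ints[ints$mirna_id %in% gene_ids(me), , drop = FALSE]
  if (nrow(ints) == 0) {
    stopf("no surviving interaction names a miRNA present in the matrix")
  }
  groups <- split(ints$mirna_id, ints$gene_id)
  vals <- t(vapply(groups, function(mirs) {
    colMeans(me$values[unique(mirs), , drop = FALSE])
  }, numeric(ncol(me$values))))
  colnames(vals) <- sample_ids(me)
  omics_layer(vals, "ME")
}

#' Z-score normalize an omics layer
#'
#' Transforms every entry by `(x - mu) / sigma` where `mu` and `sigma` are
#' the mean and standard deviation of the entire matrix (global
#' standardization; a per-gene variant is available via `scope`). Values are
#' then rounded half-to-even at the fourth decimal place so all layers carry
#' a common, diff-stable precision.
#'
#' Global (whole-matrix) scope is the default: per-gene centering would
#' force every gene's mean to zero and with it the mean risk score GS of
#' every gene towards zero, collapsing the Score ranking to the bare vote
#' count.
#'
#' @param layer An [omics_layer()].
#' @param scope `"global"` (default) or `"per_gene"`.
#' @return The normalized layer, values rounded to 4 decimals.
#' @export
zscore_normalize <- function(layer, scope = c("global", "per_gene")) {
  stopifnot(inherits(layer, "omics_layer"))
  scope <- match.arg(scope)
  v <- layer$values
  if (scope == "global") {
    s <- stats::sd(as.vector(v))
    if (!is.finite(s) || s == 0) stopf("matrix standard deviation is zero")
    v <- (v - mean(v)) / s
  } else {
    mu <- rowMeans(v)
    s <- apply(v, 1, stats::sd)
    if (any(!is.finite(s)) || any(s == 0)) {
      stopf("zero standard deviation in %d gene row(s)", sum(s == 0))
    }
    v <- (v - mu) / s
  }
  out <- layer
  out$values <- round(v, 4)  # round() is half-to-even in R
  out
}

#' Align four omics layers and a clinical table on shared genes and samples
#'
#' The sample set is the intersection of all four layers' samples and the
#' clinical table; the gene set is the intersection of all four layers' gene
#' ids. Rows and columns are reordered identically across layers, and the
#' clinical rows follow the same sample order.
#'
#' @param layers Named list with elements `GE`, `SCNA`, `DM`, `ME`, each an
#'   [omics_layer()] of the matching kind (gene ids must be unique; run
#'   [aggregate_duplicates()] first).
#' @param clinical A [clinical_table()].
#' @return A [multi_omics_dataset()].
#' @export
align_dataset <- function(layers, clinical) {
  if (!setequal(names(layers), LAYER_KINDS)) {
    stopf("layers must be named %s", paste(LAYER_KINDS, collapse = ", "))
  }
  layers <- layers[LAYER_KINDS]
  samples <- Reduce(intersect, c(lapply(layers, sample_ids),
                                 list(clinical$sample_id)))
  if (length(samples) == 0) stopf("empty sample intersection")
  genes <- Reduce(intersect, lapply(layers, gene_ids))
  if (length(genes) == 0) stopf("empty gene intersection")
  message(sprintf("align_dataset: %d shared genes, %d shared samples",
                  length(genes), length(samples)))
  aligned <- lapply(layers, function(l) {
    out <- l
    out$values <- l$values[genes, samples, drop = FALSE]
    out
  })
  clin <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  multi_omics_dataset(aligned, clin)
}

#' Run the full harmonization chain on raw layers
#'
#' Applies, in order: sample-type filter on the clinical table, per-layer
#' missingness filter, GE/ME abundance filters, duplicate-probe averaging,
#' miRNA-to-gene mapping (when an interaction table is given), sample/gene
#' alignment, and z-score normalization.
#'
#' @param layers Named list of raw [omics_layer()]s (`GE`,`SCNA`,`DM`,`ME`).
#' @param clinical A [clinical_table()].
#' @param interactions Optional miRNA-mRNA interaction data.frame for
#'   [map_mirna_to_genes()]; `NULL` when the ME layer is already gene-keyed.
#' @param sample_type Sample type code to keep, default `"01"`.
#' @param max_missing_frac Missingness threshold, default 0.05.
#' @param zscore_scope `"global"` or `"per_gene"`.
#' @return A harmonized [multi_omics_dataset()].
#' @export
harmonize <- function(layers, clinical, interactions = NULL,
                      sample_type = "01", max_missing_frac = 0.05,
                      zscore_scope = "global") {
  clinical <- filter_sample_type(clinical, sample_type)
  layers <- lapply(layers, filter_missing, max_missing_frac = max_missing_frac)
  layers <- lapply(layers, filter_expression)
  layers <- lapply(layers, aggregate_duplicates)
  if (!is.null(interactions)) {
    layers$ME <- map_mirna_to_genes(layers$ME, interactions)
  }
  dataset <- align_dataset(layers, clinical)
  dataset$layers <- lapply(dataset$layers, zscore_normalize,
                           scope = zscore_scope)
  dataset
}
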