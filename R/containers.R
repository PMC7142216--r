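#' Construct an omics layer
#'
#' An omics layer is one molecular modality measured as a gene x sample
#' numeric matrix: gene expression (`"GE"`), somatic copy-number alteration
#' (`"SCNA"`), DNA methylation (`"DM"`), or miRNA expression (`"ME"`).
#' Rows are genes (or miRNAs/probes before harmonization), columns are
#' samples; row and column names carry the identifiers.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames. Duplicate sample ids are rejected; duplicate gene ids are
#'   allowed before [aggregate_duplicates()].
#' @param kind One of `"GE"`, `"SCNA"`, `"DM"`, `"ME"`.
#' @return An object of class `omics_layer`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' omics_layer(m, "GE")
omics_layer <- function(values, kind) {
  kind <- match.arg(kind, LAYER_KINDS)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("omics_layer values must have gene rownames and sample colnames")
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicate sample ids in %s layer: %s", kind,
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  }
  structure(list(kind = kind, values = values), class = "omics_layer")
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("<omics_layer %s> %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_layer <- function(x) dim(x$values)

gene_ids <- function(layer) rownames(layer$values)
sample_ids <- function(layer) colnames(layer$values)

#' Construct a clinical table
#'
#' Per-sample survival follow-up: observed time in days, event indicator
#' (1 = death observed, 0 = censored), optional age/sex covariates and the
#' TCGA-style sample type code (`"01"` = primary solid tumor).
#'
#' @param sample_id Character vector of unique sample ids.
#' @param time Positive follow-up times in days.
#' @param event 0/1 event indicators.
#' @param age,sex Optional covariates (not used by the scoring pipeline).
#' @param sample_type_code Character codes, default `"01"` for all samples.
#' @return A `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(sample_id, time, event, age = NA, sex = NA,
                           sample_type_code = "01") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicate sample ids in clinical table")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stopf("survival times must be positive and finite")
  }
  if (!all(event %in% c(0, 1))) stopf("event indicator must be 0/1")
  out <- data.frame(
    sample_id = sample_id,
    time = as.numeric(time),
    event = as.integer(event),
    age = rep_len(age, length(sample_id)),
    sex = rep_len(as.character(sex), length(sample_id)),
    sample_type_code = rep_len(as.character(sample_type_code),
                               length(sample_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Construct a multi-omics dataset
#'
#' Bundles four sample- and gene-aligned omics layers with a clinical table.
#' Use [align_dataset()] to build one from unaligned layers.
#'
#' @param layers Named list of four [omics_layer()] objects
#'   (`GE`, `SCNA`, `DM`, `ME`) sharing identical gene and sample id vectors.
#' @param clinical A [clinical_table()] whose rows match the layers' sample
#'   order.
#' @return An object of class `multi_omics_dataset`.
#' @export
multi_omics_dataset <- function(layers, clinical) {
  if (!setequal(names(layers), LAYER_KINDS)) {
    stopf("layers must be named %s", paste(LAYER_KINDS, collapse = ", "))
  }
  layers <- layers[LAYER_KINDS]
  ref_genes <- gene_ids(layers[[1]])
  ref_samples <- sample_ids(layers[[1]])
  for (l in layers) {
    if (!identical(gene_ids(l), ref_genes) ||
        !identical(sample_ids(l), ref_samples)) {
      stopf("all layers must share identical gene and sample id vectors")
    }
  }
  if (!identical(clinical$sample_id, ref_samples)) {
    stopf("clinical rows must match the layers' sample order")
  }
  structure(list(layers = layers, clinical = clinical),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf(
    "<multi_omics_dataset> %d genes x %d samples, %d events (%.0f%% censored)\n",
    nrow(x$layers$GE$values), ncol(x$layers$GE$values),
    sum(x$clinical$event), 100 * mean(x$clinical$event == 0)))
  invisible(x)
}

dataset_genes <- function(dataset) gene_ids(dataset$layers$GE)
dataset_samples <- function(dataset) sample_ids(dataset$layers$GE)

# n x 4 covariate matrix (GE, SCNA, DM, ME) for one gene.
gene_covariates <- function(dataset, gene, kinds = LAYER_KINDS) {
  out <- vapply(kinds, function(k) dataset$layers[[k]]$values[gene, ],
                numeric(length(dataset_samples(dataset))))
  colnames(out) <- kinds
  out
}
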