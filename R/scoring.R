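#' Univariate Cox screen with per-layer voting
#'
#' For every gene and each of the four omics layers, fits a univariate Cox
#' proportional-hazards model with that layer's values as the single
#' covariate. A gene is voted survival-related on a layer (flag 1) iff the
#' fit converged and the likelihood-ratio p-value is below `alpha`. The
#' flags A, B, C, D correspond to the GE, SCNA, DM and ME layers; the sign
#' of the per-layer coefficient is retained (beta > 0 marks a risk factor).
#'
#' Per-gene fit failures are never fatal: the gene is flagged 0 on that
#' layer.
#'
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param alpha Vote threshold on the likelihood-ratio p-value, default 0.05.
#' @param p_adjust `"none"` (default: raw per-test votes, as the Score
#'   procedure defines them) or `"BH"` to vote on Benjamini-Hochberg
#'   adjusted p-values within each layer.
#' @return A data.frame with one row per gene: `gene_id`, vote flags
#'   `A`,`B`,`C`,`D`, and per-layer `beta_<kind>` / `p_<kind>` columns
#'   (raw p-values are always reported).
#' @export
univariate_screen <- function(dataset, alpha = 0.05,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  genes <- dataset_genes(dataset)
  time <- dataset$clinical$time
  event <- dataset$clinical$event
  res <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (i in seq_along(LAYER_KINDS)) {
    k <- LAYER_KINDS[i]
    flag <- names(VOTE_FLAGS)[i]
    vals <- dataset$layers[[k]]$values
    betas <- rep(NA_real_, length(genes))
    ps <- rep(NA_real_, length(genes))
    votes <- integer(length(genes))
    for (g in seq_along(genes)) {
      fit <- tryCatch(fit_cox(vals[g, ], time, event), error = function(e) NULL)
      if (!is.null(fit) && fit$converged && is.finite(fit$p_lrt)) {
        betas[g] <- fit$beta
        ps[g] <- fit$p_lrt
      }
    }
    p_vote <- if (p_adjust == "BH") stats::p.adjust(ps, method = "BH") else ps
    votes <- as.integer(!is.na(p_vote) & p_vote < alpha)
    res[[flag]] <- votes
    res[[paste0("beta_", k)]] <- betas
    res[[paste0("p_", k)]] <- ps
  }
  res
}

#' Select candidate survival-related genes by vote count
#'
#' A gene is a candidate when it was voted survival-related in at least
#' `min_votes` of the four omics layers.
#'
#' @param votes Output of [univariate_screen()].
#' @param min_votes Minimum number of layer votes, default 2.
#' @return Character vector of candidate gene ids.
#' @export
select_candidates <- function(votes, min_votes = 2) {
  vote_sum <- votes$A + votes$B + votes$C + votes$D
  votes$gene_id[vote_sum >= min_votes]
}

#' Per-gene multivariate Cox fit across the four omics layers
#'
#' Fits `h(t | M) = h0(t) exp(b1 GE + b2 SCNA + b3 DM + b4 ME)` on one
#' gene's four layer vectors. The gene is retained only when the fit
#' converged and all three overall tests (likelihood ratio, Wald, score)
#' have p < `alpha`; otherwise a rejection record naming the failed test(s)
#' is returned.
#'
#' @param gene_id One gene id present in the dataset.
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param alpha Gate threshold for all three tests, default 0.05.
#' @param kinds Layers to include; the default is all four. Passing the
#'   voted subset gives the reduced fit of
#'   [score_variant_voted_layers_only()].
#' @return A list: `gene_id`, `retained` flag, `fit` (a `cox_fit`), `kinds`,
#'   and for rejections `failed` (character vector among
#'   `"convergence"`, `"lrt"`, `"wald"`, `"score"`).
#' @export
fit_multiomics <- function(gene_id, dataset, alpha = 0.05,
                           kinds = LAYER_KINDS) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  if (!gene_id %in% dataset_genes(dataset)) {
    stopf("gene %s not present in dataset", gene_id)
  }
  m <- gene_covariates(dataset, gene_id, kinds)
  fit <- tryCatch(
    fit_cox(m, dataset$clinical$time, dataset$clinical$event),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$beta)) {
    return(list(gene_id = gene_id, retained = FALSE, fit = fit,
                kinds = kinds, failed = "convergence"))
  }
  failed <- c("lrt", "wald", "score")[
    c(fit$p_lrt >= alpha, fit$p_wald >= alpha, fit$p_score >= alpha)]
  list(gene_id = gene_id, retained = length(failed) == 0, fit = fit,
       kinds = kinds, failed = failed)
}

#' Per-sample risk score RS = B . V
#'
#' Dot product of a gene's multivariate Cox coefficients with its per-sample
#' omics vectors: the gene's predicted log relative hazard for each patient.
#'
#' @param fit A `cox_fit` from [fit_multiomics()].
#' @param V n x p matrix of per-sample omics values, columns in the same
#'   layer order as the fit's coefficients.
#' @return Numeric vector of per-sample risk scores.
#' @export
compute_rs <- function(fit, V) {
  V <- as.matrix(V)
  if (ncol(V) != length(fit$beta)) {
    stopf("V has %d columns but the fit has %d coefficients",
          ncol(V), length(fit$beta))
  }
  drop(V %*% fit$beta)
}

#' Gene score GS: mean risk score over samples
#'
#' @param rs Per-sample risk scores from [compute_rs()].
#' @return `sum(rs) / m` where `m` is the number of samples.
#' @export
compute_gs <- function(rs) {
  if (length(rs) < 1) stopf("empty risk-score vector")
  mean(rs)
}

#' Ranking statistic Score = A + B + C + D + GS
#'
#' Combines the univariate vote count with the multivariate mean risk score.
#' Higher scores mark genes more relevant to survival.
#'
#' @param votes Numeric/integer vector of the four 0/1 vote flags
#'   (A, B, C, D), or a one-row slice of the [univariate_screen()] table.
#' @param gs The gene score from [compute_gs()].
#' @param abs_gs Use `|GS|` instead of the signed GS (sensitivity variant;
#'   the Score is defined on the signed value, the default).
#' @return The scalar Score.
#' @export
compute_score <- function(votes, gs, abs_gs = FALSE) {
  if (is.data.frame(votes)) votes <- unlist(votes[1, c("A", "B", "C", "D")])
  if (length(votes) != 4 || !all(votes %in% c(0, 1))) {
    stopf("votes must be four 0/1 flags")
  }
  sum(votes) + if (abs_gs) abs(gs) else gs
}

#' Score all candidate genes
#'
#' Runs the integration stage over the candidates: per-gene multivariate Cox
#' fit, triple-test gate, RS/GS/Score computation.
#'
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param votes Output of [univariate_screen()]; computed here when `NULL`.
#' @param alpha Screen and gate threshold, default 0.05.
#' @param min_votes Candidate vote threshold, default 2.
#' @return A list with `records` (data.frame: `gene_id`, `A`..`D`,
#'   `beta_GE`..`beta_ME` multivariate coefficients, `gs`, `score`, `p_lrt`,
#'   `p_wald`, `p_score`), `rejects` (data.frame: `gene_id`, `reason`),
#'   `votes`, and `rs` (sample x gene matrix of per-sample risk scores of
#'   the retained genes).
#' @export
score_genes <- function(dataset, votes = NULL, alpha = 0.05, min_votes = 2) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  if (is.null(votes)) votes <- univariate_screen(dataset, alpha)
  candidates <- select_candidates(votes, min_votes)
  records <- list()
  rejects <- list()
  rs_mat <- list()
  for (g in candidates) {
    mf <- fit_multiomics(g, dataset, alpha)
    if (!mf$retained) {
      rejects[[g]] <- data.frame(
        gene_id = g, reason = paste(mf$failed, collapse = "+"),
        stringsAsFactors = FALSE)
      next
    }
    V <- gene_covariates(dataset, g)
    rs <- compute_rs(mf$fit, V)
    gs <- compute_gs(rs)
    vrow <- votes[votes$gene_id == g, c("A", "B", "C", "D")]
    rec <- data.frame(gene_id = g,
                      vrow,
                      beta_GE = mf$fit$beta[1], beta_SCNA = mf$fit$beta[2],
                      beta_DM = mf$fit$beta[3], beta_ME = mf$fit$beta[4],
                      gs = gs, score = compute_score(vrow, gs),
                      p_lrt = mf$fit$p_lrt, p_wald = mf$fit$p_wald,
                      p_score = mf$fit$p_score,
                      stringsAsFactors = FALSE)
    records[[g]] <- rec
    rs_mat[[g]] <- rs
  }
  records <- if (length(records)) do.call(rbind, c(records, make.row.names = FALSE))
             else data.frame()
  rejects <- if (length(rejects)) do.call(rbind, c(rejects, make.row.names = FALSE))
             else data.frame(gene_id = character(0), reason = character(0))
  rs <- if (length(rs_mat)) do.call(cbind, rs_mat) else NULL
  list(records = records, rejects = rejects, votes = votes, rs = rs)
}

#' Rank scored genes and take the top-k biomarker panel
#'
#' Sorts by Score descending; ties are broken by vote sum descending, then
#' multivariate likelihood-ratio p ascending, then gene id, so the ranking
#' is deterministic.
#'
#' @param records The `records` data.frame from [score_genes()].
#' @param k Panel size, default 10. When fewer genes are retained the full
#'   table is returned with a warning.
#' @param cancer_label Optional label carried in the result.
#' @return A `biomarker_panel`: the ranked records with a `rank` column,
#'   restricted to the top `k`, plus attributes `cancer_label` and
#'   `gene_ids`.
#' @export
rank_genes <- function(records, k = 10, cancer_label = NA_character_) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stopf("no retained genes to rank")
  }
  vote_sum <- records$A + records$B + records$C + records$D
  ord <- order(-records$score, -vote_sum, records$p_lrt, records$gene_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (k > nrow(out)) {
    warnf("only %d retained genes; returning all (k = %d requested)",
          nrow(out), k)
    k <- nrow(out)
  }
  out <- out[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cancer_label") <- cancer_label
  attr(out, "gene_ids") <- out$gene_id
  class(out) <- c("biomarker_panel", "data.frame")
  out
}

#' Score variant restricted to the voted layers
#'
#' Robustness check: the multivariate fit and the GS term are recomputed
#' using only the omics layers on which the gene was voted survival-related;
#' the Score is the vote sum plus the reduced-model GS. For a gene voted on
#' all four layers this is identical to the full path.
#'
#' @param gene_id One candidate gene id.
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param votes Output of [univariate_screen()].
#' @param alpha Gate threshold, default 0.05.
#' @return A list: `gene_id`, `score` (NA when the reduced fit is rejected),
#'   `retained`, `kinds` used.
#' @export
score_variant_voted_layers_only <- function(gene_id, dataset, votes,
                                            alpha = 0.05) {
  vrow <- votes[votes$gene_id == gene_id, , drop = FALSE]
  if (nrow(vrow) != 1) stopf("gene %s not found in votes table", gene_id)
  flags <- unlist(vrow[1, c("A", "B", "C", "D")])
  kinds <- LAYER_KINDS[flags == 1]
  if (length(kinds) == 0) stopf("gene %s has no voted layer", gene_id)
  mf <- fit_multiomics(gene_id, dataset, alpha, kinds = kinds)
  if (!mf$retained) {
    return(list(gene_id = gene_id, score = NA_real_, retained = FALSE,
                kinds = kinds))
  }
  V <- gene_covariates(dataset, gene_id, kinds)
  gs <- compute_gs(compute_rs(mf$fit, V))
  list(gene_id = gene_id, score = sum(flags) + gs, retained = TRUE,
       kinds = kinds)
}

#' Merged-matrix screening variant
#'
#' Alternative feature-selection route: the same gene measured in different
#' omics layers is treated as a distinct feature of one merged matrix. Per
#' gene, its four layer features enter one multivariate Cox fit; a feature
#' counts as survival-related when its per-coefficient Wald p-value is below
#' `alpha`. Genes with at least `min_hits` survival-related features are
#' returned.
#'
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param alpha Per-feature significance threshold, default 0.05.
#' @param min_hits Minimum significant features per gene, default 2.
#' @return Character vector of gene ids.
#' @export
merged_matrix_screen <- function(dataset, alpha = 0.05, min_hits = 2) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  genes <- dataset_genes(dataset)
  time <- dataset$clinical$time
  event <- dataset$clinical$event
  hits <- vapply(genes, function(g) {
    fit <- tryCatch(fit_cox(gene_covariates(dataset, g), time, event),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$beta)) return(0L)
    z <- fit$beta / fit$se
    p <- 2 * stats::pnorm(-abs(z))
    sum(p < alpha)
  }, integer(1))
  genes[hits >= min_hits]
}
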