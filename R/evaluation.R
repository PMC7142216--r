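#' Panel-level per-sample risk scores
#'
#' One multivariate Cox model over all covariates of the panel (k genes x
#' the selected layers) is fitted on the given samples; the per-sample risk
#' is the fitted linear predictor. When the plain fit is singular or fails
#' to converge, a ridge-stabilized refit is used (penalty starting at 1e-6
#' on the coefficient norm, escalated tenfold until the fit succeeds), since
#' panels of 4k collinear covariates frequently produce ill-conditioned
#' information matrices.
#'
#' @param panel A `biomarker_panel` from [rank_genes()], or a character
#'   vector of gene ids.
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param sample_subset Optional integer/character index of samples to fit
#'   and score; default all.
#' @param kinds Layers used as covariates, default all four. Restricting to
#'   one layer gives the single-omics comparison model.
#' @return Named numeric vector of risk scores (linear predictor), one per
#'   selected sample.
#' @export
panel_risk_scores <- function(panel, dataset, sample_subset = NULL,
                              kinds = LAYER_KINDS) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  genes <- if (is.character(panel)) panel else attr(panel, "gene_ids")
  if (!all(genes %in% dataset_genes(dataset))) {
    stopf("panel genes missing from dataset: %s",
          paste(setdiff(genes, dataset_genes(dataset)), collapse = ", "))
  }
  samples <- dataset_samples(dataset)
  idx <- if (is.null(sample_subset)) seq_along(samples)
         else if (is.character(sample_subset)) match(sample_subset, samples)
         else sample_subset
  X <- panel_design(dataset, genes, kinds, idx)
  if (nrow(X) < ncol(X) + 1) {
    stopf("subset of %d samples is too small for %d covariates",
          nrow(X), ncol(X))
  }
  time <- dataset$clinical$time[idx]
  event <- dataset$clinical$event[idx]
  beta <- panel_cox_beta(X, time, event)
  risk <- drop(X %*% beta)
  names(risk) <- samples[idx]
  risk
}

# Covariate matrix of a panel: k genes x selected layers, subset rows.
panel_design <- function(dataset, genes, kinds, idx) {
  X <- do.call(cbind, lapply(genes, function(g) {
    gene_covariates(dataset, g, kinds)[idx, , drop = FALSE]
  }))
  colnames(X) <- as.vector(outer(kinds, genes,
                                 function(k, g) paste(g, k, sep = ".")))
  X
}

# Panel Cox coefficients with ridge fallback for singular fits.
panel_cox_beta <- function(X, time, event) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ X)),
    error = function(e) NULL
  )
  if (!is.null(fit) && !anyNA(stats::coef(fit))) return(unname(stats::coef(fit)))
  theta <- 1e-6
  for (i in 1:9) {
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(time, event) ~ survival::ridge(X, theta = theta,
                                                      scale = FALSE))),
      error = function(e) NULL
    )
    if (!is.null(fit) && !anyNA(stats::coef(fit))) {
      return(unname(stats::coef(fit)))
    }
    theta <- theta * 10
  }
  stopf("panel Cox fit failed even with ridge stabilization")
}

#' Median split into high- and low-risk groups
#'
#' Samples at or below the median risk form the low-risk group, samples
#' above it the high-risk group (ties go to low), so both groups are
#' non-empty and near-balanced for Kaplan-Meier display.
#'
#' @param risk Per-sample risk scores.
#' @return Factor with levels `low`, `high`.
#' @export
stratify <- function(risk) {
  if (length(risk) < 2) stopf("need at least two samples to stratify")
  med <- stats::median(risk)
  if (all(risk == risk[1])) stopf("all risk scores identical; cannot stratify")
  labels <- ifelse(risk > med, "high", "low")
  if (!all(c("high", "low") %in% labels)) {
    # heavy ties at the median can empty one side; split at the midpoint rank
    ord <- order(risk)
    labels <- character(length(risk))
    labels[ord] <- rep(c("low", "high"),
                       c(floor(length(risk) / 2),
                         length(risk) - floor(length(risk) / 2)))
  }
  factor(labels, levels = c("low", "high"))
}

#' Resampled C-index distribution of a biomarker panel
#'
#' Repeats `reps` times: draw `floor(frac * n)` samples without replacement,
#' fit the panel risk model on them, and compute Harrell's C-index of the
#' fitted risk against the same subsample's survival. Reports the values,
#' their median, and a one-sided sign-test p-value for median C > 0.5.
#'
#' @param panel A `biomarker_panel` or character vector of gene ids.
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param frac Subsample fraction, default 0.9.
#' @param reps Number of resamples, default 100.
#' @param seed Integer seed; same seed reproduces the 100 values exactly.
#' @param kinds Layers for the risk model, default all four.
#' @param holdout If `FALSE` (default) the C-index is evaluated on the same
#'   subsample the model was fitted on (in-sample discrimination of the
#'   fitted model). If `TRUE`, the model fitted on the subsample scores the
#'   held-out remainder instead: an honest but noisier estimate.
#' @return A `cindex_distribution`: list with `values`, `median`,
#'   `p_sign_test`, `subsample_frac`, `n_reps`, `seed`, `n_failed`.
#' @export
cindex_resampling <- function(panel, dataset, frac = 0.9, reps = 100,
                              seed = 1L, kinds = LAYER_KINDS,
                              holdout = FALSE) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  n <- length(dataset_samples(dataset))
  m <- floor(frac * n)
  if (holdout && m >= n) stopf("holdout mode needs frac < 1")
  values <- numeric(reps)
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      val <- NA_real_
      for (attempt in 1:4) {  # initial draw + up to 3 redraws
        idx <- sample(n, m)
        val <- tryCatch({
          genes <- if (is.character(panel)) panel else attr(panel, "gene_ids")
          X_fit <- panel_design(dataset, genes, kinds, idx)
          beta <- panel_cox_beta(X_fit, dataset$clinical$time[idx],
                                 dataset$clinical$event[idx])
          eval_idx <- if (holdout) setdiff(seq_len(n), idx) else idx
          risk <- drop(panel_design(dataset, genes, kinds,
                                    eval_idx) %*% beta)
          concordance_index(risk, dataset$clinical$time[eval_idx],
                            dataset$clinical$event[eval_idx])
        }, error = function(e) NA_real_)
        if (!is.na(val)) break
      }
      if (is.na(val)) n_failed <- n_failed + 1L
      values[r] <- val
    }
  })
  ok <- values[!is.na(values)]
  n_above <- sum(ok > 0.5)
  n_informative <- sum(ok != 0.5)
  p_sign <- if (n_informative == 0) 1 else {
    stats::pbinom(n_above - 1, n_informative, 0.5, lower.tail = FALSE)
  }
  structure(list(
    values = values, median = stats::median(ok), p_sign_test = p_sign,
    subsample_frac = frac, n_reps = reps, seed = as.integer(seed),
    n_failed = n_failed
  ), class = "cindex_distribution")
}

#' @export
print.cindex_distribution <- function(x, ...) {
  cat(sprintf(
    "<cindex_distribution> %d reps at %.0f%%: median C = %.3f (sign-test p = %.3g)\n",
    x$n_reps, 100 * x$subsample_frac, x$median, x$p_sign_test))
  invisible(x)
}

#' Decision-curve analysis
#'
#' For each threshold probability `p_t`, a sample is test-positive when its
#' predicted event probability is at least `p_t`, and the clinical net
#' benefit is `TP/n - FP/n * p_t/(1 - p_t)`: true positives credited,
#' false positives debited at the odds of the threshold, which encodes the
#' relative harm of unnecessary treatment. The curve is reported alongside
#' the treat-all line (`nb_all`) and the treat-none line (`nb_none = 0`).
#'
#' @param probability Per-sample predicted event probabilities in `[0, 1]`.
#' @param event 0/1 observed event indicators.
#' @param thresholds Threshold grid in (0, 1), default `seq(0.01, 0.80, 0.01)`.
#' @return A `net_benefit_curve` data.frame: `threshold`, `nb_model`,
#'   `nb_all`, `nb_none`, with attribute `n`.
#' @export
#' @examples
#' p <- c(rep(0.9, 50), rep(0.1, 50))
#' y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
#' dc <- decision_curve(p, y, thresholds = 0.2)
#' dc$nb_model  # 30/100 - 20/100 * 0.2/0.8 = 0.25
decision_curve <- function(probability, event,
                           thresholds = seq(0.01, 0.80, by = 0.01)) {
  n <- length(probability)
  if (n == 0) stopf("empty input")
  if (length(event) != n) stopf("probability and event lengths differ")
  if (any(probability < 0 | probability > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stopf("thresholds must lie strictly inside (0, 1)")
  }
  prevalence <- mean(event == 1)
  odds <- thresholds / (1 - thresholds)
  nb_model <- vapply(seq_along(thresholds), function(i) {
    pos <- probability >= thresholds[i]
    tp <- sum(pos & event == 1)
    fp <- sum(pos & event == 0)
    tp / n - fp / n * odds[i]
  }, numeric(1))
  out <- data.frame(
    threshold = thresholds,
    nb_model = nb_model,
    nb_all = prevalence - (1 - prevalence) * odds,
    nb_none = 0
  )
  attr(out, "n") <- n
  class(out) <- c("net_benefit_curve", "data.frame")
  out
}

#' Map a risk score to an event probability for decision curves
#'
#' Logistic regression of the observed event indicator on the risk score,
#' fitted and evaluated on the same samples: the simplest monotone mapping
#' of a Cox linear predictor into `[0, 1]`.
#'
#' @param risk Per-sample risk scores.
#' @param event 0/1 event indicators.
#' @return Fitted per-sample probabilities.
#' @export
risk_to_probability <- function(risk, event) {
  fit <- stats::glm(event ~ risk, family = stats::binomial())
  unname(stats::fitted(fit))
}

#' Multi-omics versus single-omics C-index comparison
#'
#' Runs [cindex_resampling()] once with the full four-layer panel risk model
#' and once per single layer, all with the same seed so every source sees
#' identical subsample memberships (paired comparison).
#'
#' @param panel A `biomarker_panel` or character vector of gene ids.
#' @param dataset A harmonized [multi_omics_dataset()].
#' @param frac,reps,seed As in [cindex_resampling()].
#' @return Named list of `cindex_distribution` objects:
#'   `multi`, `GE`, `SCNA`, `DM`, `ME`.
#' @export
single_vs_multi_comparison <- function(panel, dataset, frac = 0.9,
                                       reps = 100, seed = 1L) {
  out <- list(multi = cindex_resampling(panel, dataset, frac, reps, seed))
  for (k in LAYER_KINDS) {
    out[[k]] <- cindex_resampling(panel, dataset, frac, reps, seed, kinds = k)
  }
  out
}
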