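#' Simulation configuration for synthetic multi-omics survival data
#'
#' Describes a synthetic cohort: four omics layers (GE, SCNA, DM, ME) on a
#' shared gene and sample set, right-censored survival whose hazard depends
#' log-linearly on a small set of planted driver genes, and optional
#' missingness / duplicate-probe structure to exercise the harmonization
#' filters.
#'
#' Cross-layer dependence follows the biology the layers represent: promoter
#' methylation (DM) and miRNA expression (ME) are anti-correlated with gene
#' expression, copy number (SCNA) is positively correlated with it. The
#' correlation magnitude per layer pair is `cross_layer_rho`.
#'
#' @param n_genes,n_samples Cohort dimensions.
#' @param n_drivers Number of planted prognostic driver genes.
#' @param driver_layers List of length `n_drivers`; each element a character
#'   subset of `c("GE","SCNA","DM","ME")` naming the layers through which
#'   that driver acts. Recycled if a single subset is given.
#' @param effect_size Log hazard ratio per 1 SD of a driver's layer value
#'   (unitless).
#' @param cross_layer_rho Magnitude of cross-layer correlation in `[0, 1)`;
#'   the sign per pair is fixed by the biology above. Default 0.5.
#' @param baseline_hazard Baseline event rate per day. Default 1e-3
#'   (median survival roughly two years under the null).
#' @param censor_rate Target fraction of censored samples in `[0, 1)`.
#' @param missing_frac Fraction of entries set missing per layer.
#' @param dup_probe_frac Fraction of genes given a duplicate probe row
#'   (pre-harmonization layers only).
#' @param seed Integer RNG seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes, n_samples, n_drivers = 0,
                       driver_layers = list(c("GE", "DM")),
                       effect_size = 1.0, cross_layer_rho = 0.5,
                       baseline_hazard = 1e-3, censor_rate = 0.3,
                       missing_frac = 0, dup_probe_frac = 0, seed = 1L) {
  if (n_genes < 1 || n_samples < 1) stopf("n_genes and n_samples must be >= 1")
  if (n_drivers > n_genes) stopf("n_drivers must not exceed n_genes")
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (cross_layer_rho < 0 || cross_layer_rho >= 1) {
    stopf("cross_layer_rho must be in [0, 1)")
  }
  if (missing_frac < 0 || missing_frac > 1 || dup_probe_frac < 0 ||
      dup_probe_frac > 1) {
    stopf("missing_frac and dup_probe_frac must be fractions in [0, 1]")
  }
  if (n_drivers > 0) {
    driver_layers <- rep_len(driver_layers, n_drivers)
    ok <- vapply(driver_layers,
                 function(l) length(l) >= 1 && all(l %in% LAYER_KINDS),
                 logical(1))
    if (!all(ok)) {
      stopf("each driver needs >= 1 designated layer among %s",
            paste(LAYER_KINDS, collapse = ", "))
    }
  } else {
    driver_layers <- list()
  }
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_drivers = as.integer(n_drivers), driver_layers = driver_layers,
    effect_size = effect_size, cross_layer_rho = cross_layer_rho,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    missing_frac = missing_frac, dup_probe_frac = dup_probe_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate right-censored survival times from a proportional-hazards model
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(linear_predictor)` (constant baseline hazard, the
#' simplest model satisfying proportional hazards). Censoring times are drawn
#' from an independent exponential whose rate is solved numerically so the
#' expected censored fraction equals `censor_rate`; the observed time is the
#' minimum of the two.
#'
#' @param linear_predictor Per-sample log relative hazard.
#' @param baseline_hazard Baseline event rate per day (> 0).
#' @param censor_rate Target censored fraction in `[0, 1)`.
#' @param seed Integer seed; same seed gives identical output.
#' @return A list with `time` (days) and `event` (1 = death observed).
#' @export
#' @examples
#' s <- generate_survival(rep(0, 5), baseline_hazard = 0.01,
#'                        censor_rate = 0, seed = 1)
#' s$event  # all 1: nothing is censored
generate_survival <- function(linear_predictor, baseline_hazard,
                              censor_rate = 0, seed = 1L) {
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (any(!is.finite(linear_predictor))) {
    stopf("linear predictor values must be finite")
  }
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  rate <- baseline_hazard * exp(linear_predictor)
  with_seed(seed, {
    t_event <- stats::rexp(length(rate), rate = rate)
    if (censor_rate == 0) {
      list(time = t_event, event = rep(1L, length(rate)))
    } else {
      # Solve for the censoring rate c: mean_i c/(c + rate_i) = censor_rate.
      f <- function(logc) mean(exp(logc) / (exp(logc) + rate)) - censor_rate
      logc <- stats::uniroot(f, lower = log(min(rate)) - 20,
                             upper = log(max(rate)) + 20)$root
      t_cens <- stats::rexp(length(rate), rate = exp(logc))
      list(time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
    }
  })
}

#' Generate a synthetic multi-omics dataset with planted drivers
#'
#' Produces four gene- and sample-aligned omics layers, a clinical table with
#' survival generated from the planted drivers, and the ground truth of which
#' genes drive hazard through which layers.
#'
#' Per gene, a latent standard-normal factor is mixed into each layer with
#' signed loadings (`+` for GE and SCNA, `-` for DM and ME), which guarantees
#' the configured correlation signs (DM and ME anti-correlated with GE, SCNA
#' positively correlated) at magnitude `cross_layer_rho` without specifying a
#' full covariance. Layer values are unit-variance normal around a
#' layer-specific baseline (abundance-like positive shifts for GE and ME,
#' centered for SCNA and DM). The
#' per-sample log relative hazard is the sum over drivers and their
#' designated layers of the planted layer effect times the layer value,
#' where the planted effect is `effect_size` signed by the layer's
#' regulatory direction (`+` for GE/SCNA, `-` for DM/ME), so a multi-layer
#' driver acts coherently through its correlated layers.
#'
#' When `missing_frac > 0` or `dup_probe_frac > 0`, the returned layers carry
#' missing entries / duplicated probe rows (injected after survival
#' generation, so the clinical outcome reflects the clean signal); such
#' layers must pass through the harmonization filters before screening.
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (a [multi_omics_dataset()], or a plain list
#'   of unaligned layers + clinical when injection is active), and `truth`
#'   (data.frame: `gene_id`, one log-hazard-ratio column per layer; non-driver
#'   genes have all-zero rows omitted).
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(50, 80, n_drivers = 2, seed = 42))
#' sim$truth
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    genes <- sprintf("gene%04d", seq_len(cf$n_genes))
    samples <- sprintf("sample%04d", seq_len(cf$n_samples))
    rho <- cf$cross_layer_rho
    load <- sqrt(rho)
    noise <- sqrt(1 - rho)
    latent <- matrix(stats::rnorm(cf$n_genes * cf$n_samples),
                     cf$n_genes, cf$n_samples)
    sign_of <- c(GE = 1, SCNA = 1, DM = -1, ME = -1)
    # GE and ME are reported on abundance-like (positive-shifted) scales so
    # the downstream expression filters behave as they do on real data;
    # SCNA (log-ratio-like) and DM stay centered. The hazard uses the
    # centered signal, and Cox fits are shift-invariant.
    offset_of <- c(GE = 3, SCNA = 0, DM = 0, ME = 3)
    centered <- lapply(LAYER_KINDS, function(k) {
      vals <- sign_of[[k]] * load * latent +
        noise * matrix(stats::rnorm(cf$n_genes * cf$n_samples),
                       cf$n_genes, cf$n_samples)
      dimnames(vals) <- list(genes, samples)
      vals
    })
    names(centered) <- LAYER_KINDS
    layers <- lapply(LAYER_KINDS, function(k) {
      omics_layer(centered[[k]] + offset_of[[k]], k)
    })
    names(layers) <- LAYER_KINDS

    # A driver's hazard effect is carried by its activity, which loads
    # positively on GE/SCNA and negatively on DM/ME; the planted
    # log-hazard-ratio per layer therefore carries the layer's regulatory
    # sign, so a two-layer driver acts coherently rather than
    # self-cancelling.
    effects <- matrix(0, cf$n_genes, 4, dimnames = list(genes, LAYER_KINDS))
    driver_ids <- character(0)
    if (cf$n_drivers > 0) {
      driver_ids <- sample(genes, cf$n_drivers)
      for (d in seq_len(cf$n_drivers)) {
        ls <- cf$driver_layers[[d]]
        effects[driver_ids[d], ls] <- cf$effect_size * sign_of[ls]
      }
    }
    lp <- rep(0, cf$n_samples)
    for (g in which(rowSums(effects != 0) > 0)) {
      for (k in LAYER_KINDS) {
        if (effects[g, k] != 0) {
          lp <- lp + effects[g, k] * centered[[k]][g, ]
        }
      }
    }

    surv <- generate_survival(lp, cf$baseline_hazard, cf$censor_rate,
                              seed = derive_seed(cf$seed, 104729L))
    clinical <- clinical_table(samples, surv$time, surv$event)

    truth <- data.frame(gene_id = driver_ids,
                        effects[driver_ids, , drop = FALSE],
                        row.names = NULL, stringsAsFactors = FALSE)

    inject <- cf$missing_frac > 0 || cf$dup_probe_frac > 0
    if (!inject) {
      return(list(dataset = multi_omics_dataset(layers, clinical),
                  truth = truth))
    }
    layers <- lapply(layers, function(l) {
      v <- l$values
      if (cf$missing_frac > 0) {
        idx <- which(stats::runif(length(v)) < cf$missing_frac)
        v[idx] <- NA_real_
      }
      if (cf$dup_probe_frac > 0) {
        ndup <- floor(cf$dup_probe_frac * nrow(v))
        if (ndup > 0) {
          dup_rows <- sample(nrow(v), ndup)
          extra <- v[dup_rows, , drop = FALSE] +
            matrix(stats::rnorm(ndup * ncol(v), sd = 0.05), ndup, ncol(v))
          v <- rbind(v, extra)  # duplicate gene ids on purpose
        }
      }
      out <- l
      out$values <- v
      out
    })
    list(dataset = list(layers = layers, clinical = clinical), truth = truth)
  })
}

#' Write a synthetic dataset to TSV fixtures
#'
#' Writes one TSV per layer (genes as rows, first column `gene_id`, one
#' column per sample), a clinical TSV and a ground-truth TSV. Reading the
#' files back with [read_omics_matrix()] / [read_clinical()] reproduces the
#' dataset exactly.
#'
#' @param dataset A [multi_omics_dataset()].
#' @param truth Ground-truth data.frame as returned by [generate_dataset()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_fixture <- function(dataset, truth, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in LAYER_KINDS) {
    p <- file.path(directory, paste0(tolower(k), ".tsv"))
    write_omics_matrix(dataset$layers[[k]], p)
    paths <- c(paths, p)
  }
  p_clin <- file.path(directory, "clinical.tsv")
  utils::write.table(dataset$clinical, p_clin, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_truth <- file.path(directory, "truth.tsv")
  utils::write.table(truth, p_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p_clin, p_truth))
}
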