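#' Read a gene x sample TSV matrix as an omics layer
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' `NA` / empty cells become missing values. Duplicate sample ids are an
#' error; duplicate gene ids are allowed (they are probe duplicates to be
#' averaged by [aggregate_duplicates()]).
#'
#' @param path Path to the TSV file.
#' @param kind Layer kind: `"GE"`, `"SCNA"`, `"DM"` or `"ME"`.
#' @return An [omics_layer()].
#' @export
read_omics_matrix <- function(path, kind) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2) stopf("%s: expected gene-id column plus sample columns", path)
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stopf("%s: duplicate sample id(s): %s", path,
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("%s: non-numeric cell at row %d (gene %s), column %s", path,
          bad[1, 1], genes[bad[1, 1]], samples[bad[1, 2]])
  }
  dimnames(num) <- list(genes, samples)
  omics_layer(num, kind)
}

#' Write an omics layer as a gene x sample TSV matrix
#'
#' @param layer An [omics_layer()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_omics_matrix <- function(layer, path) {
  stopifnot(inherits(layer, "omics_layer"))
  # %.17g guarantees the decimal text parses back to the identical double
  txt <- matrix(formatC(layer$values, digits = 17, format = "g"),
                nrow(layer$values), ncol(layer$values))
  txt[is.na(layer$values)] <- "NA"
  df <- data.frame(gene_id = gene_ids(layer), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(layer))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical TSV
#'
#' Expects columns `sample_id`, `time`, `event`; `age`, `sex` and
#' `sample_type_code` are optional (`sample_type_code` defaults to `"01"`).
#'
#' @param path Path to the TSV file.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stopf("%s: clinical table needs columns %s", path,
          paste(need, collapse = ", "))
  }
  clinical_table(
    sample_id = df$sample_id,
    time = as.numeric(df$time),
    event = as.integer(df$event),
    age = if ("age" %in% names(df)) suppressWarnings(as.numeric(df$age)) else NA,
    sex = if ("sex" %in% names(df)) df$sex else NA,
    sample_type_code = df$sample_type_code %||% "01"
  )
}

#' Read a miRNA-mRNA interaction TSV
#'
#' Expects columns `mirna_id`, `gene_id`, `n_experiments`,
#' `n_anticorrelated_cancers`. Duplicate (miRNA, gene) pairs are an error.
#'
#' @param path Path to the TSV file.
#' @return A data.frame for [map_mirna_to_genes()].
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id", "n_experiments", "n_anticorrelated_cancers")
  if (!all(need %in% names(df))) {
    stopf("%s: interaction table needs columns %s", path,
          paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[, c("mirna_id", "gene_id")])) {
    stopf("%s: duplicate (mirna_id, gene_id) pair(s)", path)
  }
  if (any(df$n_experiments < 0) || any(df$n_anticorrelated_cancers < 0)) {
    stopf("%s: interaction counts must be non-negative", path)
  }
  df
}

#' Read a GMT gene-set collection
#'
#' GMT: one term per line, tab-separated: term id, description, then gene
#' ids. An optional `namespace` filter keeps only terms whose description
#' field equals it (used to restrict GO to biological-process terms).
#'
#' @param path Path to the GMT file.
#' @param namespace Optional description filter (e.g. `"BP"`).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path, namespace = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) next
    if (!is.null(namespace) && parts[2] != namespace) next
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Pipeline run configuration
#'
#' Collects the paths and tuning parameters of a full run. All parameters
#' are validated; the object serializes to / from a flat `key=value` text
#' file via [write_run_config()] / [read_run_config()].
#'
#' @param ge,scna,dm,me,clinical Input TSV paths (`NULL` entries allowed
#'   when the matching object is passed to [run_pipeline()] directly).
#' @param interactions Optional interaction TSV path.
#' @param alpha Screen/gate threshold in (0, 1), default 0.05.
#' @param min_votes Candidate vote threshold (1..4), default 2.
#' @param top_k Panel size, default 10.
#' @param frac Resampling fraction in (0, 1], default 0.9.
#' @param reps Resampling repetitions, default 100.
#' @param seed Global integer seed; stages derive their own seeds from it
#'   by fixed offsets.
#' @param zscore_mode `"global"` or `"per_gene"`.
#' @param thresholds Decision-curve threshold grid.
#' @return A `run_config` list.
#' @export
run_config <- function(ge = NULL, scna = NULL, dm = NULL, me = NULL,
                       clinical = NULL, interactions = NULL,
                       alpha = 0.05, min_votes = 2, top_k = 10,
                       frac = 0.9, reps = 100, seed = 1L,
                       zscore_mode = "global",
                       thresholds = seq(0.01, 0.80, by = 0.01)) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (min_votes < 1 || min_votes > 4) stopf("min_votes must be in 1..4")
  if (top_k < 1) stopf("top_k must be positive")
  if (frac <= 0 || frac > 1) stopf("frac must be in (0, 1]")
  if (reps < 1) stopf("reps must be positive")
  structure(list(
    ge = ge, scna = scna, dm = dm, me = me, clinical = clinical,
    interactions = interactions, alpha = alpha,
    min_votes = as.integer(min_votes), top_k = as.integer(top_k),
    frac = frac, reps = as.integer(reps), seed = as.integer(seed),
    zscore_mode = match.arg(zscore_mode, c("global", "per_gene")),
    thresholds = thresholds
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the flat `key=value` serialization.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    if (is.null(v)) "" else paste(format(v, digits = 15, trim = TRUE),
                                  collapse = ",")
  }
  writeLines(paste0(names(config), "=", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) if (length(x) < 2 || !nzchar(x[2])) NULL else x[2]),
    vapply(kv, `[`, character(1), 1))
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])
  run_config(
    ge = vals$ge, scna = vals$scna, dm = vals$dm, me = vals$me,
    clinical = vals$clinical, interactions = vals$interactions,
    alpha = num(vals$alpha), min_votes = num(vals$min_votes),
    top_k = num(vals$top_k), frac = num(vals$frac), reps = num(vals$reps),
    seed = num(vals$seed), zscore_mode = vals$zscore_mode,
    thresholds = num(vals$thresholds)
  )
}

#' Run the full discovery workflow
#'
#' Executes harmonization, the univariate voting screen, candidate
#' selection, per-gene multivariate integration, Score ranking, resampled
#' C-index validation of the panel, and decision-curve analysis; every
#' intermediate table is written as TSV to `out_dir` along with a run
#' manifest recording the configuration and the per-stage gene/sample
#' counts.
#'
#' @param config A [run_config()]; its paths are used unless `layers` /
#'   `clinical` / `interactions` are supplied in-memory.
#' @param out_dir Output directory (created).
#' @param layers Optional named list of raw [omics_layer()]s.
#' @param clinical Optional [clinical_table()].
#' @param interactions Optional interaction data.frame.
#' @return Invisibly, a list with `dataset`, `votes`, `scored`, `panel`,
#'   `cindex`, `dca`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, layers = NULL, clinical = NULL,
                         interactions = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- "read_inputs"
  result <- tryCatch({
    if (is.null(layers)) {
      layers <- list(GE = read_omics_matrix(config$ge, "GE"),
                     SCNA = read_omics_matrix(config$scna, "SCNA"),
                     DM = read_omics_matrix(config$dm, "DM"),
                     ME = read_omics_matrix(config$me, "ME"))
    }
    if (is.null(clinical)) clinical <- read_clinical(config$clinical)
    if (is.null(interactions) && !is.null(config$interactions)) {
      interactions <- read_interactions(config$interactions)
    }
    manifest <- list()
    manifest$input_genes <- vapply(layers, function(l) nrow(l$values),
                                   integer(1))
    manifest$input_samples <- vapply(layers, function(l) ncol(l$values),
                                     integer(1))
    manifest$input_clinical <- nrow(clinical)

    stage <- "harmonize"
    dataset <- suppressMessages(
      harmonize(layers, clinical, interactions,
                max_missing_frac = 0.05, zscore_scope = config$zscore_mode))
    manifest$harmonized_genes <- length(dataset_genes(dataset))
    manifest$harmonized_samples <- length(dataset_samples(dataset))
    logline("harmonize: %d genes x %d samples",
            manifest$harmonized_genes, manifest$harmonized_samples)

    stage <- "univariate_screen"
    votes <- univariate_screen(dataset, config$alpha)
    utils::write.table(votes, file.path(out_dir, "votes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    candidates <- select_candidates(votes, config$min_votes)
    manifest$candidates <- length(candidates)
    logline("screen: %d candidate genes (min_votes = %d)",
            length(candidates), config$min_votes)
    if (length(candidates) == 0) {
      logline("no candidate genes; stopping after the screen")
      manifest$retained <- 0L
      write_manifest(manifest, config, out_dir)
      return(invisible(list(dataset = dataset, votes = votes, scored = NULL,
                            panel = NULL, cindex = NULL, dca = NULL,
                            manifest = manifest)))
    }

    stage <- "score_genes"
    scored <- score_genes(dataset, votes, config$alpha, config$min_votes)
    manifest$retained <- nrow(scored$records)
    logline("integration: %d genes pass the triple-test gate",
            manifest$retained)
    utils::write.table(scored$rejects, file.path(out_dir, "rejects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (manifest$retained == 0) {
      logline("no genes retained; stopping before ranking")
      write_manifest(manifest, config, out_dir)
      return(invisible(list(dataset = dataset, votes = votes, scored = scored,
                            panel = NULL, cindex = NULL, dca = NULL,
                            manifest = manifest)))
    }
    utils::write.table(scored$records, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "rank_genes"
    panel <- rank_genes(scored$records, k = config$top_k)
    utils::write.table(as.data.frame(panel), file.path(out_dir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$panel_size <- nrow(panel)

    stage <- "cindex_resampling"
    cindex <- cindex_resampling(panel, dataset, frac = config$frac,
                                reps = config$reps,
                                seed = derive_seed(config$seed, 1L))
    utils::write.table(
      data.frame(rep = seq_along(cindex$values), cindex = cindex$values),
      file.path(out_dir, "cindex.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(median_cindex = cindex$median,
                 p_sign_test = cindex$p_sign_test),
      file.path(out_dir, "cindex_summary.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    logline("validation: median C-index %.3f (sign-test p = %.3g)",
            cindex$median, cindex$p_sign_test)

    stage <- "decision_curve"
    risk <- panel_risk_scores(panel, dataset)
    prob <- risk_to_probability(risk, dataset$clinical$event)
    dca <- decision_curve(prob, dataset$clinical$event, config$thresholds)
    utils::write.table(as.data.frame(dca), file.path(out_dir, "dca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "km_groups"
    groups <- stratify(risk)
    for (g in levels(groups)) {
      km <- km_estimate(dataset$clinical$time[groups == g],
                        dataset$clinical$event[groups == g])
      utils::write.table(as.data.frame(km),
                         file.path(out_dir, paste0("km_", g, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$logrank_p <- logrank_test(groups, dataset$clinical$time,
                                       dataset$clinical$event)
    write_manifest(manifest, config, out_dir)
    list(dataset = dataset, votes = votes, scored = scored, panel = panel,
         cindex = cindex, dca = dca, manifest = manifest)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s (partial outputs in %s)",
          stage, conditionMessage(e), out_dir)
  })
  invisible(result)
}

write_manifest <- function(manifest, config, out_dir) {
  lines <- c(
    sprintf("seed=%d", config$seed),
    sprintf("alpha=%g", config$alpha),
    sprintf("min_votes=%d", config$min_votes),
    sprintf("top_k=%d", config$top_k),
    sprintf("frac=%g", config$frac),
    sprintf("reps=%d", config$reps),
    sprintf("zscore_mode=%s", config$zscore_mode),
    sprintf("package_version=%s",
            as.character(utils::packageVersion("panprog"))),
    vapply(names(manifest), function(k) {
      sprintf("%s=%s", k, paste(format(manifest[[k]], digits = 6,
                                       trim = TRUE), collapse = ","))
    }, character(1))
  )
  writeLines(lines, file.path(out_dir, "manifest.txt"))
}
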