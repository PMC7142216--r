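#' Hypergeometric gene-set enrichment
#'
#' For each term, tests over-representation of the query genes with the
#' upper-tail cumulative hypergeometric probability
#' `P(X >= i)` where, within the universe of `N` genes, `M` belong to the
#' term, `n` are in the query, and `i` is the overlap. Query and term genes
#' outside the universe are dropped (with a warning for the query).
#'
#' @param query Character vector of interesting gene ids.
#' @param collection Named list of character vectors (term id -> gene ids),
#'   e.g. from [read_gmt()].
#' @param universe Character vector: the whole gene background.
#' @param alpha Significance threshold on the raw p-value, default 0.05.
#'   Benjamini-Hochberg adjusted p-values are also reported.
#' @return A data.frame sorted by `p` ascending: `term_id`, `N`, `M`, `n`,
#'   `i_hit`, `p`, `p_bh`, `significant`.
#' @export
#' @examples
#' hypergeom_enrich(c("g1", "g2"), list(t1 = c("g1", "g2", "g3")),
#'                  universe = paste0("g", 1:10))
hypergeom_enrich <- function(query, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stopf("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    term_genes <- intersect(unique(collection[[term]]), universe)
    M <- length(term_genes)
    i_hit <- length(intersect(query, term_genes))
    p <- stats::phyper(i_hit - 1, M, N - M, n, lower.tail = FALSE)
    data.frame(term_id = term, N = N, M = M, n = n, i_hit = i_hit, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SAM-style differential expression between two sample groups
#'
#' Significance analysis of microarrays: per gene, a moderated t-like
#' statistic `d = (mean_a - mean_b) / (s + s0)` with the pooled standard
#' error `s` and a fudge constant `s0` (the 5th percentile of the gene-wise
#' standard errors) that damps genes with tiny variance. False discovery is
#' assessed by group-label permutations: at each observed `|d|` cutoff, the
#' q-value is the median number of permuted `|d*|` exceeding the cutoff
#' divided by the observed count, monotonized so q never decreases as the
#' cutoff loosens. A gene is called when `q < q_thresh` and
#' `|log2 fold change| > fc_thresh`, with fold change computed from group
#' means of the (un-logged) values with a pseudo-count of 1.
#'
#' @param expr_a,expr_b Gene x sample matrices sharing rownames (e.g. tumor
#'   and normal).
#' @param q_thresh q-value threshold, default 0.05.
#' @param fc_thresh `|log2 FC|` threshold, default 1.
#' @param n_perm Number of label permutations, default 200 (minimum 10).
#' @param seed Integer seed for the permutations.
#' @return A data.frame: `gene_id`, `d_stat`, `log2_fc`, `q_value`,
#'   `called`.
#' @export
sam_de <- function(expr_a, expr_b, q_thresh = 0.05, fc_thresh = 1.0,
                   n_perm = 200, seed = 1L) {
  expr_a <- as.matrix(expr_a)
  expr_b <- as.matrix(expr_b)
  if (!identical(rownames(expr_a), rownames(expr_b))) {
    common <- intersect(rownames(expr_a), rownames(expr_b))
    if (length(common) == 0) stopf("no shared gene ids between groups")
    expr_a <- expr_a[common, , drop = FALSE]
    expr_b <- expr_b[common, , drop = FALSE]
  }
  na <- ncol(expr_a)
  nb <- ncol(expr_b)
  if (na < 2 || nb < 2) stopf("each group needs at least 2 samples")
  if (n_perm < 10) stopf("n_perm must be at least 10")

  d_of <- function(xa, xb, s0) {
    ma <- rowMeans(xa)
    mb <- rowMeans(xb)
    ss <- (rowSums((xa - ma)^2) + rowSums((xb - mb)^2)) / (na + nb - 2)
    s <- sqrt((1 / na + 1 / nb) * ss)
    list(d = (ma - mb) / (s + s0), s = s)
  }

  first <- d_of(expr_a, expr_b, 0)
  s0 <- stats::quantile(first$s, 0.05, names = FALSE)
  d_obs <- (rowMeans(expr_a) - rowMeans(expr_b)) / (first$s + s0)

  pooled <- cbind(expr_a, expr_b)
  abs_obs <- abs(d_obs)
  ord <- order(abs_obs, decreasing = TRUE)
  cutoffs <- abs_obs[ord]
  exceed_perm <- matrix(0, n_perm, length(cutoffs))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      lab <- sample(na + nb)
      dp <- d_of(pooled[, lab[seq_len(na)], drop = FALSE],
                 pooled[, lab[-seq_len(na)], drop = FALSE], s0)$d
      # count permuted |d*| >= each cutoff: n minus the strictly-smaller count
      sorted_dp <- sort(abs(dp))
      exceed_perm[p, ] <- length(dp) -
        findInterval(cutoffs, sorted_dp, left.open = TRUE)
    }
  })
  false_calls <- apply(exceed_perm, 2, stats::median)
  observed_calls <- seq_along(cutoffs)  # genes with |d| >= cutoff, sorted
  q_sorted <- pmin(1, false_calls / observed_calls)
  # monotonize: q non-decreasing as the cutoff loosens
  q_sorted <- cummax(q_sorted)
  q <- numeric(length(d_obs))
  q[ord] <- q_sorted

  mean_a <- rowMeans(expr_a)
  mean_b <- rowMeans(expr_b)
  log2_fc <- log2((mean_a + 1) / (mean_b + 1))
  called <- q < q_thresh & abs(log2_fc) > fc_thresh
  data.frame(gene_id = rownames(expr_a), d_stat = unname(d_obs),
             log2_fc = unname(log2_fc), q_value = unname(q),
             called = unname(called), stringsAsFactors = FALSE)
}
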