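# Shared pipeline fixture: five two-layer drivers among 120 genes.
scoring_sim <- make_driver_dataset(seed = 42)
scoring_votes <- univariate_screen(scoring_sim$dataset)
scoring_res <- score_genes(scoring_sim$dataset, scoring_votes)

test_that("univariate screen votes per layer at the 0.05 threshold", {
  v <- scoring_votes
  expect_true(all(c("A", "B", "C", "D") %in% names(v)))
  expect_true(all(unlist(v[, c("A", "B", "C", "D")]) %in% 0:1))
  # vote flag agrees with the reported likelihood-ratio p-value
  expect_identical(v$A, as.integer(!is.na(v$p_GE) & v$p_GE < 0.05))
  expect_identical(v$C, as.integer(!is.na(v$p_DM) & v$p_DM < 0.05))
  # planted two-layer drivers are voted on >= 2 layers
  dv <- v[v$gene_id %in% scoring_sim$truth$gene_id, ]
  expect_true(all(dv$A + dv$B + dv$C + dv$D >= 2))
})

test_that("candidate selection applies the at-least-two-votes rule", {
  v <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  A = c(1, 1, 1, 0), B = c(1, 0, 1, 0),
                  C = c(0, 0, 1, 0), D = c(0, 0, 1, 0))
  expect_setequal(select_candidates(v), c("g1", "g3"))
  expect_setequal(select_candidates(v, min_votes = 1), c("g1", "g2", "g3"))
  expect_setequal(select_candidates(v, min_votes = 4), "g3")
})

test_that("multivariate gate retains only genes passing all three tests", {
  recs <- scoring_res$records
  expect_true(all(recs$p_lrt < 0.05 & recs$p_wald < 0.05 &
                  recs$p_score < 0.05))
  if (nrow(scoring_res$rejects) > 0) {
    expect_true(all(grepl("lrt|wald|score|convergence",
                          scoring_res$rejects$reason)))
  }
  # drivers overwhelmingly survive the gate
  expect_gte(sum(scoring_sim$truth$gene_id %in% recs$gene_id), 4)
})

test_that("rs, gs and score compose exactly", {
  fit <- list(beta = c(0.5, -1, 2, 0))
  class(fit) <- "cox_fit"
  V <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0,
                1, 1, 1, 1), 3, 4, byrow = TRUE)
  rs <- compute_rs(fit, V)
  expect_equal(rs, c(0.5, -1, 1.5))
  expect_equal(compute_gs(rs), mean(rs))
  expect_equal(compute_score(c(1, 1, 0, 0), 0.3), 2.3)
  expect_equal(compute_score(c(0, 0, 0, 0), 0), 0)
  expect_equal(compute_score(c(1, 1, 1, 1), -0.2), 3.8)
  expect_error(compute_rs(fit, matrix(1, 2, 3)), "columns")
  expect_error(compute_gs(numeric(0)), "empty")
  expect_error(compute_score(c(2, 0, 0, 0), 0), "0/1")

  set.seed(12)
  B <- rnorm(4)
  V2 <- matrix(rnorm(40), 10, 4)
  fit2 <- structure(list(beta = B), class = "cox_fit")
  brute <- vapply(1:10, function(j) sum(B * V2[j, ]), numeric(1))
  expect_equal(compute_rs(fit2, V2), brute)
})

test_that("every retained record satisfies the Score decomposition", {
  recs <- scoring_res$records
  vote_sum <- recs$A + recs$B + recs$C + recs$D
  expect_equal(recs$score, vote_sum + recs$gs)
  expect_true(all(vote_sum %in% 2:4))
  # gs equals the mean of the stored per-sample risk scores
  expect_equal(unname(colMeans(scoring_res$rs)[recs$gene_id]), recs$gs)
})

test_that("ranking is by descending score with deterministic tie-breaks", {
  recs <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    A = 1, B = 1, C = 0, D = 0,
    gs = c(1.1, 0.4, 0.9),
    score = c(3.1, 2.4, 2.9),
    p_lrt = c(0.01, 0.02, 0.03)
  )
  panel <- rank_genes(recs, k = 2)
  expect_identical(panel$gene_id, c("gA", "gC"))
  expect_identical(panel$rank, 1:2)
  expect_warning(full <- rank_genes(recs, k = 10), "only 3")
  expect_equal(nrow(full), 3)
  expect_error(rank_genes(data.frame()), "no retained")

  # exact score ties break by vote sum, then p_lrt, then gene id
  tied <- data.frame(
    gene_id = c("gZ", "gY", "gX"),
    A = c(1, 1, 1), B = c(1, 1, 1), C = c(0, 1, 0), D = c(1, 1, 1),
    gs = 0.5, score = 3.5, p_lrt = c(0.02, 0.02, 0.01)
  )
  expect_identical(rank_genes(tied, k = 3)$gene_id, c("gY", "gX", "gZ"))
})

test_that("screen and selection are monotone in alpha and min_votes", {
  ds <- scoring_sim$dataset
  v05 <- scoring_votes
  v10 <- univariate_screen(ds, alpha = 0.10)
  expect_true(all(v10$A >= v05$A & v10$B >= v05$B &
                  v10$C >= v05$C & v10$D >= v05$D))
  c2 <- select_candidates(v05, 2)
  c3 <- select_candidates(v05, 3)
  expect_true(all(c3 %in% c2))
})

test_that("the pipeline is deterministic for a fixed dataset and seed", {
  sim2 <- make_driver_dataset(seed = 42)
  expect_identical(sim2, scoring_sim)
  res2 <- score_genes(sim2$dataset, univariate_screen(sim2$dataset))
  expect_identical(res2$records, scoring_res$records)
})

test_that("planted drivers dominate the top of the ranking", {
  panel <- rank_genes(scoring_res$records,
                      k = min(10, nrow(scoring_res$records)))
  expect_gte(sum(scoring_sim$truth$gene_id %in% panel$gene_id), 4)
})

test_that("voted-layers-only variant reduces to the full path on 4-vote genes", {
  recs <- scoring_res$records
  four <- recs$gene_id[recs$A + recs$B + recs$C + recs$D == 4]
  skip_if(length(four) == 0, "no 4-vote gene in this fixture")
  g <- four[1]
  variant <- score_variant_voted_layers_only(g, scoring_sim$dataset,
                                             scoring_votes)
  expect_equal(variant$score, recs$score[recs$gene_id == g])
  expect_identical(variant$kinds, c("GE", "SCNA", "DM", "ME"))
})

test_that("variant scores track full scores in rank", {
  recs <- scoring_res$records
  vs <- vapply(recs$gene_id, function(g) {
    score_variant_voted_layers_only(g, scoring_sim$dataset,
                                    scoring_votes)$score
  }, numeric(1))
  ok <- !is.na(vs)
  expect_gte(sum(ok), 3)
  expect_gt(cor(recs$score[ok], vs[ok], method = "spearman"), 0.8)
})

test_that("merged-matrix screen recovers drivers and rejects null data", {
  merged <- merged_matrix_screen(scoring_sim$dataset)
  cands <- select_candidates(scoring_votes)
  # planted drivers come out of both feature-selection routes (the full
  # containment seen on real data is empirical, not structural)
  expect_gte(sum(scoring_sim$truth$gene_id %in% merged), 4)
  expect_gte(sum(scoring_sim$truth$gene_id %in% intersect(merged, cands)), 4)

  # null data: (almost) nothing comes out
  null_sim <- generate_dataset(sim_config(80, 150, n_drivers = 0,
                                          effect_size = 0, seed = 5))
  expect_lte(length(merged_matrix_screen(null_sim$dataset)), 4)
})

test_that("BH-adjusted voting is conservative relative to raw voting", {
  v_raw <- scoring_votes
  v_bh <- univariate_screen(scoring_sim$dataset, p_adjust = "BH")
  expect_true(all(v_bh$A <= v_raw$A & v_bh$B <= v_raw$B &
                  v_bh$C <= v_raw$C & v_bh$D <= v_raw$D))
  # raw p-values are reported unchanged
  expect_identical(v_bh$p_GE, v_raw$p_GE)
})

test_that("the |GS| sensitivity variant only flips negative contributions", {
  expect_equal(compute_score(c(1, 1, 0, 0), -0.3, abs_gs = TRUE), 2.3)
  expect_equal(compute_score(c(1, 1, 0, 0), 0.3, abs_gs = TRUE),
               compute_score(c(1, 1, 0, 0), 0.3))
})
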