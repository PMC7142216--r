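make_layer <- function(values, kind = "GE", genes = NULL, samples = NULL) {
  genes <- genes %||% paste0("g", seq_len(nrow(values)))
  samples <- samples %||% paste0("s", seq_len(ncol(values)))
  m <- matrix(values, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  omics_layer(m, kind)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sample-type filter keeps only the requested code", {
  clin <- clinical_table(c("a", "b", "c"), c(10, 20, 30), c(1, 0, 1),
                         sample_type_code = c("01", "01", "11"))
  expect_equal(nrow(filter_sample_type(clin)), 2)
  expect_identical(filter_sample_type(clin)$sample_id, c("a", "b"))
  all01 <- clinical_table(c("a", "b"), c(1, 2), c(1, 1))
  expect_identical(filter_sample_type(all01), all01)
  all11 <- clinical_table(c("a", "b"), c(1, 2), c(1, 1),
                          sample_type_code = "11")
  expect_warning(out <- filter_sample_type(all11), "no samples")
  expect_equal(nrow(out), 0)
})

test_that("missingness filter drops genes above the threshold, strictly", {
  v <- matrix(1, 3, 100)
  v[1, 1:6] <- NA   # 6% missing: removed
  v[2, 1:5] <- NA   # exactly 5%: kept
  layer <- make_layer(v)
  out <- filter_missing(layer)
  expect_identical(rownames(out$values), c("g2", "g3"))
  expect_false(anyNA(out$values))
  # residual missing entries imputed by the gene-row mean
  v2 <- matrix(c(2, NA, 4, 4, 4, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  out2 <- filter_missing(omics_layer(v2, "GE"), max_missing_frac = 0.5)
  expect_equal(out2$values["g1", "s2"], 3)  # mean of 2 and 4
  # no missing values: identity
  expect_identical(filter_missing(layer)$values,
                   filter_missing(filter_missing(layer))$values)
})

test_that("expression filters apply the strict majority / 10% rules", {
  v <- rbind(c(rep(1, 51), rep(0, 49)),   # positive in 51/100: kept
             c(rep(1, 50), rep(0, 50)))   # positive in 50/100: removed
  out <- filter_expression(make_layer(v, "GE"))
  expect_identical(rownames(out$values), "g1")

  vme <- rbind(c(rep(2, 11), rep(0, 89)),  # > 1 in 11/100: kept
               c(rep(2, 10), rep(0, 90)))  # > 1 in 10/100: removed
  outme <- filter_expression(make_layer(vme, "ME"))
  expect_identical(rownames(outme$values), "g1")

  scna <- make_layer(matrix(rnorm(20), 4, 5), "SCNA")
  expect_identical(filter_expression(scna), scna)
})

test_that("duplicate probes are averaged per sample", {
  v <- matrix(c(1, 3, 5,
                3, 5, 7,
                2, 2, 2), 3, 3, byrow = TRUE,
              dimnames = list(c("gA", "gA", "gB"), paste0("s", 1:3)))
  out <- aggregate_duplicates(omics_layer(v, "GE"))
  expect_equal(out$values["gA", ], c(s1 = 2, s2 = 4, s3 = 6))
  expect_equal(out$values["gB", ], c(s1 = 2, s2 = 2, s3 = 2))

  # three probes: equals the directly summed mean
  v3 <- matrix(rnorm(12), 4, 3,
               dimnames = list(c("gX", "gX", "gX", "gY"), paste0("s", 1:3)))
  out3 <- aggregate_duplicates(omics_layer(v3, "GE"))
  expect_equal(out3$values["gX", ], colSums(v3[1:3, ]) / 3)

  uniq <- make_layer(matrix(rnorm(6), 2, 3))
  expect_identical(aggregate_duplicates(uniq), uniq)
})

test_that("miRNA mapping filters interactions and averages bound miRNAs", {
  me <- make_layer(rbind(c(2, 2), c(4, 4), c(9, 9)), "ME",
                   genes = c("mir1", "mir2", "mir3"),
                   samples = c("s1", "s2"))
  ints <- data.frame(
    mirna_id = c("mir1", "mir2", "mir3"),
    gene_id = c("TP53", "TP53", "TP53"),
    n_experiments = c(6, 5, 4),       # mir3 excluded: only 4 experiments
    n_anticorrelated_cancers = c(1, 2, 5)
  )
  out <- map_mirna_to_genes(me, ints)
  expect_identical(rownames(out$values), "TP53")
  expect_equal(unname(out$values["TP53", ]), c(3, 3))  # mean of 2 and 4

  one <- map_mirna_to_genes(me, ints[1, ])
  expect_equal(unname(one$values["TP53", ]), c(2, 2))  # single miRNA copied

  expect_error(map_mirna_to_genes(me, ints, min_experiments = 100),
               "min_experiments = 100")
})

test_that("z-score normalization standardizes the whole matrix to 4 decimals", {
  layer <- make_layer(matrix(c(1, 3, 2, 4), 2, 2))
  out <- zscore_normalize(layer)
  expect_equal(mean(out$values), 0, tolerance = 1e-3)
  expect_equal(sd(as.vector(out$values)), 1, tolerance = 1e-3)
  expect_true(all(out$values == round(out$values, 4)))

  expect_error(zscore_normalize(make_layer(matrix(5, 2, 2))), "deviation")

  # per-gene scope centers every row
  big <- make_layer(matrix(rnorm(200, mean = 7, sd = 3), 10, 20))
  pg <- zscore_normalize(big, scope = "per_gene")
  expect_true(all(abs(rowMeans(pg$values)) < 1e-3))
})

test_that("alignment intersects samples and genes across layers and clinical", {
  mk <- function(kind, genes, samples) {
    make_layer(matrix(rnorm(length(genes) * length(samples)),
                      length(genes), length(samples)),
               kind, genes = genes, samples = samples)
  }
  layers <- list(
    GE = mk("GE", c("g1", "g2", "g3"), c("a", "b", "c")),
    SCNA = mk("SCNA", c("g2", "g3", "g4"), c("a", "b")),
    DM = mk("DM", c("g2", "g3"), c("a", "b", "c")),
    ME = mk("ME", c("g3", "g2"), c("b", "a"))
  )
  clin <- clinical_table(c("a", "b"), c(5, 6), c(1, 0))
  suppressMessages(ds <- align_dataset(layers, clin))
  expect_length(ds$clinical$sample_id, 2)
  for (k in c("GE", "SCNA", "DM", "ME")) {
    expect_identical(rownames(ds$layers[[k]]$values), c("g2", "g3"))
    expect_identical(colnames(ds$layers[[k]]$values),
                     ds$clinical$sample_id)
  }
  # disjoint gene sets fail
  layers$DM <- mk("DM", c("zz"), c("a", "b"))
  expect_error(suppressMessages(align_dataset(layers, clin)), "gene")
})

test_that("filters are idempotent", {
  set.seed(8)
  v <- matrix(rnorm(400), 20, 20)
  v[sample(400, 30)] <- NA
  v[1:4, ] <- abs(v[1:4, ])
  layer <- make_layer(v, "GE")
  f1 <- filter_missing(layer)
  expect_identical(filter_missing(f1), f1)
  e1 <- filter_expression(f1)
  expect_identical(filter_expression(e1), e1)
  a1 <- aggregate_duplicates(e1)
  expect_identical(aggregate_duplicates(a1), a1)
})

test_that("harmonize runs the full chain and aligns everything", {
  sim <- generate_dataset(sim_config(60, 80, n_drivers = 2,
                                     missing_frac = 0.02,
                                     dup_probe_frac = 0.1, seed = 12))
  ds <- suppressMessages(harmonize(sim$dataset$layers, sim$dataset$clinical))
  genes <- rownames(ds$layers$GE$values)
  expect_false(anyDuplicated(genes) > 0)
  for (k in c("SCNA", "DM", "ME")) {
    expect_identical(rownames(ds$layers[[k]]$values), genes)
    expect_identical(colnames(ds$layers[[k]]$values),
                     ds$clinical$sample_id)
  }
  expect_false(anyNA(ds$layers$GE$values))
  expect_equal(mean(ds$layers$DM$values), 0, tolerance = 1e-3)
})
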