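test_that("percentile handles constants, the textbook case, and edge errors", {
  expect_equal(percentile(c(5, 5, 5), 10), 5)
  expect_equal(percentile(c(5, 5, 5), 90), 5)
  expect_equal(percentile(c(1, 2, 3, 4), 25), 1.75)
  expect_error(percentile(numeric(0), 50), "empty")
  expect_error(percentile(1:3, 101), "\\[0, 100\\]")
})

test_that("percentile equals the library quantile reference on random input", {
  set.seed(51)
  for (i in 1:1000) {
    x <- rnorm(sample(1:40, 1))
    q <- runif(1, 0, 100)
    expect_equal(percentile(x, q), oracle_percentile(x, q), tolerance = 1e-12)
  }
})

screen_design <- function() {
  sample_design(
    sample_id = paste(rep(default_regions(), each = 3), 1:3, sep = "_"),
    region = rep(default_regions(), each = 3),
    replicate = rep(1:3, 6)
  )
}

expr_one_gene <- function(values, design, gene = "g1") {
  matrix(values, 1, 18, dimnames = list(gene, design$sample_id))
}

test_that("highly-expressed screen applies its three conditions as stated", {
  design <- screen_design()
  cfg <- screen_config()
  ot <- design$region == "OT"

  # strict dominance: (10, 12, 11) in target, zero elsewhere
  v <- rep(0, 18); v[ot] <- c(10, 12, 11)
  expr <- expr_one_gene(v, design)
  highly <- screen_highly_expressed(expr, design, pass_all_de("g1"), cfg)
  expect_identical(highly$OT, "g1")
  expect_identical(highly$OBT, character(0))

  # constant gene: 10 > 10 is false, percentile condition strict
  expr <- expr_one_gene(rep(10, 18), design)
  highly <- screen_highly_expressed(expr, design, pass_all_de("g1"), cfg)
  expect_true(all(lengths(highly) == 0))

  # hand-evaluated interpolation: target (5,5,5); one other sample at 6,
  # fourteen at 0 -> 90th percentile of the pooled 15 is 0 (h = 12.6)
  v <- rep(0, 18); v[ot] <- 5; v[which(!ot)[1]] <- 6
  expr <- expr_one_gene(v, design)
  expect_equal(percentile(v[!ot], 90), 0)
  highly <- screen_highly_expressed(expr, design, pass_all_de("g1"), cfg)
  expect_identical(highly$OT, "g1")

  # the DE gate: same gene fails when padj >= alpha
  de_block <- pass_all_de("g1")
  de_block$OT$padj <- 0.2
  highly <- screen_highly_expressed(expr, design, de_block, cfg)
  expect_identical(highly$OT, character(0))

  # the FPKM floor: dominant but dim gene fails min_fpkm
  v <- rep(0, 18); v[ot] <- 0.5
  expr <- expr_one_gene(v, design)
  highly <- screen_highly_expressed(expr, design, pass_all_de("g1"), cfg)
  expect_identical(highly$OT, character(0))
})

test_that("specificity ratios reproduce the published marker table", {
  fx <- published_marker_fpkm()
  cfg <- screen_config()

  expect_equal(specificity_ratio("itnp", "RB", fx$expr, fx$design, cfg),
               (3442.64 + 0.01) / (1.36 + 0.01), tolerance = 1e-12)
  expect_gt(specificity_ratio("itnp", "RB", fx$expr, fx$design, cfg), 2500)

  viaat <- specificity_ratio("viaat", "OT", fx$expr, fx$design, cfg)
  expect_equal(viaat, (77.56 + 0.01) / (34.04 + 0.01), tolerance = 1e-12)
  expect_lt(viaat, 10)
})

test_that("the pseudocount dominates an all-zero background", {
  design <- screen_design()
  v <- rep(0, 18); v[design$region == "OT"] <- 1
  expr <- expr_one_gene(v, design)
  expect_equal(specificity_ratio("g1", "OT", expr, design, screen_config()),
               1.01 / 0.01, tolerance = 1e-12)
})

test_that("the fold screen keeps 50x spikes and drops 5x genes", {
  design <- screen_design()
  cfg <- screen_config()
  make_expr <- function(target, other) {
    v <- rep(other, 18); v[design$region == "OT"] <- target
    expr_one_gene(v, design)
  }
  expr50 <- make_expr(50, 1)
  spec <- screen_specific(list(OT = "g1"), expr50, design, cfg)
  expect_identical(spec$OT$gene_id, "g1")
  expect_equal(spec$OT$ratio, 50.01 / 1.01, tolerance = 1e-12)

  expr5 <- make_expr(5, 1)
  spec <- screen_specific(list(OT = "g1"), expr5, design, cfg)
  expect_equal(nrow(spec$OT), 0L)

  empty <- screen_specific(list(OT = character(0)), expr5, design, cfg)
  expect_equal(nrow(empty$OT), 0L)
})

test_that("marker selection is top-k by ratio with deterministic tie-breaks", {
  cfg <- screen_config(top_k = 3)
  single <- list(OT = data.frame(gene_id = "gA", mean_fpkm_target = 5,
                                 agg_fpkm_other = 0.1, ratio = 20))
  expect_identical(select_markers(single, cfg)$OT$gene_id, "gA")

  four <- list(OT = data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    mean_fpkm_target = c(10, 10, 10, 10),
    agg_fpkm_other = 1,
    ratio = c(100, 50, 20, 12)))
  expect_identical(select_markers(four, cfg)$OT$gene_id, c("g1", "g2", "g3"))

  # ties: ratio, then target mean FPKM, then gene id, regardless of input order
  set.seed(61)
  tied <- data.frame(gene_id = c("gb", "ga", "gc", "gd"),
                     mean_fpkm_target = c(5, 5, 9, 5),
                     agg_fpkm_other = 1,
                     ratio = c(30, 30, 30, 30))
  for (i in 1:5) {
    perm <- tied[sample(nrow(tied)), ]
    got <- select_markers(list(OT = perm), cfg)$OT$gene_id
    expect_identical(got, c("gc", "ga", "gb"))
  }
})

test_that("the full screen recovers spiked markers and keeps sets nested", {
  sim <- simulate_counts(sim_config(n_genes = 600L, target_lib_size = 2e5,
                                    seed = 5L))
  sets <- run_screen_pipeline(sim$counts, sim$lengths, sim$design)

  for (r in names(sets$highly)) {
    expect_true(all(sets$specific[[r]]$gene_id %in% sets$highly[[r]]))
    expect_true(all(sets$markers[[r]]$gene_id %in% sets$specific[[r]]$gene_id))
    expect_lte(nrow(sets$markers[[r]]), sets$config$top_k)
  }
  # with max aggregation and a >1 threshold no gene is specific to 2 regions
  all_specific <- unlist(lapply(sets$specific, `[[`, "gene_id"))
  expect_false(anyDuplicated(all_specific) > 0)

  # this scaled-down problem (600 genes, 0.2M-read libraries) is noisier
  # than the default study size, so the smoke bound sits below the
  # default-scale expectation exercised elsewhere
  m <- evaluate_recovery(sim$truth, sets)
  expect_gte(m$sensitivity, 0.7)
  expect_gte(m$precision, 0.9)
})

test_that("boosting a gene's target counts never drops it from its sets", {
  sim <- simulate_counts(sim_config(n_genes = 600L, target_lib_size = 2e5,
                                    seed = 5L))
  sets <- run_screen_pipeline(sim$counts, sim$lengths, sim$design)
  r <- "OBT"
  g <- sets$specific[[r]]$gene_id[1]
  expect_false(is.na(g))
  boosted <- sim$counts
  cols <- sim$design$region == r
  boosted[g, cols] <- boosted[g, cols] * 2L
  sets2 <- run_screen_pipeline(boosted, sim$lengths, sim$design)
  expect_true(g %in% sets2$highly[[r]])
  expect_true(g %in% sets2$specific[[r]]$gene_id)
})

test_that("an all-zero count matrix yields empty sets everywhere", {
  design <- screen_design()
  counts <- matrix(0L, 5, 18,
                   dimnames = list(sprintf("g%d", 1:5), design$sample_id))
  lengths <- setNames(rep(1000L, 5), rownames(counts))
  sets <- run_screen_pipeline(counts, lengths, design)
  expect_true(all(lengths(sets$highly) == 0))
  expect_true(all(vapply(sets$specific, nrow, integer(1)) == 0))
  expect_true(all(vapply(sets$markers, nrow, integer(1)) == 0))
})

test_that("screen configs round-trip through YAML with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.01", "fold_threshold: 5", "other_aggregation: mean"),
             path)
  cfg <- read_screen_config(path)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$fold_threshold, 5)
  expect_equal(cfg$other_aggregation, "mean")
  expect_equal(cfg$q_lo, 25)

  writeLines("bogus_key: 1", path)
  expect_error(read_screen_config(path), "unknown screen config key")
  expect_error(screen_config(fold_threshold = 1), "fold_threshold")
})

test_that("screen outputs are written per region with a summary", {
  sim <- simulate_counts(sim_config(n_genes = 200L, target_lib_size = 1e5,
                                    seed = 8L))
  sets <- run_screen_pipeline(sim$counts, sim$lengths, sim$design)
  out <- withr::local_tempdir()
  write_screen_results(sets, out)
  expect_true(file.exists(file.path(out, "highly_OT.tsv")))
  expect_true(file.exists(file.path(out, "specific_RB.tsv")))
  expect_true(file.exists(file.path(out, "markers.tsv")))
  summary <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summary$config$fold_threshold, 10)
  expect_named(summary$n_specific, default_regions())
})
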