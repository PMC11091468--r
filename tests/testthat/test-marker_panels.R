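test_that("panel validation rejects malformed panels", {
  expect_error(marker_panel("p", list(a = character(0))), "empty")
  expect_error(marker_panel("p", list(a = c("g1", "g1"))),
               "duplicate gene id within panel entry")
  expect_error(marker_panel("p", setNames(list("g1", "g2"), c("a", "a"))),
               "duplicate type label")
})

test_that("bundled panels load and carry the expected cell types", {
  neurons <- default_neuron_panel()
  expect_s3_class(neurons, "marker_panel")
  expect_setequal(names(neurons$entries),
                  c("glutamatergic", "GABAergic", "glycinergic",
                    "dopaminergic", "serotonergic", "noradrenergic",
                    "cholinergic"))
  expect_identical(neurons$entries$glycinergic, "slc6a5")

  nonneuronal <- default_nonneuronal_panel()
  expect_setequal(names(nonneuronal$entries),
                  c("oligodendrocytes", "microglia", "endothelial",
                    "radial_astrocytes", "neuroprogenitors"))
  expect_identical(nonneuronal$entries$radial_astrocytes, "cx43")
})

test_that("single-gene types peak where their gene does", {
  fx <- published_marker_fpkm()
  # every published marker as its own one-gene "type": top region must be
  # the gene's assigned region, 18/18
  panel <- marker_panel("per_gene",
                        setNames(as.list(fx$truth$gene_id), fx$truth$gene_id))
  prof <- profile_panel(fx$expr, fx$design, panel)
  expect_identical(unname(prof$argmax[fx$truth$gene_id]),
                   fx$truth$assigned_region)
  # the glycinergic marker peaks in the medulla oblongata
  glyc <- profile_panel(fx$expr, fx$design,
                        marker_panel("glyc", list(glycinergic = "slc6a5")))
  expect_identical(unname(glyc$argmax), "Mo")
  expect_equal(glyc$values["glycinergic", "Mo"], 22.71)
})

test_that("multi-gene types sum region means and report rankings", {
  design <- sample_design(sample_id = c("r1", "r2"), region = c("OBT", "Hy"),
                          replicate = c(1L, 1L), regions = c("OBT", "Hy"))
  expr <- matrix(c(3, 4, 5, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("r1", "r2")))
  prof <- profile_panel(expr, design,
                        marker_panel("p", list(combo = c("gA", "gB"))))
  expect_equal(unname(prof$values["combo", ]), c(8, 4))
  expect_identical(unname(prof$argmax), "OBT")
  expect_identical(prof$ranking$combo, c("OBT", "Hy"))

  # mean aggregation halves the two-gene sum
  prof_mean <- profile_panel(expr, design,
                             marker_panel("p", list(combo = c("gA", "gB"))),
                             aggregation = "mean")
  expect_equal(unname(prof_mean$values["combo", ]), c(4, 2))
})

test_that("profiles are additive over disjoint gene lists", {
  fx <- published_marker_fpkm()
  p1 <- profile_panel(fx$expr, fx$design,
                      marker_panel("a", list(t = c("itnp", "vtnp"))))
  p2 <- profile_panel(fx$expr, fx$design,
                      marker_panel("b", list(t = c("rln3", "prph"))))
  p12 <- profile_panel(fx$expr, fx$design,
                       marker_panel("ab", list(t = c("itnp", "vtnp", "rln3",
                                                     "prph"))))
  expect_equal(p12$values["t", ], p1$values["t", ] + p2$values["t", ])
})

test_that("profiles ignore gene order and sample order", {
  sim <- simulate_counts(sim_config(n_genes = 50L, markers_per_region = 0L,
                                    target_lib_size = 1e5, seed = 4L))
  expr <- compute_fpkm(sim$counts, sim$lengths)
  panel <- marker_panel("p", list(t = c("g0001", "g0002", "g0003")))
  panel_rev <- marker_panel("p", list(t = c("g0003", "g0001", "g0002")))
  base <- profile_panel(expr, sim$design, panel)
  expect_equal(profile_panel(expr, sim$design, panel_rev)$values, base$values)

  perm <- sample(ncol(expr))
  design_perm <- sample_design(sim$design$sample_id[perm],
                               as.character(sim$design$region)[perm],
                               sim$design$replicate[perm])
  expect_equal(profile_panel(expr[, perm], design_perm, panel)$values,
               base$values)
})

test_that("missing panel genes warn and are reported, all-missing errors", {
  fx <- published_marker_fpkm()
  panel <- marker_panel("p", list(t = c("itnp", "no_such_gene")))
  expect_warning(prof <- profile_panel(fx$expr, fx$design, panel),
                 "no_such_gene")
  expect_identical(prof$unmatched$t, "no_such_gene")
  expect_identical(prof$matched$t, "itnp")
  expect_equal(unname(prof$values["t", "RB"]), 3442.64)

  ghost <- marker_panel("p", list(t = "no_such_gene"))
  expect_error(suppressWarnings(profile_panel(fx$expr, fx$design, ghost)),
               "matched no genes")
})

test_that("receptor families total their member genes' region means", {
  design <- sample_design(sample_id = c("r1", "r2"), region = c("OBT", "Hy"),
                          replicate = c(1L, 1L), regions = c("OBT", "Hy"))
  expr <- matrix(c(1, 2, 10, 20, 100, 200), 3, 2, byrow = TRUE,
                 dimnames = list(c("rcp1", "rcp2", "rcp3"), c("r1", "r2")))
  fam <- marker_panel("receptors",
                      list(glutamate = c("rcp1", "rcp2", "rcp3"),
                           single = "rcp2"))
  prof <- aggregate_receptor_expression(expr, design, fam)
  expect_equal(unname(prof$values["glutamate", ]), c(111, 222))
  expect_equal(unname(prof$values["single", ]), c(10, 20))
})

test_that("profiles write to TSV with the argmax column", {
  fx <- published_marker_fpkm()
  prof <- profile_panel(fx$expr, fx$design,
                        marker_panel("p", list(t = "itnp", u = "aldoca")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- utils::read.delim(path)
  expect_identical(back$argmax_region, c("RB", "Ce"))
})
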