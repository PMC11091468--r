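#' Simulation configuration
#'
#' Parameters of the synthetic bulk RNA-seq experiment the screen is
#' validated against: a 6-region x 3-replicate design with negative-binomial
#' counts, log-normal baseline expression, and spiked region-specific genes
#' of known fold.
#'
#' @param n_genes Number of genes (default 2000).
#' @param regions Region labels (default the six dissection regions).
#' @param reps_per_region Replicates per region (default 3).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   FPKM (defaults log(10) and 1.5).
#' @param phi NB dispersion, variance `mu + phi * mu^2` (default 0.1).
#' @param markers_per_region Spiked region-specific genes per region
#'   (default 10).
#' @param marker_fold Multiplicative spike applied to expected FPKM in the
#'   assigned region only (default 20).
#' @param length_range Gene length range in bp, sampled uniformly (default
#'   500-5000).
#' @param target_lib_size Expected library size per sample (default 1e6).
#' @param seed Integer seed governing all draws; per-stage sub-seeds are
#'   derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, regions = default_regions(),
                       reps_per_region = 3L,
                       baseline_meanlog = log(10), baseline_sdlog = 1.5,
                       phi = 0.1, markers_per_region = 10L, marker_fold = 20,
                       length_range = c(500L, 5000L),
                       target_lib_size = 1e6, seed = 1L) {
  stopifnot(n_genes >= 1L, reps_per_region >= 1L, length(regions) >= 2L,
            phi >= 0, marker_fold >= 1, markers_per_region >= 0L,
            target_lib_size > 0, length_range[1L] > 0,
            length_range[2L] >= length_range[1L])
  if (markers_per_region * length(regions) > n_genes) {
    stop("markers_per_region * number of regions exceeds n_genes")
  }
  structure(list(n_genes = as.integer(n_genes), regions = regions,
                 reps_per_region = as.integer(reps_per_region),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, phi = phi,
                 markers_per_region = as.integer(markers_per_region),
                 marker_fold = marker_fold,
                 length_range = as.integer(length_range),
                 target_lib_size = target_lib_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Derived per-stage seed, kept within 32-bit integer range.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483600)
}

#' Simulate a region-labelled count matrix with spiked markers
#'
#' Draws per-gene baseline expected FPKM log-normally, rescales the
#' baselines by one constant so that `sum(FPKM * length_kb) = 1e6` (the
#' FPKM conservation identity), assigns `markers_per_region` spiked genes
#' per region whose expected FPKM is multiplied by `marker_fold` in that
#' region only, inverts the FPKM formula to expected counts, renormalizes
#' each sample's expectation to the target library size (depth is set by
#' the sequencing run, not by tissue expression), and draws counts
#' NB(mean mu, variance mu + phi * mu^2). Spiked genes are drawn from genes
#' holding at most 0.1% of the expected library, so a spike never rewrites
#' a sample's composition and the nominal fold is the fold realized in
#' FPKM. Each stage (lengths, baselines, spike assignment, counts) uses its
#' own sub-seed, so the run is fully reproducible from `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List with `counts` (integer matrix), `lengths` (named bp vector),
#'   `design` (a `sample_design`), `truth` (data.frame `gene_id`,
#'   `assigned_region`, `true_fold`) and `expected_fpkm` (the noise-free
#'   gene x sample expectation, for diagnostics).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  regs <- config$regions
  gene_ids <- sprintf("g%04d", seq_len(n))

  design <- sample_design(
    sample_id = paste(rep(regs, each = config$reps_per_region),
                      rep(seq_len(config$reps_per_region), length(regs)),
                      sep = "_"),
    region = rep(regs, each = config$reps_per_region),
    replicate = rep(seq_len(config$reps_per_region), length(regs)),
    regions = regs
  )

  set.seed(stage_seed(config$seed, 1))
  len <- sample(config$length_range[1L]:config$length_range[2L], n,
                replace = TRUE)
  names(len) <- gene_ids

  set.seed(stage_seed(config$seed, 2))
  baseline <- stats::rlnorm(n, meanlog = config$baseline_meanlog,
                            sdlog = config$baseline_sdlog)
  baseline <- baseline * 1e6 / sum(baseline * len / 1000)

  set.seed(stage_seed(config$seed, 3))
  n_spiked <- config$markers_per_region * length(regs)
  # spikes must leave library composition essentially intact, or the nominal
  # fold is not the fold realized in FPKM: restrict eligibility to genes
  # holding <= 0.1% of the expected library (the mean share is 1/n_genes)
  share <- baseline * (len / 1000) / 1e6
  eligible <- which(share <= 0.001)
  if (length(eligible) < n_spiked) {
    eligible <- order(share)[seq_len(min(n, n_spiked))]
  }
  spiked_idx <- if (n_spiked > 0L) {
    eligible[sample.int(length(eligible), n_spiked)]
  } else integer(0)
  truth <- data.frame(
    gene_id = gene_ids[spiked_idx],
    assigned_region = rep(regs, each = config$markers_per_region),
    true_fold = rep(config$marker_fold, n_spiked),
    stringsAsFactors = FALSE
  )

  fold <- matrix(1, nrow = n, ncol = nrow(design),
                 dimnames = list(gene_ids, design$sample_id))
  for (k in seq_len(nrow(truth))) {
    cols <- design$region == truth$assigned_region[k]
    fold[truth$gene_id[k], cols] <- truth$true_fold[k]
  }

  expected_fpkm <- baseline * fold
  mu <- expected_fpkm * (len / 1000) * config$target_lib_size / 1e6
  # sequencing depth is fixed by the run, not by tissue expression: spikes
  # change composition, so renormalize each sample's expectation to target
  mu <- sweep(mu, 2L, config$target_lib_size / colSums(mu), "*")

  set.seed(stage_seed(config$seed, 4))
  counts <- if (config$phi > 0) {
    matrix(stats::rnbinom(length(mu), size = 1 / config$phi, mu = mu),
           nrow = n, dimnames = dimnames(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu),
           nrow = n, dimnames = dimnames(mu))
  }
  storage.mode(counts) <- "integer"

  list(counts = counts, lengths = len, design = design, truth = truth,
       expected_fpkm = expected_fpkm)
}

#' Evaluate marker recovery against simulation truth
#'
#' Sensitivity is the fraction of spiked genes found in their assigned
#' region's specific set; precision is the fraction of specific-set calls
#' (over all regions) that are true spikes of that region. When the
#' pipeline makes no specific calls at all, precision is reported as 1.0
#' with `zero_calls = TRUE` (no false calls were made).
#'
#' @param truth Truth data.frame from [simulate_counts()].
#' @param result A `region_gene_sets` from [run_screen_pipeline()], or a
#'   named per-region list of specific-gene tables / gene-id vectors.
#' @return List with `sensitivity`, `precision`, `zero_calls`, and a
#'   `per_region` data.frame (`region`, `n_true`, `n_called`, `n_correct`).
#' @export
evaluate_recovery <- function(truth, result) {
  specific <- if (inherits(result, "region_gene_sets")) result$specific else result
  called <- lapply(specific, function(x) {
    if (is.data.frame(x)) x$gene_id else as.character(x)
  })
  regions <- union(names(called), unique(truth$assigned_region))
  per_region <- do.call(rbind, lapply(regions, function(r) {
    truth_r <- truth$gene_id[truth$assigned_region == r]
    called_r <- if (r %in% names(called)) called[[r]] else character(0)
    data.frame(region = r, n_true = length(truth_r),
               n_called = length(called_r),
               n_correct = length(intersect(truth_r, called_r)),
               stringsAsFactors = FALSE)
  }))
  n_true <- sum(per_region$n_true)
  n_called <- sum(per_region$n_called)
  n_correct <- sum(per_region$n_correct)
  list(
    sensitivity = if (n_true > 0L) n_correct / n_true else NA_real_,
    precision = if (n_called > 0L) n_correct / n_called else 1.0,
    zero_calls = n_called == 0L,
    per_region = per_region
  )
}

#' Write and read a simulation truth table
#'
#' @param truth Truth data.frame.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if ("true_fold" %in% names(d)) d$true_fold <- as.numeric(d$true_fold)
  d
}

#' Published marker FPKM table for the six brain regions
#'
#' The 18-candidate-marker x 6-region table of mean FPKM values from the
#' published study of teleost brain-region markers that this pipeline operationalizes (three
#' candidate markers per region), transcribed verbatim, together with each
#' gene's assigned region. Treated as region means (one value per region),
#' it drives the worked-example tests of the specificity ratio and the
#' panel profiler.
#'
#' @return List with `expr` (18 x 6 matrix, columns OBT/Hy/OT/Ce/Mo/RB),
#'   `truth` (data.frame `gene_id`, `assigned_region`) and `design` (a
#'   `sample_design` with one pseudo-sample per region, so region means
#'   equal the printed values).
#' @export
published_marker_fpkm <- function() {
  path <- system.file("extdata", "published_marker_fpkm.tsv",
                      package = "regionmarkers", mustWork = TRUE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  regs <- default_regions()
  expr <- as.matrix(d[, regs])
  rownames(expr) <- d$gene_id
  design <- sample_design(sample_id = regs, region = regs,
                          replicate = rep(1L, length(regs)))
  list(expr = expr,
       truth = data.frame(gene_id = d$gene_id,
                          assigned_region = d$assigned_region,
                          stringsAsFactors = FALSE),
       design = design)
}
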