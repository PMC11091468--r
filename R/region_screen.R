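#' Screen configuration
#'
#' Bundles the tunable thresholds of the two-step marker screen.
#'
#' @param alpha Adjusted-p threshold for the differential-expression gate
#'   (default 0.05).
#' @param q_lo Lower percentile evaluated within the target region (default
#'   25).
#' @param q_hi Upper percentile evaluated over all other samples pooled
#'   (default 90).
#' @param min_fpkm Expression floor on the target-region mean FPKM (default
#'   1).
#' @param fold_threshold Specificity ratio required for a region-specific
#'   call (default 10).
#' @param epsilon Pseudocount in FPKM units added to both sides of every
#'   ratio (default 0.01; printed marker tables contain exact zeros, so a
#'   pseudocount is mandatory, and 0.01 sits below the smallest nonzero
#'   entry of the reference table).
#' @param other_aggregation How the non-target regions are summarized for
#'   the fold rule: `"max"` (strictest reading; default) or `"mean"` of the
#'   per-region mean FPKMs.
#' @param top_k Markers retained per region (default 3).
#' @return A `screen_config` list.
#' @export
screen_config <- function(alpha = 0.05, q_lo = 25, q_hi = 90, min_fpkm = 1,
                          fold_threshold = 10, epsilon = 0.01,
                          other_aggregation = c("max", "mean"), top_k = 3L) {
  other_aggregation <- match.arg(other_aggregation)
  stopifnot(alpha > 0, alpha < 1,
            q_lo >= 0, q_hi <= 100, q_lo < q_hi,
            fold_threshold > 1, epsilon > 0, top_k >= 1L)
  structure(list(alpha = alpha, q_lo = q_lo, q_hi = q_hi,
                 min_fpkm = min_fpkm, fold_threshold = fold_threshold,
                 epsilon = epsilon, other_aggregation = other_aggregation,
                 top_k = as.integer(top_k)),
            class = "screen_config")
}

#' Read a screen configuration from YAML
#'
#' Keys mirror the arguments of [screen_config()] exactly; absent keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `screen_config`.
#' @export
read_screen_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screen_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) stop("unknown screen config key(s): ", paste(bad, collapse = ", "))
  do.call(screen_config, vals)
}

#' Linear-interpolation percentile
#'
#' The percentile of a vector at `q` in \[0, 100\], by linear interpolation
#' on the sorted values at fractional rank `h = (n - 1) * q / 100`. This is
#' the convention most numeric libraries default to. The screen's pass/fail
#' behaviour at three replicates is sensitive to the percentile definition,
#' so it is fixed here rather than configurable.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in \[0, 100\].
#' @return A value between `min(values)` and `max(values)`.
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("percentile of an empty vector is undefined")
  if (q < 0 || q > 100) stop("q must lie in [0, 100]")
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * q / 100
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo + 1] + (h - lo) * (x[hi + 1] - x[lo + 1])
}

#' Per-region mean FPKM
#'
#' @param expr FPKM matrix (genes x samples).
#' @param design A `sample_design` aligned to `expr` columns.
#' @return Matrix genes x regions of mean FPKM.
#' @export
region_mean_fpkm <- function(expr, design) {
  regs <- levels(design$region)
  out <- vapply(regs, function(r) {
    rowMeans(expr[, design$sample_id[design$region == r], drop = FALSE])
  }, numeric(nrow(expr)))
  if (nrow(expr) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(expr), regs))
  out
}

#' Screen region-highly expressed genes
#'
#' A gene is called highly expressed in a region when (i) its region-vs-rest
#' adjusted p-value is below `alpha`, (ii) the `q_lo`-th percentile of its
#' FPKM over the region's replicates strictly exceeds the `q_hi`-th
#' percentile of its FPKM over all remaining samples pooled, and (iii) its
#' mean FPKM in the region is at least `min_fpkm`. The pooled reading of
#' "all other regions" treats the non-target samples as one population.
#'
#' @param expr FPKM matrix.
#' @param design A `sample_design`.
#' @param de Named list of region-vs-rest result data.frames (one per
#'   region, as from [region_vs_rest()]).
#' @param config A `screen_config`.
#' @return Named list (per region) of gene-id character vectors.
#' @export
screen_highly_expressed <- function(expr, design, de, config = screen_config()) {
  regs <- levels(design$region)
  out <- stats::setNames(vector("list", length(regs)), regs)
  for (r in regs) {
    der <- de[[r]]
    if (is.null(der)) stop("no DE result supplied for region ", r)
    if (!identical(der$gene_id, rownames(expr))) {
      stop("DE result for region ", r, " does not match the expression gene universe")
    }
    in_region <- design$region == r
    target <- expr[, in_region, drop = FALSE]
    other <- expr[, !in_region, drop = FALSE]
    q_t <- apply(target, 1L, percentile, q = config$q_lo)
    q_o <- apply(other, 1L, percentile, q = config$q_hi)
    pass <- der$padj < config$alpha &
      q_t > q_o &
      rowMeans(target) >= config$min_fpkm
    out[[r]] <- rownames(expr)[pass]
  }
  out
}

#' Specificity ratio of one gene for one region
#'
#' `(mean FPKM in region + epsilon) / (AGG over other regions of per-region
#' mean FPKM + epsilon)`, where AGG is the configured aggregation (max or
#' mean).
#'
#' @param gene Gene id.
#' @param region Target region label.
#' @param expr FPKM matrix.
#' @param design A `sample_design`.
#' @param config A `screen_config`.
#' @return A positive ratio.
#' @export
specificity_ratio <- function(gene, region, expr, design,
                              config = screen_config()) {
  if (!gene %in% rownames(expr)) stop("unknown gene id: ", gene)
  means <- region_mean_fpkm(expr[gene, , drop = FALSE], design)
  specificity_ratios_from_means(means, region, config)[[1L]]
}

# Vectorized ratio over a genes-x-regions mean-FPKM matrix.
specificity_ratios_from_means <- function(means, region, config) {
  if (!region %in% colnames(means)) stop("unknown region label: ", region)
  other <- means[, colnames(means) != region, drop = FALSE]
  agg <- switch(config$other_aggregation,
                max = apply(other, 1L, max),
                mean = rowMeans(other))
  stats::setNames((means[, region] + config$epsilon) / (agg + config$epsilon),
                  rownames(means))
}

#' Screen region-specifically expressed genes
#'
#' Restricts each region's highly expressed set to genes whose specificity
#' ratio meets `fold_threshold`.
#'
#' @param highly Named per-region list of highly expressed gene ids.
#' @param expr FPKM matrix.
#' @param design A `sample_design`.
#' @param config A `screen_config`.
#' @return Named list of data.frames with columns `gene_id`,
#'   `mean_fpkm_target`, `agg_fpkm_other`, `ratio`, sorted by descending
#'   ratio.
#' @export
screen_specific <- function(highly, expr, design, config = screen_config()) {
  means <- region_mean_fpkm(expr, design)
  out <- stats::setNames(vector("list", length(highly)), names(highly))
  for (r in names(highly)) {
    genes <- highly[[r]]
    if (length(genes) == 0L) {
      out[[r]] <- empty_specific_table()
      next
    }
    ratios <- specificity_ratios_from_means(means[genes, , drop = FALSE], r, config)
    keep <- ratios >= config$fold_threshold
    genes <- genes[keep]
    tab <- data.frame(
      gene_id = genes,
      mean_fpkm_target = unname(means[genes, r]),
      agg_fpkm_other = unname((means[genes, r] + config$epsilon) / ratios[keep] -
                                config$epsilon),
      ratio = unname(ratios[keep]),
      stringsAsFactors = FALSE
    )
    out[[r]] <- tab[order(-tab$ratio, -tab$mean_fpkm_target, tab$gene_id), ,
                    drop = FALSE]
    rownames(out[[r]]) <- NULL
  }
  out
}

empty_specific_table <- function() {
  data.frame(gene_id = character(0), mean_fpkm_target = numeric(0),
             agg_fpkm_other = numeric(0), ratio = numeric(0),
             stringsAsFactors = FALSE)
}

#' Select top marker genes per region
#'
#' The markers of a region are its `top_k` specific genes with the highest
#' specificity ratio; ties are broken by descending target-region mean FPKM,
#' then lexicographic gene id, so the selection is deterministic.
#'
#' @param specific Named per-region list of specific-gene tables from
#'   [screen_specific()].
#' @param config A `screen_config`.
#' @return Named list of data.frames, each at most `top_k` rows.
#' @export
select_markers <- function(specific, config = screen_config()) {
  lapply(specific, function(tab) {
    ord <- order(-tab$ratio, -tab$mean_fpkm_target, tab$gene_id)
    out <- tab[ord, , drop = FALSE][seq_len(min(config$top_k, nrow(tab))), ,
                                    drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the full marker screen
#'
#' Composes FPKM normalization, per-region differential expression against
#' the pooled rest, the percentile screen for region-highly expressed genes,
#' the fold screen for region-specifically expressed genes, and marker
#' selection.
#'
#' @param counts Count matrix aligned to `design`.
#' @param lengths Gene lengths (bp) covering every gene.
#' @param design A `sample_design`.
#' @param config A `screen_config`.
#' @return A `region_gene_sets` list with elements `highly`, `specific`,
#'   `markers` (per-region), plus `fpkm`, `de` and the `config` used.
#' @export
run_screen_pipeline <- function(counts, lengths, design,
                                config = screen_config()) {
  counts <- validate_counts(counts)
  regs <- levels(design$region)
  if (all(counts == 0)) {
    # no expressed gene anywhere: every set is empty and FPKM is all zero
    fpkm <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
    empty <- stats::setNames(lapply(regs, function(r) character(0)), regs)
    spec <- stats::setNames(lapply(regs, function(r) empty_specific_table()), regs)
    return(structure(list(highly = empty, specific = spec, markers = spec,
                          fpkm = fpkm, de = NULL, config = config),
                     class = "region_gene_sets"))
  }
  fpkm <- compute_fpkm(counts, lengths)
  de <- stats::setNames(lapply(regs, function(r) {
    region_vs_rest(counts, design, r, expr = fpkm, epsilon = config$epsilon)
  }), regs)
  highly <- screen_highly_expressed(fpkm, design, de, config)
  specific <- screen_specific(highly, fpkm, design, config)
  markers <- select_markers(specific, config)
  structure(list(highly = highly, specific = specific, markers = markers,
                 fpkm = fpkm, de = de, config = config),
            class = "region_gene_sets")
}

#' @export
print.region_gene_sets <- function(x, ...) {
  cat("Region gene sets (", length(x$highly), " regions)\n", sep = "")
  for (r in names(x$highly)) {
    cat(sprintf("  %-4s highly: %4d  specific: %3d  markers: %s\n",
                r, length(x$highly[[r]]), nrow(x$specific[[r]]),
                paste(x$markers[[r]]$gene_id, collapse = ", ")))
  }
  invisible(x)
}

#' Write per-region screen outputs
#'
#' Writes `highly_<region>.tsv`, `specific_<region>.tsv`, a combined
#' `markers.tsv` and a `summary.json` (config echo and set sizes) under
#' `out_dir`.
#'
#' @param sets A `region_gene_sets`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_results <- function(sets, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (r in names(sets$highly)) {
    utils::write.table(data.frame(gene_id = sets$highly[[r]]),
                       file.path(out_dir, paste0("highly_", r, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sets$specific[[r]],
                       file.path(out_dir, paste0("specific_", r, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  markers <- do.call(rbind, lapply(names(sets$markers), function(r) {
    tab <- sets$markers[[r]]
    if (nrow(tab) == 0L) return(NULL)
    cbind(region = r, tab)
  }))
  if (is.null(markers)) {
    markers <- data.frame(region = character(0), gene_id = character(0),
                          mean_fpkm_target = numeric(0),
                          agg_fpkm_other = numeric(0), ratio = numeric(0))
  }
  utils::write.table(markers, file.path(out_dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    config = unclass(sets$config),
    n_highly = as.list(vapply(sets$highly, length, integer(1))),
    n_specific = as.list(vapply(sets$specific, nrow, integer(1))),
    n_markers = as.list(vapply(sets$markers, nrow, integer(1)))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
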