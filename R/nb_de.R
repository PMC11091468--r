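#' Scale counts to a common library size
#'
#' Linearly scales each sample's counts to the geometric mean of the library
#' sizes and rounds half-to-even, so that group sums are exchangeable for the
#' conditional exact test. The rounding rule is fixed for reproducibility.
#'
#' @param counts Numeric matrix (genes x samples) or vector of counts.
#' @param lib_sizes Per-sample library sizes (recycled along columns).
#' @return Matrix/vector of scaled integer counts.
#' @keywords internal
scale_to_common_libsize <- function(counts, lib_sizes) {
  ref <- exp(mean(log(lib_sizes)))
  if (is.matrix(counts)) {
    round(sweep(counts, 2L, ref / lib_sizes, "*"))
  } else {
    round(counts * ref / lib_sizes)
  }
}

#' Estimate a common negative-binomial dispersion
#'
#' Moment estimator of the shared overdispersion phi in the variance
#' function `var = mu + phi * mu^2`. Counts are first linearly scaled to the
#' geometric-mean library size (no rounding; the estimator is continuous).
#' For every gene, each group with at least two replicates contributes a
#' within-group moment estimate `(s2 - m) / m^2` from its sample mean `m`
#' and variance `s2`; these are combined per gene with degrees-of-freedom
#' weights, clamped at zero, and the common dispersion is their median over
#' genes with positive mean in every contributing group. Deterministic;
#' `phi = 0` degenerates to Poisson.
#'
#' @param counts Count matrix (genes x samples).
#' @param groups Factor (length `ncol(counts)`) or character vector giving
#'   the two-group partition of samples.
#' @param lib_sizes Optional per-sample library sizes; column sums by
#'   default.
#' @return A single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, groups, lib_sizes = NULL) {
  if (all(counts == 0)) stop("cannot estimate dispersion from an all-zero matrix")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("groups must define a two-group partition")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  ref <- exp(mean(log(lib_sizes)))
  scaled <- sweep(counts, 2L, ref / lib_sizes, "*")
  raw <- NULL
  dfs <- numeric(0)
  for (g in levels(groups)) {
    sub <- scaled[, groups == g, drop = FALSE]
    if (ncol(sub) < 2L) next
    m <- rowMeans(sub)
    s2 <- apply(sub, 1L, stats::var)
    phi_g <- ifelse(m > 0, (s2 - m) / m^2, NA_real_)
    raw <- cbind(raw, phi_g)
    dfs <- c(dfs, ncol(sub) - 1)
  }
  if (is.null(raw)) {
    stop("dispersion estimation needs at least one group with >= 2 replicates")
  }
  per_gene <- apply(raw, 1L, function(r) {
    ok <- !is.na(r)
    if (!any(ok)) return(NA_real_)
    sum(r[ok] * dfs[ok]) / sum(dfs[ok])
  })
  stats::median(pmax(0, per_gene), na.rm = TRUE)
}

# Conditional double-tail p-value from the two group sums.
# S_a ~ NB(n_a * mu, phi / n_a), S_b ~ NB(n_b * mu, phi / n_b) with
# mu = T / (n_a + n_b); conditional on T = S_a + S_b the p-value sums the
# probabilities of all splits no more probable than the observed one
# (ties included with relative tolerance 1e-7, the exact-binomial
# convention). phi = 0 uses the Poisson limit.
exact_p_from_sums <- function(s_a, t_total, n_a, n_b, phi) {
  if (t_total == 0) return(1)
  s <- 0:t_total
  mu <- t_total / (n_a + n_b)
  if (phi > 0) {
    logf <- stats::dnbinom(s, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      stats::dnbinom(t_total - s, size = n_b / phi, mu = n_b * mu, log = TRUE)
  } else {
    logf <- stats::dpois(s, n_a * mu, log = TRUE) +
      stats::dpois(t_total - s, n_b * mu, log = TRUE)
  }
  logf <- logf - max(logf)
  w <- exp(logf)
  p <- sum(w[logf <= logf[s_a + 1L] + log1p(1e-7)]) / sum(w)
  min(max(p, .Machine$double.xmin), 1)
}

#' Negative-binomial conditional exact test for one gene
#'
#' Two-sided exact test of a difference in expression between two groups of
#' replicate counts, under a negative-binomial model with shared dispersion
#' `phi` (variance `mu + phi * mu^2`). Counts are scaled to the
#' geometric-mean library size (rounded half-to-even), summed per group, and
#' the double-tail p-value is computed conditional on the total: the sum of
#' probabilities of every split of the total whose probability does not
#' exceed the observed split's. The group-sum law uses the exactness of
#' NB sums under a shared dispersion: a sum of n i.i.d. NB(mu, phi) is
#' NB(n * mu, phi / n).
#'
#' @param counts_a,counts_b Non-negative replicate counts for the gene in
#'   groups A and B.
#' @param phi Common dispersion, >= 0 (0 = Poisson).
#' @param lib_sizes_a,lib_sizes_b Optional library sizes per replicate; equal
#'   libraries assumed when omitted.
#' @return Two-sided p-value in (0, 1]; an all-zero gene returns 1 so it can
#'   never be called differential.
#' @export
nb_exact_test <- function(counts_a, counts_b, phi,
                          lib_sizes_a = NULL, lib_sizes_b = NULL) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("counts must be non-negative")
  if (length(counts_a) < 1L || length(counts_b) < 1L) {
    stop("each group needs at least one replicate")
  }
  if (phi < 0) stop("phi must be >= 0")
  if (!is.null(lib_sizes_a) || !is.null(lib_sizes_b)) {
    if (is.null(lib_sizes_a) || is.null(lib_sizes_b)) {
      stop("provide library sizes for both groups or neither")
    }
    libs <- c(lib_sizes_a, lib_sizes_b)
    scaled <- scale_to_common_libsize(c(counts_a, counts_b), libs)
    counts_a <- scaled[seq_along(counts_a)]
    counts_b <- scaled[-seq_along(counts_a)]
  }
  s_a <- sum(counts_a)
  s_b <- sum(counts_b)
  exact_p_from_sums(s_a, s_a + s_b, length(counts_a), length(counts_b), phi)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validating front end to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order, each >= its raw p-value.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Region-vs-rest differential expression
#'
#' Tests every gene for differential expression between one region's samples
#' and all remaining samples pooled as a single group, using the
#' negative-binomial conditional exact test with a common moment-estimated
#' dispersion, then adjusts p-values by Benjamini-Hochberg across genes.
#' Fold changes are computed on FPKM with a pseudocount:
#' `log2((mean_region + eps) / (mean_rest + eps))`.
#'
#' @param counts Count matrix aligned to `design`.
#' @param design A `sample_design`.
#' @param region Target region label.
#' @param expr FPKM matrix with the same dimnames as `counts`; computed from
#'   `counts` and `lengths` when omitted and `lengths` is given.
#' @param lengths Optional gene lengths, used only when `expr` is missing.
#' @param epsilon Pseudocount (FPKM units) for the fold change; default 0.01.
#' @param phi Optional fixed dispersion; estimated from the region-vs-rest
#'   partition when `NULL`.
#' @return A data.frame with columns `gene_id`, `log2fc`, `pvalue`, `padj`.
#' @export
region_vs_rest <- function(counts, design, region, expr = NULL,
                           lengths = NULL, epsilon = 0.01, phi = NULL) {
  counts <- validate_counts(counts)
  if (!identical(colnames(counts), design$sample_id)) {
    stop("counts columns must match the design sample order")
  }
  if (!region %in% levels(design$region)) stop("unknown region label: ", region)
  if (is.null(expr)) {
    if (is.null(lengths)) stop("provide either expr (FPKM) or lengths")
    expr <- compute_fpkm(counts, lengths)
  }
  if (!identical(rownames(expr), rownames(counts))) {
    stop("expr and counts must share the same gene universe and order")
  }
  in_region <- design$region == region
  if (!any(!in_region)) stop("the rest group is empty")
  lib_sizes <- colSums(counts)
  if (is.null(phi)) {
    phi <- estimate_common_dispersion(counts, ifelse(in_region, "target", "rest"),
                                      lib_sizes = lib_sizes)
  }
  scaled <- scale_to_common_libsize(counts, lib_sizes)
  s_a <- rowSums(scaled[, in_region, drop = FALSE])
  s_b <- rowSums(scaled[, !in_region, drop = FALSE])
  n_a <- sum(in_region)
  n_b <- sum(!in_region)
  pvals <- vapply(seq_len(nrow(counts)), function(i) {
    exact_p_from_sums(s_a[i], s_a[i] + s_b[i], n_a, n_b, phi)
  }, numeric(1))
  mean_target <- rowMeans(expr[, in_region, drop = FALSE])
  mean_rest <- rowMeans(expr[, !in_region, drop = FALSE])
  data.frame(
    gene_id = rownames(counts),
    log2fc = log2((mean_target + epsilon) / (mean_rest + epsilon)),
    pvalue = pvals,
    padj = bh_adjust(pvals),
    stringsAsFactors = FALSE
  )
}
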