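# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the package internals: plain loops,
# linear-scale probabilities, library quantile routines.

# Brute-force double-tail p-value for the conditional NB exact test:
# enumerate every split (s, T - s) of the total, with group sums distributed
# NB(n_k * mu, phi / n_k) at mu = T / (n_a + n_b), and sum the probabilities
# of all splits no more probable than the observed one.
oracle_exact_p <- function(s_a, t_total, n_a, n_b, phi) {
  if (t_total == 0) return(1)
  mu <- t_total / (n_a + n_b)
  f <- numeric(t_total + 1)
  for (s in 0:t_total) {
    if (phi > 0) {
      f[s + 1] <- dnbinom(s, size = n_a / phi, mu = n_a * mu) *
        dnbinom(t_total - s, size = n_b / phi, mu = n_b * mu)
    } else {
      f[s + 1] <- dpois(s, n_a * mu) * dpois(t_total - s, n_b * mu)
    }
  }
  f_obs <- f[s_a + 1]
  sum(f[f <= f_obs * (1 + 1e-7)]) / sum(f)
}

# Sort-based percentile reference: stats::quantile with the linear
# interpolation convention (type 7).
oracle_percentile <- function(values, q) {
  unname(stats::quantile(values, probs = q / 100, type = 7))
}

# Small random count experiment for IO / property tests.
make_random_experiment <- function(n_genes = 50, seed = 1) {
  set.seed(seed)
  design <- sample_design(
    sample_id = paste(rep(default_regions(), each = 3), 1:3, sep = "_"),
    region = rep(default_regions(), each = 3),
    replicate = rep(1:3, 6)
  )
  counts <- matrix(rpois(n_genes * nrow(design), lambda = 50),
                   nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   design$sample_id))
  storage.mode(counts) <- "integer"
  lengths <- setNames(sample(500:5000, n_genes, replace = TRUE),
                      rownames(counts))
  list(counts = counts, lengths = lengths, design = design)
}

# A DE-result list that passes every gene in every region (padj = 0), to
# isolate the percentile/fold conditions in screen tests.
pass_all_de <- function(gene_ids, regions = default_regions()) {
  setNames(lapply(regions, function(r) {
    data.frame(gene_id = gene_ids, log2fc = 0, pvalue = 0, padj = 0,
               stringsAsFactors = FALSE)
  }), regions)
}
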