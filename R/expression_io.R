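#' Read and validate a sample design table
#'
#' The design table describes the experiment layout: one row per sequencing
#' library, with the brain region it was dissected from and a replicate index.
#' The default region set is the six regions of the dissection scheme this
#' pipeline was built around: telencephalon plus olfactory bulbs (OBT),
#' hypothalamus (Hy), optic tectum (OT), cerebellum (Ce), medulla oblongata
#' (Mo) and remaining brain (RB).
#'
#' @param path Path to a tab-separated file with columns `sample_id`,
#'   `region`, `replicate`.
#' @param regions Character vector of admissible region labels.
#' @return A `data.frame` with columns `sample_id` (character), `region`
#'   (factor with levels `regions`, dropped to those present) and `replicate`
#'   (integer), classed `sample_design`.
#' @export
read_design <- function(path, regions = default_regions()) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "region", "replicate")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) {
    stop("design table is missing column(s): ", paste(missing, collapse = ", "))
  }
  sample_design(d$sample_id, d$region, d$replicate, regions = regions)
}

#' Construct a sample design
#'
#' @param sample_id Unique character labels, one per library.
#' @param region Region label per library; must be drawn from `regions`.
#' @param replicate Positive integer replicate index per library.
#' @param regions Admissible region labels.
#' @return A validated `sample_design` data.frame.
#' @export
sample_design <- function(sample_id, region, replicate,
                          regions = default_regions()) {
  sample_id <- as.character(sample_id)
  region <- as.character(region)
  replicate <- as.integer(replicate)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(region), regions)
  if (length(bad) > 0L) {
    stop("region label(s) not in the configured region set: ",
         paste(bad, collapse = ", "))
  }
  if (length(unique(region)) < 2L) {
    stop("a design needs at least 2 distinct regions")
  }
  if (any(is.na(replicate)) || any(replicate < 1L)) {
    stop("replicate indices must be positive integers")
  }
  d <- data.frame(sample_id = sample_id,
                  region = factor(region, levels = intersect(regions, region)),
                  replicate = replicate,
                  stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Default brain region labels
#'
#' @return The six region labels used throughout: OBT, Hy, OT, Ce, Mo, RB.
#' @export
default_regions <- function() c("OBT", "Hy", "OT", "Ce", "Mo", "RB")

#' Samples belonging to a region
#'
#' @param design A `sample_design`.
#' @param region A single region label present in the design.
#' @return Character vector of sample ids.
#' @export
region_samples <- function(design, region) {
  if (!region %in% levels(design$region)) {
    stop("unknown region label: ", region)
  }
  design$sample_id[design$region == region]
}

#' Read a count matrix aligned to a design
#'
#' Reads a tab-separated gene-by-sample table of non-negative integer
#' fragment counts. The header row holds sample ids, the first column
#' (`gene_id`) holds gene ids. Columns are reordered to the design's sample
#' order; extra columns are an error, as are missing design samples.
#'
#' @param path Path to the counts TSV.
#' @param design A `sample_design` the columns must match.
#' @return Integer matrix (genes x samples) with dimnames, validated by
#'   [validate_counts()].
#' @export
read_counts <- function(path, design) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "gene_id") {
    stop("first column of a counts table must be 'gene_id', got '",
         names(d)[1L], "'")
  }
  gene_ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  missing <- setdiff(design$sample_id, colnames(m))
  if (length(missing) > 0L) {
    stop("counts table is missing design sample(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(m), design$sample_id)
  if (length(extra) > 0L) {
    stop("counts table has sample column(s) not in the design: ",
         paste(extra, collapse = ", "))
  }
  m <- m[, design$sample_id, drop = FALSE]
  rownames(m) <- gene_ids
  validate_counts(m)
}

#' Validate a count matrix
#'
#' @param m Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @return The matrix with integer storage mode, invisibly unchanged
#'   otherwise.
#' @export
validate_counts <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1L) stop("counts must be a matrix with at least 1 gene")
  if (is.null(rownames(m))) stop("counts matrix must carry gene ids as rownames")
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene id: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing count at gene '", rownames(m)[idx[1L]],
         "', sample '", colnames(m)[idx[2L]], "'")
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at gene '", rownames(m)[idx[1L]],
         "', sample '", colnames(m)[idx[2L]], "'")
  }
  if (any(m != round(m))) {
    idx <- which(m != round(m), arr.ind = TRUE)[1L, ]
    stop("non-integer count at gene '", rownames(m)[idx[1L]],
         "', sample '", colnames(m)[idx[2L]], "'")
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' @param m Count matrix with gene-id rownames and sample-id colnames.
#' @param path Output path; tab-separated, first column `gene_id`.
#' @export
write_counts <- function(m, path) {
  write_expr_table(m, path)
}

#' Read a gene length table
#'
#' @param path TSV with columns `gene_id` and `length_bp`.
#' @return Named integer vector of lengths in base pairs.
#' @export
read_lengths <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(d))) {
    stop("lengths table must have columns gene_id and length_bp")
  }
  len <- as.integer(d$length_bp)
  names(len) <- as.character(d$gene_id)
  if (anyDuplicated(names(len))) stop("duplicate gene id in lengths table")
  if (any(is.na(len)) || any(len <= 0L)) stop("gene lengths must be positive integers")
  len
}

#' Compute FPKM from counts and gene lengths
#'
#' FPKM(g, s) = counts(g, s) * 1e9 / (length(g) * N_s), with N_s the library
#' size of sample s taken as its raw column sum. No between-sample
#' normalization beyond this is applied; `lib_sizes` is the hook for
#' alternatives.
#'
#' @param counts Validated count matrix (genes x samples).
#' @param lengths Named vector of gene lengths in bp covering every gene in
#'   `counts`; genes without a length are a hard error, never dropped.
#' @param lib_sizes Optional named per-sample library sizes overriding the
#'   column sums.
#' @return Numeric matrix of FPKM values with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, lib_sizes = NULL) {
  counts <- validate_counts(counts)
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L) {
    stop("no length for gene(s): ", paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L))
  }
  len <- as.numeric(lengths[rownames(counts)])
  if (any(len <= 0)) stop("gene lengths must be > 0")
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  } else {
    lib_sizes <- lib_sizes[colnames(counts)]
  }
  if (any(lib_sizes <= 0)) {
    stop("zero-total library: ",
         paste(colnames(counts)[lib_sizes <= 0], collapse = ", "))
  }
  fpkm <- sweep(counts * 1e9 / len, 2L, as.numeric(lib_sizes), "/")
  dimnames(fpkm) <- dimnames(counts)
  fpkm
}

#' Write a gene-by-sample expression table
#'
#' @param m Numeric matrix with gene-id rownames.
#' @param path Output TSV path; first column is `gene_id`.
#' @export
write_expr_table <- function(m, path) {
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an FPKM (or any gene-by-sample numeric) table
#'
#' @param path TSV with `gene_id` first column and sample columns.
#' @return Numeric matrix with gene-id rownames.
#' @export
read_expr_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Write a design table
#'
#' @param design A `sample_design`.
#' @param path Output TSV path.
#' @export
write_design <- function(design, path) {
  d <- data.frame(sample_id = design$sample_id,
                  region = as.character(design$region),
                  replicate = design$replicate)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene length table
#'
#' @param lengths Named vector of lengths in bp.
#' @param path Output TSV path with columns gene_id, length_bp.
#' @export
write_lengths <- function(lengths, path) {
  d <- data.frame(gene_id = names(lengths), length_bp = as.integer(lengths))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
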