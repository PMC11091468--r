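#' Read a qPCR Ct table
#'
#' @param path TSV with columns `gene_id`, `sample_id`, `region`, `ct`
#'   (threshold cycles, > 0).
#' @return A data.frame of Ct records.
#' @export
read_ct <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  required <- c("gene_id", "sample_id", "region", "ct")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L) stop("Ct table missing column(s): ",
                                 paste(missing, collapse = ", "))
  if (any(!is.finite(d$ct)) || any(d$ct <= 0)) stop("Ct values must be positive")
  d
}

#' Relative expression by the 2^-ddCt method
#'
#' Normalizes a target gene's Ct to a reference gene within each sample
#' (dCt = Ct_target - Ct_reference), averages dCt per region, subtracts the
#' calibrator region's mean dCt (ddCt), and reports relative expression
#' 2^-ddCt. The calibrator region's relative expression is 1 by
#' construction; amplification efficiency is fixed at 2. Per-replicate
#' relative expression (2^-(dCt - mean dCt of calibrator)) yields the
#' reported per-region SD.
#'
#' @param ct Ct data.frame as from [read_ct()].
#' @param gene Target gene id.
#' @param reference Reference (endogenous control) gene id, e.g. beta-actin.
#' @param calibrator Calibrator region label; no default — reports always
#'   state the calibrator used.
#' @return A data.frame per region: `region`, `n`, `mean_dct`, `ddct`,
#'   `rel_expr`, `rel_expr_sd`, plus attributes `reference` and
#'   `calibrator`.
#' @export
ddct_relative_expression <- function(ct, gene, reference, calibrator) {
  tgt <- ct[ct$gene_id == gene, , drop = FALSE]
  ref <- ct[ct$gene_id == reference, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("no Ct records for target gene ", gene)
  if (nrow(ref) == 0L) stop("no Ct records for reference gene ", reference)
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  missing_ref <- setdiff(tgt$sample_id, names(ref_ct))
  if (length(missing_ref) > 0L) {
    stop("reference gene not measured in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  tgt$dct <- tgt$ct - ref_ct[tgt$sample_id]
  if (!calibrator %in% tgt$region) {
    stop("calibrator region '", calibrator, "' has no measurements for ", gene)
  }
  mean_dct <- tapply(tgt$dct, tgt$region, mean)
  cal_dct <- mean_dct[[calibrator]]
  per_rep <- 2^(-(tgt$dct - cal_dct))
  sds <- tapply(per_rep, tgt$region, stats::sd)
  regions <- names(mean_dct)
  out <- data.frame(
    region = regions,
    n = as.integer(tapply(tgt$dct, tgt$region, length)[regions]),
    mean_dct = as.numeric(mean_dct[regions]),
    ddct = as.numeric(mean_dct[regions] - cal_dct),
    rel_expr = 2^(-(as.numeric(mean_dct[regions]) - cal_dct)),
    rel_expr_sd = as.numeric(sds[regions]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "calibrator") <- calibrator
  out
}
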