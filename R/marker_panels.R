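#' Construct a marker panel
#'
#' A panel maps cell-type (or receptor-family) labels to lists of marker
#' gene ids. Paralogs annotated under one name (the `-1`/`-2` convention)
#' are listed as separate gene ids within one entry.
#'
#' @param panel_name Panel label.
#' @param entries Named list: type label -> character vector of gene ids.
#' @return A validated `marker_panel`.
#' @export
marker_panel <- function(panel_name, entries) {
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("every panel entry must be named")
  }
  if (anyDuplicated(names(entries))) stop("duplicate type label in panel")
  for (label in names(entries)) {
    genes <- entries[[label]]
    if (length(genes) == 0L) stop("panel entry '", label, "' is empty")
    if (anyDuplicated(genes)) {
      stop("duplicate gene id within panel entry '", label, "'")
    }
  }
  structure(list(panel_name = panel_name,
                 entries = lapply(entries, as.character)),
            class = "marker_panel")
}

#' Read a marker panel from YAML or JSON
#'
#' The file must carry `panel_name` and `entries` (type label -> gene list).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` panel file.
#' @return A `marker_panel`.
#' @export
read_panel <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!all(c("panel_name", "entries") %in% names(vals))) {
    stop("panel file must have keys panel_name and entries")
  }
  marker_panel(vals$panel_name, vals$entries)
}

#' Bundled neurotransmitter-type neuron panel
#'
#' Marker genes distinguishing seven neurotransmitter-type neurons
#' (glutamatergic, GABAergic, glycinergic, dopaminergic, serotonergic,
#' noradrenergic, cholinergic), as used for teleost brain-region profiling.
#'
#' @return A `marker_panel`.
#' @export
default_neuron_panel <- function() {
  read_panel(system.file("extdata", "panel_neurons.yaml",
                         package = "regionmarkers", mustWork = TRUE))
}

#' Bundled non-neuronal cell panel
#'
#' Marker genes for oligodendrocytes, microglia, endothelial cells, radial
#' astrocytes and neuroprogenitors.
#'
#' @return A `marker_panel`.
#' @export
default_nonneuronal_panel <- function() {
  read_panel(system.file("extdata", "panel_nonneuronal.yaml",
                         package = "regionmarkers", mustWork = TRUE))
}

#' Profile a marker panel across regions
#'
#' For every panel entry, sums the per-region mean FPKM of its marker genes
#' (an unweighted sum, matching "total expression" of a family) and reports
#' the top region and the full region ranking. Panel genes absent from the
#' expression matrix are reported — and entries left with no matched gene
#' are dropped with a warning — rather than silently treated as zeros.
#'
#' @param expr FPKM matrix (genes x samples).
#' @param design A `sample_design` aligned to `expr`.
#' @param panel A `marker_panel`.
#' @param aggregation `"sum"` (default) or `"mean"` over the entry's matched
#'   genes; mean is for comparing panels of unequal size.
#' @return A `distribution_profile`: list with `values` (type x region
#'   matrix), `argmax` (named character), `ranking` (per type, regions in
#'   descending order), `matched`/`unmatched` gene report, `panel_name`.
#' @export
profile_panel <- function(expr, design, panel,
                          aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(panel, "marker_panel"))
  means <- region_mean_fpkm(expr, design)
  regs <- colnames(means)
  matched <- list()
  unmatched <- list()
  rows <- list()
  for (label in names(panel$entries)) {
    genes <- panel$entries[[label]]
    hit <- genes[genes %in% rownames(expr)]
    miss <- setdiff(genes, hit)
    matched[[label]] <- hit
    unmatched[[label]] <- miss
    if (length(miss) > 0L) {
      warning("panel '", panel$panel_name, "' entry '", label,
              "': unmatched gene(s) ", paste(miss, collapse = ", "))
    }
    if (length(hit) == 0L) next
    vals <- colSums(means[hit, , drop = FALSE])
    if (aggregation == "mean") vals <- vals / length(hit)
    rows[[label]] <- vals
  }
  if (length(rows) == 0L) {
    stop("panel '", panel$panel_name, "' matched no genes in the expression matrix")
  }
  dropped <- setdiff(names(panel$entries), names(rows))
  if (length(dropped) > 0L) {
    warning("panel entries with no matched genes dropped: ",
            paste(dropped, collapse = ", "))
  }
  values <- do.call(rbind, rows)
  colnames(values) <- regs
  argmax <- apply(values, 1L, function(v) regs[which.max(v)])
  ranking <- apply(values, 1L, function(v) regs[order(-v)], simplify = FALSE)
  structure(list(panel_name = panel$panel_name, values = values,
                 argmax = argmax, ranking = ranking,
                 matched = matched, unmatched = unmatched,
                 aggregation = aggregation),
            class = "distribution_profile")
}

#' Total receptor-family expression across regions
#'
#' Applies the same computation as [profile_panel()] to receptor families:
#' each entry is a family of receptor genes and its per-region value is the
#' summed mean FPKM. Receptor gene lists are user-supplied (a faithful
#' default list would require the genome annotation, so none is bundled).
#'
#' @inheritParams profile_panel
#' @param receptor_panel A `marker_panel` of receptor families.
#' @return A `distribution_profile`.
#' @export
aggregate_receptor_expression <- function(expr, design, receptor_panel,
                                          aggregation = c("sum", "mean")) {
  profile_panel(expr, design, receptor_panel, aggregation = aggregation)
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat("Distribution profile '", x$panel_name, "' (", x$aggregation,
      " of region-mean FPKM)\n", sep = "")
  print(round(x$values, 2))
  cat("Top region per type:\n")
  for (label in names(x$argmax)) {
    cat(sprintf("  %-20s %s\n", label, x$argmax[[label]]))
  }
  n_miss <- sum(lengths(x$unmatched))
  if (n_miss > 0L) {
    cat(n_miss, "panel gene(s) were not found in the expression matrix\n")
  }
  invisible(x)
}

#' Write a distribution profile as TSV
#'
#' @param profile A `distribution_profile`.
#' @param path Output path; rows are types, columns regions, plus an
#'   `argmax_region` column.
#' @export
write_profile <- function(profile, path) {
  d <- data.frame(type = rownames(profile$values), profile$values,
                  argmax_region = profile$argmax[rownames(profile$values)],
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
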