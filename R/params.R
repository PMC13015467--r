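#' Global analysis parameters
#'
#' Constructs the parameter set shared by every stage of the fusion
#' analysis. Defaults follow the published pipeline settings for long-read
#' glioma fusion analysis: a 50 bp breakpoint window for cross-caller
#' deduplication, a minimum of 3 supporting reads, the 200 bp near-exon
#' reclassification rule, essentiality-screen thresholds (dependency
#' probability >= 0.9, gene effect <= -1), the proportional
#' breakpoint-proximity rule (10% of gene length clamped to [500, 2000] bp),
#' a 100 bp structural boundary tolerance, differential-expression cutoffs
#' (FDR <= 0.05, |log2FC| >= 1), the expression filter (>= 10 counts in at
#' least min-group-size samples and >= 15 total counts), and the
#' glioma-keyword set used to subset cancer-census tumor types.
#'
#' @param dedup_window_bp breakpoint window (bp) for cross-caller merging
#'   and reciprocal matching.
#' @param min_support_reads minimum supporting reads for a fusion.
#' @param near_exon_bp intronic breakpoints within this distance of an exon
#'   boundary are reclassified as near-exon (counted as exonic).
#' @param dep_prob_min dependency-probability threshold for "highly
#'   essential" candidates.
#' @param gene_effect_max gene-effect threshold (at or below marks a hit).
#' @param prox_fraction fraction of gene length for the breakpoint
#'   proximity threshold.
#' @param prox_min_bp,prox_max_bp clamp bounds (bp) for the proximity
#'   threshold.
#' @param boundary_tol_bp tolerance (bp) for exon-boundary and transcript
#'   start/end comparisons.
#' @param de_fdr_max,de_abs_lfc_min significance and fold-change cutoffs
#'   for differential expression.
#' @param expr_min_count,expr_min_total per-sample and total count cutoffs
#'   for the expression filter.
#' @param glioma_keywords keywords matched (case-insensitive substring)
#'   against tumor-type tokens to build the glioma census subset.
#' @param glioma_exclusions tumor-type tokens containing any of these terms
#'   never match a keyword (e.g. "paraganglioma").
#' @param mane_tag GTF tag value marking the MANE transcript.
#' @param mito_chroms chromosome names treated as mitochondrial.
#'
#' @return A named list of class `FusionParams`.
#' @examples
#' p <- fusionParams()
#' p$dedup_window_bp
#' @export
fusionParams <- function(dedup_window_bp = 50L,
                         min_support_reads = 3L,
                         near_exon_bp = 200L,
                         dep_prob_min = 0.9,
                         gene_effect_max = -1,
                         prox_fraction = 0.10,
                         prox_min_bp = 500L,
                         prox_max_bp = 2000L,
                         boundary_tol_bp = 100L,
                         de_fdr_max = 0.05,
                         de_abs_lfc_min = 1,
                         expr_min_count = 10L,
                         expr_min_total = 15L,
                         glioma_keywords = c("glioma", "astrocytoma",
                                             "glioblastoma",
                                             "oligodendroglioma", "CNS"),
                         glioma_exclusions = "paraganglioma",
                         mane_tag = "MANE_Select",
                         mito_chroms = c("chrM", "MT")) {
  p <- list(
    dedup_window_bp = as.integer(dedup_window_bp),
    min_support_reads = as.integer(min_support_reads),
    near_exon_bp = as.integer(near_exon_bp),
    dep_prob_min = dep_prob_min,
    gene_effect_max = gene_effect_max,
    prox_fraction = prox_fraction,
    prox_min_bp = as.integer(prox_min_bp),
    prox_max_bp = as.integer(prox_max_bp),
    boundary_tol_bp = as.integer(boundary_tol_bp),
    de_fdr_max = de_fdr_max,
    de_abs_lfc_min = de_abs_lfc_min,
    expr_min_count = as.integer(expr_min_count),
    expr_min_total = as.integer(expr_min_total),
    glioma_keywords = as.character(glioma_keywords),
    glioma_exclusions = as.character(glioma_exclusions),
    mane_tag = as.character(mane_tag),
    mito_chroms = as.character(mito_chroms)
  )
  num <- c("dedup_window_bp", "min_support_reads", "near_exon_bp",
           "dep_prob_min", "prox_fraction", "prox_min_bp", "prox_max_bp",
           "boundary_tol_bp", "de_fdr_max", "de_abs_lfc_min",
           "expr_min_count", "expr_min_total")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive number")
    }
  }
  if (!is.numeric(p$gene_effect_max) || length(p$gene_effect_max) != 1L) {
    stop("parameter 'gene_effect_max' must be a single number")
  }
  if (p$prox_min_bp > p$prox_max_bp) {
    stop("prox_min_bp must be <= prox_max_bp")
  }
  class(p) <- "FusionParams"
  p
}

#' Override parameters from a flat key-value config file
#'
#' Reads `key = value` (or `key: value`) lines; keys must name
#' [fusionParams()] fields. Comma-separated values become vectors. Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path path to the config file.
#' @param base parameter set to override (default [fusionParams()]).
#' @return A `FusionParams` list.
#' @export
readParamsConfig <- function(path, base = fusionParams()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("unparseable config line: ", ln)
    key <- sub("^.*\\.", "", m[2])  # allow dotted namespaces
    val <- trimws(strsplit(m[3], ",")[[1]])
    suppressWarnings(numval <- as.numeric(val))
    over[[key]] <- if (!anyNA(numval)) numval else val
  }
  unknown <- setdiff(names(over), names(unclass(base)))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(fusionParams, utils::modifyList(unclass(base), over))
}

#' @export
print.FusionParams <- function(x, ...) {
  cat("FusionParams with", length(unclass(x)), "fields\n")
  flat <- vapply(unclass(x), function(v) paste(v, collapse = ","), "")
  cat(paste0("  ", format(names(flat)), " : ", flat), sep = "\n")
  invisible(x)
}
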