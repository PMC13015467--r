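#' Extract the glioma-specific subset of a cancer gene census table
#'
#' Tumor-type annotations are tokenized on commas/semicolons; a gene is
#' included when at least one token contains a glioma keyword
#' (case-insensitive substring) and that token does not contain an
#' excluded term, so "glioma" inside "paraganglioma" never matches.
#'
#' @param census_table data.frame with a gene column and a tumor-type text
#'   column.
#' @param keywords glioma-related keywords (default from
#'   [fusionParams()]).
#' @param exclusions tokens containing these terms are skipped.
#' @param gene_col,type_col column names (defaults "gene",
#'   "tumor_types").
#' @return character vector of glioma-subset gene symbols.
#' @examples
#' tb <- data.frame(gene = c("G1", "G2", "G3"),
#'                  tumor_types = c("glioblastoma, AML", "paraganglioma",
#'                                  "leukaemia"))
#' buildGliomaSubset(tb)  # G1 only
#' @export
buildGliomaSubset <- function(census_table,
                              keywords = fusionParams()$glioma_keywords,
                              exclusions = fusionParams()$glioma_exclusions,
                              gene_col = "gene",
                              type_col = "tumor_types") {
  if (!all(c(gene_col, type_col) %in% names(census_table))) {
    stop("schema error: census table needs columns '", gene_col,
         "' and '", type_col, "'")
  }
  kw <- tolower(keywords)
  ex <- tolower(exclusions)
  hit <- vapply(seq_len(nrow(census_table)), function(i) {
    toks <- tolower(trimws(
      strsplit(as.character(census_table[[type_col]][i]), "[,;]")[[1]]))
    toks <- toks[nzchar(toks)]
    for (tok in toks) {
      if (any(vapply(ex, function(e) grepl(e, tok, fixed = TRUE),
                     logical(1)))) next
      if (any(vapply(kw, function(k) grepl(k, tok, fixed = TRUE),
                     logical(1)))) return(TRUE)
    }
    FALSE
  }, logical(1))
  unique(as.character(census_table[[gene_col]][hit]))
}

#' Per-gene essentiality summaries from dependency screens
#'
#' For glioma-subtype cell lines (selected by `cell_line_filter` on the
#' lineage table), computes each gene's maximum dependency probability and
#' minimum gene-effect score, and flags highly essential candidates
#' (max probability >= `dep_prob_min`) and strong-effect hits
#' (min effect <= `gene_effect_max`).
#'
#' @param dep_matrix numeric matrix, genes x cell lines, dependency
#'   probabilities.
#' @param effect_matrix numeric matrix, genes x cell lines, gene-effect
#'   scores.
#' @param cell_lines data.frame with columns `cell_line` and `lineage`,
#'   or NULL to use every column.
#' @param lineage_labels lineage values selecting glioma-subtype lines
#'   (default: diffuse-glioma subtype labels).
#' @param params a [fusionParams()] list (thresholds).
#' @return data.frame: gene, max_dependency_prob, min_gene_effect,
#'   depmap_essential, depmap_effect_hit. Genes present in only one matrix
#'   get NA for the missing summary and FALSE for its flag.
#' @export
depmapEssentiality <- function(dep_matrix, effect_matrix,
                               cell_lines = NULL,
                               lineage_labels = c("glioblastoma",
                                                  "astrocytoma",
                                                  "anaplastic astrocytoma",
                                                  "oligodendroglioma",
                                                  "gliosarcoma"),
                               params = fusionParams()) {
  pick <- function(m) {
    if (is.null(cell_lines)) return(m)
    sel <- cell_lines$cell_line[tolower(cell_lines$lineage) %in%
                                  tolower(lineage_labels)]
    m[, colnames(m) %in% sel, drop = FALSE]
  }
  dep <- pick(as.matrix(dep_matrix))
  eff <- pick(as.matrix(effect_matrix))
  if (ncol(dep) == 0L && ncol(eff) == 0L) {
    stop("configuration error: cell-line filter selected no lines")
  }
  genes <- sort(union(rownames(dep), rownames(eff)))
  max_dep <- rep(NA_real_, length(genes))
  min_eff <- rep(NA_real_, length(genes))
  mi <- match(genes, rownames(dep))
  has <- !is.na(mi) & ncol(dep) > 0L
  if (any(has)) {
    max_dep[has] <- apply(dep[mi[has], , drop = FALSE], 1L, max,
                          na.rm = TRUE)
  }
  mi <- match(genes, rownames(eff))
  has <- !is.na(mi) & ncol(eff) > 0L
  if (any(has)) {
    min_eff[has] <- apply(eff[mi[has], , drop = FALSE], 1L, min,
                          na.rm = TRUE)
  }
  data.frame(gene = genes,
             max_dependency_prob = max_dep,
             min_gene_effect = min_eff,
             depmap_essential = !is.na(max_dep) &
               max_dep >= params$dep_prob_min,
             depmap_effect_hit = !is.na(min_eff) &
               min_eff <= params$gene_effect_max,
             stringsAsFactors = FALSE)
}

#' Bundle prioritization resources
#'
#' @param panel_genes,census_genes gate gene symbol vectors.
#' @param glioma_subset glioma-subset symbols ([buildGliomaSubset()]).
#' @param oncogenes,tsgs oncogene / tumor-suppressor symbols (union over
#'   the configured sources; a gene may be both).
#' @param depmap_summary data.frame from [depmapEssentiality()], or NULL.
#' @param cns_fusion_partners symbols reported as recurrent CNS-tumor
#'   fusion partners.
#' @return A named list of class `FusionResources`.
#' @export
fusionResources <- function(panel_genes = character(),
                            census_genes = character(),
                            glioma_subset = character(),
                            oncogenes = character(),
                            tsgs = character(),
                            depmap_summary = NULL,
                            cns_fusion_partners = character()) {
  r <- list(panel_genes = unique(panel_genes),
            census_genes = unique(census_genes),
            glioma_subset = unique(glioma_subset),
            oncogenes = unique(oncogenes),
            tsgs = unique(tsgs),
            depmap_summary = depmap_summary,
            cns_fusion_partners = unique(cns_fusion_partners))
  class(r) <- "FusionResources"
  r
}

.geneEvidence <- function(genes, res) {
  dm <- res$depmap_summary
  md <- rep(NA_real_, length(genes)); me <- rep(NA_real_, length(genes))
  ess <- rep(FALSE, length(genes)); eh <- rep(FALSE, length(genes))
  if (!is.null(dm)) {
    i <- match(genes, dm$gene)
    ok <- !is.na(i)
    md[ok] <- dm$max_dependency_prob[i[ok]]
    me[ok] <- dm$min_gene_effect[i[ok]]
    ess[ok] <- dm$depmap_essential[i[ok]]
    eh[ok] <- dm$depmap_effect_hit[i[ok]]
  }
  data.frame(in_panel = genes %in% res$panel_genes,
             in_census = genes %in% res$census_genes,
             in_glioma_subset = genes %in% res$glioma_subset,
             is_oncogene = genes %in% res$oncogenes,
             is_tsg = genes %in% res$tsgs,
             max_dependency_prob = md,
             min_gene_effect = me,
             depmap_essential = ess,
             depmap_effect_hit = eh,
             cns_fusion_partner = genes %in% res$cns_fusion_partners,
             stringsAsFactors = FALSE)
}

#' Annotate fusion partner genes against cancer/glioma resources
#'
#' Populates per-partner evidence (panel/census/glioma-subset membership,
#' oncogene/TSG status, essentiality summaries, CNS fusion-partner flag)
#' and the fusion-level `onc_tsg_link` flag (one partner an oncogene and
#' the other a tumor suppressor).
#'
#' @param ann_fus annotated fusion data.frame ([annotateFusions()]).
#' @param res a [fusionResources()] list.
#' @return The data.frame with per-partner evidence columns (suffixes
#'   `_5`/`_3`) and `onc_tsg_link`.
#' @export
annotateFusionGenes <- function(ann_fus, res) {
  e5 <- .geneEvidence(ann_fus$gene5, res)
  e3 <- .geneEvidence(ann_fus$gene3, res)
  names(e5) <- paste0(names(e5), "_5")
  names(e3) <- paste0(names(e3), "_3")
  out <- cbind(ann_fus, e5, e3)
  out$onc_tsg_link <-
    (e5$is_oncogene_5 & e3$is_tsg_3) | (e5$is_tsg_5 & e3$is_oncogene_3)
  out
}

#' Cohort-level prioritization summary
#'
#' Fractions of fusions with each evidence category on at least one
#' partner and on both partners, plus the oncogene-TSG link count. For
#' CNS fusion partners both the any-fusion fraction and the count of
#' distinct involved genes are reported.
#'
#' @param pri_fus data.frame from [annotateFusionGenes()].
#' @return data.frame category/n_any/frac_any/n_both/frac_both; zero rows
#'   for empty input.
#' @export
summarizePrioritization <- function(pri_fus) {
  cats <- c(in_panel = "panel", in_census = "census",
            in_glioma_subset = "glioma_subset", is_oncogene = "oncogene",
            is_tsg = "tsg", depmap_essential = "depmap_essential",
            depmap_effect_hit = "depmap_effect_hit",
            cns_fusion_partner = "cns_fusion_partner")
  n <- nrow(pri_fus)
  if (n == 0L) {
    return(data.frame(category = character(), n_any = integer(),
                      frac_any = numeric(), n_both = integer(),
                      frac_both = numeric()))
  }
  rows <- lapply(names(cats), function(f) {
    a <- pri_fus[[paste0(f, "_5")]]; b <- pri_fus[[paste0(f, "_3")]]
    data.frame(category = cats[[f]],
               n_any = sum(a | b), frac_any = sum(a | b) / n,
               n_both = sum(a & b), frac_both = sum(a & b) / n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    category = "onc_tsg_link", n_any = sum(pri_fus$onc_tsg_link),
    frac_any = sum(pri_fus$onc_tsg_link) / n,
    n_both = sum(pri_fus$onc_tsg_link),
    frac_both = sum(pri_fus$onc_tsg_link) / n,
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
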