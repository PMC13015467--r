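#' Gene class sets used by the filtering cascade
#'
#' Bundles the cancer-gene gate lists (fusion panel, cancer gene census),
#' the blacklist classes (pseudogenes, ribosomal-protein genes, HLA
#' genes), mitochondrial chromosome names, and the healthy-tissue control
#' fusion pairs.
#'
#' @param panel_genes character vector of fusion-panel gene symbols.
#' @param census_genes character vector of cancer-gene-census symbols.
#' @param pseudogenes,ribosomal_genes,hla_genes blacklist gene symbols.
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @param control_pairs character vector of unordered control gene pairs
#'   as "A::B" (sorted), or a two-column data.frame of gene pairs.
#' @return A named list of class `GeneClassSets`.
#' @export
geneClassSets <- function(panel_genes = character(),
                          census_genes = character(),
                          pseudogenes = character(),
                          ribosomal_genes = character(),
                          hla_genes = character(),
                          mito_chroms = c("chrM", "MT"),
                          control_pairs = character()) {
  if (is.data.frame(control_pairs)) {
    control_pairs <- controlPairKeys(control_pairs[[1]], control_pairs[[2]])
  }
  s <- list(panel_genes = unique(as.character(panel_genes)),
            census_genes = unique(as.character(census_genes)),
            pseudogenes = unique(as.character(pseudogenes)),
            ribosomal_genes = unique(as.character(ribosomal_genes)),
            hla_genes = unique(as.character(hla_genes)),
            mito_chroms = as.character(mito_chroms),
            control_pairs = unique(as.character(control_pairs)))
  class(s) <- "GeneClassSets"
  s
}

#' Canonical unordered gene-pair keys
#' @param a,b character vectors of partner gene symbols.
#' @return character vector "X::Y" with the pair sorted.
#' @export
controlPairKeys <- function(a, b) {
  if (length(a) == 0L) return(character(0))
  mapply(function(x, y) paste(sort(c(x, y)), collapse = "::"),
         as.character(a), as.character(b), USE.NAMES = FALSE)
}

#' Read a one-symbol-per-line gene list
#' @param path file path; blank lines and `#` comments ignored.
#' @return character vector of symbols.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a two-column TSV of control fusion pairs
#' @param path file path (columns gene1, gene2; header optional).
#' @return character vector of unordered pair keys.
#' @export
readControlPairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = TRUE)
  if (!all(c("gene1", "gene2") %in% names(df))) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            header = FALSE)
    names(df)[1:2] <- c("gene1", "gene2")
  }
  unique(controlPairKeys(df$gene1, df$gene2))
}

# ---- individual stages ----------------------------------------------------

#' Cancer-gene gate
#'
#' Retains a fusion iff at least one partner is in the fusion panel or the
#' cancer gene census.
#'
#' @param x a FusionCallSet.
#' @param sets a [geneClassSets()] list.
#' @return Filtered FusionCallSet.
#' @export
geneListGate <- function(x, sets) {
  gate <- union(sets$panel_genes, sets$census_genes)
  if (length(gate) == 0L) {
    stop("configuration error: empty panel and census gene sets")
  }
  df <- fusionCalls(x)
  keep <- df$gene5 %in% gate | df$gene3 %in% gate
  FusionCallSet(df[keep, , drop = FALSE])
}

#' Minimum read-support filter
#'
#' @param x a FusionCallSet.
#' @param min_reads minimum supporting reads (inclusive; default 3).
#' @return Filtered FusionCallSet.
#' @export
supportFilter <- function(x, min_reads = 3L) {
  df <- fusionCalls(x)
  FusionCallSet(df[df$support >= min_reads, , drop = FALSE])
}

#' Blacklist filter
#'
#' Removes a fusion when either partner is a pseudogene, ribosomal-protein
#' gene or HLA gene, or when either breakpoint lies on a mitochondrial
#' chromosome.
#'
#' @param x a FusionCallSet.
#' @param sets a [geneClassSets()] list.
#' @param annotation optional [GenomeAnnotation-class]; genes whose GTF
#'   biotype contains "pseudogene" are blacklisted even when absent from
#'   the pseudogene list.
#' @return Filtered FusionCallSet.
#' @export
blacklistFilter <- function(x, sets, annotation = NULL) {
  df <- fusionCalls(x)
  if (nrow(df) == 0L) return(x)
  bad_genes <- unique(c(sets$pseudogenes, sets$ribosomal_genes,
                        sets$hla_genes))
  if (!is.null(annotation)) {
    gm <- S4Vectors::mcols(geneRanges(annotation))
    pseudo <- gm$gene_name[!is.na(gm$biotype) &
                             grepl("pseudogene", gm$biotype)]
    bad_genes <- unique(c(bad_genes, pseudo))
  }
  rm_gene <- df$gene5 %in% bad_genes | df$gene3 %in% bad_genes
  rm_mito <- df$chrom5 %in% sets$mito_chroms |
    df$chrom3 %in% sets$mito_chroms
  FusionCallSet(df[!(rm_gene | rm_mito), , drop = FALSE])
}

#' Strand-consistency filter
#'
#' A reported call is orientation-consistent when the breakpoint strands
#' equal the annotated strands of both partner genes, the only
#' configuration in which reading the fusion 5' to 3' traverses gene5 then
#' gene3 in their coding directions. Calls reporting unknown strand (".")
#' on either side are retained with a warning flag (`strand_warn`), as are
#' calls involving unannotated genes.
#'
#' @param x a FusionCallSet.
#' @param annotation a [GenomeAnnotation-class].
#' @return Filtered FusionCallSet; surviving permissive calls carry a
#'   `strand_warn` column.
#' @export
strandConsistencyFilter <- function(x, annotation) {
  df <- fusionCalls(x)
  if (nrow(df) == 0L) return(x)
  ann5 <- vapply(df$gene5, function(g) geneStrand(annotation, g), "")
  ann3 <- vapply(df$gene3, function(g) geneStrand(annotation, g), "")
  unknown <- df$strand5 == "." | df$strand3 == "."
  unann <- is.na(ann5) | is.na(ann3)
  consistent <- !unknown & !unann & df$strand5 == ann5 & df$strand3 == ann3
  keep <- consistent | unknown | unann
  out <- df[keep, , drop = FALSE]
  out$strand_warn <- (unknown | unann)[keep]
  FusionCallSet(out)
}

#' Healthy-tissue control subtraction
#'
#' Removes fusions whose unordered gene pair was observed in control
#' (healthy brain) samples.
#'
#' @param x a FusionCallSet.
#' @param control_pairs character vector of unordered pair keys
#'   (see [controlPairKeys()]), or a [geneClassSets()] list.
#' @return Filtered FusionCallSet.
#' @export
controlSubtraction <- function(x, control_pairs) {
  if (inherits(control_pairs, "GeneClassSets")) {
    control_pairs <- control_pairs$control_pairs
  }
  df <- fusionCalls(x)
  if (nrow(df) == 0L || length(control_pairs) == 0L) return(x)
  pair <- controlPairKeys(df$gene5, df$gene3)
  FusionCallSet(df[!(pair %in% control_pairs), , drop = FALSE])
}

# ---- cascade --------------------------------------------------------------

.auditRow <- function(stage, before, after) {
  rk <- setdiff(fusionKey(before), fusionKey(after))
  data.frame(stage = stage, n_in = length(before), n_out = length(after),
             removed = paste(sort(rk), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Apply the full filtering cascade with an audit trail
#'
#' Fixed stage order: cancer-gene gate, read-support filter, blacklist
#' filter, strand-consistency filter, control subtraction, and removal of
#' fusions with both breakpoints intronic/intergenic/unannotated (the
#' breakpoint-class drop, which annotates breakpoints via
#' [annotateFusions()]). Every removal is attributed to its stage in the
#' audit table.
#'
#' @param x a harmonized FusionCallSet.
#' @param sets a [geneClassSets()] list.
#' @param annotation a [GenomeAnnotation-class].
#' @param params a [fusionParams()] list.
#' @return list with elements `calls` (retained, annotated fusions as a
#'   data.frame from [annotateFusions()]), `callset` (the retained
#'   FusionCallSet) and `audit` (data.frame stage/n_in/n_out/removed).
#' @export
applyCascade <- function(x, sets, annotation, params = fusionParams()) {
  audit <- list()
  cur <- x
  step <- function(name, fn) {
    nxt <- fn(cur)
    audit[[length(audit) + 1L]] <<- .auditRow(name, cur, nxt)
    cur <<- nxt
  }
  step("gene_list_gate", function(z) geneListGate(z, sets))
  step("support_filter",
       function(z) supportFilter(z, params$min_support_reads))
  step("blacklist_filter",
       function(z) blacklistFilter(z, sets, annotation))
  step("strand_consistency",
       function(z) strandConsistencyFilter(z, annotation))
  step("control_subtraction", function(z) controlSubtraction(z, sets))

  ann_fus <- annotateFusions(cur, annotation, params)
  kept <- dropUnannotatable(ann_fus)
  kept_keys <- if (nrow(kept)) fusionKey(kept) else character(0)
  cur_keys <- fusionKey(cur)
  dropped <- setdiff(cur_keys, kept_keys)
  audit[[length(audit) + 1L]] <- data.frame(
    stage = "breakpoint_class_drop", n_in = length(cur),
    n_out = nrow(kept), removed = paste(sort(dropped), collapse = ";"),
    stringsAsFactors = FALSE)

  keep_rows <- fusionKey(fusionCalls(cur)) %in% kept_keys
  list(calls = kept,
       callset = FusionCallSet(fusionCalls(cur)[keep_rows, , drop = FALSE]),
       audit = do.call(rbind, audit))
}
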