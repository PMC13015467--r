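#' Proportional clamped breakpoint-proximity threshold
#'
#' 10% of the gene length, clamped to a 500 bp floor and a 2 kb ceiling
#' (defaults from [fusionParams()]).
#'
#' @param gene_length_bp gene span length in bp (>= 1).
#' @param params a [fusionParams()] list.
#' @return threshold in bp.
#' @examples
#' proximityThreshold(3000)   # 500
#' proximityThreshold(12000)  # 1200
#' proximityThreshold(50000)  # 2000
#' @export
proximityThreshold <- function(gene_length_bp, params = fusionParams()) {
  stopifnot(all(gene_length_bp >= 1))
  pmin(pmax(params$prox_fraction * gene_length_bp, params$prox_min_bp),
       params$prox_max_bp)
}

#' Non-canonical transcript boundaries of an isoform
#'
#' Compares the isoform's transcript start and end (5' and 3' ends in
#' transcription direction) with those of the gene's canonical transcript
#' (tier 1 MANE, else tier 2 longest protein-coding; if neither exists the
#' longest tier-3 transcript is used and the result flagged low
#' confidence). A boundary differing by more than `tol` is non-canonical.
#'
#' @param exons isoform exon chain (data.frame start/end) or a chain
#'   string.
#' @param ann a [GenomeAnnotation-class].
#' @param gene the gene the isoform is assigned to.
#' @param tol boundary tolerance in bp (default 100).
#' @return list with `kinds` (subset of "noncanonical_start",
#'   "noncanonical_end"), `canonical_tx` and `low_confidence`.
#' @export
noncanonicalBoundary <- function(exons, ann, gene, tol = 100L) {
  if (is.character(exons)) exons <- parseExonChain(exons)
  tiers <- selectTranscriptTiers(ann, gene)
  low_conf <- FALSE
  canon <- tiers$tier1
  if (is.na(canon)) canon <- tiers$tier2
  if (is.na(canon)) {
    tx <- ann@transcripts
    cand <- tx[tx$transcript_id %in% tiers$tier3, , drop = FALSE]
    cand <- cand[order(-cand$spliced_length, cand$transcript_id), ,
                 drop = FALSE]
    canon <- cand$transcript_id[1]
    low_conf <- TRUE
  }
  strand <- geneStrand(ann, gene)
  cex <- exonChain(ann, canon)
  kinds <- character(0)
  if (abs(.chainTxStart(exons, strand) -
            .chainTxStart(cex, strand)) > tol) {
    kinds <- c(kinds, "noncanonical_start")
  }
  iso_end <- if (strand == "-") min(exons$start) else max(exons$end)
  can_end <- if (strand == "-") min(cex$start) else max(cex$end)
  if (abs(iso_end - can_end) > tol) {
    kinds <- c(kinds, "noncanonical_end")
  }
  list(kinds = kinds, canonical_tx = canon, low_confidence = low_conf)
}

#' Breakpoint-proximal isoform boundaries for one fusion
#'
#' For the 5' partner gene, finds isoforms with a non-canonical transcript
#' end within the clamped proximity threshold of the 5' breakpoint
#' (premature termination); for the 3' partner, isoforms with a
#' non-canonical transcript start within threshold of the 3' breakpoint
#' (novel initiation). `same_sample` marks hits from the fusion-bearing
#' sample.
#'
#' @param fusion one-row data.frame (or list) with sample_id, gene5, pos5,
#'   gene3, pos3.
#' @param isoforms isoform record data.frame (isoform_id, gene, sample_id,
#'   strand, exons).
#' @param ann a [GenomeAnnotation-class].
#' @param params a [fusionParams()] list.
#' @return data.frame of hits: fusion key columns, role
#'   (5prime/3prime), isoform_id, kind, distance_bp, threshold_bp,
#'   same_sample.
#' @export
breakpointProximalIsoforms <- function(fusion, isoforms, ann,
                                       params = fusionParams()) {
  empty <- data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), role = character(),
                      isoform_id = character(), kind = character(),
                      distance_bp = integer(), threshold_bp = integer(),
                      same_sample = logical(), stringsAsFactors = FALSE)
  one_role <- function(gene, bp, role, want_kind) {
    sub <- isoforms[isoforms$gene == gene, , drop = FALSE]
    if (nrow(sub) == 0L || is.na(.resolveGene(ann, gene))) return(empty)
    gl <- geneLength(ann, gene)
    thr <- as.integer(proximityThreshold(gl, params))
    strand <- geneStrand(ann, gene)
    rows <- lapply(seq_len(nrow(sub)), function(i) {
      ex <- parseExonChain(sub$exons[i])
      nb <- noncanonicalBoundary(ex, ann, gene,
                                 tol = params$boundary_tol_bp)
      if (!(want_kind %in% nb$kinds)) return(NULL)
      bound <- if (want_kind == "noncanonical_end") {
        if (strand == "-") min(ex$start) else max(ex$end)
      } else {
        .chainTxStart(ex, strand)
      }
      d <- abs(bound - bp)
      if (d > thr) return(NULL)
      data.frame(sample_id = fusion$sample_id, gene5 = fusion$gene5,
                 gene3 = fusion$gene3, role = role,
                 isoform_id = sub$isoform_id[i], kind = want_kind,
                 distance_bp = as.integer(d), threshold_bp = thr,
                 same_sample = sub$sample_id[i] == fusion$sample_id,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(empty)
    do.call(rbind, rows)
  }
  rbind(one_role(fusion$gene5, fusion$pos5, "5prime", "noncanonical_end"),
        one_role(fusion$gene3, fusion$pos3, "3prime",
                 "noncanonical_start"))
}

#' Flag fusion-like isoform patterns
#'
#' A fusion is fusion-like when it has at least one 5'-role hit (premature
#' termination near the 5' breakpoint) and at least one 3'-role hit (novel
#' initiation near the 3' breakpoint) in the same sample. An
#' expression-asymmetry annotation (5' partner below / 3' partner above
#' the configured percentile cutoffs, computed from group-wise isoform
#' summaries when supplied) is attached but never used as a filter.
#'
#' @param hits data.frame from [breakpointProximalIsoforms()] (possibly
#'   several fusions row-bound).
#' @param expr optional [expressionSummaries()] data.frame for the
#'   isoforms.
#' @param low_pct,high_pct percentile cutoffs for the asymmetry
#'   annotation.
#' @return data.frame per fusion: sample_id, gene5, gene3, fusion_like,
#'   n_hits_5, n_hits_3, expr_asymmetry (NA when `expr` is NULL).
#' @export
fusionLikePattern <- function(hits, expr = NULL, low_pct = 50,
                              high_pct = 50) {
  if (nrow(hits) == 0L) {
    return(data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), fusion_like = logical(),
                      n_hits_5 = integer(), n_hits_3 = integer(),
                      expr_asymmetry = logical()))
  }
  key <- paste(hits$sample_id, hits$gene5, hits$gene3, sep = "|")
  out <- lapply(unique(key), function(k) {
    h <- hits[key == k, , drop = FALSE]
    ss <- h[h$same_sample, , drop = FALSE]
    flike <- any(ss$role == "5prime") && any(ss$role == "3prime")
    asym <- NA
    if (!is.null(expr) && nrow(ss)) {
      pct_of <- function(ids) {
        p <- expr$percentile[expr$isoform_id %in% ids]
        if (length(p)) stats::median(p) else NA_real_
      }
      p5 <- pct_of(ss$isoform_id[ss$role == "5prime"])
      p3 <- pct_of(ss$isoform_id[ss$role == "3prime"])
      asym <- !is.na(p5) && !is.na(p3) && p5 <= low_pct && p3 >= high_pct
    }
    data.frame(sample_id = h$sample_id[1], gene5 = h$gene5[1],
               gene3 = h$gene3[1], fusion_like = flike,
               n_hits_5 = sum(h$role == "5prime"),
               n_hits_3 = sum(h$role == "3prime"),
               expr_asymmetry = asym, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
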