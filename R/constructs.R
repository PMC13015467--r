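#' Spliced transcript sequence from a genome
#'
#' Concatenates the exon sequences of a transcript (reverse-complemented
#' for minus-strand transcripts) from a genome [Biostrings::DNAStringSet]
#' named by chromosome.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param seqs genome DNAStringSet.
#' @param transcript_id transcript identifier.
#' @return character scalar, the spliced sequence 5' to 3'.
#' @export
transcriptSequence <- function(ann, seqs, transcript_id) {
  tx <- ann@transcripts
  i <- match(transcript_id, tx$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  chrom <- tx$chrom[i]
  if (!chrom %in% names(seqs)) stop("chromosome absent from FASTA: ", chrom)
  ex <- ann@exons[[transcript_id]]
  pieces <- vapply(seq_len(nrow(ex)), function(k) {
    as.character(Biostrings::subseq(seqs[[chrom]], ex$start[k], ex$end[k]))
  }, "")
  s <- paste(pieces, collapse = "")
  if (tx$strand[i] == "-") {
    s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# CDS start/end of a transcript in spliced (transcription-direction)
# coordinates; list(start, end) or NULL when non-coding
.cdsTxBounds <- function(ann, tid) {
  tx <- ann@transcripts
  i <- match(tid, tx$transcript_id)
  if (is.na(tx$cds_start[i])) return(NULL)
  ex <- ann@exons[[tid]]
  st <- tx$strand[i]
  g_first <- if (st == "-") tx$cds_end[i] else tx$cds_start[i]
  g_last <- if (st == "-") tx$cds_start[i] else tx$cds_end[i]
  list(start = .genomicToTx(ex, st, g_first),
       end = .genomicToTx(ex, st, g_last))
}

# snap a near-exon genomic position onto the nearest exon boundary of a
# transcript; positions already exonic are returned unchanged
.snapToExon <- function(ex, pos, near_exon_bp) {
  if (any(ex$start <= pos & pos <= ex$end)) return(pos)
  bounds <- c(ex$start, ex$end)
  d <- abs(bounds - pos)
  if (min(d) > near_exon_bp) return(NA_integer_)
  bounds[which.min(d)]
}

#' Select the reference transcript anchoring a construct
#'
#' Returns the highest-tier transcript (MANE, longest protein-coding,
#' then remaining transcripts by descending spliced length) in which the
#' breakpoint classifies as CDS or near-exon (< `near_exon_bp` from an
#' exon boundary); if none qualifies, falls back in the same tier order to
#' the first transcript whose span contains the breakpoint.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param gene gene name.
#' @param pos genomic breakpoint.
#' @param params a [fusionParams()] list.
#' @return transcript id.
#' @export
selectReferenceTranscript <- function(ann, gene, pos,
                                      params = fusionParams()) {
  gid <- .resolveGene(ann, gene)
  if (is.na(gid)) stop("selection error: gene not annotated: ", gene)
  tiers <- selectTranscriptTiers(ann, gene)
  tx <- ann@transcripts
  t3 <- tx[tx$transcript_id %in% tiers$tier3, , drop = FALSE]
  t3 <- t3[order(-t3$spliced_length, t3$transcript_id), , drop = FALSE]
  ordered <- unique(c(tiers$tier1, tiers$tier2, t3$transcript_id))
  ordered <- ordered[!is.na(ordered)]
  for (tid in ordered) {
    cl <- .classifyInTranscript(ann, tid, pos)
    if (identical(cl$class, "CDS")) return(tid)
    if (identical(cl$class, "intronic") &&
        cl$dist < params$near_exon_bp) {
      return(tid)
    }
  }
  for (tid in ordered) {
    i <- match(tid, tx$transcript_id)
    if (pos >= tx$tx_start[i] && pos <= tx$tx_end[i]) return(tid)
  }
  stop("selection error: breakpoint ", pos,
       " lies outside every transcript of ", gene)
}

.newConstruct <- function(fusion, t5, t3, cdna, junction_offset,
                          ref3_upstream, t3_seg_start_tx, cds3,
                          utr_rule) {
  x <- list(sample_id = fusion$sample_id, gene5 = fusion$gene5,
            gene3 = fusion$gene3, transcript5 = t5, transcript3 = t3,
            cdna = cdna, junction_offset = junction_offset,
            frame_status = NA_character_,
            premature_stop_pos = NA_integer_,
            orf_protein = NA_character_,
            microhomology_len = NA_integer_,
            utr_rule = utr_rule,
            ref3_upstream = ref3_upstream,
            t3_seg_start_tx = t3_seg_start_tx,
            t3_cds_start_tx = if (is.null(cds3)) NA_integer_ else
              cds3$start,
            t3_cds_end_tx = if (is.null(cds3)) NA_integer_ else cds3$end)
  class(x) <- "FusionConstruct"
  if (junction_offset <= 0L || junction_offset >= nchar(cdna)) {
    stop("assembly error: junction offset outside the construct")
  }
  x
}

#' Assemble a breakpoint-defined fusion cDNA
#'
#' The 5' moiety is the spliced reference-transcript sequence of the 5'
#' gene from its CDS start (ATG) through the last transcript base at or
#' before the 5' breakpoint; the 3' moiety runs from the first transcript
#' base at or after the 3' breakpoint through the transcript end.
#' Near-exon breakpoints are snapped to the nearest exon boundary of the
#' selected transcript before splicing. An optional junction override
#' (experimentally confirmed genomic coordinates) replaces the reported
#' breakpoints.
#'
#' @param fusion one-row data.frame/list with sample_id, gene5, pos5,
#'   gene3, pos3.
#' @param t5,t3 reference transcript ids
#'   ([selectReferenceTranscript()]).
#' @param ann a [GenomeAnnotation-class].
#' @param seqs genome DNAStringSet.
#' @param params a [fusionParams()] list.
#' @param junction_override optional list(pos5 =, pos3 =) genomic
#'   coordinates.
#' @return A `FusionConstruct` (sequence and junction only; see
#'   [orfAnalysis()]).
#' @export
assembleFusionCdna <- function(fusion, t5, t3, ann, seqs,
                               params = fusionParams(),
                               junction_override = NULL) {
  tx <- ann@transcripts
  bp5 <- if (!is.null(junction_override)) junction_override$pos5 else
    fusion$pos5
  bp3 <- if (!is.null(junction_override)) junction_override$pos3 else
    fusion$pos3
  i5 <- match(t5, tx$transcript_id); i3 <- match(t3, tx$transcript_id)
  ex5 <- ann@exons[[t5]]; ex3 <- ann@exons[[t3]]
  bp5 <- .snapToExon(ex5, bp5, params$near_exon_bp)
  bp3 <- .snapToExon(ex3, bp3, params$near_exon_bp)
  if (is.na(bp5) || is.na(bp3)) {
    stop("assembly error: breakpoint not representable on the spliced ",
         "transcript (deep intronic)")
  }
  cds5 <- .cdsTxBounds(ann, t5)
  if (is.null(cds5)) {
    stop("assembly error: 5' transcript ", t5, " lacks a CDS")
  }
  seq5 <- transcriptSequence(ann, seqs, t5)
  seq3 <- transcriptSequence(ann, seqs, t3)
  p5 <- .genomicToTx(ex5, tx$strand[i5], bp5)
  p3 <- .genomicToTx(ex3, tx$strand[i3], bp3)
  if (p5 < cds5$start) {
    stop("assembly error: 5' breakpoint upstream of the CDS start; ",
         "apply the 5'-UTR rule (apply5utrRule)")
  }
  seg5 <- substr(seq5, cds5$start, p5)
  seg3 <- substr(seq3, p3, nchar(seq3))
  .newConstruct(fusion, t5, t3, paste0(seg5, seg3), nchar(seg5),
                ref3_upstream = substr(seq3, 1L, p3 - 1L),
                t3_seg_start_tx = p3, cds3 = .cdsTxBounds(ann, t3),
                utr_rule = FALSE)
}

#' Assemble a construct for a 5'-UTR breakpoint
#'
#' When the 5' breakpoint falls in the 5' UTR (untranslated, so the
#' truncation point has no protein-level meaning), the construct instead
#' carries the entire 5'-gene coding sequence (stop codon removed) fused
#' to the 3'-gene sequence downstream of the 3' breakpoint.
#'
#' @inheritParams assembleFusionCdna
#' @return A `FusionConstruct`.
#' @export
apply5utrRule <- function(fusion, t5, t3, ann, seqs,
                          params = fusionParams(),
                          junction_override = NULL) {
  tx <- ann@transcripts
  bp5 <- if (!is.null(junction_override)) junction_override$pos5 else
    fusion$pos5
  bp3 <- if (!is.null(junction_override)) junction_override$pos3 else
    fusion$pos3
  cl5 <- .classifyInTranscript(ann, t5, bp5)
  if (!identical(cl5$class, "UTR5")) {
    stop("precondition violation: 5' breakpoint does not classify as ",
         "UTR5 on ", t5, " (got ", cl5$class, ")")
  }
  cds5 <- .cdsTxBounds(ann, t5)
  if (is.null(cds5)) stop("5' transcript ", t5, " lacks a CDS")
  i3 <- match(t3, tx$transcript_id)
  ex3 <- ann@exons[[t3]]
  bp3 <- .snapToExon(ex3, bp3, params$near_exon_bp)
  if (is.na(bp3)) {
    stop("assembly error: 3' breakpoint not representable on the ",
         "spliced transcript")
  }
  seq5 <- transcriptSequence(ann, seqs, t5)
  seq3 <- transcriptSequence(ann, seqs, t3)
  # entire CDS minus its stop codon, so translation reads into the 3' gene
  seg5 <- substr(seq5, cds5$start, cds5$end - 3L)
  p3 <- .genomicToTx(ex3, tx$strand[i3], bp3)
  seg3 <- substr(seq3, p3, nchar(seq3))
  x <- .newConstruct(fusion, t5, t3, paste0(seg5, seg3), nchar(seg5),
                     ref3_upstream = substr(seq3, 1L, p3 - 1L),
                     t3_seg_start_tx = p3,
                     cds3 = .cdsTxBounds(ann, t3), utr_rule = TRUE)
  x
}

#' Open-reading-frame analysis of a fusion construct
#'
#' Translates the construct from the 5' CDS start in frame 0 (standard
#' nuclear codon table). The construct is in frame when the codon phase
#' of the 3' moiety at the junction matches the 3' gene's native CDS
#' phase at its breakpoint. The first stop codon preceding the 3' gene's
#' natural stop sets `premature_stop_pos` (1-based codon index);
#' `orf_protein` is the translation up to (not including) the first
#' stop. Constructs assembled under the 5'-UTR rule report
#' `out_of_frame_5UTR_rule` instead of `out_of_frame` (the 5' moiety is a
#' complete, in-frame CDS by construction).
#'
#' @param construct a `FusionConstruct`.
#' @return The construct with frame_status, premature_stop_pos and
#'   orf_protein filled.
#' @export
orfAnalysis <- function(construct) {
  cdna <- construct$cdna
  if (nchar(cdna) < 3L) stop("construct shorter than one codon")
  ncod <- nchar(cdna) %/% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cdna, 1L, ncod * 3L)),
    if.fuzzy.codon = "X"))
  stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
  stops <- stops[stops > 0L]

  jo <- construct$junction_offset
  p3 <- construct$t3_seg_start_tx
  cs3 <- construct$t3_cds_start_tx
  ce3 <- construct$t3_cds_end_tx
  in_frame <- FALSE
  if (!is.na(cs3)) {
    if (p3 >= cs3) {
      in_frame <- ((p3 - cs3) %% 3L) == (jo %% 3L)
    } else {
      # 3' segment begins upstream of the 3' CDS; frame holds when the
      # 3' CDS start lands on a codon boundary of the construct
      in_frame <- ((jo + (cs3 - p3)) %% 3L) == 0L
    }
  }
  construct$frame_status <- if (in_frame) {
    "in_frame"
  } else if (isTRUE(construct$utr_rule)) {
    "out_of_frame_5UTR_rule"
  } else {
    "out_of_frame"
  }

  # natural stop codon of the 3' gene, in construct coordinates
  nat_start <- NA_integer_
  if (!is.na(ce3) && ce3 >= p3) {
    nat_start <- jo + (ce3 - p3 + 1L) - 2L
  }
  first_stop <- if (length(stops)) stops[1] else NA_integer_
  if (!is.na(first_stop)) {
    nt_start <- 3L * (first_stop - 1L) + 1L
    premature <- is.na(nat_start) || nt_start < nat_start
    if (premature) construct$premature_stop_pos <- first_stop
    construct$orf_protein <- substr(aa, 1L, first_stop - 1L)
  } else {
    construct$orf_protein <- aa
  }
  construct
}

#' Maximal junction microhomology between two upstream flanks
#'
#' Largest k such that the last k bases of the 5'-gene reference segment
#' equal the k bases of the 3'-gene reference immediately preceding its
#' breakpoint — junction bases assignable to either partner.
#'
#' @param up5 reference sequence ending at the 5' junction side.
#' @param up3 3'-gene reference sequence immediately preceding its
#'   breakpoint.
#' @return integer k (0 when no homology).
#' @export
microhomologyLength <- function(up5, up3) {
  kmax <- min(nchar(up5), nchar(up3))
  k <- 0L
  while (k < kmax &&
         substr(up5, nchar(up5) - k, nchar(up5) - k) ==
           substr(up3, nchar(up3) - k, nchar(up3) - k)) {
    k <- k + 1L
  }
  k
}

#' Junction microhomology of a fusion construct
#'
#' @param construct a `FusionConstruct`.
#' @return The construct with `microhomology_len` set.
#' @export
junctionMicrohomology <- function(construct) {
  up5 <- substr(construct$cdna, 1L, construct$junction_offset)
  construct$microhomology_len <- microhomologyLength(
    up5, construct$ref3_upstream)
  construct
}

#' Design a fusion construct end to end
#'
#' Selects reference transcripts, dispatches the 5'-UTR rule when the 5'
#' breakpoint classifies as UTR5 on the selected transcript, assembles
#' the cDNA, and runs ORF and microhomology analysis.
#'
#' @inheritParams assembleFusionCdna
#' @return A completed `FusionConstruct`.
#' @export
designFusionConstruct <- function(fusion, ann, seqs,
                                  params = fusionParams(),
                                  junction_override = NULL) {
  t5 <- selectReferenceTranscript(ann, fusion$gene5, fusion$pos5, params)
  t3 <- selectReferenceTranscript(ann, fusion$gene3, fusion$pos3, params)
  bp5 <- if (!is.null(junction_override)) junction_override$pos5 else
    fusion$pos5
  cl5 <- .classifyInTranscript(ann, t5, bp5)
  x <- if (identical(cl5$class, "UTR5")) {
    apply5utrRule(fusion, t5, t3, ann, seqs, params, junction_override)
  } else {
    assembleFusionCdna(fusion, t5, t3, ann, seqs, params,
                       junction_override)
  }
  junctionMicrohomology(orfAnalysis(x))
}

#' @export
print.FusionConstruct <- function(x, ...) {
  cat(sprintf("FusionConstruct %s::%s [%s]\n", x$gene5, x$gene3,
              x$sample_id))
  cat(sprintf("  transcripts: %s | %s\n", x$transcript5, x$transcript3))
  cat(sprintf("  cDNA %d nt, junction at %d; frame: %s\n",
              nchar(x$cdna), x$junction_offset,
              ifelse(is.na(x$frame_status), "(pending)", x$frame_status)))
  if (!is.na(x$premature_stop_pos)) {
    cat(sprintf("  premature stop at codon %d\n", x$premature_stop_pos))
  }
  if (!is.na(x$microhomology_len)) {
    cat(sprintf("  junction microhomology: %d nt\n",
                x$microhomology_len))
  }
  invisible(x)
}
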