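#' Read a GENCODE-style GTF into a GenomeAnnotation
#'
#' Parses gene/transcript/exon/CDS features (via [rtracklayer::import])
#' after a line-level sanity scan that reports malformed lines by line
#' number. MANE status is taken from the transcript's `tag` attributes
#' (tag value configurable through `params$mane_tag`); because attribute
#' keys may repeat, the raw lines are scanned for the tag in addition to
#' the parsed metadata. Coding status comes from
#' `transcript_type`/`transcript_biotype` (gene biotype as fallback).
#'
#' @param path path to a GTF file.
#' @param params a [fusionParams()] list (only `mane_tag` is used).
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' sim <- simulateAnnotation(n_genes = 3, seed = 1)
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(sim$gtf, gtf)
#' ann <- readAnnotation(gtf)
#' ann
#' @export
readAnnotation <- function(path, params = fusionParams()) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop("GTF parse error at line ", i, ": expected 9 tab-separated ",
           "fields, found ", length(f))
    }
    st <- suppressWarnings(as.integer(f[4]))
    en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en)) {
      stop("GTF parse error at line ", i, ": non-numeric coordinates")
    }
    if (st > en) {
      stop("GTF parse error at line ", i, ": start (", st,
           ") exceeds end (", en, ")")
    }
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  biotype_col <- intersect(c("gene_type", "gene_biotype"), names(md))[1]
  txtype_col <- intersect(c("transcript_type", "transcript_biotype"),
                          names(md))[1]

  # MANE tag from raw lines (attribute keys can repeat)
  mane_re <- paste0('tag\\s+"', params$mane_tag, '"')
  mane_lines <- lines[body][grepl(mane_re, lines[body])]
  mane_tx <- unique(sub('.*transcript_id\\s+"([^"]+)".*', "\\1",
                        mane_lines[grepl('transcript_id\\s+"', mane_lines)]))
  if (!is.na(match("tag", names(md)))) {
    mane_tx <- union(mane_tx,
                     unique(stats::na.omit(
                       md$transcript_id[!is.na(md$tag) &
                                          md$tag == params$mane_tag])))
  }

  is_ex <- type == "exon"
  is_cds <- type == "CDS"
  is_tx <- type == "transcript"
  is_gene <- type == "gene"

  tx_ids <- unique(md$transcript_id[is_ex])
  if (length(tx_ids) == 0L) stop("GTF contains no exon features")

  exdf <- data.frame(transcript_id = md$transcript_id[is_ex],
                     start = GenomicRanges::start(gr)[is_ex],
                     end = GenomicRanges::end(gr)[is_ex],
                     stringsAsFactors = FALSE)
  exons <- lapply(split(exdf[c("start", "end")], exdf$transcript_id),
                  function(d) {
                    d <- d[order(d$start, d$end), , drop = FALSE]
                    rownames(d) <- NULL
                    d
                  })

  # per-transcript metadata anchored on exon features
  first_ex <- !duplicated(md$transcript_id) & !is.na(md$transcript_id)
  anchor <- match(tx_ids, md$transcript_id[is_ex])
  ex_idx <- which(is_ex)
  a <- ex_idx[anchor]
  tx_gene <- md$gene_id[a]
  tx_chrom <- as.character(GenomicRanges::seqnames(gr))[a]
  tx_strand <- as.character(GenomicRanges::strand(gr))[a]

  txt <- rep(NA_character_, length(tx_ids))
  if (!is.na(txtype_col)) {
    src <- md[[txtype_col]]
    got <- tapply(src[is_ex], md$transcript_id[is_ex],
                  function(v) v[!is.na(v)][1])
    txt <- as.character(got[tx_ids])
    if (any(is.na(txt)) && any(is_tx)) {
      m <- match(tx_ids, md$transcript_id[is_tx])
      fill <- src[which(is_tx)][m]
      txt[is.na(txt)] <- as.character(fill[is.na(txt)])
    }
  }

  cds_start <- rep(NA_integer_, length(tx_ids))
  cds_end <- rep(NA_integer_, length(tx_ids))
  if (any(is_cds)) {
    cs <- tapply(GenomicRanges::start(gr)[is_cds],
                 md$transcript_id[is_cds], min)
    ce <- tapply(GenomicRanges::end(gr)[is_cds],
                 md$transcript_id[is_cds], max)
    m <- match(tx_ids, names(cs))
    cds_start[!is.na(m)] <- as.integer(cs[m[!is.na(m)]])
    cds_end[!is.na(m)] <- as.integer(ce[m[!is.na(m)]])
  }

  spl <- vapply(exons[tx_ids],
                function(d) sum(d$end - d$start + 1L), integer(1))
  tx_start <- vapply(exons[tx_ids], function(d) min(d$start), integer(1))
  tx_end <- vapply(exons[tx_ids], function(d) max(d$end), integer(1))

  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = tx_gene,
    chrom = tx_chrom,
    strand = tx_strand,
    tx_start = tx_start,
    tx_end = tx_end,
    is_mane = tx_ids %in% mane_tx,
    is_protein_coding = !is.na(txt) & txt == "protein_coding",
    cds_start = cds_start,
    cds_end = cds_end,
    spliced_length = spl,
    stringsAsFactors = FALSE)
  # a transcript with CDS is coding even if biotype was absent
  transcripts$is_protein_coding <- transcripts$is_protein_coding |
    !is.na(transcripts$cds_start)
  transcripts <- transcripts[order(transcripts$transcript_id), ,
                             drop = FALSE]
  rownames(transcripts) <- NULL

  # gene table: name/biotype from gene features when present
  gid <- unique(transcripts$gene_id)
  gname <- gid
  gbio <- rep(NA_character_, length(gid))
  if (any(is_gene)) {
    m <- match(gid, md$gene_id[is_gene])
    gw <- which(is_gene)
    nn <- md$gene_name[gw][m]
    gname[!is.na(nn)] <- as.character(nn[!is.na(nn)])
    if (!is.na(biotype_col)) {
      bb <- md[[biotype_col]][gw][m]
      gbio <- as.character(bb)
    }
    # exon outside its gene feature's span is a validation error
    gfs <- GenomicRanges::start(gr)[gw][m]
    gfe <- GenomicRanges::end(gr)[gw][m]
    for (k in seq_along(gid)) {
      if (is.na(gfs[k])) next
      tx_k <- transcripts[transcripts$gene_id == gid[k], ]
      if (min(tx_k$tx_start) < gfs[k] || max(tx_k$tx_end) > gfe[k]) {
        stop("validation error: exon outside the span of gene ", gid[k])
      }
    }
  } else {
    nn <- tapply(md$gene_name[is_ex], md$gene_id[is_ex],
                 function(v) v[!is.na(v)][1])
    hit <- !is.na(nn[gid])
    gname[hit] <- as.character(nn[gid][hit])
  }
  gsp_s <- tapply(transcripts$tx_start, transcripts$gene_id, min)[gid]
  gsp_e <- tapply(transcripts$tx_end, transcripts$gene_id, max)[gid]
  gchrom <- transcripts$chrom[match(gid, transcripts$gene_id)]
  gstrand <- transcripts$strand[match(gid, transcripts$gene_id)]
  genes <- GenomicRanges::GRanges(
    seqnames = gchrom,
    ranges = IRanges::IRanges(start = as.integer(gsp_s),
                              end = as.integer(gsp_e)),
    strand = gstrand)
  S4Vectors::mcols(genes)$gene_id <- gid
  S4Vectors::mcols(genes)$gene_name <- gname
  S4Vectors::mcols(genes)$biotype <- gbio
  names(genes) <- gname
  ord <- order(gid)
  genes <- genes[ord]

  new("GenomeAnnotation", genes = genes, transcripts = transcripts,
      exons = exons)
}

#' Write a GenomeAnnotation back to GTF text
#'
#' Emits gene, transcript, exon and CDS features with GENCODE-style
#' attributes (including the MANE tag). Coordinates round-trip exactly
#' through [readAnnotation()].
#'
#' @param ann a GenomeAnnotation.
#' @param path optional file path; when NULL the GTF lines are returned.
#' @param mane_tag tag value written for MANE transcripts.
#' @return Invisibly (or visibly when `path` is NULL), the GTF lines.
#' @export
writeAnnotation <- function(ann, path = NULL, mane_tag = "MANE_Select") {
  stopifnot(is(ann, "GenomeAnnotation"))
  g <- ann@genes
  tx <- ann@transcripts
  out <- character(0)
  gm <- S4Vectors::mcols(g)
  for (i in seq_along(g)) {
    gid <- gm$gene_id[i]
    bt <- if (is.na(gm$biotype[i])) "unknown" else gm$biotype[i]
    gattr <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                     gid, gm$gene_name[i], bt)
    out <- c(out, sprintf("%s\tFusionScope\tgene\t%d\t%d\t.\t%s\t.\t%s",
                          as.character(GenomicRanges::seqnames(g))[i],
                          GenomicRanges::start(g)[i],
                          GenomicRanges::end(g)[i],
                          as.character(GenomicRanges::strand(g))[i],
                          gattr))
    for (j in which(tx$gene_id == gid)) {
      tid <- tx$transcript_id[j]
      ttype <- if (tx$is_protein_coding[j]) "protein_coding" else bt
      tag <- if (tx$is_mane[j]) sprintf(' tag "%s";', mane_tag) else ""
      tattr <- sprintf(
        '%s transcript_id "%s"; transcript_type "%s";%s',
        gattr, tid, ttype, tag)
      out <- c(out, sprintf(
        "%s\tFusionScope\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        tx$chrom[j], tx$tx_start[j], tx$tx_end[j], tx$strand[j], tattr))
      ex <- ann@exons[[tid]]
      for (k in seq_len(nrow(ex))) {
        out <- c(out, sprintf(
          "%s\tFusionScope\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
          tx$chrom[j], ex$start[k], ex$end[k], tx$strand[j], tattr, k))
      }
      if (!is.na(tx$cds_start[j])) {
        cs <- tx$cds_start[j]; ce <- tx$cds_end[j]
        for (k in seq_len(nrow(ex))) {
          s <- max(ex$start[k], cs); e <- min(ex$end[k], ce)
          if (s <= e) {
            out <- c(out, sprintf(
              "%s\tFusionScope\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              tx$chrom[j], s, e, tx$strand[j], tattr))
          }
        }
      }
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---- accessors ------------------------------------------------------------

#' Gene span GRanges of an annotation
#' @param ann a GenomeAnnotation.
#' @return GRanges named by gene name.
#' @export
geneRanges <- function(ann) {
  stopifnot(is(ann, "GenomeAnnotation"))
  ann@genes
}

#' Transcript metadata table of an annotation
#' @param ann a GenomeAnnotation.
#' @return data.frame, one row per transcript.
#' @export
transcriptTable <- function(ann) {
  stopifnot(is(ann, "GenomeAnnotation"))
  ann@transcripts
}

#' Exon chain of one transcript
#' @param ann a GenomeAnnotation.
#' @param transcript_id transcript identifier.
#' @return data.frame with columns start, end (1-based closed, sorted).
#' @export
exonChain <- function(ann, transcript_id) {
  stopifnot(is(ann, "GenomeAnnotation"))
  ex <- ann@exons[[transcript_id]]
  if (is.null(ex)) stop("unknown transcript: ", transcript_id)
  ex
}

# resolve a gene name or id to the gene_id, NA when absent
.resolveGene <- function(ann, gene) {
  gm <- S4Vectors::mcols(ann@genes)
  i <- match(gene, gm$gene_name)
  if (is.na(i)) i <- match(gene, gm$gene_id)
  if (is.na(i)) return(NA_character_)
  gm$gene_id[i]
}

.geneIndex <- function(ann, gene) {
  gid <- .resolveGene(ann, gene)
  if (is.na(gid)) return(NA_integer_)
  match(gid, S4Vectors::mcols(ann@genes)$gene_id)
}

#' Genomic length of a gene span
#'
#' Span end minus span start plus one, over the union of the gene's
#' transcripts. Used by the proportional breakpoint-proximity rule.
#'
#' @param ann a GenomeAnnotation.
#' @param gene gene name or gene id.
#' @return integer length in bp; NA if the gene is not annotated.
#' @export
geneLength <- function(ann, gene) {
  i <- .geneIndex(ann, gene)
  if (is.na(i)) return(NA_integer_)
  GenomicRanges::width(ann@genes)[i]
}

#' Annotated strand of a gene
#' @param ann a GenomeAnnotation.
#' @param gene gene name or id.
#' @return "+", "-" or NA when unannotated.
#' @export
geneStrand <- function(ann, gene) {
  i <- .geneIndex(ann, gene)
  if (is.na(i)) return(NA_character_)
  as.character(GenomicRanges::strand(ann@genes))[i]
}

#' Select the three transcript tiers of a gene
#'
#' Tier 1 is the MANE transcript (if any); tier 2 the protein-coding
#' transcript with maximal spliced (summed exon) length, ties broken by
#' lexicographically smallest transcript id; tier 3 all transcripts.
#'
#' @param ann a GenomeAnnotation.
#' @param gene gene name or id.
#' @return list with elements `tier1` (transcript id or NA), `tier2`
#'   (transcript id or NA), `tier3` (character vector of all transcript
#'   ids).
#' @export
selectTranscriptTiers <- function(ann, gene) {
  gid <- .resolveGene(ann, gene)
  if (is.na(gid)) stop("gene not in annotation: ", gene)
  tx <- ann@transcripts[ann@transcripts$gene_id == gid, , drop = FALSE]
  if (nrow(tx) == 0L) stop("gene has no transcripts: ", gene)
  tier1 <- NA_character_
  if (any(tx$is_mane)) {
    cand <- sort(tx$transcript_id[tx$is_mane])
    tier1 <- cand[1]
  }
  tier2 <- NA_character_
  pc <- tx[tx$is_protein_coding, , drop = FALSE]
  if (nrow(pc)) {
    pc <- pc[order(-pc$spliced_length, pc$transcript_id), , drop = FALSE]
    tier2 <- pc$transcript_id[1]
  }
  list(tier1 = tier1, tier2 = tier2, tier3 = sort(tx$transcript_id))
}

# ---- coordinate helpers ---------------------------------------------------

# spliced length of an exon chain
.splicedLen <- function(ex) sum(ex$end - ex$start + 1L)

# genomic coordinate of the 5' end of a transcript in transcription
# direction
.txStart5 <- function(ex, strand) {
  if (strand == "-") max(ex$end) else min(ex$start)
}

# genomic coordinate of the 3' end in transcription direction
.txEnd3 <- function(ex, strand) {
  if (strand == "-") min(ex$start) else max(ex$end)
}

# map a genomic position to a 1-based transcript coordinate (transcription
# direction); NA when the position is intronic/outside
.genomicToTx <- function(ex, strand, gpos) {
  hit <- which(ex$start <= gpos & gpos <= ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  w <- ex$end - ex$start + 1L
  if (strand == "-") {
    after <- if (hit < nrow(ex)) sum(w[(hit + 1L):nrow(ex)]) else 0L
    as.integer(after + (ex$end[hit] - gpos) + 1L)
  } else {
    before <- if (hit > 1L) sum(w[1L:(hit - 1L)]) else 0L
    as.integer(before + (gpos - ex$start[hit]) + 1L)
  }
}

# minimum distance from a (typically intronic) genomic position to any
# exon boundary of the chain
.distToExonBoundary <- function(ex, gpos) {
  min(abs(c(ex$start, ex$end) - gpos))
}
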