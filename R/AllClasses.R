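#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' GenomeAnnotation: tiered gene/transcript/exon model
#'
#' Container for a GTF-derived gene annotation. Gene spans are held as a
#' [GenomicRanges::GRanges] (one range per gene, the union span over its
#' transcripts); transcript metadata (strand, MANE flag, coding flag,
#' genomic CDS bounds, spliced length) as a data.frame; and per-transcript
#' exon chains as a named list of two-column data.frames with 1-based
#' fully-closed coordinates sorted by position.
#'
#' @slot genes GRanges of gene spans; mcols carry gene_id, gene_name,
#'   biotype.
#' @slot transcripts data.frame with one row per transcript.
#' @slot exons named list (by transcript_id) of data.frames with columns
#'   start, end.
#'
#' @export
setClass("GenomeAnnotation",
         representation(genes = "GRanges",
                        transcripts = "data.frame",
                        exons = "list"))

setValidity("GenomeAnnotation", function(object) {
  tx <- object@transcripts
  need <- c("transcript_id", "gene_id", "chrom", "strand", "tx_start",
            "tx_end", "is_mane", "is_protein_coding", "cds_start",
            "cds_end", "spliced_length")
  if (!all(need %in% names(tx))) {
    return(paste("transcripts lacks columns:",
                 paste(setdiff(need, names(tx)), collapse = ", ")))
  }
  if (anyDuplicated(tx$transcript_id)) {
    return("duplicated transcript_id")
  }
  if (!all(tx$transcript_id %in% names(object@exons))) {
    return("every transcript needs an exon chain")
  }
  for (tid in tx$transcript_id) {
    ex <- object@exons[[tid]]
    if (nrow(ex) < 1L) return(paste("transcript", tid, "has no exons"))
    if (any(ex$start > ex$end)) {
      return(paste("exon with start > end in", tid))
    }
    if (is.unsorted(ex$start) ||
        (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))) {
      return(paste("exons overlapping or unsorted in", tid))
    }
  }
  # CDS within exon union
  has_cds <- !is.na(tx$cds_start)
  for (i in which(has_cds)) {
    ex <- object@exons[[tx$transcript_id[i]]]
    cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
    if (!any(ex$start <= cs & cs <= ex$end) ||
        !any(ex$start <= ce & ce <= ex$end)) {
      return(paste("CDS outside exon union for", tx$transcript_id[i]))
    }
  }
  # transcripts share their gene's chromosome
  gchrom <- stats::setNames(as.character(seqnames(object@genes)),
                            mcols(object@genes)$gene_id)
  if (!all(tx$chrom == gchrom[tx$gene_id])) {
    return("transcript chromosome differs from its gene's")
  }
  TRUE
})

#' @describeIn GenomeAnnotation compact display
#' @param object a GenomeAnnotation
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@genes), "genes,",
      nrow(object@transcripts), "transcripts on",
      length(unique(as.character(seqnames(object@genes)))),
      "sequence(s)\n")
  nm <- sum(object@transcripts$is_mane)
  cat("  MANE-tagged transcripts:", nm, "| protein-coding transcripts:",
      sum(object@transcripts$is_protein_coding), "\n")
})

#' FusionCallSet: normalized multi-caller fusion calls
#'
#' One row per caller-reported fusion event: sample, 5'/3' partner genes,
#' the two genomic breakpoints with strands, read support, and caller
#' provenance (semicolon-joined set). `reciprocal_of` links a surviving
#' orientation to its collapsed reciprocal.
#'
#' @slot calls data.frame with columns sample_id, gene5, chrom5, pos5,
#'   strand5, gene3, chrom3, pos3, strand3, support, callers,
#'   reciprocal_of.
#' @export
setClass("FusionCallSet", representation(calls = "data.frame"))

.call_cols <- c("sample_id", "gene5", "chrom5", "pos5", "strand5",
                "gene3", "chrom3", "pos3", "strand3", "support", "callers")

setValidity("FusionCallSet", function(object) {
  df <- object@calls
  if (!all(.call_cols %in% names(df))) {
    return(paste("calls lacks columns:",
                 paste(setdiff(.call_cols, names(df)), collapse = ", ")))
  }
  if (nrow(df) == 0L) return(TRUE)
  if (any(!nzchar(df$gene5)) || any(!nzchar(df$gene3))) {
    return("empty partner gene name")
  }
  if (any(is.na(df$support)) || any(df$support < 1L)) {
    return("support must be >= 1")
  }
  if (any(!nzchar(df$callers))) return("callers must be non-empty")
  if (any(df$pos5 < 1L) || any(df$pos3 < 1L)) {
    return("breakpoint positions must be >= 1")
  }
  if (!all(df$strand5 %in% c("+", "-", ".")) ||
      !all(df$strand3 %in% c("+", "-", "."))) {
    return("strands must be '+', '-' or '.' (unknown)")
  }
  TRUE
})

#' Construct a FusionCallSet from a data.frame
#'
#' @param calls data.frame of normalized calls (see class docs). A missing
#'   `reciprocal_of` column is added as NA.
#' @return A `FusionCallSet`.
#' @export
FusionCallSet <- function(calls = data.frame()) {
  if (nrow(calls) == 0L && ncol(calls) == 0L) {
    calls <- data.frame(sample_id = character(), gene5 = character(),
                        chrom5 = character(), pos5 = integer(),
                        strand5 = character(), gene3 = character(),
                        chrom3 = character(), pos3 = integer(),
                        strand3 = character(), support = integer(),
                        callers = character(),
                        reciprocal_of = character(),
                        stringsAsFactors = FALSE)
  }
  if (!"reciprocal_of" %in% names(calls)) {
    calls$reciprocal_of <- NA_character_
  }
  calls$pos5 <- as.integer(calls$pos5)
  calls$pos3 <- as.integer(calls$pos3)
  calls$support <- as.integer(calls$support)
  rownames(calls) <- NULL
  new("FusionCallSet", calls = calls)
}

#' @describeIn FusionCallSet number of calls
#' @param x a FusionCallSet
#' @export
setMethod("length", "FusionCallSet", function(x) nrow(x@calls))

#' @describeIn FusionCallSet compact display
#' @param object a FusionCallSet
#' @export
setMethod("show", "FusionCallSet", function(object) {
  df <- object@calls
  cat("FusionCallSet:", nrow(df), "calls,",
      length(unique(df$sample_id)), "sample(s)\n")
  if (nrow(df)) {
    cat("  callers:",
        paste(sort(unique(unlist(strsplit(df$callers, ";")))),
              collapse = ", "), "\n")
    cat("  support: median", stats::median(df$support), "| mean",
        round(mean(df$support), 2), "\n")
  }
})

#' Extract the call table from a FusionCallSet
#' @param x a FusionCallSet.
#' @param ... unused.
#' @return data.frame of calls.
#' @export
fusionCalls <- function(x, ...) {
  stopifnot(is(x, "FusionCallSet"))
  x@calls
}
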