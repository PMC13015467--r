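# Hand-built fixtures and independent oracles shared across test files.

# A two-chromosome toy annotation:
#   ALPHA (chr1, +): T1 MANE, 3 exons 101-200/301-400/501-700, CDS 151-560
#                    T2 coding, 2 exons 101-200/501-700 (shorter)
#   BETA  (chr1, -): B1 MANE, 2 exons 1001-1100/1301-1500, CDS 1051-1450
#   GAMMA (chr2, +): G1 non-coding, 1 exon 2001-2500
#   DELTA (chr2, +): D1 coding (no MANE) 2 ex 5001-5200/5401-5600,
#                    CDS 5051-5550; D2 coding 1 ex 5001-5200, CDS 5051-5180
toyGtf <- function() {
  c(
    paste0("chr1\ttest\tgene\t101\t700\t.\t+\t.\t",
           'gene_id "GA"; gene_name "ALPHA"; gene_type "protein_coding";'),
    paste0("chr1\ttest\ttranscript\t101\t700\t.\t+\t.\t",
           'gene_id "GA"; gene_name "ALPHA"; transcript_id "T1"; ',
           'transcript_type "protein_coding"; tag "basic"; ',
           'tag "MANE_Select";'),
    sprintf(paste0("chr1\ttest\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "GA"; transcript_id "T1"; ',
                   'transcript_type "protein_coding";'),
            c(101L, 301L, 501L), c(200L, 400L, 700L)),
    sprintf(paste0("chr1\ttest\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "GA"; transcript_id "T1"; ',
                   'transcript_type "protein_coding";'),
            c(151L, 301L, 501L), c(200L, 400L, 560L)),
    paste0("chr1\ttest\ttranscript\t101\t700\t.\t+\t.\t",
           'gene_id "GA"; gene_name "ALPHA"; transcript_id "T2"; ',
           'transcript_type "protein_coding";'),
    sprintf(paste0("chr1\ttest\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "GA"; transcript_id "T2"; ',
                   'transcript_type "protein_coding";'),
            c(101L, 501L), c(200L, 700L)),
    sprintf(paste0("chr1\ttest\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "GA"; transcript_id "T2"; ',
                   'transcript_type "protein_coding";'),
            c(151L, 501L), c(200L, 560L)),
    paste0("chr1\ttest\tgene\t1001\t1500\t.\t-\t.\t",
           'gene_id "GB"; gene_name "BETA"; gene_type "protein_coding";'),
    paste0("chr1\ttest\ttranscript\t1001\t1500\t.\t-\t.\t",
           'gene_id "GB"; gene_name "BETA"; transcript_id "B1"; ',
           'transcript_type "protein_coding"; tag "MANE_Select";'),
    sprintf(paste0("chr1\ttest\texon\t%d\t%d\t.\t-\t.\t",
                   'gene_id "GB"; transcript_id "B1"; ',
                   'transcript_type "protein_coding";'),
            c(1001L, 1301L), c(1100L, 1500L)),
    sprintf(paste0("chr1\ttest\tCDS\t%d\t%d\t.\t-\t0\t",
                   'gene_id "GB"; transcript_id "B1"; ',
                   'transcript_type "protein_coding";'),
            c(1051L, 1301L), c(1100L, 1450L)),
    paste0("chr2\ttest\tgene\t2001\t2500\t.\t+\t.\t",
           'gene_id "GC"; gene_name "GAMMA"; gene_type "lncRNA";'),
    paste0("chr2\ttest\ttranscript\t2001\t2500\t.\t+\t.\t",
           'gene_id "GC"; gene_name "GAMMA"; transcript_id "C1"; ',
           'transcript_type "lncRNA";'),
    paste0("chr2\ttest\texon\t2001\t2500\t.\t+\t.\t",
           'gene_id "GC"; transcript_id "C1"; transcript_type "lncRNA";'),
    paste0("chr2\ttest\tgene\t5001\t5600\t.\t+\t.\t",
           'gene_id "GD"; gene_name "DELTA"; gene_type "protein_coding";'),
    paste0("chr2\ttest\ttranscript\t5001\t5600\t.\t+\t.\t",
           'gene_id "GD"; gene_name "DELTA"; transcript_id "D1"; ',
           'transcript_type "protein_coding";'),
    sprintf(paste0("chr2\ttest\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "GD"; transcript_id "D1"; ',
                   'transcript_type "protein_coding";'),
            c(5001L, 5401L), c(5200L, 5600L)),
    sprintf(paste0("chr2\ttest\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "GD"; transcript_id "D1"; ',
                   'transcript_type "protein_coding";'),
            c(5051L, 5401L), c(5200L, 5550L)),
    paste0("chr2\ttest\ttranscript\t5001\t5200\t.\t+\t.\t",
           'gene_id "GD"; gene_name "DELTA"; transcript_id "D2"; ',
           'transcript_type "protein_coding";'),
    paste0("chr2\ttest\texon\t5001\t5200\t.\t+\t.\t",
           'gene_id "GD"; transcript_id "D2"; ',
           'transcript_type "protein_coding";'),
    paste0("chr2\ttest\tCDS\t5051\t5180\t.\t+\t0\t",
           'gene_id "GD"; transcript_id "D2"; ',
           'transcript_type "protein_coding";')
  )
}

toyAnnotation <- function() {
  tf <- tempfile(fileext = ".gtf")
  writeLines(toyGtf(), tf)
  on.exit(unlink(tf))
  readAnnotation(tf)
}

# one normalized call row
mkCall <- function(sample_id = "s1", gene5 = "ALPHA", chrom5 = "chr1",
                   pos5 = 350L, strand5 = "+", gene3 = "BETA",
                   chrom3 = "chr1", pos3 = 1350L, strand3 = "-",
                   support = 5L, callers = "LongGF") {
  data.frame(sample_id = sample_id, gene5 = gene5, chrom5 = chrom5,
             pos5 = pos5, strand5 = strand5, gene3 = gene3,
             chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
             support = support, callers = callers,
             stringsAsFactors = FALSE)
}

mkCallSet <- function(...) FusionCallSet(do.call(rbind, list(...)))

# one isoform structure record
mkIso <- function(id, gene = "G1", sample = "s1", strand = "+",
                  novelty = "NIC", chain = "100-200,300-400") {
  data.frame(isoform_id = id, gene = gene, sample_id = sample,
             strand = strand, novelty = novelty, exons = chain,
             stringsAsFactors = FALSE)
}

# Construct-design fixture on chrT (+ strand, fully controlled bases):
#   FIVE:  exons 101-160 / 201-280, CDS 111..270 (spliced 11..130)
#          spliced = G x10 | ATG | (GCT) x38 | TAA | C x10
#   THREE: exons 401-460 / 501-600, CDS 421..580 (spliced 21..140)
#          spliced = A x13 GCTGCTG | ATG | (GAT) x38 | TAA | T x20
constructFixture <- function() {
  spliced5 <- paste0(strrep("G", 10), "ATG", strrep("GCT", 38), "TAA",
                     strrep("C", 10))
  spliced3 <- paste0(strrep("A", 13), "GCTGCTG", "ATG",
                     strrep("GAT", 38), "TAA", strrep("T", 20))
  chr <- rep("A", 700)
  place <- function(chr, at, s) {
    chr[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    chr
  }
  chr <- place(chr, 101L, substr(spliced5, 1, 60))
  chr <- place(chr, 201L, substr(spliced5, 61, 140))
  chr <- place(chr, 401L, substr(spliced3, 1, 60))
  chr <- place(chr, 501L, substr(spliced3, 61, 160))
  seqs <- Biostrings::DNAStringSet(paste(chr, collapse = ""))
  names(seqs) <- "chrT"
  gtf <- c(
    paste0("chrT\tt\tgene\t101\t280\t.\t+\t.\t",
           'gene_id "F5G"; gene_name "FIVE"; gene_type "protein_coding";'),
    paste0("chrT\tt\ttranscript\t101\t280\t.\t+\t.\t",
           'gene_id "F5G"; transcript_id "F5T"; ',
           'transcript_type "protein_coding"; tag "MANE_Select";'),
    sprintf(paste0("chrT\tt\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "F5G"; transcript_id "F5T";'),
            c(101L, 201L), c(160L, 280L)),
    sprintf(paste0("chrT\tt\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "F5G"; transcript_id "F5T";'),
            c(111L, 201L), c(160L, 270L)),
    paste0("chrT\tt\tgene\t401\t600\t.\t+\t.\t",
           'gene_id "F3G"; gene_name "THREE"; ',
           'gene_type "protein_coding";'),
    paste0("chrT\tt\ttranscript\t401\t600\t.\t+\t.\t",
           'gene_id "F3G"; transcript_id "F3T"; ',
           'transcript_type "protein_coding"; tag "MANE_Select";'),
    sprintf(paste0("chrT\tt\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "F3G"; transcript_id "F3T";'),
            c(401L, 501L), c(460L, 600L)),
    sprintf(paste0("chrT\tt\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "F3G"; transcript_id "F3T";'),
            c(421L, 501L), c(460L, 580L)))
  tf <- tempfile(fileext = ".gtf")
  writeLines(gtf, tf)
  ann <- readAnnotation(tf)
  unlink(tf)
  list(ann = ann, seqs = seqs, spliced5 = spliced5, spliced3 = spliced3)
}

mkFusion <- function(pos5, pos3, sample_id = "s1") {
  list(sample_id = sample_id, gene5 = "FIVE", pos5 = pos5,
       gene3 = "THREE", pos3 = pos3)
}

# ---- independent oracles --------------------------------------------------

# exhaustive single-linkage clustering over pairwise window adjacency
oracleSingleLinkage <- function(pos5, pos3, window) {
  n <- length(pos5)
  adj <- outer(pos5, pos5, function(a, b) abs(a - b) <= window) &
    outer(pos3, pos3, function(a, b) abs(a - b) <= window)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# naive region classification: scan tiers in order, plain interval checks
oracleClassify <- function(ann, gene, pos, near_exon_bp = 200L) {
  tx <- transcriptTable(ann)
  gm <- S4Vectors::mcols(geneRanges(ann))
  gi <- match(gene, gm$gene_name)
  if (is.na(gi)) return("unannotated")
  gid <- gm$gene_id[gi]
  tiers <- selectTranscriptTiers(ann, gene)
  classify_one <- function(tid) {
    i <- match(tid, tx$transcript_id)
    ex <- exonChain(ann, tid)
    if (pos < min(ex$start) || pos > max(ex$end)) return("absent")
    inx <- FALSE
    for (k in seq_len(nrow(ex))) {
      if (pos >= ex$start[k] && pos <= ex$end[k]) inx <- TRUE
    }
    if (!inx) return("intronic")
    if (is.na(tx$cds_start[i])) return("noncoding_exon")
    if (pos >= tx$cds_start[i] && pos <= tx$cds_end[i]) return("CDS")
    left <- pos < tx$cds_start[i]
    if (tx$strand[i] == "+") {
      if (left) "UTR5" else "UTR3"
    } else {
      if (left) "UTR3" else "UTR5"
    }
  }
  tier_list <- list(tiers$tier1, tiers$tier2, tiers$tier3)
  intronic_seen <- NULL
  for (ts in tier_list) {
    ts <- ts[!is.na(ts)]
    if (!length(ts)) next
    cls <- vapply(ts, classify_one, "")
    for (pref in c("CDS", "UTR5", "UTR3", "noncoding_exon")) {
      if (pref %in% cls) return(pref)
    }
    if ("intronic" %in% cls && is.null(intronic_seen)) {
      tid <- ts[cls == "intronic"][1]
      d <- min(vapply(ts[cls == "intronic"], function(t) {
        ex <- exonChain(ann, t)
        min(abs(c(ex$start, ex$end) - pos))
      }, numeric(1)))
      intronic_seen <- d
    }
  }
  if (!is.null(intronic_seen)) {
    if (intronic_seen <= near_exon_bp) return("near_exon")
    return("intronic")
  }
  "intergenic"
}

# naive codon-table translation and stop scan (standard nuclear table,
# codons enumerated TTT, TTC, TTA, TTG, TCT, ...)
.ORACLE_CODONS <- {
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(0)
  for (x in b) for (y in b) for (z in b) {
    codons <- c(codons, paste0(x, y, z))
  }
  names(aa) <- codons
  aa
}

oracleTranslate <- function(seq) {
  n <- nchar(seq) %/% 3L
  vapply(seq_len(n), function(i) {
    cod <- substr(seq, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", cod)) "X" else .ORACLE_CODONS[[cod]]
  }, "")
}

# exhaustive microhomology: largest k with matching suffixes
oracleMicrohomology <- function(up5, up3) {
  best <- 0L
  for (k in seq_len(min(nchar(up5), nchar(up3)))) {
    if (substr(up5, nchar(up5) - k + 1L, nchar(up5)) ==
        substr(up3, nchar(up3) - k + 1L, nchar(up3))) {
      best <- k
    }
  }
  best
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
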