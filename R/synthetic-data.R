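# map a 1-based spliced (transcription-direction) coordinate to genomic
.txToGenomic <- function(ex, strand, tpos) {
  w <- ex$end - ex$start + 1L
  if (strand == "-") {
    ord <- rev(seq_len(nrow(ex)))
  } else {
    ord <- seq_len(nrow(ex))
  }
  off <- 0L
  for (i in ord) {
    if (tpos <= off + w[i]) {
      k <- tpos - off
      return(if (strand == "-") ex$end[i] - k + 1L else
        ex$start[i] + k - 1L)
    }
    off <- off + w[i]
  }
  NA_integer_
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate a genome annotation with sequences
#'
#' Seeded generator of a GENCODE-style annotation on two synthetic
#' chromosomes (chrA, chrB) plus a mitochondrial contig (chrM): per gene
#' 1-4 transcripts (the primary transcript MANE-tagged for most coding
#' genes), 1-8 exons, CDS/UTRs consistent with the exon chains (ATG
#' planted at each CDS start, TAA at each CDS end). Configurable
#' fractions of genes carry pseudogene biotype, ribosomal-protein names
#' (RPL/RPS) or HLA names, and two genes sit on chrM when `n_genes` is
#' large enough; these exercise the blacklist stages.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param frac_pseudo,frac_ribo,frac_hla fractions of special gene
#'   classes.
#' @return list with `gtf` (character lines), `fasta` (character lines),
#'   `annotation` (a [GenomeAnnotation-class] re-read from the generated
#'   GTF), and `gene_classes` (data.frame gene/class).
#' @export
simulateAnnotation <- function(n_genes, seed = 1L, frac_pseudo = 0.08,
                               frac_ribo = 0.06, frac_hla = 0.04) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  n_pseudo <- round(n_genes * frac_pseudo)
  n_ribo <- round(n_genes * frac_ribo)
  n_hla <- round(n_genes * frac_hla)
  n_mito <- if (n_genes >= 8) 2L else 0L
  n_norm <- n_genes - n_pseudo - n_ribo - n_hla - n_mito
  stopifnot(n_norm >= 1)
  classes <- c(rep("normal", n_norm), rep("pseudogene", n_pseudo),
               rep("ribosomal", n_ribo), rep("hla", n_hla),
               rep("mito", n_mito))
  names_by_class <- function(cl) {
    switch(cl,
           normal = sprintf("GENE%03d", seq_len(n_norm)),
           pseudogene = sprintf("PSDG%02d", seq_len(max(n_pseudo, 0))),
           ribosomal = sprintf("RPL%02d", seq_len(max(n_ribo, 0))),
           hla = sprintf("HLA-X%02d", seq_len(max(n_hla, 0))),
           mito = sprintf("MT-SIM%d", seq_len(max(n_mito, 0))))
  }
  gene_names <- unlist(lapply(unique(classes), names_by_class))
  gene_names <- gene_names[seq_len(n_genes)]
  # interleave classes deterministically across chromosomes
  perm <- sample(n_genes)
  gene_names <- gene_names[perm]
  classes <- classes[perm]

  cursor <- c(chrA = 1000L, chrB = 1000L, chrM = 200L)
  tx_rows <- list(); exon_list <- list(); gene_rows <- list()
  for (g in seq_len(n_genes)) {
    cl <- classes[g]
    chrom <- if (cl == "mito") "chrM" else
      if (g %% 2L == 0L) "chrB" else "chrA"
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample.int(8L, 1L)
    ex_len <- sample(150:600, n_ex, replace = TRUE)
    intron <- if (n_ex > 1L) sample(400:2000, n_ex - 1L,
                                    replace = TRUE) else integer(0)
    start <- cursor[chrom]
    s <- integer(n_ex); e <- integer(n_ex)
    pos <- start
    for (k in seq_len(n_ex)) {
      s[k] <- pos; e[k] <- pos + ex_len[k] - 1L
      pos <- e[k] + (if (k < n_ex) intron[k] else 0L) + 1L
    }
    backbone <- data.frame(start = s, end = e)
    cursor[chrom] <- max(e) + sample(2000:4000, 1L)

    gid <- sprintf("SIMG%04d", g)
    coding_gene <- !(cl == "pseudogene")
    biotype <- if (cl == "pseudogene") "processed_pseudogene" else
      "protein_coding"
    n_tx <- sample.int(min(4L, max(1L, n_ex)), 1L)
    for (t in seq_len(n_tx)) {
      tid <- sprintf("%s.T%d", gid, t)
      if (t == 1L || n_ex == 1L) {
        ex <- backbone
      } else {
        # drop internal exons or truncate, keeping a valid subchain
        if (n_ex > 2L && stats::runif(1) < 0.6) {
          keep <- sort(c(1L, n_ex,
                         sample(2:(n_ex - 1L),
                                sample.int(n_ex - 2L, 1L))))
          keep <- unique(keep)
        } else {
          keep <- seq_len(sample(2:n_ex, 1L))
        }
        ex <- backbone[keep, , drop = FALSE]
        rownames(ex) <- NULL
      }
      spl <- sum(ex$end - ex$start + 1L)
      is_coding <- coding_gene && spl >= 300L &&
        !(t > 1L && stats::runif(1) < 0.3)
      cds_start <- NA_integer_; cds_end <- NA_integer_
      if (is_coding) {
        utr5 <- sample(30:90, 1L)
        utr3 <- sample(30:90, 1L)
        cds_len <- ((spl - utr5 - utr3) %/% 3L) * 3L
        s1 <- utr5 + 1L
        s2 <- s1 + cds_len - 1L
        g1 <- .txToGenomic(ex, strand, s1)
        g2 <- .txToGenomic(ex, strand, s2)
        cds_start <- min(g1, g2); cds_end <- max(g1, g2)
      }
      is_mane <- coding_gene && t == 1L && is_coding &&
        stats::runif(1) < 0.85
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = chrom,
        strand = strand, tx_start = min(ex$start), tx_end = max(ex$end),
        is_mane = is_mane, is_protein_coding = is_coding,
        cds_start = cds_start, cds_end = cds_end, spliced_length = spl,
        stringsAsFactors = FALSE)
      exon_list[[tid]] <- ex
    }
    gene_rows[[g]] <- data.frame(gene_id = gid, gene_name = gene_names[g],
                                 chrom = chrom, strand = strand,
                                 biotype = biotype, class = cl,
                                 stringsAsFactors = FALSE)
  }
  transcripts <- do.call(rbind, tx_rows)
  gdf <- do.call(rbind, gene_rows)
  gs <- tapply(transcripts$tx_start, transcripts$gene_id, min)
  ge <- tapply(transcripts$tx_end, transcripts$gene_id, max)
  genes <- GenomicRanges::GRanges(
    seqnames = gdf$chrom,
    ranges = IRanges::IRanges(start = as.integer(gs[gdf$gene_id]),
                              end = as.integer(ge[gdf$gene_id])),
    strand = gdf$strand)
  S4Vectors::mcols(genes)$gene_id <- gdf$gene_id
  S4Vectors::mcols(genes)$gene_name <- gdf$gene_name
  S4Vectors::mcols(genes)$biotype <- gdf$biotype
  names(genes) <- gdf$gene_name
  ord <- order(gdf$gene_id)
  transcripts <- transcripts[order(transcripts$transcript_id), ,
                             drop = FALSE]
  rownames(transcripts) <- NULL
  ann0 <- new("GenomeAnnotation", genes = genes[ord],
              transcripts = transcripts, exons = exon_list)
  gtf <- writeAnnotation(ann0)

  # chromosome sequences with planted start/stop codons at CDS bounds
  chrom_len <- vapply(c("chrA", "chrB", "chrM"), function(ch) {
    i <- gdf$chrom == ch
    if (!any(i)) return(1000L)
    as.integer(max(ge[gdf$gene_id[i]]) + 500L)
  }, integer(1))
  seqs <- lapply(chrom_len, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  names(seqs) <- names(chrom_len)
  plant <- function(chrom, ex, strand, spos, codon) {
    for (k in 0:2) {
      gpos <- .txToGenomic(ex, strand, spos + k)
      base <- substr(codon, k + 1L, k + 1L)
      seqs[[chrom]][gpos] <<- if (strand == "-") .COMP[[base]] else base
    }
  }
  for (i in seq_len(nrow(transcripts))) {
    if (is.na(transcripts$cds_start[i])) next
    tid <- transcripts$transcript_id[i]
    ex <- exon_list[[tid]]
    st <- transcripts$strand[i]
    b <- .cdsTxBounds(ann0, tid)
    plant(transcripts$chrom[i], ex, st, b$start, "ATG")
    plant(transcripts$chrom[i], ex, st, b$end - 2L, "TAA")
  }
  fasta <- unlist(lapply(names(seqs), function(ch) {
    s <- paste(seqs[[ch]], collapse = "")
    c(paste0(">", ch),
      substring(s, seq(1L, nchar(s), 60L),
                pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s))))
  }))

  # round-trip through the reader so the generated GTF is validated
  tf <- tempfile(fileext = ".gtf")
  writeLines(gtf, tf)
  ann <- readAnnotation(tf)
  unlink(tf)
  list(gtf = gtf, fasta = fasta, annotation = ann,
       gene_classes = gdf[c("gene_id", "gene_name", "chrom", "strand",
                            "biotype", "class")])
}

# pick a CDS-internal breakpoint on the gene's tier transcript, at least
# `margin` bp (genomic) from both transcript ends; NA when impossible
.pickCdsBreakpoint <- function(ann, gene, margin = 300L) {
  tiers <- selectTranscriptTiers(ann, gene)
  tid <- if (!is.na(tiers$tier1)) tiers$tier1 else tiers$tier2
  if (is.na(tid)) return(NA_integer_)
  tx <- ann@transcripts
  i <- match(tid, tx$transcript_id)
  if (is.na(tx$cds_start[i])) return(NA_integer_)
  ex <- ann@exons[[tid]]
  lo <- max(tx$cds_start[i], tx$tx_start[i] + margin)
  hi <- min(tx$cds_end[i], tx$tx_end[i] - margin)
  if (lo > hi) return(NA_integer_)
  cand <- integer(0)
  for (k in seq_len(nrow(ex))) {
    s <- max(ex$start[k], lo); e <- min(ex$end[k], hi)
    if (s <= e) cand <- c(cand, s:e)
  }
  if (!length(cand)) return(NA_integer_)
  cand[sample.int(length(cand), 1L)]
}

#' Simulate multi-caller fusion call tables with ground truth
#'
#' Plants `n_true` true fusions between clean protein-coding genes (CDS
#' breakpoints, support >= 3, consistent strands) and emits each through
#' 1-3 callers with uniform breakpoint jitter of at most `jitter_bp`
#' (default 20, below half the 50 bp merge window so multi-caller
#' emissions always merge). A fraction of true fusions get a
#' lower-support reciprocal echo. Artifacts are planted per class so that
#' exactly one stage removes each: `low_support` (support < 3),
#' `blacklisted` (pseudogene/ribosomal/HLA partner), `no_cancer_gene`
#' (neither partner in panel/census), `strand_inconsistent` (reported
#' strands flipped), `control_shared` (pair in the healthy-tissue control
#' set), `unannotatable` (both breakpoints intergenic).
#'
#' @param sim result of [simulateAnnotation()].
#' @param n_true number of true fusions.
#' @param n_artifacts artifacts planted per artifact class.
#' @param jitter_bp maximal breakpoint jitter (<= 25).
#' @param n_samples number of tumor sample ids.
#' @param seed RNG seed.
#' @param reciprocal_frac fraction of true fusions with a reciprocal
#'   echo.
#' @return list with `caller_tables` (named list of three data.frames),
#'   `truth` (data.frame of planted fusions and artifacts), `resources`
#'   (list: panel_genes, census_genes, control_pairs).
#' @export
simulateFusionCalls <- function(sim, n_true = 10L, n_artifacts = 1L,
                                jitter_bp = 20L, n_samples = 4L,
                                seed = 1L, reciprocal_frac = 0.3) {
  stopifnot(jitter_bp <= 25L)
  set.seed(seed + 1000L)
  ann <- sim$annotation
  gc <- sim$gene_classes
  clean <- gc$gene_name[gc$class == "normal"]
  bad <- gc$gene_name[gc$class %in% c("pseudogene", "ribosomal", "hla")]
  # genes with usable CDS breakpoints
  bp_of <- vapply(clean, function(g) {
    p <- .pickCdsBreakpoint(ann, g)
    if (is.na(p)) NA_integer_ else p
  }, integer(1))
  usable <- clean[!is.na(bp_of)]
  samples <- sprintf("TUMOR%02d", seq_len(n_samples))
  callers <- c("LongGF", "JAFFAL", "FusionSeeker")

  # genes for the no-cancer-gene class are reserved up front and never
  # reused, so they stay out of the census and fail only the gene gate
  ncg_pool <- character(0)
  if (n_artifacts > 0L) {
    if (length(usable) < 2L * n_artifacts + 4L) {
      stop("not enough usable genes; increase n_genes")
    }
    ncg_pool <- sample(usable, 2L * n_artifacts)
    usable <- setdiff(usable, ncg_pool)
    if (length(bad) == 0L) {
      stop("annotation has no blacklist-class genes; increase n_genes ",
           "or the special-gene fractions")
    }
  }
  need_pairs <- n_true + n_artifacts * 5L
  if (length(usable) < 2L ||
      need_pairs > choose(length(usable), 2L)) {
    stop("not enough usable genes for ", need_pairs,
         " distinct fusion pairs; increase n_genes")
  }

  # fusion pairs are globally unique and gene-disjoint within a sample,
  # so per-gene breakpoints and planted isoform truncations never leak
  # between co-sampled fusions
  seen_pairs <- character(0)
  used_in_sample <- stats::setNames(
    replicate(n_samples, character(0), simplify = FALSE), samples)
  draw_genes <- function(smp, pool, n = 2L) {
    for (attempt in 1:500) {
      avail <- setdiff(pool, used_in_sample[[smp]])
      if (length(avail) < n) break
      p <- sample(avail, n)
      key <- paste(sort(p), collapse = "::")
      if (n == 2L && key %in% seen_pairs) next
      if (n == 2L) seen_pairs <<- c(seen_pairs, key)
      used_in_sample[[smp]] <<- c(used_in_sample[[smp]], p)
      return(p)
    }
    stop("could not draw a distinct within-sample fusion pair; ",
         "increase n_genes or n_samples")
  }
  # two-choice balancing keeps any one sample from exhausting the pool
  pick_sample <- function() {
    cand <- sample(samples, min(2L, n_samples))
    load <- vapply(used_in_sample[cand], length, 1L)
    cand[which.min(load)]
  }

  truth <- list(); emissions <- list()
  emit <- function(sample_id, g5, g3, bp5, bp3, strand5, strand3,
                   support, caller, jitter = TRUE) {
    support <- max(1L, support)
    j5 <- if (jitter) sample(-jitter_bp:jitter_bp, 1L) else 0L
    j3 <- if (jitter) sample(-jitter_bp:jitter_bp, 1L) else 0L
    emissions[[length(emissions) + 1L]] <<- data.frame(
      caller = caller, sample_id = sample_id, gene5 = g5,
      chrom5 = as.character(GenomicRanges::seqnames(
        ann@genes))[.geneIndex(ann, g5)],
      pos5 = bp5 + j5, strand5 = strand5, gene3 = g3,
      chrom3 = as.character(GenomicRanges::seqnames(
        ann@genes))[.geneIndex(ann, g3)],
      pos3 = bp3 + j3, strand3 = strand3, support = support,
      stringsAsFactors = FALSE)
  }

  plant <- function(pair, class, sample_id, support_rng,
                    flip_strand = FALSE, intergenic = FALSE,
                    echo = FALSE) {
    g5 <- pair[1]; g3 <- pair[2]
    if (intergenic) {
      bp5 <- GenomicRanges::end(ann@genes)[.geneIndex(ann, g5)] + 5000L
      bp3 <- GenomicRanges::end(ann@genes)[.geneIndex(ann, g3)] + 5000L
    } else {
      bp5 <- bp_of[[g5]]; bp3 <- bp_of[[g3]]
    }
    s5 <- geneStrand(ann, g5); s3 <- geneStrand(ann, g3)
    if (flip_strand) {
      s5 <- if (s5 == "+") "-" else "+"
      s3 <- if (s3 == "+") "-" else "+"
    }
    support <- sample(support_rng, 1L)
    use <- sample(callers, sample.int(3L, 1L))
    for (ca in use) {
      # per-emission variation clamped inside the class's support range,
      # so each artifact class keeps its defining property
      sup_e <- support + sample(-1:1, 1L) * as.integer(length(use) > 1L)
      sup_e <- min(max(sup_e, min(support_rng)), max(support_rng))
      emit(sample_id, g5, g3, bp5, bp3, s5, s3, sup_e, ca)
    }
    echo_support <- NA_integer_
    if (echo) {
      echo_support <- max(1L, support - sample(1:2, 1L))
      emit(sample_id, g3, g5, bp3, bp5, s3, s5, echo_support,
           sample(callers, 1L))
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      class = class, sample_id = sample_id, gene5 = g5, gene3 = g3,
      bp5 = bp5, bp3 = bp3, support = support, n_callers = length(use),
      echo_support = echo_support, stringsAsFactors = FALSE)
  }

  for (k in seq_len(n_true)) {
    smp <- pick_sample()
    plant(draw_genes(smp, usable), "true", smp, 3:12,
          echo = stats::runif(1) < reciprocal_frac)
  }
  for (k in seq_len(n_artifacts)) {
    smp <- pick_sample()
    plant(draw_genes(smp, usable), "low_support", smp, 1:2)
    smp <- pick_sample()
    plant(draw_genes(smp, usable), "control_shared", smp, 3:8)
    smp <- pick_sample()
    plant(draw_genes(smp, usable), "unannotatable", smp, 3:8,
          intergenic = TRUE)
    smp <- pick_sample()
    plant(draw_genes(smp, ncg_pool), "no_cancer_gene", smp, 3:8)
    smp <- pick_sample()
    plant(draw_genes(smp, usable), "strand_inconsistent", smp, 3:8,
          flip_strand = TRUE)
    # blacklisted: swap one partner for a blacklist gene
    g_bad <- sample(bad, 1L)
    gsp <- GenomicRanges::start(ann@genes)[.geneIndex(ann, g_bad)]
    gse <- GenomicRanges::end(ann@genes)[.geneIndex(ann, g_bad)]
    bpb <- as.integer((gsp + gse) / 2)
    smp <- pick_sample()
    g_ok <- draw_genes(smp, usable, n = 1L)
    sup <- sample(3:8, 1L)
    emit(smp, g_ok, g_bad, bp_of[[g_ok]], bpb, geneStrand(ann, g_ok),
         geneStrand(ann, g_bad), sup, sample(callers, 1L))
    truth[[length(truth) + 1L]] <- data.frame(
      class = "blacklisted", sample_id = smp, gene5 = g_ok,
      gene3 = g_bad, bp5 = bp_of[[g_ok]], bp3 = bpb, support = sup,
      n_callers = 1L, echo_support = NA_integer_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  em <- do.call(rbind, emissions)
  caller_tables <- lapply(callers, function(ca) {
    d <- em[em$caller == ca, setdiff(names(em), "caller"), drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(caller_tables) <- callers

  # resources: census covers every planted gene except the
  # no-cancer-gene pairs; panel a subset of true-fusion genes
  ncg <- truth[truth$class == "no_cancer_gene", ]
  ncg_genes <- unique(c(ncg$gene5, ncg$gene3))
  involved <- unique(c(truth$gene5, truth$gene3))
  census <- setdiff(involved, union(ncg_genes, bad))
  true_genes <- unique(c(truth$gene5[truth$class == "true"],
                         truth$gene3[truth$class == "true"]))
  panel <- sort(sample(true_genes, max(1L, length(true_genes) %/% 4L)))
  ctrl <- truth[truth$class == "control_shared", ]
  control_pairs <- unique(controlPairKeys(ctrl$gene5, ctrl$gene3))
  list(caller_tables = caller_tables, truth = truth,
       resources = list(panel_genes = panel, census_genes = sort(census),
                        control_pairs = control_pairs))
}

#' Simulate isoform structures, counts and DE tables with ground truth
#'
#' Generates known isoforms (from the annotation) plus planted novel
#' isoform clusters (well separated: inter-cluster boundary distance
#' > 2 x `tol`; intra-cluster jitter <= `tol`/3), fusion-like truncated
#' isoforms for a subset of the true fusions (5'-gene isoforms ending
#' near bp5 and 3'-gene isoforms starting near bp3 in the fusion's
#' sample; a further subset gets only the 5' truncation as a negative
#' control), negative-binomial counts with planted differential
#' expression, and two DE result tables with controlled agreement strata
#' (both-significant concordant, one-only, discordant).
#'
#' @param sim result of [simulateAnnotation()].
#' @param truth truth data.frame from [simulateFusionCalls()].
#' @param n_samples_per_group samples per group (glioma uses the fusion
#'   sample ids padded to this size; controls are CTRLxx).
#' @param seed RNG seed.
#' @param tol structural tolerance the clusters are built against.
#' @param n_cluster_genes genes receiving planted novel clusters.
#' @return list with `isoforms` (record data.frame), `counts` (matrix),
#'   `lengths` (effective lengths), `group_labels`, `de_a`, `de_b`
#'   (result tables), `iso_truth` (cluster labels), `de_truth` (strata),
#'   `fusionlike_truth` (per planted fusion: fusion_like flag).
#' @export
simulateIsoformFixtures <- function(sim, truth, n_samples_per_group = 6L,
                                    seed = 1L, tol = 100L,
                                    n_cluster_genes = 4L) {
  set.seed(seed + 2000L)
  ann <- sim$annotation
  gc <- sim$gene_classes
  tumor <- unique(truth$sample_id)
  extra <- max(0L, n_samples_per_group - length(tumor))
  tumor <- c(tumor, sprintf("TUMORX%02d", seq_len(extra)))[
    seq_len(max(n_samples_per_group, length(tumor)))]
  ctrl <- sprintf("CTRL%02d", seq_len(n_samples_per_group))

  fusion_genes <- unique(c(truth$gene5, truth$gene3))
  cand <- setdiff(gc$gene_name[gc$class == "normal"], fusion_genes)
  tx <- ann@transcripts
  gm <- S4Vectors::mcols(ann@genes)

  records <- list(); iso_truth <- list()
  add_rec <- function(id, gene, sample_id, strand, novelty, ex) {
    records[[length(records) + 1L]] <<- data.frame(
      isoform_id = id, gene = gene, sample_id = sample_id,
      strand = strand, novelty = novelty, exons = formatExonChain(ex),
      stringsAsFactors = FALSE)
  }

  # known isoforms: every annotated transcript of protein-coding,
  # non-mitochondrial genes, listed once (pooled across samples)
  keep_g <- gc$gene_name[gc$biotype == "protein_coding" &
                           gc$chrom != "chrM"]
  for (g in keep_g) {
    gid <- .resolveGene(ann, g)
    for (tid in tx$transcript_id[tx$gene_id == gid]) {
      add_rec(tid, g, "POOLED", geneStrand(ann, g), "known",
              exonChain(ann, tid))
    }
  }

  # planted novel clusters on genes uninvolved in fusions
  cl_genes <- sample(cand, min(n_cluster_genes, length(cand)))
  cl_id <- 0L
  for (g in cl_genes) {
    gid <- .resolveGene(ann, g)
    base_tid <- tx$transcript_id[tx$gene_id == gid][1]
    base <- exonChain(ann, base_tid)
    strand <- geneStrand(ann, g)
    n_cl <- sample(1:3, 1L)
    for (c0 in seq_len(n_cl)) {
      cl_id <- cl_id + 1L
      shift <- (c0 - 1L) * (2L * tol + 150L)  # separation > 2*tol
      n_mem <- sample(3:6, 1L)
      for (m in seq_len(n_mem)) {
        jit <- sample(-(tol %/% 3L):(tol %/% 3L), 2L * nrow(base),
                      replace = TRUE)
        ex <- base
        ex$start <- ex$start + shift +
          jit[seq_len(nrow(base)) * 2L - 1L]
        ex$end <- ex$end + shift + jit[seq_len(nrow(base)) * 2L]
        ex$end <- pmax(ex$end, ex$start + 20L)
        id <- sprintf("NOV_%s_c%d_m%d", g, cl_id, m)
        add_rec(id, g, sample(tumor, 1L), strand,
                sample(c("NIC", "NNIC"), 1L), ex)
        iso_truth[[length(iso_truth) + 1L]] <- data.frame(
          isoform_id = id, gene = g, cluster = cl_id,
          stringsAsFactors = FALSE)
      }
    }
  }

  # fusion-like truncations at planted breakpoints
  tr <- truth[truth$class == "true", , drop = FALSE]
  fl <- list()
  if (nrow(tr)) {
    n_fl <- max(1L, nrow(tr) %/% 2L)
    pick <- seq_len(nrow(tr)) <= n_fl  # deterministic subset
    neg5only <- rep(FALSE, nrow(tr))
    if (sum(!pick) > 0L) neg5only[which(!pick)[1]] <- TRUE
    trunc_chain <- function(g, bp, side) {
      gid <- .resolveGene(ann, g)
      tiers <- selectTranscriptTiers(ann, g)
      tid <- if (!is.na(tiers$tier1)) tiers$tier1 else tiers$tier2
      ex <- exonChain(ann, tid)
      strand <- geneStrand(ann, g)
      # side "end": isoform terminates at bp (5' partner, premature
      # termination); side "start": isoform initiates at bp (3' partner)
      if ((side == "end") == (strand == "+")) {
        keep <- ex$start <= bp
        ex <- ex[keep, , drop = FALSE]
        ex$end[nrow(ex)] <- bp
      } else {
        keep <- ex$end >= bp
        ex <- ex[keep, , drop = FALSE]
        ex$start[1L] <- bp
      }
      ex
    }
    for (i in seq_len(nrow(tr))) {
      if (!pick[i] && !neg5only[i]) next
      g5 <- tr$gene5[i]; g3 <- tr$gene3[i]
      id5 <- sprintf("TRUNC5_%s_%d", g5, i)
      add_rec(id5, g5, tr$sample_id[i], geneStrand(ann, g5), "NIC",
              trunc_chain(g5, tr$bp5[i], "end"))
      if (pick[i]) {
        id3 <- sprintf("TRUNC3_%s_%d", g3, i)
        add_rec(id3, g3, tr$sample_id[i], geneStrand(ann, g3), "NNIC",
                trunc_chain(g3, tr$bp3[i], "start"))
      }
      fl[[length(fl) + 1L]] <- data.frame(
        sample_id = tr$sample_id[i], gene5 = g5, gene3 = g3,
        fusion_like = pick[i], stringsAsFactors = FALSE)
    }
  }
  isoforms <- do.call(rbind, records)

  # counts with planted DE on known isoforms
  ids <- isoforms$isoform_id[isoforms$novelty == "known"]
  ids <- unique(ids)
  n_iso <- length(ids)
  samples <- c(tumor, ctrl)
  groups <- c(rep("glioma", length(tumor)), rep("control", length(ctrl)))
  mu <- exp(stats::rnorm(n_iso, log(60), 1))
  n_de <- max(2L, n_iso %/% 10L)
  de_idx <- sample.int(n_iso, n_de)
  de_sign <- sample(c(1, -1), n_de, replace = TRUE)
  lfc_true <- numeric(n_iso)
  lfc_true[de_idx] <- de_sign * stats::runif(n_de, 1.8, 3)
  counts <- matrix(0L, n_iso, length(samples),
                   dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    m <- mu * ifelse(groups[j] == "glioma", 2^lfc_true, 1)
    counts[, j] <- stats::rnbinom(n_iso, mu = m, size = 10)
  }
  lens <- vapply(ids, function(id) {
    i <- match(id, tx$transcript_id)
    if (!is.na(i)) tx$spliced_length[i] else 1000L
  }, integer(1))

  # DE result tables with controlled agreement strata
  strata <- rep("null", n_iso)
  strata[de_idx] <- "both_sig"
  non_de <- setdiff(seq_len(n_iso), de_idx)
  n_extra <- min(length(non_de) %/% 4L, 5L)
  one_only <- non_de[seq_len(n_extra)]
  discord <- non_de[n_extra + seq_len(n_extra)]
  strata[one_only] <- "one_only"
  strata[discord] <- "discordant"
  mk_de <- function(which_tab) {
    lfc <- stats::rnorm(n_iso, 0, 0.3)
    fdr <- stats::runif(n_iso, 0.1, 1)
    b <- strata == "both_sig"
    lfc[b] <- lfc_true[b] + stats::rnorm(sum(b), 0, 0.1)
    fdr[b] <- stats::runif(sum(b), 0, 0.01)
    o <- strata == "one_only"
    if (which_tab == "a") {
      lfc[o] <- 2 + stats::rnorm(sum(o), 0, 0.1)
      fdr[o] <- stats::runif(sum(o), 0, 0.01)
    }
    d <- strata == "discordant"
    lfc[d] <- (if (which_tab == "a") 2 else -2) +
      stats::rnorm(sum(d), 0, 0.1)
    fdr[d] <- stats::runif(sum(d), 0, 0.01)
    data.frame(isoform_id = ids, log2_fc = lfc, fdr = fdr,
               method = if (which_tab == "a") "edgeR" else "DESeq2",
               stringsAsFactors = FALSE)
  }
  list(isoforms = isoforms, counts = counts, lengths = lens,
       group_labels = groups,
       de_a = mk_de("a"), de_b = mk_de("b"),
       iso_truth = if (length(iso_truth)) do.call(rbind, iso_truth) else
         data.frame(isoform_id = character(), gene = character(),
                    cluster = integer()),
       de_truth = data.frame(isoform_id = ids, stratum = strata,
                             lfc_true = lfc_true,
                             stringsAsFactors = FALSE),
       fusionlike_truth = if (length(fl)) do.call(rbind, fl) else
         data.frame(sample_id = character(), gene5 = character(),
                    gene3 = character(), fusion_like = logical()))
}
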