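test_that("classification walks the tiers and records the tier used", {
  ann <- toyAnnotation()
  # inside the MANE CDS
  r <- classifyBreakpoint(ann, "ALPHA", 350L)
  expect_equal(r$region_class, "CDS")
  expect_equal(r$tier_used, "MANE")
  expect_equal(r$transcript_id, "T1")
  # ALPHA 450: intronic in T1 (intron 401-500) but exonic (CDS) in T2
  r2 <- classifyBreakpoint(ann, "ALPHA", 550L)
  expect_equal(r2$region_class, "CDS")  # in both; MANE resolves first
  r3 <- classifyBreakpoint(ann, "ALPHA", 450L)
  expect_equal(r3$region_class, "intronic")  # intronic in both tiers
  # DELTA 5300: intronic in D1 (no MANE tier), outside D2
  r4 <- classifyBreakpoint(ann, "DELTA", 5300L)
  expect_equal(r4$region_class, "intronic")
  expect_equal(r4$tier_used, "longest_coding")
  # UTRs by strand: ALPHA(+) 120 is 5' UTR; BETA(-) 1020 is 3' UTR
  expect_equal(classifyBreakpoint(ann, "ALPHA", 120L)$region_class,
               "UTR5")
  expect_equal(classifyBreakpoint(ann, "ALPHA", 600L)$region_class,
               "UTR3")
  expect_equal(classifyBreakpoint(ann, "BETA", 1020L)$region_class,
               "UTR3")
  expect_equal(classifyBreakpoint(ann, "BETA", 1480L)$region_class,
               "UTR5")
  # non-coding exon, intergenic, unannotated
  expect_equal(classifyBreakpoint(ann, "GAMMA", 2100L)$region_class,
               "noncoding_exon")
  ig <- classifyBreakpoint(ann, "ALPHA", 12000L)
  expect_equal(ig$region_class, "intergenic")
  expect_equal(ig$tier_used, "none")
  un <- classifyBreakpoint(ann, "NOSUCH", 100L)
  expect_equal(un$region_class, "unannotated")
  expect_equal(un$tier_used, "none")
})

test_that("a breakpoint intronic in MANE but exonic in a lower tier is
           reclassified with that tier", {
  # MANE skips the middle exon; the longest coding transcript keeps it
  tf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tt\tgene\t100\t1000\t.\t+\t.\t",
           'gene_id "GX"; gene_name "XG"; gene_type "protein_coding";'),
    paste0("chr1\tt\ttranscript\t100\t1000\t.\t+\t.\t",
           'gene_id "GX"; transcript_id "XM"; ',
           'transcript_type "protein_coding"; tag "MANE_Select";'),
    sprintf(paste0("chr1\tt\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "GX"; transcript_id "XM";'),
            c(100L, 800L), c(200L, 1000L)),
    sprintf(paste0("chr1\tt\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "GX"; transcript_id "XM";'),
            c(150L, 800L), c(200L, 950L)),
    paste0("chr1\tt\ttranscript\t100\t1000\t.\t+\t.\t",
           'gene_id "GX"; transcript_id "XL"; ',
           'transcript_type "protein_coding";'),
    sprintf(paste0("chr1\tt\texon\t%d\t%d\t.\t+\t.\t",
                   'gene_id "GX"; transcript_id "XL";'),
            c(100L, 450L, 800L), c(200L, 550L, 1000L)),
    sprintf(paste0("chr1\tt\tCDS\t%d\t%d\t.\t+\t0\t",
                   'gene_id "GX"; transcript_id "XL";'),
            c(150L, 450L, 800L), c(200L, 550L, 950L))), tf)
  ann <- readAnnotation(tf)
  r <- classifyBreakpoint(ann, "XG", 500L)
  expect_equal(r$region_class, "CDS")
  expect_equal(r$tier_used, "longest_coding")
  expect_equal(r$transcript_id, "XL")
  unlink(tf)
})

test_that("near-exon reclassification is bounded, intronic-only and
           idempotent", {
  mk <- function(cls, d) list(region_class = cls, tier_used = "MANE",
                              distance_to_boundary = d,
                              transcript_id = "T1")
  expect_equal(reclassifyNearExon(mk("intronic", 150L))$region_class,
               "near_exon")
  expect_equal(reclassifyNearExon(mk("intronic", 200L))$region_class,
               "near_exon")
  expect_equal(reclassifyNearExon(mk("intronic", 201L))$region_class,
               "intronic")
  for (cls in c("CDS", "UTR5", "UTR3", "noncoding_exon", "near_exon",
                "intergenic")) {
    expect_equal(reclassifyNearExon(mk(cls, 10L))$region_class, cls)
  }
  # idempotence
  once <- reclassifyNearExon(mk("intronic", 50L))
  expect_equal(reclassifyNearExon(once), once)
})

test_that("classification matches the interval-membership oracle over a
           scanned window", {
  ann <- toyAnnotation()
  for (gene in c("ALPHA", "BETA", "GAMMA", "DELTA")) {
    gr <- geneRanges(ann)[gene]
    from <- GenomicRanges::start(gr) - 300L
    to <- GenomicRanges::end(gr) + 300L
    for (pos in seq(from, to, by = 7L)) {
      got <- reclassifyNearExon(classifyBreakpoint(ann, gene, pos))
      expect_equal(got$region_class, oracleClassify(ann, gene, pos),
                   info = paste(gene, pos))
    }
  }
})

test_that("functional flags and the uninformative-breakpoint drop", {
  ann <- toyAnnotation()
  df <- rbind(
    mkCall(pos5 = 350L, pos3 = 1480L),  # CDS / UTR5
    mkCall(pos5 = 350L, pos3 = 1350L),  # CDS / CDS
    mkCall(pos5 = 50L, pos3 = 900L))    # intergenic / intergenic
  af <- annotateFusions(FusionCallSet(df), ann)
  expect_equal(af$functional_any, c(TRUE, TRUE, FALSE))
  expect_equal(af$functional_both, c(FALSE, TRUE, FALSE))
  expect_true(all(af$functional_both <= af$functional_any))
  kept <- dropUnannotatable(af)
  expect_equal(nrow(kept), 2L)
  # one informative breakpoint is enough to survive
  one <- annotateFusions(
    FusionCallSet(mkCall(pos5 = 50L, pos3 = 1480L)), ann)
  expect_equal(one$class5, "intergenic")
  expect_equal(one$class3, "UTR5")
  expect_equal(nrow(dropUnannotatable(one)), 1L)
  # intronic within 200 bp of a boundary counts as exonic (near-exon)
  ne <- annotateFusions(
    FusionCallSet(mkCall(pos5 = 450L, pos3 = 1480L)), ann)
  expect_equal(ne$class5, "near_exon")
  expect_true(ne$functional_any)
})

test_that("breakpoint class summaries report per-role fractions", {
  ann <- toyAnnotation()
  df <- rbind(mkCall(pos5 = 350L, pos3 = 1020L),   # CDS / UTR3
              mkCall(pos5 = 600L, pos3 = 1350L))   # UTR3 / CDS
  s <- summarizeBreakpointClasses(annotateFusions(FusionCallSet(df),
                                                  ann))
  c5 <- s$classes[s$classes$role == "5prime", ]
  expect_equal(c5$fraction[c5$class == "CDS/near_exon"], 0.5)
  expect_equal(c5$fraction[c5$class == "UTR3"], 0.5)
  expect_equal(sum(c5$fraction), 1)
  t5 <- s$tiers[s$tiers$role == "5prime", ]
  expect_equal(t5$fraction[t5$tier == "MANE"], 1)
  empty <- summarizeBreakpointClasses(
    annotateFusions(FusionCallSet(), ann))
  expect_equal(nrow(empty$classes), 0L)
})
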