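test_that("spliced transcript sequences come out 5' to 3'", {
  fx <- constructFixture()
  expect_equal(transcriptSequence(fx$ann, fx$seqs, "F5T"), fx$spliced5)
  expect_equal(transcriptSequence(fx$ann, fx$seqs, "F3T"), fx$spliced3)
})

test_that("reference transcript selection prioritizes CDS/near-exon and
           errors outside every transcript", {
  ann <- toyAnnotation()
  expect_equal(selectReferenceTranscript(ann, "ALPHA", 350L), "T1")
  # intronic within 200 bp of a boundary still selects the transcript
  expect_equal(selectReferenceTranscript(ann, "DELTA", 5300L), "D1")
  expect_error(selectReferenceTranscript(ann, "ALPHA", 12000L),
               "selection error")
})

test_that("breakpoints at exon boundaries concatenate whole exon
           blocks", {
  fx <- constructFixture()
  # bp5 at the end of FIVE exon 1 (160); bp3 at the start of THREE
  # exon 2 (501)
  con <- assembleFusionCdna(mkFusion(160L, 501L), "F5T", "F3T", fx$ann,
                            fx$seqs)
  expect_equal(con$junction_offset, 50L)  # CDS start 11 .. spliced 60
  expect_equal(con$cdna, paste0(substr(fx$spliced5, 11, 60),
                                substr(fx$spliced3, 61, 160)))
  # the 5' prefix and 3' suffix are exact substrings of the spliced
  # references
  expect_true(grepl(substr(con$cdna, 1, con$junction_offset),
                    fx$spliced5, fixed = TRUE))
  expect_true(grepl(substr(con$cdna, con$junction_offset + 1,
                           nchar(con$cdna)), fx$spliced3, fixed = TRUE))
})

test_that("a mid-exon 5' breakpoint ends the 5' segment exactly there", {
  fx <- constructFixture()
  # genomic 202 = spliced position 62 on FIVE
  con <- assembleFusionCdna(mkFusion(202L, 501L), "F5T", "F3T", fx$ann,
                            fx$seqs)
  expect_equal(con$junction_offset, 52L)
  expect_equal(substr(con$cdna, 1, 52), substr(fx$spliced5, 11, 62))
})

test_that("frame status follows the codon phase of the 3' moiety", {
  fx <- constructFixture()
  # jo = 52 matches the 3' phase at spliced 61 ((61-21) mod 3 == 1)
  inf <- orfAnalysis(assembleFusionCdna(mkFusion(202L, 501L), "F5T",
                                        "F3T", fx$ann, fx$seqs))
  expect_equal(inf$frame_status, "in_frame")
  expect_true(is.na(inf$premature_stop_pos))
  expect_equal(nchar(inf$orf_protein), 43L)
  # one more 5' base shifts the phase and trips an early TGA
  oof <- orfAnalysis(assembleFusionCdna(mkFusion(203L, 501L), "F5T",
                                        "F3T", fx$ann, fx$seqs))
  expect_equal(oof$frame_status, "out_of_frame")
  expect_equal(oof$premature_stop_pos, 19L)
  expect_equal(nchar(oof$orf_protein), 18L)
  # both agree with the naive codon-scan oracle
  for (con in list(inf, oof)) {
    aa <- oracleTranslate(con$cdna)
    stop1 <- which(aa == "*")[1]
    if (is.na(stop1)) {
      expect_equal(nchar(con$orf_protein), length(aa))
    } else {
      expect_equal(con$orf_protein,
                   paste(aa[seq_len(stop1 - 1L)], collapse = ""))
    }
  }
})

test_that("a stop codon exactly at the junction truncates the ORF to the
           5' moiety", {
  fx <- constructFixture()
  # bp5 at spliced 61 (genomic 201) gives a 51 nt 5' segment (17
  # codons); bp3 at genomic 578 starts the 3' segment on THREE's stop
  con <- orfAnalysis(assembleFusionCdna(mkFusion(201L, 578L), "F5T",
                                        "F3T", fx$ann, fx$seqs))
  expect_equal(con$junction_offset, 51L)
  expect_equal(nchar(con$orf_protein), 17L)
  # that stop is THREE's natural stop, not a premature one
  expect_true(is.na(con$premature_stop_pos))
  aa <- oracleTranslate(con$cdna)
  expect_equal(which(aa == "*")[1], 18L)
})

test_that("the 5'-UTR rule uses the entire 5' CDS", {
  fx <- constructFixture()
  # genomic 105 is spliced position 5, inside FIVE's 5' UTR
  con <- designFusionConstruct(mkFusion(105L, 501L), fx$ann, fx$seqs)
  expect_true(con$utr_rule)
  expect_equal(con$junction_offset, 117L)  # CDS minus stop codon
  expect_equal(substr(con$cdna, 1, 117), substr(fx$spliced5, 11, 127))
  expect_equal(con$frame_status, "out_of_frame_5UTR_rule")
  # a CDS breakpoint must not take the UTR path
  expect_error(apply5utrRule(mkFusion(202L, 501L), "F5T", "F3T",
                             fx$ann, fx$seqs), "precondition")
  # a 3' breakpoint at the transcript start appends the whole 3'
  # transcript
  full <- apply5utrRule(mkFusion(105L, 401L), "F5T", "F3T", fx$ann,
                        fx$seqs)
  expect_equal(substr(full$cdna, 118, nchar(full$cdna)), fx$spliced3)
})

test_that("junction microhomology finds bases assignable to either
           gene", {
  fx <- constructFixture()
  # 5' segment ending at spliced 62 finishes with GCTGCTG, identical to
  # the 7 bases of THREE immediately upstream of its CDS start
  con <- junctionMicrohomology(
    assembleFusionCdna(mkFusion(202L, 421L), "F5T", "F3T", fx$ann,
                       fx$seqs))
  expect_equal(con$microhomology_len, 7L)
  # no-homology and full-homology corner cases on raw flanks
  expect_equal(microhomologyLength("AAAC", "AAAG"), 0L)
  expect_equal(microhomologyLength(strrep("A", 20), strrep("A", 20)),
               20L)
  # agreement with the exhaustive-k oracle on random flanks
  set.seed(13)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:20, 1),
                      replace = TRUE), collapse = "")
    if (i %% 3 == 0) {  # force shared suffixes sometimes
      k <- sample(1:5, 1)
      b <- paste0(substr(b, 1, nchar(b) - k),
                  substr(a, nchar(a) - k + 1, nchar(a)))
    }
    expect_equal(microhomologyLength(a, b), oracleMicrohomology(a, b))
  }
  # strand handling: suffix homology equals prefix homology after
  # simultaneous reverse-complement of both flanks
  prefix_match <- function(a, b) {
    k <- 0L
    while (k < min(nchar(a), nchar(b)) &&
           substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
      k <- k + 1L
    }
    k
  }
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
               collapse = "")
    b <- paste0(paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                      collapse = ""), substr(a, 9, 12))
    expect_equal(microhomologyLength(a, b),
                 prefix_match(revcomp(a), revcomp(b)))
  }
})

test_that("ORF length never exceeds the construct and deep-intronic
           breakpoints fail assembly", {
  fx <- constructFixture()
  con <- designFusionConstruct(mkFusion(202L, 501L), fx$ann, fx$seqs)
  expect_lte(nchar(con$orf_protein) * 3, nchar(con$cdna))
  expect_error(
    assembleFusionCdna(mkFusion(202L, 490L), "F5T", "F3T", fx$ann,
                       fx$seqs, params = fusionParams(near_exon_bp = 5L)),
    "assembly error")
})
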