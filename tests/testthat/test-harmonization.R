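test_that("normalization enforces the call schema and support values", {
  raw <- mkCall()
  cs <- normalizeCalls(raw, "LongGF")
  expect_equal(length(cs), 1L)
  expect_equal(fusionCalls(cs)$callers, "LongGF")
  # column mapping for caller dialects
  dial <- raw
  names(dial)[names(dial) == "support"] <- "nreads"
  cs2 <- normalizeCalls(dial, "JAFFAL",
                        col_map = c(support = "nreads"))
  expect_equal(fusionCalls(cs2)$support, 5L)
  expect_error(normalizeCalls(raw[, -1], "LongGF"), "schema error")
  bad <- raw; bad$support <- 0L
  expect_error(normalizeCalls(bad, "LongGF"), "support below 1")
  bad$support <- "abc"
  expect_error(normalizeCalls(bad, "LongGF"), "non-integer")
  # two identical rows stay two calls: dedup is a separate step
  expect_equal(length(normalizeCalls(rbind(raw, raw), "LongGF")), 2L)
})

test_that("exact dedup collapses within one caller only", {
  a <- mkCall(callers = "LongGF")
  cs <- mkCallSet(a, a)
  expect_equal(length(dedupExact(cs)), 1L)
  # identical coordinates from different callers survive exact dedup
  cs2 <- mkCallSet(mkCall(callers = "LongGF"), mkCall(callers = "JAFFAL"))
  expect_equal(length(dedupExact(cs2)), 2L)
  expect_equal(length(dedupExact(FusionCallSet())), 0L)
})

test_that("window dedup merges within 50 bp on both partners", {
  base <- mkCall(callers = "LongGF")
  near <- mkCall(pos5 = 380L, pos3 = 1360L, callers = "JAFFAL")
  far3 <- mkCall(pos5 = 380L, pos3 = 1411L, callers = "FusionSeeker")
  m <- dedupWindow(mkCallSet(base, near))
  expect_equal(length(m), 1L)
  expect_equal(fusionCalls(m)$callers, "JAFFAL;LongGF")
  # one partner beyond the window: no merge
  expect_equal(length(dedupWindow(mkCallSet(base, far3))), 2L)
})

test_that("merged representatives carry max support and its coordinates", {
  calls <- mkCallSet(
    mkCall(pos5 = 350L, pos3 = 1350L, support = 3L, callers = "LongGF"),
    mkCall(pos5 = 360L, pos3 = 1340L, support = 9L, callers = "JAFFAL"),
    mkCall(pos5 = 340L, pos3 = 1355L, support = 5L,
           callers = "FusionSeeker"))
  m <- fusionCalls(dedupWindow(calls))
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 9L)
  expect_equal(m$pos5, 360L)
  expect_equal(sort(strsplit(m$callers, ";")[[1]]),
               c("FusionSeeker", "JAFFAL", "LongGF"))
})

test_that("window dedup matches the brute-force single-linkage oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    pos5 <- 1000L + sample(0:160, n, replace = TRUE)
    pos3 <- 5000L + sample(0:160, n, replace = TRUE)
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      mkCall(pos5 = pos5[i], pos3 = pos3[i],
             support = sample(1:10, 1),
             callers = sample(c("LongGF", "JAFFAL", "FusionSeeker"), 1))
    }))
    got <- dedupWindow(FusionCallSet(df))
    comp <- oracleSingleLinkage(pos5, pos3, 50L)
    expect_equal(length(got), length(unique(comp)))
    # every representative's support equals the max over its component
    gm <- fusionCalls(got)
    for (cc in unique(comp)) {
      mem <- which(comp == cc)
      expect_true(max(df$support[mem]) %in% gm$support)
    }
  }
  # spec worked example: 5 jittered emissions across 3 callers merge to
  # one call with a 3-caller provenance set
  set.seed(7)
  emits <- do.call(rbind, lapply(1:5, function(i) {
    mkCall(pos5 = 350L + sample(-25:25, 1), pos3 = 1350L +
             sample(-25:25, 1),
           callers = c("LongGF", "JAFFAL", "FusionSeeker",
                       "LongGF", "JAFFAL")[i])
  }))
  m <- dedupWindow(FusionCallSet(emits))
  expect_equal(length(m), 1L)
  expect_length(strsplit(fusionCalls(m)$callers, ";")[[1]], 3L)
})

test_that("reciprocal collapse keeps the higher-support orientation", {
  ab <- mkCall(support = 5L)
  ba <- mkCall(gene5 = "BETA", chrom5 = "chr1", pos5 = 1352L,
               strand5 = "-", gene3 = "ALPHA", chrom3 = "chr1",
               pos3 = 348L, strand3 = "+", support = 3L)
  out <- fusionCalls(collapseReciprocals(mkCallSet(ab, ba)))
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene5, "ALPHA")
  expect_equal(out$reciprocal_of, "BETA::ALPHA")
  # equal support: both orientations kept and cross-linked
  ba$support <- 5L
  out2 <- fusionCalls(collapseReciprocals(mkCallSet(ab, ba)))
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$reciprocal_of, c("BETA::ALPHA", "ALPHA::BETA"))
  # no reciprocal present: identity
  only <- mkCallSet(ab)
  expect_equal(fusionCalls(collapseReciprocals(only)),
               fusionCalls(only))
})

test_that("harmonization operators are idempotent and non-increasing", {
  set.seed(11)
  df <- do.call(rbind, lapply(1:10, function(i) {
    mkCall(pos5 = 300L + sample(0:120, 1), pos3 = 1300L +
             sample(0:120, 1), support = sample(1:8, 1),
           callers = sample(c("LongGF", "JAFFAL"), 1))
  }))
  cs <- FusionCallSet(df)
  for (op in list(dedupExact, dedupWindow, collapseReciprocals)) {
    once <- op(cs)
    expect_lte(length(once), length(cs))
    expect_equal(fusionCalls(op(once)), fusionCalls(once))
  }
})

test_that("unique fusions are per-sample unordered gene pairs", {
  ab <- mkCall()
  ba <- mkCall(gene5 = "BETA", gene3 = "ALPHA")
  other <- mkCall(sample_id = "s2")
  expect_length(uniqueFusions(mkCallSet(ab, ba)), 1L)
  expect_length(uniqueFusions(mkCallSet(ab, other)), 2L)
  three <- mkCallSet(ab, mkCall(gene3 = "GAMMA"),
                     mkCall(gene3 = "DELTA"))
  expect_length(uniqueFusions(three), 3L)
})
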