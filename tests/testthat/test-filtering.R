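toySets <- function(...) {
  geneClassSets(panel_genes = "ALPHA", census_genes = c("BETA", "DELTA"),
                pseudogenes = "PSEUDO1", ribosomal_genes = "RPL99",
                hla_genes = "HLA-Z", ...)
}

test_that("the cancer-gene gate keeps fusions with a listed partner", {
  sets <- toySets()
  keep1 <- mkCall()                                   # ALPHA in panel
  keep2 <- mkCall(gene5 = "ALPHA", gene3 = "BETA")    # both listed
  drop1 <- mkCall(gene5 = "ZZZ1", gene3 = "ZZZ2")     # neither listed
  out <- geneListGate(mkCallSet(keep1, keep2, drop1), sets)
  expect_equal(length(out), 2L)
  expect_error(geneListGate(mkCallSet(keep1), geneClassSets()),
               "configuration error")
})

test_that("the support filter is inclusive at the minimum", {
  cs <- mkCallSet(mkCall(support = 3L), mkCall(support = 2L),
                  mkCall(support = 100L))
  out <- fusionCalls(supportFilter(cs, 3L))
  expect_equal(sort(out$support), c(3L, 100L))
})

test_that("the blacklist removes flagged partners and chrM breakpoints", {
  sets <- toySets()
  pseudo <- mkCall(gene3 = "PSEUDO1")
  mito <- mkCall(chrom3 = "chrM")
  clean <- mkCall()
  out <- fusionCalls(blacklistFilter(mkCallSet(pseudo, mito, clean),
                                     sets))
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene3, "BETA")
  # GTF pseudogene biotype acts as a fallback blacklist
  ann <- toyAnnotation()
  gm <- S4Vectors::mcols(geneRanges(ann))
  expect_false(any(grepl("pseudogene", gm$biotype)))
})

test_that("strand consistency admits only annotation-matching reports", {
  ann <- toyAnnotation()
  # enumerate the four reported-strand combinations for ALPHA(+)::BETA(-)
  combos <- expand.grid(s5 = c("+", "-"), s3 = c("+", "-"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cs <- mkCallSet(mkCall(strand5 = combos$s5[i],
                           strand3 = combos$s3[i]))
    kept <- length(strandConsistencyFilter(cs, ann))
    expect_equal(kept,
                 as.integer(combos$s5[i] == "+" && combos$s3[i] == "-"),
                 info = paste(combos$s5[i], combos$s3[i]))
  }
  # unknown strands and unannotated genes pass with a warning flag
  unk <- strandConsistencyFilter(mkCallSet(mkCall(strand5 = ".")), ann)
  expect_equal(length(unk), 1L)
  expect_true(fusionCalls(unk)$strand_warn)
  una <- strandConsistencyFilter(
    mkCallSet(mkCall(gene5 = "NOSUCH")), ann)
  expect_equal(length(una), 1L)
  expect_true(fusionCalls(una)$strand_warn)
})

test_that("control subtraction removes unordered control pairs", {
  ctrl <- controlPairKeys("BETA", "ALPHA")
  cs <- mkCallSet(mkCall(), mkCall(gene3 = "DELTA"))
  out <- fusionCalls(controlSubtraction(cs, ctrl))
  expect_equal(out$gene3, "DELTA")
  expect_equal(fusionCalls(controlSubtraction(cs, character(0))),
               fusionCalls(cs))
})

test_that("the cascade attributes each planted failure to its stage", {
  ann <- toyAnnotation()
  sets <- toySets(control_pairs = controlPairKeys("DELTA", "ALPHA"))
  calls <- mkCallSet(
    mkCall(sample_id = "s1"),                             # clean
    mkCall(sample_id = "s1", gene5 = "DELTA", pos5 = 5100L,
           chrom5 = "chr2", strand5 = "+", gene3 = "BETA"),  # clean
    mkCall(gene5 = "ZZZ1", gene3 = "ZZZ2"),               # gene gate
    mkCall(support = 2L, gene3 = "ZZZ1"),                 # support
    mkCall(gene3 = "PSEUDO1"),                            # blacklist
    mkCall(sample_id = "s2", strand5 = "-"),              # strand
    mkCall(gene5 = "DELTA", chrom5 = "chr2", pos5 = 5100L,
           strand5 = "+", gene3 = "ALPHA", chrom3 = "chr1",
           pos3 = 350L, strand3 = "+"),                   # control pair
    # both breakpoints intergenic: uninformative
    mkCall(sample_id = "s3", pos5 = 50L, pos3 = 900L))
  res <- applyCascade(calls, sets, ann)
  expect_equal(res$audit$stage,
               c("gene_list_gate", "support_filter", "blacklist_filter",
                 "strand_consistency", "control_subtraction",
                 "breakpoint_class_drop"))
  expect_equal(res$audit$n_in[1], 8L)
  expect_equal(res$audit$n_out[6], 2L)
  # removals land on the right stages
  expect_match(res$audit$removed[1], "ZZZ1::ZZZ2")
  expect_match(res$audit$removed[3], "PSEUDO1")
  expect_match(res$audit$removed[5], "ALPHA::DELTA")
  # audit chains: n_out of stage k equals n_in of stage k+1
  expect_equal(res$audit$n_in[-1], res$audit$n_out[-6])
  # all-clean input is an identity with zero removals
  clean <- mkCallSet(mkCall())
  res2 <- applyCascade(clean, sets, ann)
  expect_true(all(res2$audit$removed == ""))
  # empty input gives an empty, fully chained audit
  res3 <- applyCascade(FusionCallSet(), sets, ann)
  expect_equal(res3$audit$n_in, rep(0L, 6))
  expect_equal(nrow(res3$calls), 0L)
})

test_that("independent stages commute", {
  ann <- toyAnnotation()
  sets <- toySets(control_pairs = controlPairKeys("DELTA", "ALPHA"))
  set.seed(5)
  genes <- c("ALPHA", "BETA", "DELTA", "ZZZ1", "PSEUDO1", "RPL99")
  df <- do.call(rbind, lapply(1:20, function(i) {
    mkCall(gene5 = sample(genes, 1), gene3 = sample(genes, 1),
           support = sample(1:6, 1))
  }))
  df <- df[df$gene5 != df$gene3, ]
  cs <- FusionCallSet(df)
  stages <- list(
    function(z) geneListGate(z, sets),
    function(z) supportFilter(z, 3L),
    function(z) blacklistFilter(z, sets),
    function(z) controlSubtraction(z, sets))
  ref <- NULL
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    out <- cs
    for (k in perm) out <- stages[[k]](out)
    keys <- sort(paste(fusionKey(out), fusionCalls(out)$pos5))
    if (is.null(ref)) ref <- keys else expect_equal(keys, ref)
  }
})

test_that("filter stages are idempotent", {
  ann <- toyAnnotation()
  sets <- toySets()
  cs <- mkCallSet(mkCall(), mkCall(gene3 = "PSEUDO1"),
                  mkCall(support = 2L))
  cols <- c("sample_id", "gene5", "pos5", "gene3", "pos3", "support")
  for (op in list(function(z) geneListGate(z, sets),
                  function(z) supportFilter(z, 3L),
                  function(z) blacklistFilter(z, sets),
                  function(z) controlSubtraction(z, sets))) {
    once <- op(cs)
    expect_equal(fusionCalls(op(once))[cols], fusionCalls(once)[cols])
  }
})
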