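#' Write a self-contained simulated analysis workspace
#'
#' Runs the seeded generators and writes every pipeline input to a
#' directory: annotation GTF and genome FASTA, three caller call tables,
#' gene-list and control-pair resources (plus a census table with
#' tumor-type annotations, oncogene/TSG lists, dependency-screen
#' matrices and a CNS fusion-partner list derived from the planted
#' truth), isoform structure/count/DE tables, and the ground truth as
#' JSON.
#'
#' @param dir workspace directory (created if needed).
#' @param seed RNG seed driving all generators.
#' @param n_genes,n_true,n_artifacts,n_samples,n_samples_per_group
#'   generator sizes (see [simulateAnnotation()],
#'   [simulateFusionCalls()], [simulateIsoformFixtures()]).
#' @param jitter_bp breakpoint jitter for caller emissions.
#' @return Invisibly, a list with the in-memory generator outputs.
#' @export
simulateWorkspace <- function(dir, seed = 1L, n_genes = 50L,
                              n_true = 10L, n_artifacts = 1L,
                              n_samples = 4L, n_samples_per_group = 6L,
                              jitter_bp = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateAnnotation(n_genes, seed = seed)
  fc <- simulateFusionCalls(sim, n_true = n_true,
                            n_artifacts = n_artifacts,
                            jitter_bp = jitter_bp,
                            n_samples = n_samples, seed = seed)
  iso <- simulateIsoformFixtures(sim, fc$truth,
                                 n_samples_per_group = n_samples_per_group,
                                 seed = seed)
  writeLines(sim$gtf, file.path(dir, "annotation.gtf"))
  writeLines(sim$fasta, file.path(dir, "genome.fa"))
  for (ca in names(fc$caller_tables)) {
    utils::write.table(fc$caller_tables[[ca]],
                       file.path(dir, paste0("calls_", ca, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res <- fc$resources
  writeLines(res$panel_genes, file.path(dir, "panel_genes.txt"))
  writeLines(res$census_genes, file.path(dir, "census_genes.txt"))
  cp <- if (length(res$control_pairs)) {
    m <- do.call(rbind, strsplit(res$control_pairs, "::", fixed = TRUE))
    data.frame(gene1 = m[, 1], gene2 = m[, 2])
  } else {
    data.frame(gene1 = character(), gene2 = character())
  }
  utils::write.table(cp, file.path(dir, "control_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # census table with tumor-type annotations: census genes split between
  # glioma-related and other tumor types (deterministic alternation)
  ng <- length(res$census_genes)
  types <- rep(c("glioblastoma", "astrocytoma, AML",
                 "paraganglioma", "leukaemia, lymphoma"),
               length.out = ng)
  utils::write.table(
    data.frame(gene = res$census_genes, tumor_types = types),
    file.path(dir, "census_table.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  onc <- res$census_genes[seq_len(ng) %% 2L == 1L]
  tsg <- res$census_genes[seq_len(ng) %% 3L == 1L]
  writeLines(onc, file.path(dir, "oncogenes.txt"))
  writeLines(tsg, file.path(dir, "tsgs.txt"))
  writeLines(res$census_genes[seq_len(min(5L, ng))],
             file.path(dir, "cns_partners.txt"))

  # dependency-screen matrices over glioma and non-glioma lines
  set.seed(seed + 3000L)
  lines_df <- data.frame(
    cell_line = sprintf("LINE%02d", 1:6),
    lineage = c("glioblastoma", "astrocytoma", "oligodendroglioma",
                "melanoma", "lung", "breast"))
  all_genes <- sim$gene_classes$gene_name
  dep <- matrix(stats::runif(length(all_genes) * 6L), ncol = 6L,
                dimnames = list(all_genes, lines_df$cell_line))
  eff <- matrix(stats::rnorm(length(all_genes) * 6L, -0.3, 0.5),
                ncol = 6L, dimnames = list(all_genes, lines_df$cell_line))
  utils::write.table(data.frame(gene = rownames(dep), dep,
                                check.names = FALSE),
                     file.path(dir, "depmap_dependency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(eff), eff,
                                check.names = FALSE),
                     file.path(dir, "depmap_effect.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lines_df, file.path(dir, "depmap_cell_lines.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(iso$isoforms, file.path(dir, "isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(isoform_id = rownames(iso$counts),
                                iso$counts, check.names = FALSE),
                     file.path(dir, "isoform_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = colnames(iso$counts),
               group = iso$group_labels,
               length_placeholder = NA),
    file.path(dir, "sample_groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(isoform_id = names(iso$lengths), length = iso$lengths),
    file.path(dir, "isoform_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(iso$de_a, file.path(dir, "de_results_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(iso$de_b, file.path(dir, "de_results_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(fusions = fc$truth, isoform_clusters = iso$iso_truth,
                de_strata = iso$de_truth,
                fusion_like = iso$fusionlike_truth, seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(list(sim = sim, fusions = fc, isoforms = iso))
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full fusion analysis pipeline on a workspace
#'
#' Executes harmonize, filter (with audit), breakpoint annotation,
#' prioritization, isoform quantification and consensus differential
#' expression, novel-isoform clustering, breakpoint-isoform overlap and
#' construct design on the files of a workspace directory (layout as
#' written by [simulateWorkspace()]). Stage outputs are written as TSVs
#' under `out_dir` and returned.
#'
#' @param workspace workspace directory.
#' @param params a [fusionParams()] list (or path to a key-value config
#'   file, see [readParamsConfig()]).
#' @param out_dir output directory (default `<workspace>/results`).
#' @return list of stage outputs: `annotation`, `harmonized` (callset),
#'   `audit`, `fusions` (prioritized annotated fusions),
#'   `prioritization`, `breakpoint_summary`, `retained_ids`,
#'   `consensus_de`, `novel_ranks`, `overlap_hits`, `fusion_like`,
#'   `constructs` (report data.frame).
#' @export
runPipeline <- function(workspace, params = fusionParams(),
                        out_dir = file.path(workspace, "results")) {
  if (is.character(params)) params <- readParamsConfig(params)
  need <- c("annotation.gtf", "genome.fa", "panel_genes.txt",
            "census_genes.txt")
  for (f in need) {
    if (!file.exists(file.path(workspace, f))) {
      stop("configuration error: workspace lacks required input: ", f)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- readAnnotation(file.path(workspace, "annotation.gtf"), params)
  seqs <- Biostrings::readDNAStringSet(file.path(workspace, "genome.fa"))
  names(seqs) <- sub("\\s.*", "", names(seqs))

  call_files <- list.files(workspace, pattern = "^calls_.*\\.tsv$",
                           full.names = TRUE)
  callsets <- lapply(call_files, function(f) {
    normalizeCalls(f, sub("^calls_(.*)\\.tsv$", "\\1", basename(f)))
  })
  combined <- do.call(combineCalls, callsets)
  harmonized <- harmonizeCalls(combined, params)
  # whether cohort read-support summaries refer to pre- or post-merge
  # calls is ambiguous in practice, so both are reported
  support_summary <- list(
    pre_merge_median = stats::median(fusionCalls(combined)$support),
    post_merge_median = stats::median(fusionCalls(harmonized)$support),
    post_merge_mean = mean(fusionCalls(harmonized)$support))

  gm <- S4Vectors::mcols(geneRanges(ann))
  sets <- geneClassSets(
    panel_genes = readGeneList(file.path(workspace, "panel_genes.txt")),
    census_genes = readGeneList(file.path(workspace, "census_genes.txt")),
    pseudogenes = gm$gene_name[!is.na(gm$biotype) &
                                 grepl("pseudogene", gm$biotype)],
    ribosomal_genes = gm$gene_name[grepl("^RP[LS]", gm$gene_name)],
    hla_genes = gm$gene_name[grepl("^HLA-", gm$gene_name)],
    mito_chroms = params$mito_chroms,
    control_pairs = if (file.exists(file.path(workspace,
                                              "control_pairs.tsv"))) {
      readControlPairs(file.path(workspace, "control_pairs.tsv"))
    } else character(0))
  casc <- applyCascade(harmonized, sets, ann, params)

  resources <- fusionResources(
    panel_genes = sets$panel_genes, census_genes = sets$census_genes)
  ct_path <- file.path(workspace, "census_table.tsv")
  if (file.exists(ct_path)) {
    resources$glioma_subset <- buildGliomaSubset(
      .read_tsv(ct_path), params$glioma_keywords,
      params$glioma_exclusions)
  }
  optional_lists <- c(oncogenes = "oncogenes.txt", tsgs = "tsgs.txt",
                      cns_fusion_partners = "cns_partners.txt")
  for (slot in names(optional_lists)) {
    p <- file.path(workspace, optional_lists[[slot]])
    if (file.exists(p)) resources[[slot]] <- readGeneList(p)
  }
  dp <- file.path(workspace, "depmap_dependency.tsv")
  ep <- file.path(workspace, "depmap_effect.tsv")
  lp <- file.path(workspace, "depmap_cell_lines.tsv")
  if (file.exists(dp) && file.exists(ep)) {
    d <- .read_tsv(dp); e <- .read_tsv(ep)
    dm <- as.matrix(d[, -1, drop = FALSE]); rownames(dm) <- d[[1]]
    em <- as.matrix(e[, -1, drop = FALSE]); rownames(em) <- e[[1]]
    cl <- if (file.exists(lp)) .read_tsv(lp) else NULL
    resources$depmap_summary <- depmapEssentiality(dm, em, cl,
                                                   params = params)
  }
  fus <- annotateFusionGenes(casc$calls, resources)
  prio <- summarizePrioritization(fus)
  bp_sum <- summarizeBreakpointClasses(fus)

  # isoform analyses (optional inputs)
  consensus <- NULL; ranks <- NULL; hits <- NULL; flike <- NULL
  expr_sum <- NULL
  iso_path <- file.path(workspace, "isoforms.tsv")
  isoforms <- if (file.exists(iso_path)) readIsoformTable(iso_path) else
    NULL
  cnt_path <- file.path(workspace, "isoform_counts.tsv")
  if (file.exists(cnt_path)) {
    cdf <- .read_tsv(cnt_path)
    counts <- as.matrix(cdf[, -1, drop = FALSE])
    rownames(counts) <- cdf[[1]]
    grp <- .read_tsv(file.path(workspace, "sample_groups.tsv"))
    groups <- grp$group[match(colnames(counts), grp$sample_id)]
    lens <- .read_tsv(file.path(workspace, "isoform_lengths.tsv"))
    lv <- lens$length[match(rownames(counts), lens$isoform_id)]
    tpm <- computeTpm(counts, lv)
    expr_sum <- expressionSummaries(tpm, groups)
    keep <- expressionFilter(counts, groups, params)
    de_a <- .read_tsv(file.path(workspace, "de_results_a.tsv"))
    de_b <- .read_tsv(file.path(workspace, "de_results_b.tsv"))
    consensus <- consensusDe(de_a[de_a$isoform_id %in% keep, ],
                             de_b[de_b$isoform_id %in% keep, ], params)
  }
  if (!is.null(isoforms)) {
    groups_nov <- groupNovelIsoformsByGene(isoforms,
                                           tol = params$boundary_tol_bp)
    ranks <- rankGenesByNovelStructures(groups_nov)
    hit_list <- lapply(seq_len(nrow(fus)), function(i) {
      breakpointProximalIsoforms(fus[i, ], isoforms, ann, params)
    })
    hits <- do.call(rbind, hit_list)
    if (is.null(hits)) hits <- breakpointProximalIsoforms(
      list(sample_id = "", gene5 = "", pos5 = 1, gene3 = "", pos3 = 1),
      isoforms[0, ], ann, params)
    flike <- fusionLikePattern(hits, expr_sum)
  }

  constructs <- list()
  if (nrow(fus)) {
    for (i in which(fus$functional_both)) {
      con <- tryCatch(
        designFusionConstruct(fus[i, ], ann, seqs, params),
        error = function(e) NULL)
      if (!is.null(con)) constructs[[length(constructs) + 1L]] <- con
    }
  }
  con_df <- if (length(constructs)) {
    do.call(rbind, lapply(constructs, function(x) {
      data.frame(sample_id = x$sample_id, gene5 = x$gene5,
                 gene3 = x$gene3, transcript5 = x$transcript5,
                 transcript3 = x$transcript3, cdna_len = nchar(x$cdna),
                 junction_offset = x$junction_offset,
                 frame_status = x$frame_status,
                 premature_stop_pos = x$premature_stop_pos,
                 orf_len = nchar(x$orf_protein),
                 microhomology_len = x$microhomology_len,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame()

  wt <- function(x, f) {
    if (!is.null(x) && is.data.frame(x)) {
      utils::write.table(x, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(fusionCalls(harmonized), "harmonized_calls.tsv")
  wt(casc$audit, "filter_audit.tsv")
  wt(fus, "fusions_annotated.tsv")
  wt(prio, "prioritization_summary.tsv")
  wt(bp_sum$classes, "breakpoint_classes.tsv")
  wt(consensus, "consensus_de.tsv")
  wt(ranks, "novel_isoform_ranks.tsv")
  wt(hits, "overlap_hits.tsv")
  wt(flike, "fusion_like.tsv")
  wt(con_df, "constructs.tsv")

  list(annotation = ann, harmonized = harmonized,
       support_summary = support_summary, audit = casc$audit,
       fusions = fus, prioritization = prio,
       breakpoint_summary = bp_sum, consensus_de = consensus,
       novel_ranks = ranks, overlap_hits = hits, fusion_like = flike,
       constructs = con_df, construct_objects = constructs)
}

# ---- curated fusion table ------------------------------------------------

#' Read the packaged curated-fusion table
#'
#' Parses the curated table of functionally tested glioma fusions
#' (breakpoints, grade, panel/census involvement codes, in vivo VNC
#' phenotypes) shipped under `extdata`, including the involvement-code
#' grammar documented in the file header.
#'
#' @param path file path; default the packaged table.
#' @return data.frame with parsed columns: fusion, gene1, gene2, chrom1,
#'   pos1, chrom2, pos2, grade, clinical, gene1_panel, gene1_census,
#'   gene2_panel, gene2_census, phenotypes (list column of character
#'   vectors).
#' @export
readCuratedFusionTable <- function(path = system.file(
  "extdata", "curated_glioma_fusions.tsv", package = "FusionScope")) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    for (cc in names(df)) df[[cc]] <- as.character(df[[cc]])
  }
  parse_bp <- function(s) {
    if (length(s) == 0L) {
      return(list(chrom = character(0), pos = integer(0)))
    }
    m <- regmatches(s, regexec("^(\\S+):(\\d+)$", s))
    if (any(vapply(m, length, 1L) != 3L)) {
      stop("unparseable breakpoint: ", s[vapply(m, length, 1L) != 3L][1])
    }
    list(chrom = vapply(m, `[`, "", 2),
         pos = as.integer(vapply(m, `[`, "", 3)))
  }
  b1 <- parse_bp(df$bp1); b2 <- parse_bp(df$bp2)
  genes <- strsplit(df$fusion, "::", fixed = TRUE)
  flags <- lapply(seq_len(nrow(df)), function(i) {
    code <- trimws(df$involvement[i])
    m <- regmatches(code,
                    regexec("^(Gene1|Gene2|Both)\\s+(.+)$", code))[[1]]
    if (length(m) != 3L) {
      stop("unparseable involvement code in row ", i, ": '", code, "'")
    }
    res <- trimws(strsplit(m[3], "\\s+and\\s+")[[1]])
    if (!all(res %in% c("CHOP", "CCG"))) {
      stop("unknown resource in involvement code, row ", i, ": '",
           code, "'")
    }
    g1 <- m[2] %in% c("Gene1", "Both")
    g2 <- m[2] %in% c("Gene2", "Both")
    c(g1_panel = g1 && "CHOP" %in% res, g1_census = g1 && "CCG" %in% res,
      g2_panel = g2 && "CHOP" %in% res, g2_census = g2 && "CCG" %in% res)
  })
  flags <- do.call(rbind, flags)
  phen <- lapply(df$phenotype, function(p) {
    p <- trimws(p)
    if (p == "-" || p == "") return(character(0))
    trimws(strsplit(p, "&", fixed = TRUE)[[1]])
  })
  data.frame(fusion = df$fusion,
             gene1 = vapply(genes, `[`, "", 1),
             gene2 = vapply(genes, `[`, "", 2),
             chrom1 = b1$chrom, pos1 = b1$pos,
             chrom2 = b2$chrom, pos2 = b2$pos,
             grade = df$grade, clinical = df$clinical,
             gene1_panel = unname(flags[, "g1_panel"]),
             gene1_census = unname(flags[, "g1_census"]),
             gene2_panel = unname(flags[, "g2_panel"]),
             gene2_census = unname(flags[, "g2_census"]),
             phenotypes = I(phen),
             stringsAsFactors = FALSE)
}

#' Summarize the curated fusion table
#'
#' Exact counts over the parsed table: fusions, fusions with at least one
#' panel (CHOP) gene, at least one census (CCG) gene, at least one
#' significant in vivo phenotype, and per-grade counts.
#'
#' @param rows parsed table from [readCuratedFusionTable()].
#' @return named list of integer counts.
#' @export
summarizeCuratedTable <- function(rows) {
  list(n_fusions = nrow(rows),
       n_panel_any = sum(rows$gene1_panel | rows$gene2_panel),
       n_census_any = sum(rows$gene1_census | rows$gene2_census),
       n_phenotype_any = sum(vapply(rows$phenotypes, length, 1L) > 0L),
       n_hgg = sum(rows$grade == "HGG"),
       n_lgg = sum(rows$grade == "LGG"),
       n_vnc_area = sum(vapply(rows$phenotypes,
                               function(p) "VNC Area" %in% p,
                               logical(1))),
       n_vnc_length = sum(vapply(rows$phenotypes,
                                 function(p) "VNC Length" %in% p,
                                 logical(1))))
}
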