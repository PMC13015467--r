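.REGION_CLASSES <- c("CDS", "UTR5", "UTR3", "noncoding_exon", "near_exon",
                     "intronic", "intergenic", "unannotated")

# classify one genomic position against one transcript; returns list(class,
# dist) where class is one of CDS/UTR5/UTR3/noncoding_exon/intronic/absent
.classifyInTranscript <- function(ann, tid, pos) {
  tx <- ann@transcripts
  i <- match(tid, tx$transcript_id)
  ex <- ann@exons[[tid]]
  if (pos < tx$tx_start[i] || pos > tx$tx_end[i]) {
    return(list(class = "absent", dist = NA_integer_))
  }
  in_exon <- any(ex$start <= pos & pos <= ex$end)
  if (!in_exon) {
    return(list(class = "intronic",
                dist = .distToExonBoundary(ex, pos)))
  }
  if (is.na(tx$cds_start[i])) {
    return(list(class = "noncoding_exon", dist = 0L))
  }
  if (pos >= tx$cds_start[i] && pos <= tx$cds_end[i]) {
    return(list(class = "CDS", dist = 0L))
  }
  # exonic but outside the CDS: UTR side by transcript strand
  before_cds <- pos < tx$cds_start[i]
  cls <- if (tx$strand[i] == "-") {
    if (before_cds) "UTR3" else "UTR5"
  } else {
    if (before_cds) "UTR5" else "UTR3"
  }
  list(class = cls, dist = 0L)
}

#' Classify a fusion breakpoint against the tiered transcript model
#'
#' Evaluates the MANE transcript first (tier 1); if the position is
#' intronic there (or the tier is absent), escalates to the longest
#' protein-coding transcript (tier 2), then to all transcripts (tier 3,
#' preferring CDS over UTR over non-coding exon). Escalation stops at the
#' first tier yielding a non-intronic class, so an exonic tier-1 result is
#' never downgraded. Positions outside every transcript span of the gene
#' are intergenic; genes absent from the annotation are unannotated.
#'
#' @param ann a [GenomeAnnotation-class].
#' @param gene gene name (as reported by the caller).
#' @param pos 1-based genomic breakpoint position.
#' @return list with `region_class`, `tier_used` (MANE, longest_coding,
#'   any_transcript or none), `distance_to_boundary` (bp to the nearest
#'   exon boundary of the classifying transcript; 0 for exonic classes)
#'   and `transcript_id`.
#' @export
classifyBreakpoint <- function(ann, gene, pos) {
  gid <- .resolveGene(ann, gene)
  if (is.na(gid)) {
    return(list(region_class = "unannotated", tier_used = "none",
                distance_to_boundary = NA_integer_,
                transcript_id = NA_character_))
  }
  tiers <- selectTranscriptTiers(ann, gene)
  best_intronic <- NULL

  eval_tier <- function(tids, tier_name) {
    res <- lapply(tids, function(t) .classifyInTranscript(ann, t, pos))
    cls <- vapply(res, `[[`, "", "class")
    # prefer the most informative exonic class within the tier
    pref <- c("CDS", "UTR5", "UTR3", "noncoding_exon")
    for (p in pref) {
      hit <- which(cls == p)
      if (length(hit)) {
        return(list(region_class = p, tier_used = tier_name,
                    distance_to_boundary = 0L,
                    transcript_id = tids[hit[1]]))
      }
    }
    hit <- which(cls == "intronic")
    if (length(hit)) {
      d <- vapply(res[hit], `[[`, integer(1), "dist")
      k <- hit[which.min(d)]
      return(list(region_class = "intronic", tier_used = tier_name,
                  distance_to_boundary = min(d),
                  transcript_id = tids[k]))
    }
    NULL
  }

  tier_sets <- list(MANE = tiers$tier1, longest_coding = tiers$tier2,
                    any_transcript = tiers$tier3)
  for (tn in names(tier_sets)) {
    tids <- tier_sets[[tn]]
    tids <- tids[!is.na(tids)]
    if (length(tids) == 0L) next
    r <- eval_tier(tids, tn)
    if (is.null(r)) next
    if (r$region_class != "intronic") return(r)
    if (is.null(best_intronic)) best_intronic <- r
  }
  if (!is.null(best_intronic)) return(best_intronic)
  list(region_class = "intergenic", tier_used = "none",
       distance_to_boundary = NA_integer_, transcript_id = NA_character_)
}

#' Reclassify splice-proximal intronic breakpoints as near-exon
#'
#' Intronic breakpoints within `near_exon_bp` of an exon boundary become
#' `near_exon` (counted as exonic in summaries); every other class is a
#' fixed point.
#'
#' @param bp_ann result of [classifyBreakpoint()].
#' @param near_exon_bp distance cutoff in bp (default 200, inclusive).
#' @return The (possibly reclassified) breakpoint annotation.
#' @export
reclassifyNearExon <- function(bp_ann, near_exon_bp = 200L) {
  if (identical(bp_ann$region_class, "intronic") &&
      !is.na(bp_ann$distance_to_boundary) &&
      bp_ann$distance_to_boundary <= near_exon_bp) {
    bp_ann$region_class <- "near_exon"
  }
  bp_ann
}

#' Annotate both breakpoints of every fusion call
#'
#' Runs [classifyBreakpoint()] + [reclassifyNearExon()] on the 5' and 3'
#' breakpoints and sets the functional-potential flags:
#' `functional_any`/`functional_both` are TRUE when at least one / both
#' breakpoint classes are CDS or near-exon.
#'
#' @param x a FusionCallSet.
#' @param ann a [GenomeAnnotation-class].
#' @param params a [fusionParams()] list.
#' @return data.frame: the call columns plus class5, tier5, dist5, tx5,
#'   class3, tier3, dist3, tx3, functional_any, functional_both.
#' @export
annotateFusions <- function(x, ann, params = fusionParams()) {
  df <- fusionCalls(x)
  n <- nrow(df)
  cols <- data.frame(class5 = character(n), tier5 = character(n),
                     dist5 = rep(NA_integer_, n), tx5 = character(n),
                     class3 = character(n), tier3 = character(n),
                     dist3 = rep(NA_integer_, n), tx3 = character(n),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a5 <- reclassifyNearExon(
      classifyBreakpoint(ann, df$gene5[i], df$pos5[i]),
      params$near_exon_bp)
    a3 <- reclassifyNearExon(
      classifyBreakpoint(ann, df$gene3[i], df$pos3[i]),
      params$near_exon_bp)
    cols$class5[i] <- a5$region_class
    cols$tier5[i] <- a5$tier_used
    cols$dist5[i] <- a5$distance_to_boundary
    cols$tx5[i] <- a5$transcript_id
    cols$class3[i] <- a3$region_class
    cols$tier3[i] <- a3$tier_used
    cols$dist3[i] <- a3$distance_to_boundary
    cols$tx3[i] <- a3$transcript_id
  }
  out <- cbind(df, cols)
  functionalFlags(out)
}

#' Set functional-potential flags on annotated fusions
#'
#' @param ann_fus data.frame with class5/class3 columns.
#' @return The data.frame with `functional_any`/`functional_both`
#'   (re)computed from class membership in {CDS, near_exon}.
#' @export
functionalFlags <- function(ann_fus) {
  f5 <- ann_fus$class5 %in% c("CDS", "near_exon")
  f3 <- ann_fus$class3 %in% c("CDS", "near_exon")
  ann_fus$functional_any <- f5 | f3
  ann_fus$functional_both <- f5 & f3
  ann_fus
}

#' Drop fusions with no informative breakpoint
#'
#' Removes fusions whose breakpoints are both in
#' {intronic, intergenic, unannotated}.
#'
#' @param ann_fus annotated fusion data.frame ([annotateFusions()]).
#' @return Filtered data.frame.
#' @export
dropUnannotatable <- function(ann_fus) {
  bad <- c("intronic", "intergenic", "unannotated")
  keep <- !(ann_fus$class5 %in% bad & ann_fus$class3 %in% bad)
  out <- ann_fus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Breakpoint class distribution by 5'/3' role
#'
#' Per-role fractions over the region classes (CDS and near-exon pooled as
#' "CDS/near_exon") and tier-usage fractions.
#'
#' @param ann_fus annotated fusion data.frame.
#' @return list with `classes` (data.frame role/class/n/fraction) and
#'   `tiers` (data.frame role/tier/n/fraction); both empty for empty
#'   input.
#' @export
summarizeBreakpointClasses <- function(ann_fus) {
  if (nrow(ann_fus) == 0L) {
    return(list(classes = data.frame(role = character(),
                                     class = character(), n = integer(),
                                     fraction = numeric()),
                tiers = data.frame(role = character(), tier = character(),
                                   n = integer(), fraction = numeric())))
  }
  pool <- function(cl) ifelse(cl %in% c("CDS", "near_exon"),
                              "CDS/near_exon", cl)
  lv <- c("CDS/near_exon", "UTR5", "UTR3", "noncoding_exon", "intronic",
          "intergenic", "unannotated")
  one_role <- function(cl, role) {
    t <- table(factor(pool(cl), levels = lv))
    data.frame(role = role, class = names(t), n = as.integer(t),
               fraction = as.numeric(t) / length(cl),
               stringsAsFactors = FALSE)
  }
  tier_role <- function(tr, role) {
    t <- table(factor(tr, levels = c("MANE", "longest_coding",
                                     "any_transcript", "none")))
    data.frame(role = role, tier = names(t), n = as.integer(t),
               fraction = as.numeric(t) / length(tr),
               stringsAsFactors = FALSE)
  }
  list(classes = rbind(one_role(ann_fus$class5, "5prime"),
                       one_role(ann_fus$class3, "3prime")),
       tiers = rbind(tier_role(ann_fus$tier5, "5prime"),
                     tier_role(ann_fus$tier3, "3prime")))
}
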