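#' Transcripts-per-million from raw counts
#'
#' tpm_i = (count_i / length_i) / sum_j(count_j / length_j) * 1e6 per
#' sample; a sample with no expressed isoform gets all-zero TPM
#' (undetected transcripts are zero by construction).
#'
#' @param counts numeric matrix, isoforms x samples, non-negative.
#' @param effective_lengths positive numeric vector, one per isoform.
#' @return numeric matrix of TPM values, same dimensions as `counts`.
#' @examples
#' m <- matrix(c(10, 10, 10, 10), 4, 1,
#'             dimnames = list(paste0("i", 1:4), "s1"))
#' computeTpm(m, rep(100, 4))  # each 250000
#' @export
computeTpm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("value error: negative count")
  if (length(effective_lengths) != nrow(counts)) {
    stop("one effective length per isoform required")
  }
  if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
  rate <- counts / effective_lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2L, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  dimnames(tpm) <- dimnames(counts)
  tpm
}

#' Expression filter ahead of differential expression
#'
#' Retains an isoform iff it has at least `expr_min_count` counts in at
#' least as many samples as the smallest group, and at least
#' `expr_min_total` total counts over all samples in the comparison.
#'
#' @param counts numeric matrix, isoforms x samples.
#' @param group_labels factor/character vector, one label per sample
#'   column (>= 2 groups, no empty group).
#' @param params a [fusionParams()] list.
#' @return character vector of retained isoform ids (rownames).
#' @export
expressionFilter <- function(counts, group_labels,
                             params = fusionParams()) {
  counts <- as.matrix(counts)
  if (length(group_labels) != ncol(counts)) {
    stop("configuration error: one group label per sample required")
  }
  sizes <- table(group_labels)
  if (length(sizes) < 2L || any(sizes == 0L)) {
    stop("configuration error: need >= 2 non-empty groups")
  }
  min_group <- min(sizes)
  n_pass <- rowSums(counts >= params$expr_min_count)
  keep <- n_pass >= min_group & rowSums(counts) >= params$expr_min_total
  rownames(counts)[keep]
}

#' Consensus of two differential-expression result tables
#'
#' Intersects isoforms significant in both methods (significance <=
#' `de_fdr_max`, |log2FC| >= `de_abs_lfc_min`) with concordant fold-change
#' sign, and summarizes each as the mean log2 fold change and the maximum
#' significance value across methods.
#'
#' @param results_a,results_b data.frames with columns isoform_id,
#'   log2_fc, fdr (adjusted p-values accepted in the fdr column).
#' @param params a [fusionParams()] list.
#' @return data.frame isoform_id, mean_log2_fc, max_fdr, direction
#'   ("up"/"down"), sorted by isoform_id.
#' @export
consensusDe <- function(results_a, results_b, params = fusionParams()) {
  chk <- function(d, lab) {
    need <- c("isoform_id", "log2_fc", "fdr")
    if (!all(need %in% names(d))) {
      stop("schema error: DE table ", lab, " lacks column(s): ",
           paste(setdiff(need, names(d)), collapse = ", "))
    }
    if (anyDuplicated(d$isoform_id)) {
      stop("input error: duplicated isoform_id in DE table ", lab)
    }
    if (any(d$fdr < 0 | d$fdr > 1, na.rm = TRUE)) {
      stop("input error: significance outside [0,1] in DE table ", lab)
    }
    d
  }
  a <- chk(results_a, "A"); b <- chk(results_b, "B")
  sig <- function(d) {
    d[!is.na(d$fdr) & d$fdr <= params$de_fdr_max &
        abs(d$log2_fc) >= params$de_abs_lfc_min, , drop = FALSE]
  }
  a <- sig(a); b <- sig(b)
  common <- intersect(a$isoform_id, b$isoform_id)
  ia <- match(common, a$isoform_id); ib <- match(common, b$isoform_id)
  conc <- sign(a$log2_fc[ia]) == sign(b$log2_fc[ib])
  common <- common[conc]; ia <- ia[conc]; ib <- ib[conc]
  out <- data.frame(
    isoform_id = common,
    mean_log2_fc = (a$log2_fc[ia] + b$log2_fc[ib]) / 2,
    max_fdr = pmax(a$fdr[ia], b$fdr[ib]),
    direction = ifelse(a$log2_fc[ia] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  out <- out[order(out$isoform_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-wise expression means and percentile ranks
#'
#' For each group: the mean TPM of every isoform and its percentile rank
#' within the group's mean-TPM distribution (midranks for ties, scaled to
#' (0, 100]).
#'
#' @param tpm numeric matrix, isoforms x samples.
#' @param group_labels one label per sample column.
#' @return data.frame isoform_id, group, mean_tpm, percentile.
#' @export
expressionSummaries <- function(tpm, group_labels) {
  tpm <- as.matrix(tpm)
  if (length(group_labels) != ncol(tpm)) {
    stop("one group label per sample required")
  }
  ids <- rownames(tpm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(tpm)))
  out <- lapply(unique(group_labels), function(g) {
    m <- rowMeans(tpm[, group_labels == g, drop = FALSE])
    pr <- rank(m, ties.method = "average") / length(m) * 100
    data.frame(isoform_id = ids, group = g, mean_tpm = as.numeric(m),
               percentile = as.numeric(pr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
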