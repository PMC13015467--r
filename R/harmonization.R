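#' Normalize a raw caller table into fusion calls
#'
#' Adapts one caller's output table to the normalized call schema. Column
#' names are mapped through `col_map`; unmapped columns are expected to
#' already use the normalized names (sample_id, gene5, chrom5, pos5,
#' strand5, gene3, chrom3, pos3, strand3, support).
#'
#' @param raw data.frame, or path to a TSV file.
#' @param caller_name caller label recorded as provenance.
#' @param col_map named character vector mapping normalized column name ->
#'   raw column name, for caller dialects.
#' @return A [FusionCallSet-class] with caller provenance set.
#' @examples
#' raw <- data.frame(sample_id = "s1", gene5 = "A", chrom5 = "chr1",
#'                   pos5 = 100, strand5 = "+", gene3 = "B",
#'                   chrom3 = "chr2", pos3 = 200, strand3 = "+",
#'                   support = 5)
#' normalizeCalls(raw, "LongGF")
#' @export
normalizeCalls <- function(raw, caller_name, col_map = NULL) {
  if (is.character(raw) && length(raw) == 1L) {
    raw <- utils::read.delim(raw, stringsAsFactors = FALSE)
  }
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw)) {
        stop("schema error: mapped column '", col_map[[nm]],
             "' absent from ", caller_name, " table")
      }
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  need <- c("sample_id", "gene5", "chrom5", "pos5", "gene3", "chrom3",
            "pos3", "support")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("schema error: ", caller_name, " table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"strand5" %in% names(raw)) raw$strand5 <- "."
  if (!"strand3" %in% names(raw)) raw$strand3 <- "."
  raw$strand5[is.na(raw$strand5) | raw$strand5 == ""] <- "."
  raw$strand3[is.na(raw$strand3) | raw$strand3 == ""] <- "."
  sup <- suppressWarnings(as.numeric(raw$support))
  if (nrow(raw) && (anyNA(sup) || any(sup != floor(sup)))) {
    stop("value error: non-integer read support in ", caller_name,
         " table")
  }
  if (nrow(raw) && any(sup < 1)) {
    stop("value error: read support below 1 in ", caller_name, " table")
  }
  if (nrow(raw) == 0L) return(FusionCallSet())
  df <- data.frame(sample_id = as.character(raw$sample_id),
                   gene5 = as.character(raw$gene5),
                   chrom5 = as.character(raw$chrom5),
                   pos5 = as.integer(raw$pos5),
                   strand5 = as.character(raw$strand5),
                   gene3 = as.character(raw$gene3),
                   chrom3 = as.character(raw$chrom3),
                   pos3 = as.integer(raw$pos3),
                   strand3 = as.character(raw$strand3),
                   support = as.integer(sup),
                   callers = caller_name,
                   stringsAsFactors = FALSE)
  FusionCallSet(df)
}

#' Combine several FusionCallSets into one
#' @param ... FusionCallSet objects.
#' @return A single FusionCallSet with all calls.
#' @export
combineCalls <- function(...) {
  sets <- list(...)
  dfs <- lapply(sets, fusionCalls)
  FusionCallSet(do.call(rbind, dfs))
}

#' Per-sample unordered gene-pair key
#'
#' Distinct fusions are distinct gene pairings within a sample; a fusion
#' and its reciprocal share a key.
#'
#' @param x a FusionCallSet or a call data.frame.
#' @return character vector of keys, one per call.
#' @export
fusionKey <- function(x) {
  df <- if (is(x, "FusionCallSet")) fusionCalls(x) else x
  if (nrow(df) == 0L) return(character(0))
  pair <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "::"),
                 df$gene5, df$gene3, USE.NAMES = FALSE)
  paste(df$sample_id, pair, sep = "|")
}

# ordered-pair grouping key used by window dedup
.orderedKey <- function(df) {
  paste(df$sample_id, df$gene5, df$gene3, df$chrom5, df$chrom3, sep = "|")
}

#' Remove exact duplicates within each caller
#'
#' Within one caller, calls with identical sample, genes and breakpoints
#' collapse to a single call (support = max over duplicates). Calls from
#' different callers are untouched here; the breakpoint-window step merges
#' across callers.
#'
#' @param x a FusionCallSet.
#' @return A FusionCallSet without within-caller exact duplicates.
#' @export
dedupExact <- function(x) {
  df <- fusionCalls(x)
  if (nrow(df) == 0L) return(x)
  key <- paste(.orderedKey(df), df$pos5, df$pos3, df$callers, sep = "|")
  keep <- !duplicated(key)
  sup <- tapply(df$support, key, max)
  out <- df[keep, , drop = FALSE]
  out$support <- as.integer(sup[key[keep]])
  FusionCallSet(out)
}

#' Merge calls within a breakpoint window across callers
#'
#' Calls from one sample with the same ordered gene pair whose breakpoints
#' both lie within `window_bp` are merged by single-linkage chaining into
#' one representative call: coordinates and support come from the member
#' with maximal support (ties: smallest (pos5, pos3)), caller sets are
#' unioned.
#'
#' @param x a FusionCallSet.
#' @param window_bp merge window in bp (default 50).
#' @return A FusionCallSet of merged representatives.
#' @export
dedupWindow <- function(x, window_bp = 50L) {
  df <- fusionCalls(x)
  if (nrow(df) == 0L) return(x)
  groups <- split(seq_len(nrow(df)), .orderedKey(df))
  keep_rows <- list()
  for (idx in groups) {
    n <- length(idx)
    comp <- .linkComponents(df$pos5[idx], df$pos3[idx], window_bp)
    for (cc in unique(comp)) {
      mem <- idx[comp == cc]
      sub <- df[mem, , drop = FALSE]
      ord <- order(-sub$support, sub$pos5, sub$pos3)
      rep_row <- sub[ord[1], , drop = FALSE]
      rep_row$support <- max(sub$support)
      rep_row$callers <- paste(
        sort(unique(unlist(strsplit(sub$callers, ";")))), collapse = ";")
      # merged member strands: keep representative's
      keep_rows[[length(keep_rows) + 1L]] <- rep_row
    }
  }
  out <- do.call(rbind, keep_rows)
  out <- out[order(out$sample_id, out$gene5, out$gene3, out$pos5,
                   out$pos3), , drop = FALSE]
  FusionCallSet(out)
}

# single-linkage connected components on breakpoint pairs: an edge when
# both |dpos5| and |dpos3| <= window
.linkComponents <- function(pos5, pos3, window) {
  n <- length(pos5)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            abs(pos5[i] - pos5[j]) <= window &&
            abs(pos3[i] - pos3[j]) <= window) {
          old <- max(comp[i], comp[j]); newc <- min(comp[i], comp[j])
          comp[comp == old] <- newc
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Collapse reciprocal fusion orientations
#'
#' Two calls in one sample are reciprocal when their gene partners are
#' reversed and each breakpoint of one lies within `window_bp` of the
#' partner-matched breakpoint of the other. The orientation with higher
#' read support is retained (the survivor records the dropped orientation
#' in `reciprocal_of`); with equal support both orientations are kept and
#' cross-linked.
#'
#' @param x a FusionCallSet (window-deduplicated).
#' @param window_bp matching window in bp (default 50).
#' @return A FusionCallSet with reciprocals collapsed.
#' @export
collapseReciprocals <- function(x, window_bp = 50L) {
  df <- fusionCalls(x)
  if (nrow(df) <= 1L) return(x)
  drop <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df) - 1L)) {
    if (drop[i]) next
    for (j in (i + 1L):nrow(df)) {
      if (drop[j]) next
      if (df$sample_id[i] != df$sample_id[j]) next
      if (!(df$gene5[i] == df$gene3[j] && df$gene3[i] == df$gene5[j])) next
      if (df$chrom5[i] != df$chrom3[j] || df$chrom3[i] != df$chrom5[j]) next
      if (abs(df$pos5[i] - df$pos3[j]) > window_bp) next
      if (abs(df$pos3[i] - df$pos5[j]) > window_bp) next
      lab_i <- paste0(df$gene5[i], "::", df$gene3[i])
      lab_j <- paste0(df$gene5[j], "::", df$gene3[j])
      if (df$support[i] > df$support[j]) {
        drop[j] <- TRUE
        df$reciprocal_of[i] <- lab_j
      } else if (df$support[j] > df$support[i]) {
        drop[i] <- TRUE
        df$reciprocal_of[j] <- lab_i
      } else {
        df$reciprocal_of[i] <- lab_j
        df$reciprocal_of[j] <- lab_i
      }
    }
  }
  FusionCallSet(df[!drop, , drop = FALSE])
}

#' Run the full harmonization (exact dedup, window dedup, reciprocal
#' collapse)
#'
#' @param x a FusionCallSet of combined caller output.
#' @param params a [fusionParams()] list.
#' @return A harmonized FusionCallSet.
#' @export
harmonizeCalls <- function(x, params = fusionParams()) {
  w <- params$dedup_window_bp
  collapseReciprocals(dedupWindow(dedupExact(x), w), w)
}

#' Distinct per-sample fusions
#'
#' @param x a FusionCallSet.
#' @return character vector of distinct per-sample unordered gene-pair
#'   keys.
#' @export
uniqueFusions <- function(x) {
  sort(unique(fusionKey(x)))
}
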