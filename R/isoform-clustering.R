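#' Parse an exon-chain string
#'
#' Chains are written "start-end,start-end,..." with 1-based closed
#' coordinates sorted by position.
#'
#' @param chain character scalar.
#' @return data.frame with columns start, end.
#' @export
parseExonChain <- function(chain) {
  parts <- strsplit(chain, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(\\d+)-(\\d+)$", parts))
  if (any(vapply(m, length, 1L) != 3L)) {
    stop("unparseable exon chain: ", chain)
  }
  d <- data.frame(start = as.integer(vapply(m, `[`, "", 2)),
                  end = as.integer(vapply(m, `[`, "", 3)))
  if (any(d$start > d$end)) stop("exon with start > end in chain: ", chain)
  if (is.unsorted(d$start)) stop("exon chain not sorted: ", chain)
  d
}

#' Format an exon chain as a string
#' @param ex data.frame with start, end.
#' @return character scalar "start-end,...".
#' @export
formatExonChain <- function(ex) {
  paste(sprintf("%d-%d", ex$start, ex$end), collapse = ",")
}

#' Read an isoform structure table
#'
#' @param path TSV with columns isoform_id, gene, sample_id, strand,
#'   novelty (known/NIC/NNIC), exons (chain string).
#' @return data.frame of isoform records.
#' @export
readIsoformTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("isoform_id", "gene", "sample_id", "strand", "novelty",
            "exons")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema error: isoform table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

# boundary vector of a chain: (start1, end1, start2, end2, ...)
.chainBounds <- function(ex) {
  as.numeric(rbind(ex$start, ex$end))
}

# strand-aware transcript start (5' end in transcription direction)
.chainTxStart <- function(ex, strand) {
  if (strand == "-") max(ex$end) else min(ex$start)
}

#' Group novel isoforms by exon-chain similarity
#'
#' Within one gene, records are partitioned by exon count; within each
#' partition a record joins an existing group when its transcript start
#' (5' end in transcription direction) is within `tol` of the group
#' representative's start and every corresponding exon boundary is within
#' `tol` of the representative's. The representative is the running mean
#' of member boundaries (rounded half-up). Clustering is greedy in order
#' of genomic start (deterministic); a post-hoc pass re-validates members
#' against the final representative and splits off any record the mean
#' drifted away from.
#'
#' @param records data.frame of isoform records for a single gene
#'   (columns isoform_id, gene, sample_id, strand, exons as chain string,
#'   optionally novelty).
#' @param tol boundary tolerance in bp (default 100).
#' @return list of groups, each a list with `gene`, `exon_count`,
#'   `members` (data.frame of member records) and `representative`
#'   (data.frame start/end).
#' @export
groupNovelIsoforms <- function(records, tol = 100L) {
  if (nrow(records) == 0L) return(list())
  if (length(unique(records$gene)) != 1L) {
    stop("input error: groupNovelIsoforms takes records of one gene")
  }
  chains <- lapply(records$exons, parseExonChain)
  records$.n_exons <- vapply(chains, nrow, 1L)
  records$.gstart <- vapply(chains, function(e) min(e$start), 1L)
  ord <- order(records$.gstart, records$isoform_id)
  records <- records[ord, , drop = FALSE]
  chains <- chains[ord]

  cluster_once <- function(idx) {
    groups <- list()  # each: list(bsum, n, members=idx vector)
    for (i in idx) {
      b <- .chainBounds(chains[[i]])
      s <- .chainTxStart(chains[[i]], records$strand[i])
      placed <- FALSE
      for (k in seq_along(groups)) {
        rep_b <- groups[[k]]$bsum / groups[[k]]$n
        rep_ex <- data.frame(start = rep_b[c(TRUE, FALSE)],
                             end = rep_b[c(FALSE, TRUE)])
        rep_s <- .chainTxStart(rep_ex, records$strand[i])
        if (abs(s - rep_s) <= tol && all(abs(b - rep_b) <= tol)) {
          groups[[k]]$bsum <- groups[[k]]$bsum + b
          groups[[k]]$n <- groups[[k]]$n + 1L
          groups[[k]]$members <- c(groups[[k]]$members, i)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        groups[[length(groups) + 1L]] <- list(bsum = b, n = 1L,
                                              members = i)
      }
    }
    groups
  }

  out <- list()
  for (ne in sort(unique(records$.n_exons))) {
    idx <- which(records$.n_exons == ne)
    groups <- cluster_once(idx)
    # post-hoc validation against the final representative; violators are
    # split off and re-clustered
    final <- list()
    for (g in groups) {
      rep_b <- g$bsum / g$n
      ok <- vapply(g$members, function(i) {
        all(abs(.chainBounds(chains[[i]]) - rep_b) <= tol)
      }, logical(1))
      if (all(ok)) {
        final[[length(final) + 1L]] <- g
      } else {
        keep <- g$members[ok]
        if (length(keep)) {
          bs <- Reduce(`+`, lapply(keep, function(i)
            .chainBounds(chains[[i]])))
          final[[length(final) + 1L]] <- list(bsum = bs,
                                              n = length(keep),
                                              members = keep)
        }
        for (g2 in cluster_once(g$members[!ok])) {
          final[[length(final) + 1L]] <- g2
        }
      }
    }
    for (g in final) {
      rep_b <- floor(g$bsum / g$n + 0.5)  # half-up to integers
      rep_ex <- data.frame(start = as.integer(rep_b[c(TRUE, FALSE)]),
                           end = as.integer(rep_b[c(FALSE, TRUE)]))
      mem <- records[g$members, , drop = FALSE]
      mem$.n_exons <- NULL; mem$.gstart <- NULL
      rownames(mem) <- NULL
      out[[length(out) + 1L]] <- list(gene = records$gene[1],
                                      exon_count = ne,
                                      members = mem,
                                      representative = rep_ex)
    }
  }
  out
}

#' Group novel isoforms for every gene in a table
#'
#' Applies [groupNovelIsoforms()] per gene after restricting to novel
#' (NIC/NNIC) records.
#'
#' @param records isoform record data.frame (multiple genes allowed).
#' @param tol boundary tolerance in bp.
#' @return list of groups across genes.
#' @export
groupNovelIsoformsByGene <- function(records, tol = 100L) {
  records <- records[records$novelty %in% c("NIC", "NNIC"), , drop = FALSE]
  if (nrow(records) == 0L) return(list())
  unlist(lapply(split(records, records$gene), groupNovelIsoforms,
                tol = tol),
         recursive = FALSE, use.names = FALSE)
}

#' Most abundant novel structure per gene
#'
#' Per gene, the group with the most members; ties broken by the earliest
#' representative start coordinate.
#'
#' @param groups list of groups ([groupNovelIsoformsByGene()]).
#' @return named list (by gene) of the dominant group of each gene.
#' @export
dominantStructurePerGene <- function(groups) {
  if (length(groups) == 0L) return(list())
  genes <- vapply(groups, `[[`, "", "gene")
  out <- lapply(unique(genes), function(g) {
    gs <- groups[genes == g]
    n <- vapply(gs, function(x) nrow(x$members), 1L)
    st <- vapply(gs, function(x) min(x$representative$start), 1L)
    gs[[order(-n, st)[1]]]
  })
  names(out) <- unique(genes)
  out
}

#' Rank genes by number of distinct novel structures
#'
#' @param groups list of groups ([groupNovelIsoformsByGene()]).
#' @return data.frame gene, n_structures, n_isoforms, sorted by
#'   descending structure count then alphabetically.
#' @export
rankGenesByNovelStructures <- function(groups) {
  if (length(groups) == 0L) {
    return(data.frame(gene = character(), n_structures = integer(),
                      n_isoforms = integer()))
  }
  genes <- vapply(groups, `[[`, "", "gene")
  sizes <- vapply(groups, function(x) nrow(x$members), 1L)
  agg <- data.frame(gene = unique(genes),
                    n_structures = as.integer(table(genes)[unique(genes)]),
                    n_isoforms = as.integer(
                      tapply(sizes, genes, sum)[unique(genes)]),
                    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$n_structures, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
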