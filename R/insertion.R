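#' Collect anchored non-concordant candidate pairs
#'
#' Retains read pairs in which exactly one mate is mapped (the anchor), the
#' pair is non-concordant, and the unmapped mate classifies as an Alu read.
#' The unmapped mate's sequence carries the candidate insertion evidence.
#'
#' @param sam a \code{sam_records} data.frame ([read_sam()]).
#' @param index an [build_alu_index()] k-mer index.
#' @return data.frame with one row per qualifying pair: \code{read_id},
#'   anchor coordinates and orientation (\code{chrom}, \code{start},
#'   \code{end}, \code{strand}), and \code{mate_sequence}.
#' @export
collect_candidate_pairs <- function(sam, index) {
  out <- list()
  for (idx in split(seq_len(nrow(sam)), sam$read_id)) {
    rec <- sam[idx, ]
    if (nrow(rec) != 2L) next
    if (any(rec$is_concordant_pair)) next
    if (sum(rec$mapped) != 1L) next
    anchor <- rec[rec$mapped, ]
    mate <- rec[!rec$mapped, ]
    if (!classify_read(mate$sequence, index)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = anchor$read_id, chrom = anchor$chrom,
      start = anchor$start, end = anchor$end, strand = anchor$strand,
      mate_sequence = mate$sequence, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_candidate_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_candidate_table <- function() {
  data.frame(read_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(),
             mate_sequence = character(), stringsAsFactors = FALSE)
}

#' Assign anchors to overlapping annotated exons
#'
#' Anchors overlapping no annotated exon are dropped (they cannot be tied to
#' a known gene); an anchor overlapping several exons is assigned to each,
#' flagged \code{multi}.
#'
#' @param pairs output of [collect_candidate_pairs()].
#' @param annotation exon table ([read_gtf()]) providing gene ids.
#' @return \code{pairs} expanded per overlapped exon, with
#'   \code{gene_id}, \code{exon_start}, \code{exon_end} and \code{multi}.
#' @export
anchor_to_exons <- function(pairs, annotation) {
  if (nrow(pairs) == 0L) {
    pairs$gene_id <- character(); pairs$exon_start <- integer()
    pairs$exon_end <- integer(); pairs$multi <- logical()
    return(pairs)
  }
  ex <- annotation[!duplicated(annotation[, c("chrom", "start", "end",
                                              "gene_id")]), , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(gi_to_granges(pairs),
                                      gi_to_granges(ex),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) {
    out <- pairs[0L, ]
    out$gene_id <- character(); out$exon_start <- integer()
    out$exon_end <- integer(); out$multi <- logical()
    return(out)
  }
  out <- pairs[qi, , drop = FALSE]
  out$gene_id <- ex$gene_id[si]
  out$exon_start <- ex$start[si]
  out$exon_end <- ex$end[si]
  nhit <- table(qi)
  out$multi <- as.integer(nhit[as.character(qi)]) > 1L
  rownames(out) <- NULL
  out
}

#' Signal test on a spliced-alignment result
#'
#' A match is a signal iff it explains at least 80\% of the read, has
#' strictly more than 80\% identity, and covers 10 or more Alu bases.
#'
#' @param result a [spliced_align()] result.
#' @param min_coverage,min_identity,min_alu_bases the three cutoffs
#'   (coverage and Alu bases inclusive, identity strict).
#' @return logical.
#' @export
signal_test <- function(result, min_coverage = 0.80, min_identity = 0.80,
                        min_alu_bases = 10L) {
  result$query_coverage >= min_coverage &&
    result$identity > min_identity &&
    result$alu_bases >= min_alu_bases
}

#' Shadow test: is the read explained by local genomic sequence?
#'
#' Two searches, either of which flags the read as a shadow: the
#' \emph{unspliced} test against 500 bp intronic windows flanking the anchor
#' exon on both sides (unprocessed pre-mRNA), and the \emph{region} test
#' against the genomic stretch between and including the anchor exon and the
#' farther of its two neighbouring annotated exons (a local Alu copy). A
#' local alignment covering at least 80\% of the read at 93\% identity or
#' higher (both inclusive) is deemed real.
#'
#' @param query the unmapped mate's sequence (both orientations are tried).
#' @param anchor_exon list/row with \code{chrom}, \code{start}, \code{end}.
#' @param gene_exons annotated exons of the anchor gene (data.frame).
#' @param genome named character vector of chromosome sequences.
#' @param window intronic window width (default 500 bp); truncated at
#'   contig edges.
#' @param min_coverage,min_identity shadow cutoffs (defaults 0.80 / 0.93).
#' @return logical.
#' @export
shadow_test <- function(query, anchor_exon, gene_exons, genome,
                        window = 500L, min_coverage = 0.80,
                        min_identity = 0.93) {
  chrom_seq <- genome[[anchor_exon$chrom]]
  clen <- nchar(chrom_seq)
  targets <- character()
  ws <- max(1L, anchor_exon$start - window)
  if (ws <= anchor_exon$start - 1L)
    targets <- c(targets, substr(chrom_seq, ws, anchor_exon$start - 1L))
  we <- min(clen, anchor_exon$end + window)
  if (we >= anchor_exon$end + 1L)
    targets <- c(targets, substr(chrom_seq, anchor_exon$end + 1L, we))
  ## region test: anchor exon to the farther neighbouring exon, inclusive
  others <- gene_exons[gene_exons$chrom == anchor_exon$chrom &
                         (gene_exons$end < anchor_exon$start |
                            gene_exons$start > anchor_exon$end), ,
                       drop = FALSE]
  if (nrow(others)) {
    up <- others[others$end < anchor_exon$start, , drop = FALSE]
    dn <- others[others$start > anchor_exon$end, , drop = FALSE]
    prev_exon <- if (nrow(up)) up[which.max(up$end), ] else NULL
    next_exon <- if (nrow(dn)) dn[which.min(dn$start), ] else NULL
    dist_prev <- if (!is.null(prev_exon))
      anchor_exon$start - prev_exon$end else -Inf
    dist_next <- if (!is.null(next_exon))
      next_exon$start - anchor_exon$end else -Inf
    far <- if (dist_prev >= dist_next) prev_exon else next_exon
    if (!is.null(far)) {
      rs <- min(anchor_exon$start, far$start)
      re <- max(anchor_exon$end, far$end)
      targets <- c(targets, substr(chrom_seq, max(1L, rs), min(clen, re)))
    }
  }
  for (tg in targets) {
    if (!nzchar(tg)) next
    for (qs in c(query, revcomp(query))) {
      r <- local_align(qs, tg)
      if (r$query_coverage >= min_coverage && r$identity >= min_identity)
        return(TRUE)
    }
  }
  FALSE
}

#' Read category from the signal and shadow verdicts
#'
#' S: signal and not shadow. RU: shadow and not signal. SRU: both.
#' none: neither. The hybrid SN pool counts S together with none.
#'
#' @param signal,shadow logical vectors.
#' @return character vector over {S, RU, SRU, none}.
#' @export
categorize_mate <- function(signal, shadow) {
  ifelse(signal & !shadow, "S",
         ifelse(!signal & shadow, "RU",
                ifelse(signal & shadow, "SRU", "none")))
}

#' Single-linkage clustering of anchor reads
#'
#' Anchors are clustered by genomic overlap, separately per (orientation,
#' category); a cluster's interval is the union span of its members.
#'
#' @param records data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (anchor match orientation) and \code{category}.
#' @return list with \code{clusters} (data.frame: cluster_id, chrom, start,
#'   end, orientation, category, n_reads) and \code{assignment} (cluster_id
#'   per input row).
#' @export
cluster_anchors <- function(records) {
  assignment <- character(nrow(records))
  clusters <- list()
  grp <- paste(records$chrom, records$strand, records$category)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    r <- records[idx, ]
    red <- IRanges::reduce(IRanges::IRanges(r$start, r$end))
    ov <- IRanges::findOverlaps(IRanges::IRanges(r$start, r$end), red)
    cid <- paste0(r$chrom[1L], ":", IRanges::start(red), "-",
                  IRanges::end(red), "/", r$strand[1L], "/", r$category[1L])
    assignment[idx] <- cid[S4Vectors::subjectHits(ov)]
    clusters[[length(clusters) + 1L]] <- data.frame(
      cluster_id = cid, chrom = r$chrom[1L],
      start = IRanges::start(red), end = IRanges::end(red),
      orientation = r$strand[1L], category = r$category[1L],
      n_reads = as.integer(table(S4Vectors::subjectHits(ov))[
        as.character(seq_along(red))]),
      stringsAsFactors = FALSE)
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters)
    else data.frame(cluster_id = character(), chrom = character(),
                    start = integer(), end = integer(),
                    orientation = character(), category = character(),
                    n_reads = integer(), stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  list(clusters = clusters, assignment = assignment)
}

#' Context filter over vicinity read counts
#'
#' Let s, sn, ru, sru count the reads in the S, SN, RU and SRU clusters of a
#' vicinity. The vicinity passes iff all five hold: s >= MIN_SIGNALS;
#' sn >= MIN_SIGNALNONE; s/sn >= MIN_S2SN; s/sru >= MIN_S2SRU;
#' s/ru >= MIN_S2RU. Ratios with zero denominator are +Inf and satisfy
#' their condition. The defaults are the calibration optimum (2, 5, 0, 2,
#' 0.5).
#'
#' @param s,sn,ru,sru non-negative counts (vectorized).
#' @param params named list/vector with \code{min_signals},
#'   \code{min_signalnone}, \code{min_s2sn}, \code{min_s2sru},
#'   \code{min_s2ru}.
#' @return logical vector.
#' @export
context_filter <- function(s, sn, ru, sru, params = default_context_params()) {
  p <- as.list(params)
  ratio <- function(num, den) ifelse(den == 0, Inf, num / den)
  s >= p$min_signals &
    sn >= p$min_signalnone &
    ratio(s, sn) >= p$min_s2sn &
    ratio(s, sru) >= p$min_s2sru &
    ratio(s, ru) >= p$min_s2ru
}

#' Default context-filter parameters (the calibration optimum)
#' @return named list (2, 5, 0, 2, 0.5).
#' @export
default_context_params <- function() {
  list(min_signals = 2, min_signalnone = 5, min_s2sn = 0,
       min_s2sru = 2, min_s2ru = 0.5)
}

#' Infer insertion intervals from the clusters of a vicinity
#'
#' For each S cluster, the insertion interval runs from the S cluster
#' boundary to the boundary of the closest cluster in the opposing
#' orientation on the side the anchor points to, or to the end of the gene
#' if no opposing cluster exists there.
#'
#' @param clusters cluster table from [cluster_anchors()].
#' @param gene_span list/row with \code{start}, \code{end} of the gene.
#' @return data.frame with one row per S cluster: \code{cluster_id},
#'   \code{start}, \code{end} of the inferred interval.
#' @export
infer_insertion_interval <- function(clusters, gene_span) {
  s_clusters <- clusters[clusters$category == "S", , drop = FALSE]
  if (nrow(s_clusters) == 0L)
    stop("no S cluster in vicinity: precondition violated")
  out <- lapply(seq_len(nrow(s_clusters)), function(i) {
    sc <- s_clusters[i, ]
    opp <- clusters[clusters$orientation != sc$orientation, , drop = FALSE]
    if (sc$orientation == "+") {
      cand <- opp[opp$start >= sc$end, , drop = FALSE]
      to <- if (nrow(cand)) min(cand$start) else gene_span$end
      data.frame(cluster_id = sc$cluster_id, start = sc$end, end = to,
                 stringsAsFactors = FALSE)
    } else {
      cand <- opp[opp$end <= sc$start, , drop = FALSE]
      from <- if (nrow(cand)) max(cand$end) else gene_span$start
      data.frame(cluster_id = sc$cluster_id, start = from, end = sc$start,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  res$start <- pmin(res$start, res$end)
  rownames(res) <- NULL
  res
}
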