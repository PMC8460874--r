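#' Exon / Alu overlap enumeration
#'
#' Every (exon, Alu) pair with at least 1 bp of overlap, reported once per
#' transcript. Overlap is computed on inclusive coordinates ignoring strand
#' (the antisense requirement is applied later, in [filter_candidates()]).
#'
#' @param tx transcript exon table ([read_gtf()]).
#' @param alus Alu annotation table ([read_repeatmasker()]).
#' @return data.frame with one row per overlapping pair: exon coordinates and
#'   transcript context (rank, total exon count, neighbouring exon bounds)
#'   plus the overlapped Alu locus.
#' @export
find_alu_overlapping_exons <- function(tx, alus) {
  if (nrow(tx) == 0L || nrow(alus) == 0L) return(empty_pair_table())
  n_ex <- stats::ave(rep(1L, nrow(tx)), tx$transcript_id, FUN = sum)
  ord <- order(tx$transcript_id, tx$start)
  prev_end <- next_start <- rep(NA_integer_, nrow(tx))
  sp <- split(ord, tx$transcript_id[ord])
  for (idx in sp) {
    if (length(idx) > 1L) {
      prev_end[idx[-1L]] <- tx$end[idx[-length(idx)]]
      next_start[idx[-length(idx)]] <- tx$start[idx[-1L]]
    }
  }
  hits <- GenomicRanges::findOverlaps(gi_to_granges(tx), gi_to_granges(alus),
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(
    chrom = tx$chrom[qi], exon_start = tx$start[qi], exon_end = tx$end[qi],
    transcript_id = tx$transcript_id[qi], gene_id = tx$gene_id[qi],
    tx_strand = tx$strand[qi], exon_rank = tx$exon_rank[qi],
    n_exons = as.integer(n_ex[qi]),
    prev_exon_end = prev_end[qi], next_exon_start = next_start[qi],
    alu_start = alus$start[si], alu_end = alus$end[si],
    alu_strand = alus$strand[si], alu_subfamily = alus$subfamily[si],
    alu_family_class = alus$family_class[si],
    stringsAsFactors = FALSE)
}

empty_pair_table <- function() {
  data.frame(chrom = character(), exon_start = integer(),
             exon_end = integer(), transcript_id = character(),
             gene_id = character(), tx_strand = character(),
             exon_rank = integer(), n_exons = integer(),
             prev_exon_end = integer(), next_exon_start = integer(),
             alu_start = integer(), alu_end = integer(),
             alu_strand = character(), alu_subfamily = character(),
             alu_family_class = character(), stringsAsFactors = FALSE)
}

#' Filter exon/Alu pairs to candidate Alu exonization calls
#'
#' A pair is retained iff (i) the exon is internal to its transcript (has
#' both an upstream and a downstream exon), (ii) the Alu is antisense to the
#' transcript orientation, and (iii) the exon length L satisfies
#' \code{min_len < L < max_len} (strict bounds, default 40/400). Pairs from
#' unstranded transcripts cannot be tested for antisense orientation and are
#' dropped; their number is recorded in attribute \code{"skipped_unstranded"}.
#'
#' @param pairs output of [find_alu_overlapping_exons()].
#' @param min_len,max_len exclusive exon length bounds in bp.
#' @param sample optional sample id stamped on every call.
#' @return data.frame of calls (class \code{"alu_exon_calls"}): exon locus,
#'   gene, Alu locus, reading-frame class \code{frame = L mod 3}, and the
#'   flanking-intron coordinates implied by the transcript context.
#' @export
filter_candidates <- function(pairs, min_len = 40L, max_len = 400L,
                              sample = NA_character_) {
  unstranded <- !(pairs$tx_strand %in% c("+", "-"))
  p <- pairs[!unstranded, , drop = FALSE]
  len <- p$exon_end - p$exon_start + 1L
  keep <- p$exon_rank > 1L & p$exon_rank < p$n_exons &       # i) internal
    p$alu_strand == flip_strand(p$tx_strand) &               # ii) antisense
    len > min_len & len < max_len                            # iii) bounds
  p <- p[keep, , drop = FALSE]
  len <- len[keep]
  out <- data.frame(
    chrom = p$chrom, start = p$exon_start, end = p$exon_end,
    gene_id = p$gene_id, transcript_id = p$transcript_id,
    tx_strand = p$tx_strand, length = len, frame = as.integer(len %% 3L),
    alu_start = p$alu_start, alu_end = p$alu_end,
    alu_strand = p$alu_strand, alu_subfamily = p$alu_subfamily,
    alu_family_class = p$alu_family_class,
    iLeft_start = p$prev_exon_end + 1L, iLeft_end = p$exon_start - 1L,
    iRight_start = p$exon_end + 1L, iRight_end = p$next_exon_start - 1L,
    sample = rep_len(sample, nrow(p)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_unstranded") <- sum(unstranded)
  structure(out, class = c("alu_exon_calls", "data.frame"))
}

#' Merge per-sample Alu exon calls into a locus table
#'
#' Calls with identical exon coordinates merge into one row; distinct exon
#' coordinates over the same Alu locus stay distinct rows sharing a
#' \code{locus_id}. An exon is \code{known} iff its coordinates exactly match
#' an annotated exon.
#'
#' @param per_sample_calls named list (sample id -> calls data.frame from
#'   [filter_candidates()]), or a single calls data.frame with a
#'   \code{sample} column.
#' @param reference_exons annotation exon table used for the known/novel
#'   split (may be NULL: everything is novel).
#' @return data.frame with one row per distinct exon: \code{exon_id},
#'   \code{locus_id} (the Alu locus), supporting samples
#'   (\code{samples}, comma-separated; \code{n_samples}), and \code{known}.
#' @export
merge_across_samples <- function(per_sample_calls, reference_exons = NULL) {
  if (is.data.frame(per_sample_calls)) {
    calls <- per_sample_calls
  } else {
    calls <- do.call(rbind, lapply(names(per_sample_calls), function(s) {
      d <- per_sample_calls[[s]]
      if (nrow(d)) d$sample <- s
      d
    }))
  }
  if (is.null(calls) || nrow(calls) == 0L)
    return(data.frame(exon_id = character(), locus_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      frame = integer(), alu_subfamily = character(),
                      alu_family_class = character(), known = logical(),
                      samples = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  exon_key <- paste0(calls$chrom, ":", calls$start, "-", calls$end)
  locus_key <- paste0(calls$chrom, ":", calls$alu_start, "-", calls$alu_end)
  key <- paste(exon_key, locus_key)
  known_keys <- if (!is.null(reference_exons) && nrow(reference_exons))
    unique(paste0(reference_exons$chrom, ":", reference_exons$start, "-",
                  reference_exons$end)) else character()
  idx <- split(seq_len(nrow(calls)), key)
  rows <- lapply(idx, function(i) {
    first <- i[1L]
    data.frame(
      exon_id = exon_key[first], locus_id = locus_key[first],
      chrom = calls$chrom[first], start = calls$start[first],
      end = calls$end[first], gene_id = calls$gene_id[first],
      frame = calls$frame[first],
      alu_subfamily = calls$alu_subfamily[first],
      alu_family_class = calls$alu_family_class[first],
      known = exon_key[first] %in% known_keys,
      samples = paste(sort(unique(calls$sample[i])), collapse = ","),
      n_samples = length(unique(calls$sample[i])),
      iLeft_start = calls$iLeft_start[first],
      iLeft_end = calls$iLeft_end[first],
      iRight_start = calls$iRight_start[first],
      iRight_end = calls$iRight_end[first],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescue per-sample support from flanking-intron read counts
#'
#' Transcript assembly can miss a lowly expressed Alu exon in a sample even
#' when its two flanking splice junctions have read support there. This
#' relaxation adds a sample to an exon's support set iff \emph{both} flanking
#' introns have at least \code{min_reads} spliced reads in that sample.
#'
#' @param locus_table output of [merge_across_samples()].
#' @param junction_counts data.frame from [count_junction_reads()]
#'   (columns chrom, start, end, sample, count).
#' @param min_reads minimum spliced-read count per flanking intron
#'   (default 1).
#' @return \code{locus_table} with added columns
#'   \code{intron_support_samples}, \code{n_intron_samples} and
#'   \code{no_flanking_introns} (flag for exons lacking a known intron
#'   context, which are left unchanged).
#' @export
rescue_by_intron_support <- function(locus_table, junction_counts,
                                     min_reads = 1L) {
  jkey <- paste0(junction_counts$chrom, ":", junction_counts$start, "-",
                 junction_counts$end)
  lookup <- function(chrom, s, e, sample) {
    i <- jkey == paste0(chrom, ":", s, "-", e) &
      junction_counts$sample == sample
    if (any(i)) sum(junction_counts$count[i]) else 0
  }
  samples <- unique(junction_counts$sample)
  res <- character(nrow(locus_table))
  flag <- logical(nrow(locus_table))
  for (r in seq_len(nrow(locus_table))) {
    row <- locus_table[r, ]
    if (is.na(row$iLeft_start) || is.na(row$iRight_end) ||
        row$iLeft_end < row$iLeft_start || row$iRight_end < row$iRight_start) {
      flag[r] <- TRUE
      res[r] <- ""
      next
    }
    ok <- vapply(samples, function(s) {
      lookup(row$chrom, row$iLeft_start, row$iLeft_end, s) >= min_reads &&
        lookup(row$chrom, row$iRight_start, row$iRight_end, s) >= min_reads
    }, logical(1L))
    res[r] <- paste(sort(samples[ok]), collapse = ",")
  }
  locus_table$intron_support_samples <- res
  locus_table$n_intron_samples <- ifelse(nzchar(res),
                                         lengths(strsplit(res, ",")), 0L)
  locus_table$no_flanking_introns <- flag
  locus_table
}

#' One-call driver for the fixed-exonization arm
#'
#' Runs overlap enumeration, the three candidate filters and the
#' cross-sample merge over a set of per-sample transcript GTFs.
#'
#' @param transcript_paths named character vector (sample id -> GTF path).
#' @param alus Alu annotation table.
#' @param annotation reference exon table for the known/novel split
#'   (optional).
#' @param min_len,max_len exon length bounds (see [filter_candidates()]).
#' @return locus table as from [merge_across_samples()].
#' @export
detect_fixed_exons <- function(transcript_paths, alus, annotation = NULL,
                               min_len = 40L, max_len = 400L) {
  calls <- lapply(names(transcript_paths), function(s) {
    tx <- read_gtf(transcript_paths[[s]])
    filter_candidates(find_alu_overlapping_exons(tx, alus),
                      min_len = min_len, max_len = max_len, sample = s)
  })
  names(calls) <- names(transcript_paths)
  merge_across_samples(calls, annotation)
}
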