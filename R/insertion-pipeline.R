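#' Score all vicinities: signal/shadow classification and clustering
#'
#' Runs the front half of the non-reference insertion caller: candidate-pair
#' extraction, exon anchoring, spliced signal alignment against the
#' exon–Alu–exon concatenations (both Alu orientations and both flank
#' concatenations tried, best kept), the unspliced/region shadow tests,
#' category assignment and per-(orientation, category) clustering, one
#' vicinity per gene. The per-vicinity counts can then be re-filtered under
#' any context-parameter tuple without re-alignment (see [grid_search()]).
#'
#' @param sam \code{sam_records} data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param annotation exon table with gene ids.
#' @param alu_consensus Alu consensus sequence (character scalar).
#' @param index optional prebuilt [build_alu_index()]; by default built from
#'   the consensus (plus genomic Alu instances when \code{alus} is given).
#' @param alus optional Alu annotation table; instance sequences are added
#'   to the classifier library and used for the repeat-rich flag.
#' @param window shadow-test intronic window (bp).
#' @return list with \code{counts} (data.frame gene_id, s, sn, ru, sru),
#'   \code{clusters} (per-gene cluster tables), \code{records} (classified
#'   mate records).
#' @export
score_vicinities <- function(sam, genome, annotation, alu_consensus,
                             index = NULL, alus = NULL, window = 500L) {
  if (is.null(index)) {
    lib <- c(consensus = unname(alu_consensus))
    if (!is.null(alus) && nrow(alus)) {
      inst <- vapply(seq_len(nrow(alus)), function(i)
        substr(genome[[alus$chrom[i]]], alus$start[i], alus$end[i]), "")
      k <- 31L
      lib <- c(lib, inst[nchar(inst) >= k])
    }
    index <- build_alu_index(lib)
  }
  pairs <- collect_candidate_pairs(sam, index)
  anch <- anchor_to_exons(pairs, annotation)
  genes <- unique(anch$gene_id)
  cons_rc <- if (nzchar(alu_consensus)) revcomp(alu_consensus) else ""
  counts <- list(); clusters <- list(); records <- list()
  for (g in genes) {
    grows <- anch[anch$gene_id == g, , drop = FALSE]
    gex <- annotation[annotation$gene_id == g, , drop = FALSE]
    gex <- gex[!duplicated(gex[, c("start", "end")]), , drop = FALSE]
    chrom_seq <- genome[[grows$chrom[1L]]]
    ## a read overlapping several exons is tested in every exon context but
    ## counted once per vicinity
    rows <- grows[!duplicated(grows$read_id), , drop = FALSE]
    sig <- shd <- logical(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      contexts <- grows[grows$read_id == rows$read_id[i], , drop = FALSE]
      best <- NULL
      shadow <- FALSE
      for (ci in seq_len(nrow(contexts))) {
        r <- contexts[ci, ]
        anchor_seq <- substr(chrom_seq, r$exon_start, r$exon_end)
        up <- gex[gex$end < r$exon_start, , drop = FALSE]
        dn <- gex[gex$start > r$exon_end, , drop = FALSE]
        prev_seq <- if (nrow(up)) {
          p <- up[which.max(up$end), ]; substr(chrom_seq, p$start, p$end)
        } else NULL
        next_seq <- if (nrow(dn)) {
          p <- dn[which.min(dn$start), ]; substr(chrom_seq, p$start, p$end)
        } else NULL
        targets <- list()
        for (cons in c(alu_consensus, cons_rc)) {
          t1 <- c(exon = anchor_seq, Alu = cons)
          if (!is.null(next_seq)) t1 <- c(t1, exon2 = next_seq)
          targets[[length(targets) + 1L]] <- t1
          if (!is.null(prev_seq))
            targets[[length(targets) + 1L]] <-
              c(exon0 = prev_seq, Alu = cons, exon = anchor_seq)
        }
        for (tg in targets) {
          res <- spliced_align(r$mate_sequence, tg)
          if (is.null(best) || res$score > best$score) best <- res
        }
        shadow <- shadow ||
          shadow_test(r$mate_sequence,
                      list(chrom = r$chrom, start = r$exon_start,
                           end = r$exon_end),
                      gex, genome, window = window)
      }
      sig[i] <- signal_test(best)
      shd[i] <- shadow
    }
    rows$category <- categorize_mate(sig, shd)
    cl <- cluster_anchors(rows)
    s <- sum(rows$category == "S")
    counts[[g]] <- data.frame(
      gene_id = g, s = s,
      sn = s + sum(rows$category == "none"),
      ru = sum(rows$category == "RU"),
      sru = sum(rows$category == "SRU"), stringsAsFactors = FALSE)
    clusters[[g]] <- cl$clusters
    rows$cluster_id <- cl$assignment
    records[[g]] <- rows
  }
  counts <- if (length(counts)) do.call(rbind, counts)
    else data.frame(gene_id = character(), s = integer(), sn = integer(),
                    ru = integer(), sru = integer(), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(counts = counts, clusters = clusters, records = records)
}

#' Call non-reference Alu insertions
#'
#' Full caller: scores vicinities ([score_vicinities()]), applies the
#' five-condition context filter, and infers one insertion interval per S
#' cluster in each passing vicinity. A call is flagged repeat-rich when more
#' than \code{repeat_rich_frac} of its interval is covered by annotated
#' repeats.
#'
#' @inheritParams score_vicinities
#' @param params context-filter cutoffs ([default_context_params()]).
#' @param repeat_rich_frac covered-fraction threshold for the repeat-rich
#'   flag (default 0.5).
#' @return data.frame of insertion calls: \code{gene_id}, counts
#'   \code{s}/\code{sn}/\code{ru}/\code{sru}, the inferred
#'   \code{interval_start}/\code{interval_end} (clipped to the gene span),
#'   \code{repeat_rich}, and supporting \code{read_ids}. The vicinity count
#'   table is attached as attribute \code{"vicinities"}.
#' @export
call_insertions <- function(sam, genome, annotation, alu_consensus,
                            index = NULL, alus = NULL,
                            params = default_context_params(),
                            repeat_rich_frac = 0.5, window = 500L) {
  sc <- score_vicinities(sam, genome, annotation, alu_consensus,
                         index = index, alus = alus, window = window)
  counts <- sc$counts
  calls <- list()
  if (nrow(counts)) {
    pass <- context_filter(counts$s, counts$sn, counts$ru, counts$sru,
                           params)
    for (i in which(pass & counts$s > 0)) {
      g <- counts$gene_id[i]
      gex <- annotation[annotation$gene_id == g, , drop = FALSE]
      span <- list(start = min(gex$start), end = max(gex$end))
      iv <- infer_insertion_interval(sc$clusters[[g]], span)
      iv$start <- pmax(iv$start, span$start)
      iv$end <- pmin(iv$end, span$end)
      rr <- FALSE
      if (!is.null(alus) && nrow(alus)) {
        chrom <- gex$chrom[1L]
        rr <- vapply(seq_len(nrow(iv)), function(r) {
          a <- alus[alus$chrom == chrom, , drop = FALSE]
          if (!nrow(a)) return(FALSE)
          ov <- IRanges::intersect(
            IRanges::IRanges(iv$start[r], iv$end[r]),
            IRanges::reduce(IRanges::IRanges(a$start, a$end)))
          sum(IRanges::width(ov)) / (iv$end[r] - iv$start[r] + 1L) >
            repeat_rich_frac
        }, logical(1L))
      }
      calls[[length(calls) + 1L]] <- data.frame(
        gene_id = g, s = counts$s[i], sn = counts$sn[i], ru = counts$ru[i],
        sru = counts$sru[i], cluster_id = iv$cluster_id,
        interval_start = iv$start, interval_end = iv$end,
        repeat_rich = rr,
        read_ids = paste(sc$records[[g]]$read_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, calls)
    else data.frame(gene_id = character(), s = integer(), sn = integer(),
                    ru = integer(), sru = integer(), cluster_id = character(),
                    interval_start = integer(), interval_end = integer(),
                    repeat_rich = logical(), read_ids = character(),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "vicinities") <- counts
  out
}
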