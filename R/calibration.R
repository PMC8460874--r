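#' Excise Alu elements from a genome and lift the annotation
#'
#' Builds the simulation reference for calibration: each selected Alu span
#' is deleted from the sequence, all downstream annotation coordinates shift
#' left by the cumulative deleted length, and the genes whose spans
#' contained an excised Alu form the gold-standard set the caller is scored
#' against. Alus overlapping an annotated exon are excluded from excision
#' with a warning (deleting expressed exonic sequence would corrupt the
#' transcript models rather than simulate a missing insertion).
#'
#' @param genome named character vector of chromosome sequences.
#' @param alus_to_remove Alu annotation table (non-overlapping records).
#' @param annotation exon table to lift.
#' @return list with \code{genome} (modified), \code{annotation} (lifted),
#'   and \code{plan}: \code{excised_alus}, per-chromosome shift tables, and
#'   \code{gold_genes}.
#' @export
excise_alus <- function(genome, alus_to_remove, annotation) {
  a <- alus_to_remove[order(alus_to_remove$chrom, alus_to_remove$start), ,
                      drop = FALSE]
  for (ch in unique(a$chrom)) {
    x <- a[a$chrom == ch, ]
    if (nrow(x) > 1L && any(x$start[-1L] <= x$end[-nrow(x)]))
      stop("excision targets overlap on ", ch)
  }
  if (nrow(annotation)) {
    hits <- GenomicRanges::findOverlaps(gi_to_granges(a),
                                        gi_to_granges(annotation),
                                        ignore.strand = TRUE)
    exonic <- unique(S4Vectors::queryHits(hits))
    if (length(exonic)) {
      warning(length(exonic),
              " Alu(s) overlapping annotated exons excluded from excision")
      a <- a[-exonic, , drop = FALSE]
    }
  }
  new_genome <- genome
  shift_tables <- list()
  for (ch in unique(a$chrom)) {
    x <- a[a$chrom == ch, ]
    seq <- genome[[ch]]
    keep <- character()
    prev <- 1L
    for (i in seq_len(nrow(x))) {
      keep <- c(keep, substr(seq, prev, x$start[i] - 1L))
      prev <- x$end[i] + 1L
    }
    keep <- c(keep, substr(seq, prev, nchar(seq)))
    new_genome[[ch]] <- paste(keep, collapse = "")
    shift_tables[[ch]] <- data.frame(
      start = x$start, end = x$end,
      cum_removed = cumsum(x$end - x$start + 1L))
  }
  plan <- list(excised_alus = a, shift_tables = shift_tables)
  lifted <- annotation
  if (nrow(lifted)) {
    lifted$start <- shift_position(plan, lifted$chrom, lifted$start)
    lifted$end <- shift_position(plan, lifted$chrom, lifted$end)
  }
  gold <- character()
  if (nrow(annotation)) {
    for (g in unique(annotation$gene_id)) {
      gx <- annotation[annotation$gene_id == g, ]
      span_hit <- any(a$chrom == gx$chrom[1L] &
                        a$start >= min(gx$start) & a$end <= max(gx$end))
      if (span_hit) gold <- c(gold, g)
    }
  }
  plan$gold_genes <- gold
  list(genome = new_genome, annotation = lifted, plan = plan)
}

#' Map an original coordinate onto the excised genome (and back)
#'
#' The shift at position p is the cumulative length of excisions lying
#' entirely upstream of p. \code{invert = TRUE} maps an excised-genome
#' coordinate back to the original; applying one after the other is the
#' identity for positions outside excised spans.
#'
#' @param plan the \code{plan} component of [excise_alus()].
#' @param chrom,pos vectors of coordinates.
#' @param invert map from excised back to original coordinates.
#' @return integer vector of mapped positions.
#' @export
shift_position <- function(plan, chrom, pos, invert = FALSE) {
  out <- as.integer(pos)
  for (ch in unique(chrom)) {
    st <- plan$shift_tables[[ch]]
    if (is.null(st)) next
    i <- chrom == ch
    if (!invert) {
      shift <- vapply(pos[i], function(p)
        if (any(st$end < p)) st$cum_removed[max(which(st$end < p))] else 0L,
        numeric(1L))
      out[i] <- as.integer(pos[i] - shift)
    } else {
      new_end <- st$end - st$cum_removed  # excision points in new coords
      shift <- vapply(pos[i], function(p)
        if (any(new_end < p)) st$cum_removed[max(which(new_end < p))]
        else 0L, numeric(1L))
      out[i] <- as.integer(pos[i] + shift)
    }
  }
  out
}

#' Score predicted insertion genes against the gold set
#'
#' TP = |predicted intersect gold|, FP = |predicted \ gold|;
#' Sn = TP / |gold|, Pr = TP / (TP + FP), F = 2 Sn Pr / (Sn + Pr)
#' (0 when Sn + Pr = 0), Acc = (Sn + Pr) / 2.
#'
#' @param predicted_genes,gold_genes character vectors of gene ids.
#' @return one-row data.frame with tp, fp, sn, pr, f_value, acc.
#' @export
evaluate_predictions <- function(predicted_genes, gold_genes) {
  if (!length(gold_genes)) stop("empty gold-standard set")
  predicted_genes <- unique(predicted_genes)
  gold_genes <- unique(gold_genes)
  tp <- length(intersect(predicted_genes, gold_genes))
  fp <- length(setdiff(predicted_genes, gold_genes))
  sn <- tp / length(gold_genes)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (sn + pr > 0) 2 * sn * pr / (sn + pr) else 0
  data.frame(tp = tp, fp = fp, sn = sn, pr = pr, f_value = f,
             acc = (sn + pr) / 2)
}

#' The calibration parameter grid
#'
#' MIN_SIGNALS in {1, 2}; MIN_SIGNALNONE in 1..10; MIN_S2SN in 0..0.5 by
#' 0.1; MIN_S2SRU in 0..2 by 0.5; MIN_S2RU in {0, 0.05, 0.1, 0.15, 0.2,
#' 0.25, 0.5} — 4,200 tuples.
#'
#' @return named list of parameter value vectors.
#' @export
default_calibration_grid <- function() {
  list(min_signals = c(1, 2),
       min_signalnone = 1:10,
       min_s2sn = seq(0, 0.5, by = 0.1),
       min_s2sru = seq(0, 2, by = 0.5),
       min_s2ru = c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.5))
}

#' Grid search over the context-filter parameters
#'
#' The vicinity count table is computed once (alignment and classification
#' are parameter-independent); each tuple only re-applies the arithmetic
#' filter and is scored against the gold set. Ranked by F-value, ties
#' broken by precision then sensitivity.
#'
#' @param counts vicinity count table (gene_id, s, sn, ru, sru) as from
#'   [score_vicinities()].
#' @param gold_genes gold-standard gene ids.
#' @param grid named list of parameter vectors
#'   ([default_calibration_grid()]).
#' @return data.frame with one row per tuple: the five parameters plus tp,
#'   fp, sn, pr, f_value, acc, sorted best-first.
#' @export
grid_search <- function(counts, gold_genes, grid = default_calibration_grid()) {
  if (!length(grid) || !all(lengths(grid) > 0L)) stop("empty parameter grid")
  tuples <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(tuples)), function(i) {
    p <- as.list(tuples[i, ])
    pass <- context_filter(counts$s, counts$sn, counts$ru, counts$sru, p)
    cbind(tuples[i, , drop = FALSE],
          evaluate_predictions(counts$gene_id[pass], gold_genes))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$f_value, -out$pr, -out$sn), , drop = FALSE]
  rownames(out) <- NULL
  out
}
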