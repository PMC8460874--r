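## Isoform block structures for the read simulator: each isoform is a list
## of blocks (genomic span or novel insert) with transcript-coordinate
## bookkeeping.
build_isoforms <- function(ls, gid) {
  tx <- ls$transcripts
  out <- list()
  for (tid in unique(tx$transcript_id[tx$gene_id == gid])) {
    e <- tx[tx$transcript_id == tid, , drop = FALSE]
    e <- e[order(e$start), ]
    blocks <- data.frame(gstart = e$start, gend = e$end, novel = FALSE,
                         stringsAsFactors = FALSE)
    blocks$seq <- vapply(seq_len(nrow(blocks)), function(i)
      substr(ls$genome[[e$chrom[1L]]], blocks$gstart[i], blocks$gend[i]), "")
    out[[tid]] <- list(id = tid, chrom = e$chrom[1L], blocks = blocks)
  }
  nv <- ls$novel[[gid]]
  if (!is.null(nv)) {
    base <- out[[1L]]
    b <- base$blocks
    k <- nv$after_exon
    ins <- data.frame(gstart = NA_integer_, gend = NA_integer_,
                      novel = TRUE, seq = nv$sequence,
                      stringsAsFactors = FALSE)
    blocks <- rbind(b[seq_len(k), ], ins,
                    b[seq(k + 1L, nrow(b)), ])
    out[[paste0(base$id, ".novel")]] <-
      list(id = paste0(base$id, ".novel"), chrom = base$chrom,
           blocks = blocks)
  }
  for (nm in names(out)) {
    b <- out[[nm]]$blocks
    w <- nchar(b$seq)
    b$tend <- cumsum(w); b$tstart <- b$tend - w + 1L
    out[[nm]]$blocks <- b
    out[[nm]]$len <- sum(w)
  }
  out
}

## Map a transcript-coordinate read [ta, tb] of an isoform onto the genome.
## Returns mapped flag, pos, cigar, novel_bases and the genomic footprint.
map_read <- function(iso, ta, tb, unmappable) {
  b <- iso$blocks
  ov <- b[b$tend >= ta & b$tstart <= tb, , drop = FALSE]
  ov$lo <- pmax(ov$tstart, ta); ov$hi <- pmin(ov$tend, tb)
  novel_bases <- sum(ifelse(ov$novel, ov$hi - ov$lo + 1L, 0L))
  if (novel_bases >= unmappable || all(ov$novel))
    return(list(mapped = FALSE, novel_bases = novel_bases,
                gstart = NA_integer_, gend = NA_integer_))
  lead <- if (ov$novel[1L]) ov$hi[1L] - ov$lo[1L] + 1L else 0L
  trail <- if (nrow(ov) > 1L && ov$novel[nrow(ov)])
    ov$hi[nrow(ov)] - ov$lo[nrow(ov)] + 1L else 0L
  gb <- ov[!ov$novel, , drop = FALSE]
  cig <- character()
  if (lead > 0L) cig <- c(cig, paste0(lead, "S"))
  for (i in seq_len(nrow(gb))) {
    if (i > 1L) {
      gap <- (gb$gstart[i] + (gb$lo[i] - gb$tstart[i])) -
        (gb$gend[i - 1L] - (gb$tend[i - 1L] - gb$hi[i - 1L])) - 1L
      if (gap > 0L) cig <- c(cig, paste0(gap, "N"))
    }
    cig <- c(cig, paste0(gb$hi[i] - gb$lo[i] + 1L, "M"))
  }
  if (trail > 0L) cig <- c(cig, paste0(trail, "S"))
  gstart <- gb$gstart[1L] + (gb$lo[1L] - gb$tstart[1L])
  gend <- gb$gend[nrow(gb)] - (gb$tend[nrow(gb)] - gb$hi[nrow(gb)])
  list(mapped = TRUE, pos = gstart, cigar = paste(cig, collapse = ""),
       novel_bases = novel_bases, gstart = gstart, gend = gend)
}

#' Simulate paired-end reads from a locus set as alignment records
#'
#' Fragments are drawn per isoform at the configured fold-coverage; a
#' configurable fraction is drawn from unspliced pre-mRNA instead. The
#' generator knows every read's origin and emits alignment records directly:
#' ordinary fragments yield concordant proper pairs; reads carrying at least
#' \code{unmappable_alu_bases} of novel-insert sequence — and pre-mRNA reads
#' overlapping an intronic Alu copy by that much — are emitted unmapped with
#' their sequence retained, and their pairs non-concordant, reproducing how
#' an aligner discards unplaceable or heavily multi-mapping Alu reads. For
#' each planted insertion, \code{min_signal_pairs} junction-spanning pairs
#' are guaranteed (mapped anchor in the upstream exon, unmapped mate across
#' the exon/Alu junction).
#'
#' @param ls a [generate_locus_set()] result.
#' @param config simulation parameters (default: the locus set's own).
#' @return list with \code{sam} (a \code{sam_records} data.frame with header
#'   attribute, writable by [write_sam()]) and \code{truth} (per-read truth
#'   labels: read_id, mate, class, gene_id, novel_bases, mapped).
#' @export
simulate_reads <- function(ls, config = ls$config) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  recs <- list(); truth <- list()
  frag_id <- 0L
  emit_pair <- function(chrom, m1, m2, seq1, seq2, gene_id, class,
                        novel_bases) {
    frag_id <<- frag_id + 1L
    rid <- sprintf("frag%06d", frag_id)
    conc <- m1$mapped && m2$mapped
    if (conc && config$p_flag_noise > 0 &&
        stats::runif(1L) < config$p_flag_noise) conc <- FALSE
    f1 <- 1L + 64L + (if (conc) 2L else 0L) +
      (if (!m1$mapped) 4L else 0L) + (if (!m2$mapped) 8L else 0L) +
      (if (m2$mapped) 32L else 0L)
    f2 <- 1L + 128L + (if (conc) 2L else 0L) +
      (if (!m2$mapped) 4L else 0L) + (if (!m1$mapped) 8L else 0L) +
      (if (m2$mapped) 16L else 0L)
    row <- function(flag, m, seq) data.frame(
      read_id = rid, flag = flag,
      chrom = if (m$mapped) chrom else "*",
      pos = if (m$mapped) m$pos else 0L,
      cigar = if (m$mapped) m$cigar else "*",
      sequence = seq, stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <<- row(f1, m1, seq1)
    recs[[length(recs) + 1L]] <<- row(f2, m2, seq2)
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = rid, gene_id = gene_id, class = class,
      novel_bases = novel_bases, mapped1 = m1$mapped, mapped2 = m2$mapped,
      stringsAsFactors = FALSE)
  }
  alu_overlap <- function(chrom, gs, ge) {
    a <- ls$alus[ls$alus$chrom == chrom, , drop = FALSE]
    if (!nrow(a) || is.na(gs)) return(0L)
    sum(pmax(0L, pmin(a$end, ge) - pmax(a$start, gs) + 1L))
  }
  for (gid in unique(ls$transcripts$gene_id)) {
    isoforms <- build_isoforms(ls, gid)
    chrom <- isoforms[[1L]]$chrom
    gspan <- range(unlist(lapply(isoforms, function(i)
      c(i$blocks$gstart, i$blocks$gend))), na.rm = TRUE)
    pre <- list(id = "pre", chrom = chrom,
                blocks = data.frame(gstart = gspan[1L], gend = gspan[2L],
                                    novel = FALSE,
                                    seq = substr(ls$genome[[chrom]],
                                                 gspan[1L], gspan[2L]),
                                    stringsAsFactors = FALSE))
    pre$blocks$tstart <- 1L
    pre$blocks$tend <- nchar(pre$blocks$seq)
    pre$len <- pre$blocks$tend
    mature_seq <- function(iso) paste(iso$blocks$seq, collapse = "")
    sample_fragment <- function(iso, fs = NULL, fl = NULL, class) {
      if (is.null(fl))
        fl <- max(rl + 20L, min(iso$len, round(stats::rnorm(
          1L, config$fragment_mean, config$fragment_sd))))
      if (is.null(fs)) fs <- sample.int(iso$len - fl + 1L, 1L)
      seq <- mature_seq(iso)
      ta1 <- fs; tb1 <- fs + rl - 1L
      tb2 <- fs + fl - 1L; ta2 <- tb2 - rl + 1L
      m1 <- map_read(iso, ta1, tb1, config$unmappable_alu_bases)
      m2 <- map_read(iso, ta2, tb2, config$unmappable_alu_bases)
      ## pre-mRNA (and mature intron-retaining) reads over an intronic Alu
      ## copy exceed the mapper's hit cap: emit unmapped
      if (identical(iso$id, "pre")) {
        if (m1$mapped &&
            alu_overlap(chrom, m1$gstart, m1$gend) >=
              config$unmappable_alu_bases) m1 <- list(mapped = FALSE)
        if (m2$mapped &&
            alu_overlap(chrom, m2$gstart, m2$gend) >=
              config$unmappable_alu_bases) m2 <- list(mapped = FALSE)
      }
      s1 <- mutate_seq(substr(seq, ta1, tb1), config$error_rate)
      s2f <- mutate_seq(substr(seq, ta2, tb2), config$error_rate)
      s2 <- if (m2$mapped) s2f else revcomp(s2f)  # as sequenced when unmapped
      nb <- max(m1$novel_bases %||% 0L, m2$novel_bases %||% 0L)
      emit_pair(chrom, m1, m2, s1, s2, gid, class, nb)
    }
    for (iso in isoforms) {
      if (iso$len < rl + 20L) next
      n_frag <- ceiling(config$coverage * iso$len / (2 * rl))
      for (f in seq_len(n_frag)) {
        if (stats::runif(1L) < config$fraction_premrna)
          sample_fragment(pre, class = "premrna")
        else sample_fragment(iso, class = "mature")
      }
    }
    ## guaranteed junction-spanning signal pairs for planted insertions
    nv <- ls$novel[[gid]]
    if (!is.null(nv) && config$min_signal_pairs > 0L) {
      iso <- isoforms[[grep("novel$", names(isoforms))]]
      junction <- iso$blocks$tend[nv$after_exon]  # last exonic base
      for (p in seq_len(config$min_signal_pairs)) {
        into_alu <- 50L + 5L * (p - 1L)  # novel bases under the mate
        fl <- config$fragment_mean
        fs <- junction + into_alu - fl + 1L
        if (fs < 1L) { fl <- junction + into_alu; fs <- 1L }
        sample_fragment(iso, fs = fs, fl = fl, class = "signal_junction")
      }
    }
  }
  recs <- do.call(rbind, recs)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                   recs$read_id, recs$flag, recs$chrom, recs$pos,
                   ifelse(recs$chrom == "*", 0L, 60L), recs$cigar,
                   "*", 0L, 0L, recs$sequence, "*")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ls$genome),
                      nchar(ls$genome)))
  tmp <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), tmp)
  sam <- read_sam(tmp)
  unlink(tmp)
  list(sam = sam, truth = do.call(rbind, truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
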