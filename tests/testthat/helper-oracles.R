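## Independent oracles and small fixture builders used across the suite.

## Scalar reference DP for the aligner model, written with the classical
## per-cell affine recurrences (no vectorization, no scan tricks):
##   E[i][j] = max(H[i-1][j] + open, E[i-1][j] + ext)
##   Hp      = max(0, H[i-1][j-1] + sub, E[i][j])
##   F[i][j] = max(Hp[i][j-1] + open, F[i][j-1] + ext)
##   HnoJ    = max(Hp, F)
##   J[i][j] = max HnoJ[i][j'] over j' < j with j' a segment end, or any
##             j' < j when j is a segment start (free splice move)
##   H       = max(HnoJ, J)
## Returns the maximum local score.
oracle_align_score <- function(query, target, seg_ends = NULL,
                               match = 1, mismatch = -1,
                               gap_open = -2, gap_ext = -0.5) {
  q <- strsplit(toupper(query), "")[[1]]
  t <- strsplit(toupper(target), "")[[1]]
  n <- length(q); m <- length(t)
  seg_starts <- if (length(seg_ends)) c(1L, seg_ends[-length(seg_ends)] + 1L)
                else integer()
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    Hp <- rep(0, m + 1)
    Fv <- rep(NEG, m + 1)
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i, j + 1] + gap_open,
                             E[i, j + 1] + gap_ext)
      sub <- if (q[i] == t[j]) match else mismatch
      Hp[j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1])
      Fv[j + 1] <- max(Hp[j] + gap_open, Fv[j] + gap_ext)
    }
    hnoj <- pmax(Hp, Fv)
    for (j in 1:m) {
      jbest <- NEG
      if ((j) %in% seg_starts && j > 1) {
        for (jp in 1:(j - 1)) jbest <- max(jbest, hnoj[jp + 1])
      }
      for (b in seg_ends) if (b < j) jbest <- max(jbest, hnoj[b + 1])
      H[i + 1, j + 1] <- max(hnoj[j + 1], jbest)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

## Connected components of the interval-overlap graph (clustering oracle).
oracle_overlap_components <- function(start, end) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && start[i] <= end[j] && start[j] <= end[i] &&
          comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

## Exhaustive isoform-pair enumeration for exon skipping (oracle).
oracle_skip_events <- function(tx) {
  found <- character()
  for (g in unique(tx$gene_id)) {
    gx <- tx[tx$gene_id == g, ]
    isos <- lapply(split(gx, gx$transcript_id),
                   function(e) e[order(e$start), ])
    for (a in isos) for (b in isos) {
      if (nrow(a) < 3) next
      ka <- paste0(a$start, "-", a$end)
      kb <- paste0(b$start, "-", b$end)
      for (r in 2:(nrow(a) - 1)) {
        for (p in seq_len(length(kb) - 1)) {
          if (kb[p] == ka[r - 1] && kb[p + 1] == ka[r + 1]) {
            found <- c(found, paste(g, a$chrom[1], ka[r],
                                    a$end[r - 1] + 1, b$start[p + 1] - 1))
          }
        }
      }
    }
  }
  unique(found)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## Minimal GTF writer for fixtures.
write_fixture_gtf <- function(rows, path) {
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    rows$chrom, rows$start, rows$end, rows$strand, rows$gene_id,
    rows$transcript_id)
  writeLines(lines, path)
  path
}

## Minimal SAM writer for fixtures: rows need read_id, flag, chrom, pos,
## cigar, seq.
write_fixture_sam <- function(rows, path, sq = c(chr1 = 100000L)) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   rows$read_id, rows$flag, rows$chrom, rows$pos,
                   ifelse(rows$chrom == "*", 0L, 60L), rows$cigar, rows$seq)
  writeLines(c(header, lines), path)
  path
}

## Shared small locus set + reads for expensive end-to-end tests (built
## once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ls <- generate_locus_set(sim_config(seed = 11L))
      rr <- simulate_reads(ls)
      cache <<- list(ls = ls, rr = rr)
    }
    cache
  }
})
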