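#' Count spliced reads supporting each intron
#'
#' A spliced alignment contributes 1 to intron I iff one of its splice gaps
#' (CIGAR N operations) covers exactly I — exact-boundary matching, 1-based
#' inclusive gap spans. Unspliced reads contribute nothing.
#'
#' @param sam a \code{sam_records} data.frame ([read_sam()]).
#' @param sample sample id stamped on the output rows.
#' @param introns optional data.frame (chrom, start, end) restricting the
#'   output to these introns (zero-count introns are then reported too).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{sample}, \code{count}.
#' @export
count_junction_reads <- function(sam, sample = "sample1", introns = NULL) {
  m <- sam[sam$mapped & grepl("N", sam$cigar, fixed = TRUE), , drop = FALSE]
  gaps <- if (nrow(m)) cigar_splice_gaps(m$cigar, m$start, m$chrom)
          else data.frame(chrom = character(), start = integer(),
                          end = integer())
  key <- paste0(gaps$chrom, ":", gaps$start, "-", gaps$end)
  tab <- table(key)
  if (is.null(introns)) {
    if (!length(tab))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), sample = character(),
                        count = integer(), stringsAsFactors = FALSE))
    parts <- regmatches(names(tab),
                        regexec("^(.*):(\\d+)-(\\d+)$", names(tab)))
    data.frame(chrom = vapply(parts, `[`, "", 2L),
               start = as.integer(vapply(parts, `[`, "", 3L)),
               end = as.integer(vapply(parts, `[`, "", 4L)),
               sample = sample, count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    ikey <- paste0(introns$chrom, ":", introns$start, "-", introns$end)
    cnt <- as.integer(tab[ikey])
    cnt[is.na(cnt)] <- 0L
    data.frame(chrom = introns$chrom, start = introns$start,
               end = introns$end, sample = sample, count = cnt,
               stringsAsFactors = FALSE)
  }
}

#' Detect simple cassette (exon-skipping) events
#'
#' A simple event requires an inclusion isoform (..., A, E, B, ...) and a
#' skipping isoform (..., A, B, ...) of the same gene with \emph{identical}
#' flanking exons A and B: the exon is excised or included with no change to
#' its flanks. Different flanking-intron contexts for the same exon yield
#' distinct alternative splicing patterns.
#'
#' @param tx transcript exon table ([read_gtf()]).
#' @return data.frame with one row per (exon, flank context) pattern:
#'   exon coordinates, the two inclusion introns \code{iLeft}/\code{iRight},
#'   and the skipping intron \code{iSpan} (spanning both inclusion introns
#'   and the exon).
#' @export
detect_exon_skipping <- function(tx) {
  out <- list()
  for (g in unique(tx$gene_id)) {
    gx <- tx[tx$gene_id == g, , drop = FALSE]
    isoforms <- lapply(split(gx, gx$transcript_id),
                       function(e) e[order(e$start), , drop = FALSE])
    if (length(isoforms) < 2L) next
    keyify <- function(e) paste0(e$start, "-", e$end)
    for (inc in isoforms) {
      if (nrow(inc) < 3L) next
      for (r in 2:(nrow(inc) - 1L)) {
        a <- inc[r - 1L, ]; e <- inc[r, ]; b <- inc[r + 1L, ]
        for (skp in isoforms) {
          if (nrow(skp) < 2L) next
          ks <- keyify(skp)
          pos <- which(ks == paste0(a$start, "-", a$end))
          hit <- any(pos < nrow(skp) &
                       ks[pmin(pos + 1L, nrow(skp))] ==
                       paste0(b$start, "-", b$end))
          if (hit) {
            out[[length(out) + 1L]] <- data.frame(
              gene_id = g, chrom = e$chrom, strand = e$strand,
              exon_start = e$start, exon_end = e$end,
              iLeft_start = a$end + 1L, iLeft_end = e$start - 1L,
              iRight_start = e$end + 1L, iRight_end = b$start - 1L,
              iSpan_start = a$end + 1L, iSpan_end = b$start - 1L,
              stringsAsFactors = FALSE)
            break
          }
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), exon_start = integer(),
                      exon_end = integer(), iLeft_start = integer(),
                      iLeft_end = integer(), iRight_start = integer(),
                      iRight_end = integer(), iSpan_start = integer(),
                      iSpan_end = integer(), stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev <- ev[!duplicated(ev[, c("chrom", "exon_start", "exon_end",
                              "iLeft_start", "iRight_end")]), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Percent spliced in
#'
#' \code{PSI = (L + R) / (L + R + 2 S)} where L and R are the spliced-read
#' counts of the two inclusion introns flanking the exon and S the count of
#' the skipping intron. The skipping count is doubled because one skipping
#' junction stands against two inclusion junctions. Samples with fewer than
#' \code{min_total} supporting reads in total cannot render a reliable
#' estimate and return \code{NA}.
#'
#' @param count_iLeft,count_iRight,count_iSpan non-negative read counts
#'   (vectorized).
#' @param min_total minimum L + R + S for a defined value (default 10).
#' @return numeric in [0, 1], or NA where undefined.
#' @examples
#' compute_psi(10, 10, 10)  # 0.5
#' compute_psi(0, 0, 12)    # 0: pure skipping
#' @export
compute_psi <- function(count_iLeft, count_iRight, count_iSpan,
                        min_total = 10) {
  l <- as.numeric(count_iLeft); r <- as.numeric(count_iRight)
  s <- as.numeric(count_iSpan)
  if (any(c(l, r, s) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  tot <- l + r + s
  psi <- (l + r) / (l + r + 2 * s)
  psi[tot < min_total | tot == 0] <- NA_real_
  psi
}

#' Categorize a summary PSI value
#'
#' \code{minor} if PSI < 0.35 (the exon sits in the minor isoform),
#' \code{major} if PSI >= 0.65, \code{equal} otherwise (the lower bound of
#' the equal class is 0.35, closing the gap between the two printed
#' cutoffs).
#'
#' @param psi numeric vector in [0, 1] (NA allowed).
#' @return character vector over {minor, equal, major}; NA for undefined PSI.
#' @export
categorize_psi <- function(psi) {
  out <- rep(NA_character_, length(psi))
  ok <- !is.na(psi)
  out[ok & psi < 0.35] <- "minor"
  out[ok & psi >= 0.35 & psi < 0.65] <- "equal"
  out[ok & psi >= 0.65] <- "major"
  out
}

#' Per-sample and summary PSI for skip events
#'
#' Joins junction counts onto the three introns of each event, computes
#' per-sample PSI and the cohort summary (median by default, mean optional),
#' and assigns the isoform category from the summary.
#'
#' @param events output of [detect_exon_skipping()].
#' @param junction_counts data.frame from [count_junction_reads()] pooled
#'   over samples.
#' @param min_total per-sample low-read cutoff (see [compute_psi()]).
#' @param summary \code{"median"} or \code{"mean"} over defined samples.
#' @return \code{events} with per-sample PSI columns (\code{psi.<sample>}),
#'   \code{summary_psi} and \code{category}.
#' @export
summarize_psi <- function(events, junction_counts, min_total = 10,
                          summary = c("median", "mean")) {
  summary <- match.arg(summary)
  samples <- unique(junction_counts$sample)
  jkey <- paste0(junction_counts$chrom, ":", junction_counts$start, "-",
                 junction_counts$end, "@", junction_counts$sample)
  cnt <- function(chrom, s, e, sample) {
    i <- jkey == paste0(chrom, ":", s, "-", e, "@", sample)
    if (any(i)) sum(junction_counts$count[i]) else 0
  }
  psis <- matrix(NA_real_, nrow(events), length(samples),
                 dimnames = list(NULL, samples))
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    for (sm in samples) {
      psis[r, sm] <- compute_psi(
        cnt(ev$chrom, ev$iLeft_start, ev$iLeft_end, sm),
        cnt(ev$chrom, ev$iRight_start, ev$iRight_end, sm),
        cnt(ev$chrom, ev$iSpan_start, ev$iSpan_end, sm),
        min_total = min_total)
    }
  }
  sfun <- if (summary == "median") stats::median else mean
  events$summary_psi <- apply(psis, 1L, function(x)
    if (all(is.na(x))) NA_real_ else sfun(x, na.rm = TRUE))
  events$category <- categorize_psi(events$summary_psi)
  colnames(psis) <- paste0("psi.", samples)
  cbind(events, as.data.frame(psis))
}
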