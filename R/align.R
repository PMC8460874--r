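#' @name aligner
#' @title Local and spliced alignment engine
#'
#' @description
#' A Smith–Waterman affine-gap local aligner used for the shadow tests and
#' contig prioritization, extended with splice-style moves for the signal
#' test: when the target is a concatenation of labelled segments (anchor
#' exon, Alu consensus, adjacent exon), arbitrarily long target gaps are
#' free provided they start at a segment end or land at a segment start.
#' This lets a read jump from the end of an exon into the middle of the Alu
#' consensus (the insertion point within the Alu is unknown) without paying
#' a length-proportional penalty, exactly as a spliced aligner treats
#' introns.
#'
#' Scoring: match +1, mismatch -1, gap open -2, gap extension -0.5.
#' Identity is matches / aligned columns, where ordinary gap columns count
#' and free splice jumps do not. Query coverage is the aligned query span
#' divided by the query length.
NULL

## Core DP. segments: integer vector of segment end columns (cumulative),
## or NULL for plain local alignment. Returns score matrices + traceback
## summary.
align_core <- function(query, target, seg_ends = NULL,
                       match = 1, mismatch = -1,
                       gap_open = -2, gap_ext = -0.5) {
  q <- strsplit(toupper(query), "")[[1L]]
  t <- strsplit(toupper(target), "")[[1L]]
  n <- length(q); m <- length(t)
  if (n == 0L) stop("empty query")
  if (m == 0L) stop("empty target")
  seg_starts <- if (length(seg_ends)) c(1L, seg_ends[-length(seg_ends)] + 1L)
                else integer()
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)       # best (any state)
  E <- matrix(NEG, n + 1L, m + 1L)     # ends in query-consuming gap
  HP <- matrix(0, n + 1L, m + 1L)      # max(0, diag, E)
  FF <- matrix(NEG, n + 1L, m + 1L)    # ends in target-consuming (paid) gap
  J <- matrix(NEG, n + 1L, m + 1L)     # reached by free splice jump
  for (i in seq_len(n)) {
    sub <- ifelse(t == q[i], match, mismatch)
    E[i + 1L, -1L] <- pmax(H[i, -1L] + gap_open, E[i, -1L] + gap_ext)
    diag <- H[i, seq_len(m)] + sub
    hp <- pmax(0, diag, E[i + 1L, -1L])
    HP[i + 1L, -1L] <- hp
    a <- hp - gap_ext * seq_len(m)
    cma <- cummax(a)
    ff <- c(NEG, gap_open + gap_ext * (2:m - 1L) + cma[seq_len(m - 1L)])
    if (m == 1L) ff <- NEG
    FF[i + 1L, -1L] <- ff
    hnoj <- pmax(hp, ff)
    if (length(seg_ends)) {
      jrow <- rep(NEG, m)
      pref <- cummax(hnoj)
      for (s in seg_starts) if (s > 1L) jrow[s] <- max(jrow[s], pref[s - 1L])
      for (b in seg_ends) if (b < m)
        jrow[(b + 1L):m] <- pmax(jrow[(b + 1L):m], hnoj[b])
      J[i + 1L, -1L] <- jrow
      H[i + 1L, -1L] <- pmax(hnoj, jrow)
    } else {
      H[i + 1L, -1L] <- hnoj
    }
  }
  list(H = H, E = E, HP = HP, FF = FF, J = J, q = q, t = t,
       n = n, m = m, seg_ends = seg_ends, seg_starts = seg_starts,
       match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext)
}

## Traceback from the global maximum of H. Returns per-column operations.
align_traceback <- function(dp) {
  eps <- 1e-6
  H <- dp$H; E <- dp$E; HP <- dp$HP; FF <- dp$FF; J <- dp$J
  best <- which(H == max(H), arr.ind = TRUE)[1L, ]
  i <- best[[1L]] - 1L; j <- best[[2L]] - 1L
  score <- H[i + 1L, j + 1L]
  ops <- character(); qpos <- integer(); tpos <- integer()
  push <- function(op, qi, tj) {
    ops <<- c(ops, op); qpos <<- c(qpos, qi); tpos <<- c(tpos, tj)
  }
  if (score <= 0) {
    return(list(score = 0, ops = ops, qpos = qpos, tpos = tpos))
  }
  state <- "H"
  while (i > 0L || j > 0L) {
    if (state == "H") {
      v <- H[i + 1L, j + 1L]
      if (v <= eps) break
      if (abs(HP[i + 1L, j + 1L] - v) < eps) {
        ev <- E[i + 1L, j + 1L]
        dg <- if (i > 0L && j > 0L)
          H[i, j] + (if (dp$q[i] == dp$t[j]) dp$match else dp$mismatch)
          else -Inf
        if (abs(dg - v) < eps) {
          push(if (dp$q[i] == dp$t[j]) "M" else "X", i, j)
          i <- i - 1L; j <- j - 1L
        } else if (abs(ev - v) < eps) {
          state <- "E"
        } else break  # started here (0)
      } else if (abs(FF[i + 1L, j + 1L] - v) < eps) {
        state <- "F"
      } else {
        ## free splice jump landed at column after j'? J[i+1,j+1] == v
        src <- NA_integer_
        land_free <- j %in% dp$seg_starts
        for (jp in (j - 1L):1L) {
          if ((land_free || jp %in% dp$seg_ends) &&
              abs(pmax(HP[i + 1L, jp + 1L], FF[i + 1L, jp + 1L]) - v) < eps) {
            src <- jp; break
          }
        }
        if (is.na(src)) break
        push("S", NA_integer_, j)  # splice, target (src+1)..(j-1) skipped
        j <- src
      }
    } else if (state == "E") {
      v <- E[i + 1L, j + 1L]
      push("I", i, NA_integer_)
      if (i > 1L && abs(E[i, j + 1L] + dp$gap_ext - v) < eps) {
        i <- i - 1L
      } else {
        i <- i - 1L; state <- "H"
      }
    } else { # F: paid target gap ending at column j
      v <- FF[i + 1L, j + 1L]
      push("D", NA_integer_, j)
      if (j > 1L && abs(FF[i + 1L, j] + dp$gap_ext - v) < eps) {
        j <- j - 1L
      } else {
        j <- j - 1L; state <- "H"
      }
    }
  }
  list(score = score,
       ops = rev(ops), qpos = rev(qpos), tpos = rev(tpos))
}

## Summarize a traceback into coverage / identity / per-segment query bases.
align_summary <- function(dp, tb, qlen) {
  ops <- tb$ops
  matches <- sum(ops == "M")
  mism <- sum(ops == "X")
  ins <- sum(ops == "I")
  del <- sum(ops == "D")
  cols <- matches + mism + ins + del
  qa <- tb$qpos[!is.na(tb$qpos)]
  ta <- tb$tpos[!is.na(tb$tpos) & ops != "S"]
  list(score = tb$score,
       matches = matches, aligned_cols = cols,
       identity = if (cols > 0) matches / cols else 0,
       query_coverage = if (length(qa)) (max(qa) - min(qa) + 1L) / qlen else 0,
       query_start = if (length(qa)) min(qa) else NA_integer_,
       query_end = if (length(qa)) max(qa) else NA_integer_,
       target_start = if (length(ta)) min(ta) else NA_integer_,
       target_end = if (length(ta)) max(ta) else NA_integer_,
       ops = ops, qpos = tb$qpos, tpos = tb$tpos)
}

#' Plain affine-gap local alignment
#'
#' @param query,target DNA strings.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @return list with \code{score}, \code{identity} (matches over aligned
#'   columns, gaps counted), \code{query_coverage}, the aligned query and
#'   target ranges, \code{matches} and \code{aligned_cols}.
#' @export
local_align <- function(query, target, match = 1, mismatch = -1,
                        gap_open = -2, gap_ext = -0.5) {
  dp <- align_core(query, target, NULL, match, mismatch, gap_open, gap_ext)
  align_summary(dp, align_traceback(dp), nchar(query))
}

#' Spliced alignment of a read against labelled target segments
#'
#' The target is the in-order concatenation of the named segments (e.g.
#' anchor exon, Alu consensus, adjacent exon). Long target gaps are free at
#' segment boundaries (see \link{aligner}); both the query and its reverse
#' complement are tried and the better result kept. \code{alu_bases} counts
#' query bases placed (as match or mismatch columns) within segments whose
#' name contains "Alu" (case-insensitive).
#'
#' @param query read sequence.
#' @param target_segments named character vector of ordered segment
#'   sequences.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @return list as from [local_align()] plus \code{alu_bases} and
#'   \code{orientation} ("+" query as given, "-" reverse complement).
#' @export
spliced_align <- function(query, target_segments, match = 1, mismatch = -1,
                          gap_open = -2, gap_ext = -0.5) {
  if (!nzchar(query)) stop("empty query")
  target <- paste(target_segments, collapse = "")
  seg_ends <- cumsum(nchar(target_segments))
  is_alu <- grepl("alu", names(target_segments), ignore.case = TRUE)
  run_one <- function(qseq, orient) {
    dp <- align_core(qseq, target, seg_ends, match, mismatch,
                     gap_open, gap_ext)
    res <- align_summary(dp, align_traceback(dp), nchar(qseq))
    seg_of <- findInterval(res$tpos, c(0L, seg_ends), left.open = TRUE)
    mm <- res$ops %in% c("M", "X") & !is.na(res$tpos)
    res$alu_bases <- sum(mm & is_alu[pmax(seg_of, 1L)], na.rm = TRUE)
    res$orientation <- orient
    res
  }
  fwd <- run_one(query, "+")
  rev <- run_one(revcomp(query), "-")
  if (rev$score > fwd$score) rev else fwd
}
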