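#' Assemble reads into contigs with a small de Bruijn graph
#'
#' Deliberately simple stranded assembler: reads are decomposed into k-mers,
#' contigs are the maximal unambiguous (non-branching) paths of the de
#' Bruijn graph, short tips (dead-end unitigs no longer than 2k attached to
#' the graph at one end) are trimmed once, and no bubble popping is
#' performed — divergent haplotypes come out as separate contigs. An
#' external assembler can be substituted upstream; every consumer only sees
#' the contig table.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param k odd k-mer size (default 23).
#' @return data.frame with \code{contig_id}, \code{sequence},
#'   \code{length}, \code{supporting_read_ids} (comma-separated ids of
#'   reads sharing at least one k-mer with the contig).
#' @export
assemble_reads <- function(reads, k = 23L) {
  if (!length(reads)) stop("no reads to assemble")
  if (k %% 2L == 0L) stop("k must be odd")
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  usable <- nchar(reads) >= k
  if (!any(usable)) {
    warning("all reads shorter than k; nothing to assemble")
    return(data.frame(contig_id = character(), sequence = character(),
                      length = integer(), supporting_read_ids = character(),
                      stringsAsFactors = FALSE))
  }
  read_kmers <- lapply(toupper(reads[usable]), function(s) {
    n <- nchar(s)
    km <- substring(s, 1:(n - k + 1L), k:n)
    km[!grepl("[^ACGT]", km)]
  })
  kmers <- unique(unlist(read_kmers))
  build <- function(kmers) {
    pre <- substr(kmers, 1L, k - 1L)
    suf <- substr(kmers, 2L, k)
    nodes <- unique(c(pre, suf))
    outdeg <- table(factor(pre, levels = nodes))
    indeg <- table(factor(suf, levels = nodes))
    by_pre <- split(seq_along(kmers), pre)
    branching <- function(v) indeg[[v]] != 1L || outdeg[[v]] != 1L
    visited <- logical(length(kmers))
    unitigs <- list()
    starts <- which(vapply(pre, function(u)
      indeg[[u]] == 0L || branching(u), logical(1L)))
    walk <- function(e0) {
      path <- e0
      visited[e0] <<- TRUE
      v <- suf[e0]
      while (!branching(v)) {
        nxt <- by_pre[[v]]
        if (is.null(nxt) || visited[nxt]) break
        visited[nxt] <<- TRUE
        path <- c(path, nxt)
        v <- suf[nxt]
      }
      path
    }
    for (e0 in starts) if (!visited[e0])
      unitigs[[length(unitigs) + 1L]] <- walk(e0)
    for (e0 in seq_along(kmers)) if (!visited[e0])  # cycles
      unitigs[[length(unitigs) + 1L]] <- walk(e0)
    list(unitigs = unitigs, pre = pre, suf = suf,
         indeg = indeg, outdeg = outdeg)
  }
  g <- build(kmers)
  seq_of <- function(path, pre, suf)
    paste0(pre[path[1L]], paste(substr(suf[path], k - 1L, k - 1L),
                                collapse = ""))
  ## one round of tip trimming: dangling at exactly one end, length <= 2k
  tip <- vapply(g$unitigs, function(p) {
    a <- g$pre[p[1L]]; b <- g$suf[p[length(p)]]
    dang_start <- g$indeg[[a]] == 0L
    dang_end <- g$outdeg[[b]] == 0L
    xor(dang_start, dang_end) &&
      nchar(seq_of(p, g$pre, g$suf)) <= 2L * k
  }, logical(1L))
  if (any(tip)) {
    drop <- unlist(g$unitigs[tip])
    kmers <- kmers[-drop]
    if (!length(kmers))
      return(data.frame(contig_id = character(), sequence = character(),
                        length = integer(),
                        supporting_read_ids = character(),
                        stringsAsFactors = FALSE))
    g <- build(kmers)
  }
  seqs <- vapply(g$unitigs, seq_of, "", pre = g$pre, suf = g$suf)
  seqs <- unique(seqs)
  support <- vapply(seqs, function(cs) {
    n <- nchar(cs)
    ck <- substring(cs, 1:(n - k + 1L), k:n)
    hit <- vapply(read_kmers, function(rk) any(rk %in% ck), logical(1L))
    paste(names(read_kmers)[hit], collapse = ",")
  }, "")
  out <- data.frame(contig_id = paste0("contig", seq_along(seqs)),
                    sequence = unname(seqs), length = nchar(seqs),
                    supporting_read_ids = unname(support),
                    stringsAsFactors = FALSE)
  out[order(-out$length), , drop = FALSE]
}

#' Prioritize contigs lacking a high-quality genomic match
#'
#' Each contig is locally aligned to the gene's genomic region on both
#' strands; a high-quality alignment is >= 90\% identity at >= 80\% contig
#' coverage (both inclusive). Contigs \emph{without} such a match are the
#' prioritized candidates — sequence the region cannot explain.
#'
#' @param contigs contig table from [assemble_reads()] (or a character
#'   vector of sequences).
#' @param gene_region_sequence genomic sequence of the gene region.
#' @param min_identity,min_coverage the high-quality match thresholds.
#' @return the contig table with \code{match_identity},
#'   \code{match_coverage} (best over both strands) and \code{prioritized}.
#' @export
prioritize_contigs <- function(contigs, gene_region_sequence,
                               min_identity = 0.90, min_coverage = 0.80) {
  if (is.character(contigs))
    contigs <- data.frame(contig_id = paste0("contig",
                                             seq_along(contigs)),
                          sequence = contigs, length = nchar(contigs),
                          stringsAsFactors = FALSE)
  ident <- cov <- numeric(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    best <- list(identity = 0, query_coverage = 0, score = -Inf)
    for (tg in c(gene_region_sequence, revcomp(gene_region_sequence))) {
      r <- local_align(contigs$sequence[i], tg)
      if (r$identity >= min_identity && r$query_coverage >= min_coverage) {
        best <- r
        break
      }
      if (r$score > best$score) best <- r
    }
    ident[i] <- best$identity
    cov[i] <- best$query_coverage
  }
  contigs$match_identity <- ident
  contigs$match_coverage <- cov
  contigs$prioritized <- !(ident >= min_identity & cov >= min_coverage)
  contigs
}
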