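#' Read transcript models from a GTF file
#'
#' Parses exon features into a transcript exon table. GTF coordinates are
#' 1-based inclusive and are preserved as-is. Exon rows lacking a
#' \code{transcript_id} attribute are skipped with a warning; structurally
#' malformed lines (fewer than 9 tab-separated fields) raise an error naming
#' the offending line number.
#'
#' @param path path to a GTF file.
#' @return A \code{transcript_set}: data.frame with columns
#'   \code{transcript_id}, \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{exon_rank} (exons sorted by start within
#'   each transcript). Empty input yields a zero-row table.
#' @seealso [write_gtf()], [transcript_introns()]
#' @export
read_gtf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(body)[which(nfield < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path, ": expected 9 fields")
  }
  if (!any(body)) return(transcript_models(empty_exon_table()))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) return(transcript_models(empty_exon_table()))
  tid <- as.character(gr$transcript_id)
  if (anyNA(tid)) {
    warning(sum(is.na(tid)), " exon record(s) without transcript_id skipped")
    gr <- gr[!is.na(tid)]
    tid <- tid[!is.na(tid)]
  }
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else NA_character_
  ex <- data.frame(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  transcript_models(ex)
}

empty_exon_table <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(), exon_rank = integer(),
             stringsAsFactors = FALSE)
}

#' Validate and normalize a transcript exon table
#'
#' Sorts exons by start within each transcript, assigns \code{exon_rank},
#' and enforces the model invariants: exons of one transcript share a
#' chromosome and strand and do not overlap one another.
#'
#' @param exons data.frame with transcript_id, gene_id, chrom, strand,
#'   start, end.
#' @return the normalized table, classed \code{"transcript_set"}.
#' @export
transcript_models <- function(exons) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand",
                  "start", "end") %in% names(exons)))
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  rank <- stats::ave(exons$start, exons$transcript_id,
                     FUN = seq_along)
  exons$exon_rank <- as.integer(rank)
  for (tid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tid, ]
    if (length(unique(e$chrom)) > 1L || length(unique(e$strand)) > 1L)
      stop("transcript ", tid, ": exons span chromosomes or strands")
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("transcript ", tid, ": overlapping exons")
  }
  rownames(exons) <- NULL
  structure(exons, class = c("transcript_set", "data.frame"))
}

#' Derive introns as gaps between consecutive exons
#' @param tx a transcript exon table (from [read_gtf()]).
#' @return data.frame transcript_id, gene_id, chrom, strand, start, end,
#'   intron_rank. Intron i spans \code{exon_i.end + 1 .. exon_{i+1}.start - 1}.
#' @export
transcript_introns <- function(tx) {
  out <- lapply(split(seq_len(nrow(tx)), tx$transcript_id), function(idx) {
    e <- tx[idx, ][order(tx$start[idx]), ]
    if (nrow(e) < 2L) return(NULL)
    data.frame(transcript_id = e$transcript_id[-1L],
               gene_id = e$gene_id[-1L],
               chrom = e$chrom[-1L], strand = e$strand[-1L],
               start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L,
               intron_rank = seq_len(nrow(e) - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      intron_rank = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write transcript models to GTF
#' @param tx transcript exon table.
#' @param path output path.
#' @param source source field for column 2.
#' @return invisibly, \code{path}.
#' @export
write_gtf <- function(tx, path, source = "aluex") {
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tx$chrom, source, tx$start, tx$end, tx$strand, tx$gene_id,
    tx$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read exon features from a GFF3 annotation (read-only)
#'
#' Exon features are keyed by their \code{Parent} attribute (transcript) and,
#' where present, a \code{gene_id} attribute; used for annotation input only.
#'
#' @param path path to a GFF3 file.
#' @return a transcript exon table as from [read_gtf()].
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) return(transcript_models(empty_exon_table()))
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) sub("^transcript:", "", p[[1L]]) else NA_character_, "")
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else parent
  ex <- data.frame(transcript_id = parent, gene_id = gid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  ex <- ex[!is.na(ex$transcript_id), , drop = FALSE]
  transcript_models(ex)
}
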