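#' Read alignment records from a SAM file
#'
#' Keeps unmapped mates (with their sequences), which carry the candidate
#' Alu evidence for the non-reference insertion caller. The pair-concordance
#' flag is taken from the SAM proper-pair bit (0x2). Mapped records whose
#' CIGAR-consumed query length disagrees with the sequence length are
#' rejected with a warning.
#'
#' @param path SAM file with \code{@SQ} headers; mates of one pair share the
#'   read id (QNAME).
#' @return data.frame (class \code{"sam_records"}) with columns
#'   \code{read_id}, \code{mate_index}, \code{flag}, \code{mapped},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{cigar},
#'   \code{sequence}, \code{is_concordant_pair}. The header lines are kept in
#'   attribute \code{"header"}.
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) {
    out <- empty_sam_table()
    attr(out, "header") <- header
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L))
    stop("malformed SAM line ", which(nf < 11L)[1L], ": expected 11+ fields")
  flag <- as.integer(vapply(f, `[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- vapply(f, `[`, "", 6L)
  seqs <- vapply(f, `[`, "", 10L)
  pos <- as.integer(vapply(f, `[`, "", 4L))
  ## validate query length consumed by CIGAR against SEQ
  ok <- rep(TRUE, length(body))
  chk <- mapped & cigar != "*" & seqs != "*"
  if (any(chk)) {
    qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar[chk])
    bad <- qw != nchar(seqs[chk])
    if (any(bad)) {
      warning(sum(bad), " SAM record(s) rejected: CIGAR/SEQ length mismatch")
      ok[chk][bad] <- FALSE
    }
  }
  refw <- rep(NA_integer_, length(body))
  refw[mapped & cigar != "*"] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    cigar[mapped & cigar != "*"])
  out <- data.frame(
    read_id = vapply(f, `[`, "", 1L),
    mate_index = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                        ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)),
    flag = flag,
    mapped = mapped,
    chrom = ifelse(mapped, vapply(f, `[`, "", 3L), NA_character_),
    start = ifelse(mapped, pos, NA_integer_),
    end = ifelse(mapped, pos + refw - 1L, NA_integer_),
    strand = ifelse(!mapped, "*", ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")),
    cigar = cigar,
    sequence = seqs,
    is_concordant_pair = bitwAnd(flag, 2L) > 0L,
    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out <- structure(out, class = c("sam_records", "data.frame"))
  attr(out, "header") <- header
  out
}

empty_sam_table <- function() {
  structure(data.frame(read_id = character(), mate_index = integer(),
                       flag = integer(), mapped = logical(),
                       chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       cigar = character(), sequence = character(),
                       is_concordant_pair = logical(),
                       stringsAsFactors = FALSE),
            class = c("sam_records", "data.frame"))
}

#' Write alignment records to SAM
#' @param records a \code{sam_records} data.frame (as from [read_sam()]).
#' @param path output path.
#' @param seq_lengths named integer vector of reference lengths for the
#'   \code{@SQ} header; if NULL the header attribute of \code{records} is
#'   reused.
#' @return invisibly, \code{path}.
#' @export
write_sam <- function(records, path, seq_lengths = NULL) {
  header <- if (!is.null(seq_lengths)) {
    c("@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
              as.integer(seq_lengths)))
  } else attr(records, "header")
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                   records$read_id, records$flag,
                   ifelse(records$mapped, records$chrom, "*"),
                   ifelse(records$mapped, records$start, 0L),
                   ifelse(records$mapped, 60L, 0L),
                   ifelse(records$mapped, records$cigar, "*"),
                   "*", 0L, 0L, records$sequence, "*")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Reference spans skipped by splice gaps (CIGAR N operations)
#' @param cigar,pos vectors of CIGAR strings and 1-based leftmost positions.
#' @param chrom optional chromosome names to attach.
#' @return data.frame with one row per splice gap: \code{record} (index into
#'   the input), \code{chrom}, \code{start}, \code{end} — the intron span,
#'   1-based inclusive.
#' @export
cigar_splice_gaps <- function(cigar, pos, chrom = NA_character_) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = as.integer(pos), ops = "N")
  n <- lengths(rl)
  idx <- rep(seq_along(cigar), n)
  ul <- unlist(rl)
  data.frame(record = idx,
             chrom = rep_len(as.character(chrom), length(cigar))[idx],
             start = IRanges::start(ul), end = IRanges::end(ul),
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of sequences (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an intron-by-sample count matrix from TSV
#'
#' First column \code{intron_id}, one column per sample.
#' @param path TSV file.
#' @return numeric matrix, rownames = intron ids, colnames = sample ids.
#' @export
read_count_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Write an intron-by-sample count matrix to TSV
#' @param m numeric matrix with intron rownames and sample colnames.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_count_matrix <- function(m, path) {
  d <- data.frame(intron_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
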