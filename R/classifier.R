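#' Reverse complement of DNA strings
#' @param x character vector over {A,C,G,T,N}.
#' @return character vector.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## all k-mers of one sequence, canonical, N-containing excluded
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character())
  km <- substring(seq, 1:(n - k + 1L), k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(character())
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

#' Build a k-mer index from an Alu sequence library
#'
#' The library is typically the Alu consensus plus the annotated genomic Alu
#' instances; recently integrated (polymorphic) elements are AluY-like, so
#' an AluY-type consensus anchors the library. k-mers are canonicalized
#' (lexicographic min of the k-mer and its reverse complement); k-mers
#' containing N are excluded.
#'
#' @param alu_sequences named character vector of sequences (or a FASTA path
#'   readable by [read_fasta()]).
#' @param k k-mer length (default 31).
#' @param min_hit_frac fraction of a read's k-mers that must hit the index
#'   for the read to classify as Alu (default 0.1, low enough to keep
#'   chimeric exon–Alu mates that carry only a short Alu stretch).
#' @return list of class \code{"alu_kmer_index"} with elements \code{k},
#'   \code{kmer_set} (character), \code{min_hit_frac}.
#' @export
build_alu_index <- function(alu_sequences, k = 31L, min_hit_frac = 0.1) {
  if (is.character(alu_sequences) && length(alu_sequences) == 1L &&
      file.exists(alu_sequences))
    alu_sequences <- read_fasta(alu_sequences)
  if (!length(alu_sequences)) stop("empty Alu sequence library")
  if (min_hit_frac <= 0 || min_hit_frac > 1)
    stop("min_hit_frac must lie in (0, 1]")
  if (k > min(nchar(alu_sequences)))
    stop("k exceeds the shortest library sequence")
  kmers <- unique(unlist(lapply(alu_sequences, canonical_kmers, k = k)))
  structure(list(k = as.integer(k), kmer_set = kmers,
                 min_hit_frac = min_hit_frac),
            class = "alu_kmer_index")
}

#' Classify a read as Alu-derived or not
#'
#' A read is an Alu read iff the fraction of its k-mers found in the index
#' is at least \code{min_hit_frac}. Classification is invariant under
#' reverse-complementing the read (canonical k-mers).
#'
#' @param read_sequence character vector of read sequences.
#' @param index an [build_alu_index()] result.
#' @return logical vector; reads shorter than k return FALSE with a warning.
#' @export
classify_read <- function(read_sequence, index) {
  short <- nchar(read_sequence) < index$k
  if (any(short)) warning(sum(short), " read(s) shorter than k: classified FALSE")
  vapply(seq_along(read_sequence), function(i) {
    if (short[i]) return(FALSE)
    seq <- toupper(read_sequence[[i]])
    total <- nchar(seq) - index$k + 1L
    km <- canonical_kmers(seq, index$k)
    hits <- sum(km %in% index$kmer_set)
    hits / total >= index$min_hit_frac
  }, logical(1L))
}
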