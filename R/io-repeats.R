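#' Alu subfamily to family class
#'
#' Deterministic mapping of a RepeatMasker repeat name to one of the three
#' Alu age classes. Names beginning "Alu" but not "AluJ"/"AluS"/"AluY"
#' (e.g. "Alu", FLAM/FRAM-like entries printed as "Alu...") fall in the
#' generic bucket.
#'
#' @param subfamily character vector of repeat names (e.g. "AluSx", "AluY").
#' @return character vector over {AluJ, AluS, AluY, Alu-generic}.
#' @export
alu_family_class <- function(subfamily) {
  out <- rep("Alu-generic", length(subfamily))
  out[startsWith(subfamily, "AluJ")] <- "AluJ"
  out[startsWith(subfamily, "AluS")] <- "AluS"
  out[startsWith(subfamily, "AluY")] <- "AluY"
  out[!startsWith(subfamily, "Alu")] <- NA_character_
  out
}

#' Read Alu annotations from RepeatMasker output or BED6
#'
#' Retains only records whose repeat name starts with "Alu". BED input
#' (0-based half-open) is converted to internal 1-based inclusive
#' coordinates; RepeatMasker .out is already 1-based inclusive. A
#' RepeatMasker strand of "C" (complement) maps to "-".
#'
#' @param path input file.
#' @param dialect \code{"rm_out"} or \code{"bed6"}.
#' @return data.frame (class \code{"alu_annotation"}) with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{subfamily}, \code{family_class}.
#' @export
read_repeatmasker <- function(path, dialect = c("rm_out", "bed6")) {
  if (length(dialect) != 1L || !dialect %in% c("rm_out", "bed6"))
    stop("unknown repeat dialect: ", paste(dialect, collapse = "/"),
         " (expected 'rm_out' or 'bed6')")
  if (dialect == "rm_out") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[grepl("^[0-9]", lines)]  # drop the 3-line header
    if (!length(lines)) return(empty_alu_table())
    f <- strsplit(lines, "[[:space:]]+")
    rec <- data.frame(
      chrom = vapply(f, `[`, "", 5L),
      start = as.integer(vapply(f, `[`, "", 6L)),
      end = as.integer(vapply(f, `[`, "", 7L)),
      strand = ifelse(vapply(f, `[`, "", 9L) == "C", "-", "+"),
      subfamily = vapply(f, `[`, "", 10L),
      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "bed")  # converts to 1-based
    rec <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      subfamily = as.character(gr$name),
                      stringsAsFactors = FALSE)
  }
  rec <- rec[startsWith(rec$subfamily, "Alu"), , drop = FALSE]
  rec$family_class <- alu_family_class(rec$subfamily)
  rownames(rec) <- NULL
  structure(rec, class = c("alu_annotation", "data.frame"))
}

empty_alu_table <- function() {
  structure(data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       subfamily = character(), family_class = character(),
                       stringsAsFactors = FALSE),
            class = c("alu_annotation", "data.frame"))
}
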