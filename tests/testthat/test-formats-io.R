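test_that("genomic intervals are 1-based inclusive with positive lengths", {
  gi <- genomic_interval("chr8", 6624896, 6625037, "+")
  expect_equal(gi_length(gi), 142L)
  expect_error(genomic_interval("chr1", 0, 10), "start")
  expect_error(genomic_interval("chr1", 10, 5), "end")
  ## BED round-trip is identity
  b <- internal_to_bed(1000L, 1300L)
  expect_equal(b, list(bed_start = 999L, bed_end = 1300L))
  back <- bed_to_internal(b$bed_start, b$bed_end)
  expect_equal(back, list(start = 1000L, end = 1300L))
  ## touching intervals do not overlap
  expect_false(gi_overlaps(genomic_interval("chr1", 50, 99),
                           genomic_interval("chr1", 100, 400)))
  expect_true(gi_overlaps(genomic_interval("chr1", 100, 241),
                          genomic_interval("chr1", 90, 380)))
})

test_that("GTF parsing preserves coordinates and derives introns", {
  path <- tempfile(fileext = ".gtf")
  write_fixture_gtf(data.frame(
    chrom = "chr1", start = c(101L, 301L), end = c(200L, 400L),
    strand = "+", gene_id = "g1", transcript_id = "t1"), path)
  tx <- read_gtf(path)
  expect_equal(nrow(tx), 2L)
  introns <- transcript_introns(tx)
  expect_equal(introns$start, 201L)
  expect_equal(introns$end, 300L)
  ## empty file -> empty set
  empty <- tempfile(fileext = ".gtf")
  writeLines(character(), empty)
  expect_equal(nrow(read_gtf(empty)), 0L)
  ## malformed line names the line number
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(readLines(path), "chr1\tbroken line"), bad)
  expect_error(read_gtf(bad), "line 3")
})

test_that("interleaved transcripts separate and round-trip through GTF", {
  ## exons of two transcripts interleaved in file order
  rows <- data.frame(
    chrom = "chr2",
    start = c(500L, 100L, 900L, 300L), end = c(600L, 200L, 1000L, 400L),
    strand = c("-", "+", "-", "+"),
    gene_id = c("gB", "gA", "gB", "gA"),
    transcript_id = c("tB", "tA", "tB", "tA"))
  path <- tempfile(fileext = ".gtf")
  write_fixture_gtf(rows, path)
  tx <- read_gtf(path)
  ## reference: line-by-line parse, sorted per transcript
  ref <- rows[order(rows$transcript_id, rows$start), ]
  expect_equal(tx$start, ref$start)
  expect_equal(tx$transcript_id, ref$transcript_id)
  expect_equal(as.vector(tapply(tx$exon_rank, tx$transcript_id, max)),
               c(2L, 2L))
  out <- tempfile(fileext = ".gtf")
  write_gtf(tx, out)
  tx2 <- read_gtf(out)
  expect_equal(tx2[, names(tx2)], tx[, names(tx2)])
})

test_that("repeat readers convert coordinates and keep only Alu records", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t1300\tAluSx\t0\t-",
               "chr1\t2000\t2500\tL1PA2\t0\t+",
               "chr2\t10\t300\tAluY\t0\t+"), bed)
  a <- read_repeatmasker(bed, "bed6")
  expect_equal(nrow(a), 2L)
  expect_equal(a$start[1], 1000L)  # 0-based -> 1-based
  expect_equal(a$end[1], 1300L)
  expect_equal(a$strand[1], "-")
  expect_equal(a$family_class, c("AluS", "AluY"))
  ## RepeatMasker .out dialect: 5 repeats, 3 Alu
  rm <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query",
    "score  div. del. ins.  sequence  begin  end",
    "",
    "  463 11.4  0.0  0.0  chr1   1001  1304 (0) +  AluJb  SINE/Alu  1 304 (8) 1",
    "  300 20.0  0.0  0.0  chr1   5000  5999 (0) C  L1PA3  LINE/L1   1 999 (0) 2",
    "  410 09.1  0.0  0.0  chr1   8000  8290 (0) C  AluSx  SINE/Alu  1 290 (6) 3",
    "  120 25.0  0.0  0.0  chr2   100   400  (0) +  MIR    SINE/MIR  1 300 (0) 4",
    "  500 02.2  0.0  0.0  chr2   900   1190 (0) +  AluY   SINE/Alu  1 290 (6) 5"),
    rm)
  r <- read_repeatmasker(rm, "rm_out")
  expect_equal(nrow(r), 3L)
  expect_equal(r$subfamily, c("AluJb", "AluSx", "AluY"))
  expect_equal(r$strand, c("+", "-", "+"))
  expect_error(read_repeatmasker(bed, "bed12"), "dialect")
})

test_that("Alu family classes map deterministically from subfamily names", {
  expect_equal(alu_family_class(c("AluJb", "AluSx1", "AluYk2", "Alu",
                                  "AluFRAM")),
               c("AluJ", "AluS", "AluY", "Alu-generic", "Alu-generic"))
  expect_true(is.na(alu_family_class("L1PA2")))
})

test_that("SAM reading keeps unmapped mates and flags concordance", {
  rows <- data.frame(
    read_id = c("p1", "p1", "p2", "p2", "p3", "p3"),
    flag = c(99L, 147L,                 # proper pair
             73L, 133L,                 # mate unmapped
             65L, 129L),                # mapped pair, not proper
    chrom = c("chr1", "chr1", "chr1", "*", "chr1", "chr1"),
    pos = c(100L, 250L, 500L, 0L, 900L, 1200L),
    cigar = c("50M", "50M", "50M", "*", "20M100N30M", "50M"),
    seq = vapply(rep(50, 6), rand_seq, ""))
  path <- write_fixture_sam(rows, tempfile(fileext = ".sam"))
  sam <- read_sam(path)
  expect_equal(nrow(sam), 6L)
  expect_true(all(sam$is_concordant_pair[sam$read_id == "p1"]))
  expect_false(any(sam$is_concordant_pair[sam$read_id != "p1"]))
  un <- sam[!sam$mapped, ]
  expect_equal(nrow(un), 1L)
  expect_equal(nchar(un$sequence), 50L)
  ## spliced record: reference end includes the N gap
  spl <- sam[sam$read_id == "p3" & sam$start == 900L, ]
  expect_equal(spl$end, 900L + 20L + 100L + 30L - 1L)
  ## CIGAR/SEQ mismatch is rejected with a warning
  bad <- rows[1, ]; bad$cigar <- "60M"
  path2 <- write_fixture_sam(rbind(rows, bad), tempfile(fileext = ".sam"))
  expect_warning(sam2 <- read_sam(path2), "mismatch")
  expect_equal(nrow(sam2), 6L)
  ## round-trip through write_sam
  out <- tempfile(fileext = ".sam")
  write_sam(sam, out, c(chr1 = 100000L))
  sam3 <- read_sam(out)
  expect_equal(sam3$sequence, sam$sequence)
  expect_equal(sam3$start, sam$start)
  expect_equal(sam3$is_concordant_pair, sam$is_concordant_pair)
})

test_that("count matrix TSV round-trips", {
  m <- matrix(c(0, 12, 5, 30), 2, 2,
              dimnames = list(c("i1", "i2"), c("s1", "s2")))
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  expect_equal(read_count_matrix(path), m)
})
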