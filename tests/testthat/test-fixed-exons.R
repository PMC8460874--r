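make_tx <- function(starts, ends, tid = "t1", gid = "g1", strand = "+",
                    chrom = "chr1") {
  transcript_models(data.frame(
    transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
    start = as.integer(starts), end = as.integer(ends)))
}

make_alus <- function(starts, ends, strand = "-", chrom = "chr1",
                      subfamily = "AluSx") {
  if (!length(starts)) {
    chrom <- character(); strand <- character(); subfamily <- character()
  }
  structure(data.frame(chrom = chrom, start = as.integer(starts),
                       end = as.integer(ends), strand = strand,
                       subfamily = subfamily,
                       family_class = alu_family_class(subfamily),
                       stringsAsFactors = FALSE),
            class = c("alu_annotation", "data.frame"))
}

test_that("exon/Alu overlap pairing matches a brute-force all-pairs check", {
  tx <- rbind(make_tx(c(100, 500, 900), c(241, 600, 1000)),
              make_tx(c(2000, 2500, 3000), c(2100, 2600, 3100), tid = "t2",
                      gid = "g2"))
  tx <- transcript_models(tx)
  alus <- make_alus(c(90, 2550, 5000, 601), c(380, 2620, 5300, 899))
  pairs <- find_alu_overlapping_exons(tx, alus)
  ## brute force on inclusive coordinates
  expected <- 0L
  for (i in seq_len(nrow(tx))) for (j in seq_len(nrow(alus)))
    if (tx$start[i] <= alus$end[j] && alus$start[j] <= tx$end[i])
      expected <- expected + 1L
  expect_equal(nrow(pairs), expected)
  expect_equal(expected, 2L)  # chr1:100-241 x 90-380; chr1:2500-2600 x 2550-2620
  ## touching but not overlapping
  expect_equal(nrow(find_alu_overlapping_exons(
    make_tx(50, 99), make_alus(100, 400))), 0L)
  expect_equal(nrow(find_alu_overlapping_exons(tx, make_alus(integer(0),
                                                             integer(0)))),
               0L)
})

test_that("candidate filters enforce internal/antisense/length rules", {
  ## a 142 bp internal exon on a + transcript over a - Alu is retained in
  ## frame +1
  tx <- make_tx(c(6624000, 6624896, 6626000), c(6624200, 6625037, 6626100),
                chrom = "chr8")
  alus <- make_alus(6624800, 6625100, chrom = "chr8")
  calls <- filter_candidates(find_alu_overlapping_exons(tx, alus))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$length, 142L)
  expect_equal(calls$frame, 1L)
  ## terminal exon, otherwise qualifying -> rejected
  tx_term <- make_tx(c(6624896, 6626000), c(6625037, 6626100),
                     chrom = "chr8")
  expect_equal(nrow(filter_candidates(
    find_alu_overlapping_exons(tx_term, alus))), 0L)
  ## sense-orientation Alu -> rejected
  alus_sense <- make_alus(6624800, 6625100, strand = "+", chrom = "chr8")
  expect_equal(nrow(filter_candidates(
    find_alu_overlapping_exons(tx, alus_sense))), 0L)
  ## strict bounds: a 40 bp internal antisense exon is rejected, 41 kept
  tx40 <- make_tx(c(100, 500, 900), c(200, 539, 1000))
  alus40 <- make_alus(450, 700)
  expect_equal(nrow(filter_candidates(
    find_alu_overlapping_exons(tx40, alus40))), 0L)
  tx41 <- make_tx(c(100, 500, 900), c(200, 540, 1000))
  expect_equal(nrow(filter_candidates(
    find_alu_overlapping_exons(tx41, alus40))), 1L)
  ## 400 bp rejected under strict upper bound
  tx400 <- make_tx(c(100, 1000, 2000), c(200, 1399, 2100))
  alus400 <- make_alus(950, 1450)
  expect_equal(nrow(filter_candidates(
    find_alu_overlapping_exons(tx400, alus400))), 0L)
  ## unstranded transcript dropped and counted
  txu <- make_tx(c(100, 500, 900), c(200, 600, 1000), strand = "*")
  res <- filter_candidates(find_alu_overlapping_exons(txu, make_alus(450,
                                                                     700)))
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "skipped_unstranded"), 1L)
})

test_that("cross-sample merge groups by exon and keeps loci distinct", {
  tx <- make_tx(c(100, 500, 900), c(200, 640, 1000))
  alus <- make_alus(450, 740)
  one <- filter_candidates(find_alu_overlapping_exons(tx, alus))
  ## same exon in 3 samples -> one row supported by 3
  merged <- merge_across_samples(list(a = one, b = one, c = one))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_samples, 3L)
  expect_equal(merged$samples, "a,b,c")
  ## two different exons over one Alu -> 2 rows, 1 locus
  tx2 <- make_tx(c(100, 520, 900), c(200, 660, 1000))
  two <- filter_candidates(find_alu_overlapping_exons(tx2, alus))
  merged2 <- merge_across_samples(list(a = one, b = two))
  expect_equal(nrow(merged2), 2L)
  expect_equal(length(unique(merged2$locus_id)), 1L)
  ## known iff exact coordinate identity with an annotated exon
  ann <- make_tx(c(100, 500, 900), c(200, 640, 1000), tid = "ann1")
  merged3 <- merge_across_samples(list(a = one, b = two), ann)
  expect_equal(merged3$known[merged3$exon_id == "chr1:500-640"], TRUE)
  expect_equal(merged3$known[merged3$exon_id == "chr1:520-660"], FALSE)
})

test_that("merge is order-independent and idempotent over samples", {
  set.seed(42)
  mk <- function(shift) {
    tx <- make_tx(c(100, 500 + shift, 900), c(200, 640 + shift, 1000))
    filter_candidates(find_alu_overlapping_exons(tx, make_alus(450, 800)))
  }
  calls <- list(s1 = mk(0), s2 = mk(20), s3 = mk(0), s4 = mk(40))
  m1 <- merge_across_samples(calls)
  m2 <- merge_across_samples(rev(calls))
  expect_equal(m1, m2)
  ## brute-force grouping oracle: distinct exon keys
  all_calls <- do.call(rbind, Map(function(d, s) {
    d$sample <- s; d
  }, calls, names(calls)))
  expect_equal(nrow(m1),
               length(unique(paste(all_calls$chrom, all_calls$start,
                                   all_calls$end))))
})

test_that("intron-support rescue requires both flanking junctions", {
  tx <- make_tx(c(100, 500, 900), c(200, 640, 1000))
  one <- filter_candidates(find_alu_overlapping_exons(tx, make_alus(450,
                                                                    740)))
  merged <- merge_across_samples(list(a = one))
  ## iLeft = chr1:201-499, iRight = chr1:641-899
  jc <- data.frame(
    chrom = "chr1",
    start = c(201L, 641L, 201L, 201L, 641L),
    end = c(499L, 899L, 499L, 499L, 899L),
    sample = c("x", "x", "y", "z", "z"),
    count = c(5L, 5L, 5L, 3L, 3L))
  resc <- rescue_by_intron_support(merged, jc)
  ## x: both 5 -> added; y: one junction only; z: both 3 -> added
  expect_equal(resc$intron_support_samples, "x,z")
  expect_equal(resc$n_intron_samples, 2L)
  resc2 <- rescue_by_intron_support(merged, jc, min_reads = 4L)
  expect_equal(resc2$intron_support_samples, "x")
  ## oracle: direct lookup over all samples
  expect_equal(resc$n_intron_samples,
               sum(vapply(c("x", "y", "z"), function(s) {
                 l <- sum(jc$count[jc$start == 201 & jc$sample == s])
                 r <- sum(jc$count[jc$start == 641 & jc$sample == s])
                 l >= 1 && r >= 1
               }, logical(1))))
})

test_that("emitted calls satisfy the three filter criteria by construction", {
  set.seed(7)
  sim <- shared_sim()
  pairs <- find_alu_overlapping_exons(sim$ls$transcripts, sim$ls$alus)
  calls <- filter_candidates(pairs)
  expect_gt(nrow(calls), 0L)
  expect_true(all(calls$length > 40 & calls$length < 400))
  expect_true(all(calls$alu_strand == flip_strand(calls$tx_strand)))
  expect_true(all(calls$frame %in% 0:2))
  ## frame classes partition the calls
  expect_equal(sum(table(calls$frame)), nrow(calls))
})
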