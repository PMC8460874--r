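test_that("junction counting does exact-boundary CIGAR arithmetic", {
  rows <- data.frame(
    read_id = c("r1", "r2", "r3"),
    flag = 0L, chrom = "chr1",
    pos = c(1001L, 1001L, 2000L),
    cigar = c("50M100N50M", "100M", "30M70N30M40N20M"),
    seq = vapply(c(100, 100, 80), rand_seq, ""))
  sam <- read_sam(write_fixture_sam(rows, tempfile(fileext = ".sam")))
  jc <- count_junction_reads(sam, "s1")
  ## r1: 50M from 1001 ends at 1050, intron 1051-1150
  expect_true(any(jc$start == 1051 & jc$end == 1150 & jc$count == 1))
  ## r3 contributes two introns: 2030-2099 and 2130-2169
  expect_true(any(jc$start == 2030 & jc$end == 2099))
  expect_true(any(jc$start == 2130 & jc$end == 2169))
  ## unspliced r2 contributes nothing
  expect_equal(sum(jc$count), 3L)
})

test_that("junction counts equal brute-force per-read enumeration", {
  set.seed(31)
  introns <- data.frame(chrom = "chr1",
                        start = c(1051L, 2030L, 3000L),
                        end = c(1150L, 2099L, 3499L))
  rows <- do.call(rbind, lapply(1:20, function(i) {
    k <- sample(3, 1)
    left <- sample(20:60, 1)
    right <- sample(20:60, 1)
    pos <- introns$start[k] - left
    data.frame(read_id = paste0("r", i), flag = 0L, chrom = "chr1",
               pos = pos,
               cigar = sprintf("%dM%dN%dM", left,
                               introns$end[k] - introns$start[k] + 1L,
                               right),
               seq = rand_seq(left + right))
  }))
  sam <- read_sam(write_fixture_sam(rows, tempfile(fileext = ".sam")))
  jc <- count_junction_reads(sam, "s1", introns = introns)
  ## oracle: per-read gap enumeration from the construction itself
  expected <- vapply(seq_len(nrow(introns)), function(k) {
    sum(vapply(seq_len(nrow(rows)), function(i) {
      gapw <- introns$end[k] - introns$start[k] + 1L
      grepl(sprintf("%dN", gapw), rows$cigar[i]) &&
        rows$pos[i] + as.integer(sub("M.*", "", rows$cigar[i])) ==
          introns$start[k]
    }, logical(1)))
  }, numeric(1))
  expect_equal(jc$count, as.integer(expected))
})

test_that("simple cassette events require identical flanking exons", {
  base <- data.frame(
    transcript_id = "inc", gene_id = "g1", chrom = "chr1", strand = "+",
    start = c(100L, 500L, 900L), end = c(200L, 600L, 1000L))
  skip <- data.frame(
    transcript_id = "skp", gene_id = "g1", chrom = "chr1", strand = "+",
    start = c(100L, 900L), end = c(200L, 1000L))
  tx <- transcript_models(rbind(base, skip))
  ev <- detect_exon_skipping(tx)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$exon_start, 500L)
  expect_equal(c(ev$iLeft_start, ev$iLeft_end), c(201L, 499L))
  expect_equal(c(ev$iRight_start, ev$iRight_end), c(601L, 899L))
  ## iSpan spans both inclusion introns and the exon
  expect_equal(c(ev$iSpan_start, ev$iSpan_end), c(201L, 899L))
  ## flanking exon change (A's 3' end moves) -> not simple, no event
  skip2 <- skip; skip2$end[1] <- 250L; skip2$transcript_id <- "skp2"
  expect_equal(nrow(detect_exon_skipping(
    transcript_models(rbind(base, skip2)))), 0L)
  ## two inclusion contexts for one exon -> 2 patterns, 1 exon
  inc2 <- base; inc2$transcript_id <- "inc2"; inc2$end[1] <- 180L
  skip3 <- skip; skip3$transcript_id <- "skp3"; skip3$end[1] <- 180L
  ev2 <- detect_exon_skipping(transcript_models(rbind(base, skip, inc2,
                                                      skip3)))
  expect_equal(nrow(ev2), 2L)
  expect_equal(length(unique(paste(ev2$exon_start, ev2$exon_end))), 1L)
})

test_that("skip detection equals exhaustive isoform-pair enumeration", {
  set.seed(13)
  for (rep in 1:5) {
    ## random gene with <= 6 isoforms over a 6-exon scaffold
    starts <- cumsum(c(100, rep(500, 5)))
    ends <- starts + 99L
    isos <- lapply(seq_len(sample(3:6, 1)), function(i) {
      keep <- sort(unique(c(1L, 6L, sample(2:5, sample(2:4, 1)))))
      data.frame(transcript_id = paste0("t", i), gene_id = "g",
                 chrom = "chr1", strand = "+",
                 start = starts[keep], end = ends[keep])
    })
    tx <- transcript_models(do.call(rbind, isos))
    ev <- detect_exon_skipping(tx)
    got <- paste("g", ev$chrom, paste0(ev$exon_start, "-", ev$exon_end),
                 ev$iSpan_start, ev$iSpan_end)
    expect_setequal(got, oracle_skip_events(tx))
  }
})

test_that("PSI follows the printed formula with the low-read correction", {
  expect_equal(compute_psi(10, 10, 10), 0.5)
  expect_equal(compute_psi(0, 0, 12), 0)
  expect_equal(compute_psi(7, 9, 4), 16 / 24)
  ## below the default 10-read total -> undefined
  expect_true(is.na(compute_psi(3, 3, 3)))
  expect_true(is.na(compute_psi(0, 0, 0, min_total = 0)))
  expect_error(compute_psi(-1, 0, 0), "non-negative")
})

test_that("PSI bounds, symmetry and edge identities hold on a random grid", {
  set.seed(99)
  l <- sample(0:60, 300, TRUE); r <- sample(0:60, 300, TRUE)
  s <- sample(0:60, 300, TRUE)
  psi <- compute_psi(l, r, s, min_total = 1)
  ok <- !is.na(psi)
  expect_true(all(psi[ok] >= 0 & psi[ok] <= 1))
  ## symmetric in L and R
  expect_equal(psi, compute_psi(r, l, s, min_total = 1))
  ## PSI = 1 iff S = 0 (and L+R > 0); PSI = 0 iff L = R = 0, S > 0
  expect_equal(psi[ok] == 1, (s == 0 & l + r > 0)[ok])
  expect_equal(psi[ok] == 0, (l == 0 & r == 0 & s > 0)[ok])
})

test_that("PSI categories use the adopted boundaries", {
  expect_equal(categorize_psi(c(0.10, 0.65, 0.355, 0.349999, 0.3500,
                                0.6499, NA)),
               c("minor", "major", "equal", "minor", "equal", "equal", NA))
  ## categories partition defined values on a random grid
  set.seed(5)
  x <- runif(500)
  cat3 <- categorize_psi(x)
  expect_equal(sum(table(cat3)), 500L)
  expect_equal(unname(table(cat3)["minor"]), sum(x < 0.35))
  expect_equal(unname(table(cat3)["major"]), sum(x >= 0.65))
})

test_that("summarize_psi joins counts and categorizes the cohort median", {
  events <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       exon_start = 500L, exon_end = 600L,
                       iLeft_start = 201L, iLeft_end = 499L,
                       iRight_start = 601L, iRight_end = 899L,
                       iSpan_start = 201L, iSpan_end = 899L)
  jc <- rbind(
    data.frame(chrom = "chr1", start = c(201L, 601L, 201L),
               end = c(499L, 899L, 899L), sample = "s1",
               count = c(10L, 10L, 10L)),
    data.frame(chrom = "chr1", start = c(201L, 601L, 201L),
               end = c(499L, 899L, 899L), sample = "s2",
               count = c(30L, 30L, 0L)))
  res <- summarize_psi(events, jc)
  expect_equal(res$psi.s1, 0.5)
  expect_equal(res$psi.s2, 1)
  expect_equal(res$summary_psi, 0.75)
  expect_equal(res$category, "major")
})
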