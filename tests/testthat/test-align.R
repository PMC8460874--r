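test_that("exact chimeric reads align with full coverage and identity", {
  set.seed(4)
  exon <- rand_seq(120)
  alu <- alu_consensus_seq()
  q <- paste0(substr(exon, 81, 120), substr(alu, 1, 60))
  r <- spliced_align(q, c(exon = exon, Alu = alu))
  expect_equal(r$query_coverage, 1)
  expect_equal(r$identity, 1)
  expect_equal(r$alu_bases, 60L)
  expect_equal(r$orientation, "+")
  ## reverse-complemented query reaches the same alignment
  r2 <- spliced_align(revcomp(q), c(exon = exon, Alu = alu))
  expect_equal(r2$score, r$score)
  expect_equal(r2$alu_bases, 60L)
  expect_equal(r2$orientation, "-")
  ## junction into the middle of the Alu: the splice move is free
  q3 <- paste0(substr(exon, 81, 120), substr(alu, 101, 160))
  r3 <- spliced_align(q3, c(exon = exon, Alu = alu))
  expect_equal(r3$query_coverage, 1)
  expect_equal(r3$identity, 1)
  ## random query: coverage below any signal threshold
  r4 <- spliced_align(rand_seq(100), c(exon = exon, Alu = alu))
  expect_lt(r4$query_coverage, 0.8)
  expect_error(spliced_align("", c(exon = exon)), "empty")
})

test_that("substituted chimeras keep expected identity and Alu bases", {
  set.seed(15)
  exon <- rand_seq(150)
  alu <- alu_consensus_seq()
  q <- paste0(substr(exon, 111, 150), substr(alu, 31, 90))
  ch <- strsplit(q, "")[[1]]
  idx <- seq(5, 95, by = 10)  # 10 substitutions -> 10% divergence
  for (i in idx) ch[i] <- chartr("ACGT", "CAGT", ch[i])
  flip <- sum(strsplit(q, "")[[1]][idx] != ch[idx])
  q_mut <- paste(ch, collapse = "")
  r <- spliced_align(q_mut, c(exon = exon, Alu = alu))
  expect_gte(r$query_coverage, 0.9)
  expect_equal(r$identity, (100 - flip) / 100, tolerance = 0.03)
  expect_gte(r$alu_bases, 50)
})

test_that("plain local alignment agrees with an independent aligner", {
  set.seed(23)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    target <- rand_seq(300)
    ## embed a mutated copy of a target slice in the query
    s <- sample(200, 1)
    q <- substr(target, s, s + 79)
    q <- paste0(rand_seq(5), q, rand_seq(5))
    r <- local_align(q, target)
    ## Biostrings: gap of length L costs 1.5 + 0.5 L == our 2 + 0.5 (L - 1)
    bs <- Biostrings::pairwiseAlignment(q, target, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 1.5,
                                        gapExtension = 0.5)
    expect_equal(r$score, Biostrings::score(bs))
  }
})

test_that("spliced alignment matches the scalar full-DP oracle", {
  set.seed(77)
  for (i in 1:12) {
    segs <- c(exon = rand_seq(sample(40:80, 1)),
              Alu = rand_seq(sample(60:120, 1)),
              exon2 = rand_seq(sample(40:80, 1)))
    target <- paste(segs, collapse = "")
    ## half the queries are planted chimeras, half random
    q <- if (i %% 2 == 0) rand_seq(sample(20:40, 1)) else {
      a <- sample(nchar(segs[1]) - 14, 1)
      b <- sample(nchar(segs[2]) - 14, 1)
      paste0(substr(segs[1], a, a + 14),
             substr(segs[2], b, b + 14))
    }
    dp <- aluex:::align_core(q, target, cumsum(nchar(segs)))
    got <- max(dp$H)
    expect_equal(got, oracle_align_score(q, target, cumsum(nchar(segs))),
                 info = paste("instance", i))
    ## traceback summary is internally consistent
    res <- spliced_align(q, segs)
    expect_lte(res$matches, res$aligned_cols)
    expect_gte(res$identity, 0)
    expect_lte(res$identity, 1)
    expect_lte(res$query_coverage, 1)
  }
})

test_that("signal test applies the printed cutoffs at their boundaries", {
  mk <- function(cov, id, alu) list(query_coverage = cov, identity = id,
                                    alu_bases = alu)
  expect_true(signal_test(mk(0.80, 0.81, 10)))   # all three boundaries pass
  expect_false(signal_test(mk(0.80, 0.80, 50)))  # identity strictly > 0.80
  expect_false(signal_test(mk(0.95, 0.99, 9)))   # >= 10 Alu bases
  expect_false(signal_test(mk(0.79, 0.99, 50)))  # coverage >= 0.80
  ## threshold monotonicity: improving any metric never flips pass -> fail
  set.seed(6)
  for (i in 1:50) {
    a <- mk(runif(1), runif(1), sample(0:40, 1))
    b <- mk(min(1, a$query_coverage + 0.1), min(1, a$identity + 0.1),
            a$alu_bases + 5)
    expect_true(signal_test(b) >= signal_test(a))
  }
})

test_that("shadow test flags local genomic copies at 80%/93% inclusive", {
  set.seed(44)
  chrom <- rand_seq(3000)
  genome <- c(chr1 = chrom)
  anchor <- list(chrom = "chr1", start = 1001L, end = 1200L)
  gene_exons <- data.frame(chrom = "chr1",
                           start = c(401L, 1001L, 2001L),
                           end = c(600L, 1200L, 2200L),
                           gene_id = "g1")
  ## query copied from the intron right of the anchor exon -> unspliced hit
  q_intron <- substr(chrom, 1250, 1349)
  expect_true(shadow_test(q_intron, anchor, gene_exons, genome))
  ## novel chimera absent from the locus -> no shadow
  expect_false(shadow_test(rand_seq(100), anchor, gene_exons, genome))
  ## exactly 93% identity at full coverage passes (inclusive bound)
  ch <- strsplit(q_intron, "")[[1]]
  pos <- seq(8, 98, by = 15)[1:7]
  for (i in pos) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  q93 <- paste(ch, collapse = "")
  expect_true(shadow_test(q93, anchor, gene_exons, genome))
  ## 10 substitutions: best local window stays below 93% -> not a shadow
  ch2 <- strsplit(q_intron, "")[[1]]
  for (i in seq(5, 95, by = 10)) ch2[i] <- setdiff(c("A", "C", "G", "T"),
                                                   ch2[i])[1]
  expect_false(shadow_test(paste(ch2, collapse = ""), anchor, gene_exons,
                           genome))
  ## reverse-complement of the query is caught too
  expect_true(shadow_test(revcomp(q_intron), anchor, gene_exons, genome))
})
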