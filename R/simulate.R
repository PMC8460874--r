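#' Simulation configuration
#'
#' Defines the study conditions for the synthetic locus sets: toy genes with
#' intronic Alu copies mutated from the consensus, planted fixed
#' exonizations (an antisense intronic Alu recruited as a 120-180 bp
#' internal exon), planted non-reference insertions (an Alu-derived novel
#' exon present in the mRNA but absent from the genome), and paired-end
#' reads emitted directly as alignment records with known origins.
#'
#' @param seed RNG seed; fully determines the output.
#' @param n_genes number of genes (one per toy chromosome).
#' @param exons_per_gene integer range (min, max).
#' @param exon_len,intron_len bp ranges for exon and intron lengths; the
#'   intron minimum must leave room for an embedded Alu copy plus flanks.
#' @param n_fixed_exonizations genes carrying an antisense intronic Alu and
#'   an extra isoform that exonizes it.
#' @param n_novel_insertions genes carrying a novel (non-reference) Alu exon
#'   in their transcripts.
#' @param n_decoy_alu_genes genes with an intronic Alu copy but no event
#'   (pure shadow sources). Remaining genes are clean.
#' @param alu_divergence per-base substitution rate of genomic Alu copies
#'   relative to the consensus (old, fixed elements).
#' @param novel_divergence substitution rate of planted non-reference
#'   inserts: polymorphic insertions are young AluY-like copies and sit much
#'   closer to the consensus than fixed intronic elements.
#' @param read_length,fragment_mean,fragment_sd,coverage paired-end read
#'   model; coverage is fold-coverage per isoform.
#' @param error_rate per-base sequencing error rate.
#' @param fraction_premrna share of fragments drawn from unspliced pre-mRNA.
#' @param min_signal_pairs guaranteed junction-spanning pairs per planted
#'   insertion (anchor in the adjacent exon, mate across the novel
#'   exon junction).
#' @param unmappable_alu_bases reads carrying at least this many bases of
#'   novel-insert or repeat-copy sequence are emitted unmapped, emulating
#'   aligner behavior on multi-mapping/unplaceable Alu reads.
#' @param p_flag_noise probability of clearing the proper-pair flag on a
#'   concordant pair (mapping noise; default 0).
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       exons_per_gene = c(4L, 6L),
                       exon_len = c(120L, 250L),
                       intron_len = c(550L, 900L),
                       n_fixed_exonizations = 5L,
                       n_novel_insertions = 5L,
                       n_decoy_alu_genes = 3L,
                       alu_divergence = 0.08,
                       novel_divergence = 0.02,
                       read_length = 100L,
                       fragment_mean = 250L, fragment_sd = 25L,
                       coverage = 8,
                       error_rate = 0.002,
                       fraction_premrna = 0.15,
                       min_signal_pairs = 5L,
                       unmappable_alu_bases = 20L,
                       p_flag_noise = 0) {
  cfg <- as.list(environment())
  rates <- c(alu_divergence, novel_divergence, error_rate,
             fraction_premrna, p_flag_noise)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(c(exon_len, intron_len, read_length, fragment_mean) <= 0))
    stop("lengths must be positive")
  if (n_fixed_exonizations + n_novel_insertions + n_decoy_alu_genes >
      n_genes)
    stop("event genes exceed n_genes")
  structure(cfg, class = c("sim_config", "list"))
}

#' Bundled synthetic Alu consensus sequence
#' @return character scalar (~300 bp AluY-like synthetic consensus).
#' @export
alu_consensus_seq <- function() {
  read_fasta(system.file("extdata", "alu_consensus_synthetic.fa",
                         package = "aluex"))[[1L]]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic locus set
#'
#' One gene per toy chromosome on the + strand, flanked by 1 kb of
#' intergenic sequence. Event genes are assigned deterministically: the
#' first \code{n_novel_insertions} genes carry a planted insertion, the next
#' \code{n_fixed_exonizations} a fixed exonization, the next
#' \code{n_decoy_alu_genes} a decoy intronic Alu copy; the rest are clean.
#'
#' @param config a [sim_config()].
#' @param alu_consensus consensus sequence (default: the bundled synthetic
#'   consensus).
#' @return list of class \code{"locus_set"}: \code{genome} (named character
#'   vector), \code{transcripts} (assembled-transcript exon table, including
#'   Alu-exon isoforms of fixed-exonization genes), \code{annotation}
#'   (reference exons: the plain isoforms only), \code{alus} (planted
#'   genomic Alu copies), \code{novel} (per-gene description of planted
#'   non-reference inserts), \code{truth} (event truth table) and
#'   \code{config}.
#' @export
generate_locus_set <- function(config = sim_config(),
                               alu_consensus = alu_consensus_seq()) {
  set.seed(config$seed)
  alu_len <- nchar(alu_consensus)
  if (config$intron_len[1L] < alu_len + 120L)
    stop("intron_len minimum too small to host an Alu copy with flanks")
  pad <- 1000L
  n <- config$n_genes
  roles <- rep("clean", n)
  if (config$n_novel_insertions > 0)
    roles[seq_len(config$n_novel_insertions)] <- "novel"
  if (config$n_fixed_exonizations > 0)
    roles[config$n_novel_insertions + seq_len(config$n_fixed_exonizations)] <-
      "fixed"
  if (config$n_decoy_alu_genes > 0)
    roles[config$n_novel_insertions + config$n_fixed_exonizations +
            seq_len(config$n_decoy_alu_genes)] <- "decoy"
  genome <- character(); tx <- list(); ann <- list(); alus <- list()
  novel <- list(); truth <- list()
  for (g in seq_len(n)) {
    gid <- sprintf("gene%02d", g)
    chrom <- sprintf("chr%d", g)
    n_ex <- sample(config$exons_per_gene[1L]:config$exons_per_gene[2L], 1L)
    ex_len <- sample(config$exon_len[1L]:config$exon_len[2L], n_ex, TRUE)
    in_len <- sample(config$intron_len[1L]:config$intron_len[2L],
                     n_ex - 1L, TRUE)
    role <- roles[g]
    host_intron <- if (role %in% c("fixed", "decoy", "novel"))
      sample(seq_len(n_ex - 1L), 1L) else NA_integer_
    ## build the chromosome and exon coordinates
    pieces <- rand_dna(pad)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- pad
    alu_span <- NULL
    for (e in seq_len(n_ex)) {
      starts[e] <- pos + 1L
      pieces <- paste0(pieces, rand_dna(ex_len[e]))
      pos <- pos + ex_len[e]
      ends[e] <- pos
      if (e < n_ex) {
        ilen <- in_len[e]
        if (!is.na(host_intron) && e == host_intron &&
            role %in% c("fixed", "decoy")) {
          copy <- mutate_seq(alu_consensus, config$alu_divergence)
          copy <- revcomp(copy)  # antisense to the + strand gene
          lbuf <- (ilen - alu_len) %/% 2L
          rbuf <- ilen - alu_len - lbuf
          pieces <- paste0(pieces, rand_dna(lbuf), copy, rand_dna(rbuf))
          alu_span <- c(pos + lbuf + 1L, pos + lbuf + alu_len)
          alus[[length(alus) + 1L]] <- data.frame(
            chrom = chrom, start = alu_span[1L], end = alu_span[2L],
            strand = "-", subfamily = "AluY", family_class = "AluY",
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            type = "alu_copy", gene_id = gid, chrom = chrom,
            start = alu_span[1L], end = alu_span[2L],
            stringsAsFactors = FALSE)
        } else {
          pieces <- paste0(pieces, rand_dna(ilen))
        }
        pos <- pos + ilen
      }
    }
    pieces <- paste0(pieces, rand_dna(pad))
    genome[[chrom]] <- pieces
    ref <- data.frame(transcript_id = paste0("tx", g, ".1"), gene_id = gid,
                      chrom = chrom, strand = "+", start = starts,
                      end = ends, stringsAsFactors = FALSE)
    ann[[length(ann) + 1L]] <- ref
    tx[[length(tx) + 1L]] <- ref
    if (role == "fixed") {
      ## exonize a 120-180 bp window inside the intronic Alu copy
      w <- sample(120:180, 1L)
      off <- sample(0:(alu_len - w), 1L)
      ex_s <- alu_span[1L] + off; ex_e <- ex_s + w - 1L
      iso <- rbind(ref, data.frame(
        transcript_id = paste0("tx", g, ".1"), gene_id = gid, chrom = chrom,
        strand = "+", start = ex_s, end = ex_e, stringsAsFactors = FALSE))
      iso$transcript_id <- paste0("tx", g, ".2")
      tx[[length(tx) + 1L]] <- iso
      truth[[length(truth) + 1L]] <- data.frame(
        type = "fixed_exon", gene_id = gid, chrom = chrom,
        start = ex_s, end = ex_e, stringsAsFactors = FALSE)
    }
    if (role == "novel") {
      ## an Alu-derived novel exon present in mRNA only
      w <- sample(120:180, 1L)
      off <- sample(0:(alu_len - w), 1L)
      insert_seq <- substr(mutate_seq(alu_consensus,
                                      config$novel_divergence),
                           off + 1L, off + w)
      after_exon <- host_intron  # novel exon spliced after this exon
      ipoint <- ends[after_exon] + (starts[after_exon + 1L] -
                                      ends[after_exon]) %/% 2L
      novel[[gid]] <- list(gene_id = gid, chrom = chrom,
                           after_exon = after_exon,
                           insertion_point = ipoint,
                           sequence = insert_seq)
      truth[[length(truth) + 1L]] <- data.frame(
        type = "novel_insertion", gene_id = gid, chrom = chrom,
        start = ipoint, end = ipoint, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    genome = genome,
    transcripts = transcript_models(do.call(rbind, tx)),
    annotation = transcript_models(do.call(rbind, ann)),
    alus = if (length(alus)) structure(do.call(rbind, alus),
                                       class = c("alu_annotation",
                                                 "data.frame"))
           else empty_alu_table(),
    novel = novel,
    truth = do.call(rbind, truth),
    config = config,
    alu_consensus = alu_consensus), class = "locus_set")
}

#' Write a locus set to disk (FASTA/GTF/BED/TSV)
#' @param ls a [generate_locus_set()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_locus_set <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.gtf"),
             annotation = file.path(dir, "annotation.gtf"),
             repeats = file.path(dir, "repeats.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(ls$genome, paths[["genome"]])
  write_gtf(ls$transcripts, paths[["transcripts"]])
  write_gtf(ls$annotation, paths[["annotation"]])
  bed <- internal_to_bed(ls$alus$start, ls$alus$end)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ls$alus$chrom, bed$bed_start,
                     bed$bed_end, ls$alus$subfamily, ls$alus$strand),
             paths[["repeats"]])
  utils::write.table(ls$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
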